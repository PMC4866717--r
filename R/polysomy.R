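#' Configuration for the aneuploidy/contamination screen
#'
#' @param fit_gate An aberrant state is accepted only if the mean absolute
#'   deviation of its fit is below this fraction of the single-peak
#'   (diploid) fit deviation; default 0.30. Multiple peaks always fit at
#'   least as well as one, so this gate controls specificity.
#' @param min_fraction Minimum estimated fraction of aberrant or
#'   contaminating cells; calls below it are rejected (clean side-peak
#'   separation cannot be guaranteed). Default 0.20.
#' @param include_aa_peak Include the AA (BAF near 1) peak region in the
#'   fit; off by default, the central heterozygous peaks are sufficient.
#' @param n_bins Histogram bins over `[0, 1]`, default 100.
#' @param smoothing_window Moving-average window in bins, default 5.
#' @param min_sites Minimum usable BAF values per chromosome; below it the
#'   chromosome is reported as FAIL. Default 100.
#' @param fail_dev Absolute cap on the diploid-fit deviation (in scaled
#'   units); when no aberrant model is accepted and the diploid fit is
#'   worse than this, the state is FAIL. Default 0.3.
#' @param min_central_peak Minimum fitted central-peak magnitude (in
#'   scaled units) for the contamination model to be considered: a
#'   contaminated sample always shows a central heterozygous peak, so a
#'   three-side-peak fit without one is not a contamination pattern.
#'   Default 0.1.
#' @param contamination_min_chroms Fraction of chromosomes that must carry
#'   mutually consistent side peaks before the sample-level verdict is
#'   contamination rather than trisomy; default 0.5.
#' @param contamination_delta_spread Maximum spread of the per-chromosome
#'   peak shifts considered "the same pattern"; default 0.05.
#' @return A list of class `"polysomy_config"`.
#' @export
polysomy_config <- function(fit_gate = 0.30, min_fraction = 0.20,
                            include_aa_peak = FALSE, n_bins = 100,
                            smoothing_window = 5, min_sites = 100,
                            fail_dev = 0.3, min_central_peak = 0.1,
                            contamination_min_chroms = 0.5,
                            contamination_delta_spread = 0.05) {
  stopifnot(fit_gate > 0, fit_gate < 1,
            min_fraction >= 0, min_fraction < 0.5)
  structure(list(fit_gate = fit_gate, min_fraction = min_fraction,
                 include_aa_peak = include_aa_peak, n_bins = n_bins,
                 smoothing_window = smoothing_window, min_sites = min_sites,
                 fail_dev = fail_dev, min_central_peak = min_central_peak,
                 contamination_min_chroms = contamination_min_chroms,
                 contamination_delta_spread = contamination_delta_spread),
            class = "polysomy_config")
}

#' Build a smoothed, peak-normalized BAF distribution
#'
#' Histograms the BAF values of one chromosome, smooths the counts with a
#' moving average, finds local minima to delimit peaks, and rescales the
#' modelled central region (between the homozygous RR and AA peaks) to a
#' maximum of 1. The dominant RR peak is excluded from the modelled region;
#' the AA peak is included only on request.
#'
#' @param bafs Numeric vector of BAF values in `[0, 1]`.
#' @param config A [polysomy_config()].
#' @return A list of class `"baf_distribution"` with `bin_centers`,
#'   `density` (smoothed, scaled), `raw` (smoothed, unscaled),
#'   `fit_region` (logical mask of modelled bins), `boundaries` (indices of
#'   local minima) and `n_sites`; or state `"FAIL"` flagged via
#'   `too_few = TRUE` when fewer than `min_sites` usable values exist.
#' @export
build_baf_distribution <- function(bafs, config = polysomy_config()) {
  bafs <- bafs[!is.na(bafs)]
  nb <- config$n_bins
  centers <- (seq_len(nb) - 0.5) / nb
  out <- list(bin_centers = centers, n_sites = length(bafs),
              too_few = length(bafs) < config$min_sites)
  class(out) <- "baf_distribution"
  if (out$too_few) return(out)
  idx <- pmin(pmax(ceiling(bafs * nb), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  w <- config$smoothing_window
  sm <- as.numeric(stats::filter(counts, rep(1 / w, w), sides = 2))
  # edges: truncated windows
  half <- (w - 1L) %/% 2L
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(nb, i + half)
    sm[i] <- mean(counts[lo:hi])
  }
  y <- sm
  # local minima of the smoothed density (plateau-tolerant)
  is_min <- c(FALSE, y[2:(nb - 1)] <= y[1:(nb - 2)] &
                     y[2:(nb - 1)] <= y[3:nb], FALSE)
  mins <- which(is_min)
  # drop consecutive plateau duplicates
  if (length(mins) > 1) mins <- mins[c(TRUE, diff(mins) > 1)]
  # RR peak: maximum in the lowest fifth of the range
  rr_peak <- which.max(y[seq_len(max(nb %/% 5, 2))])
  left <- mins[mins > rr_peak]
  left <- if (length(left)) left[1] else max(rr_peak + 1L, 2L)
  if (config$include_aa_peak) {
    right <- nb
  } else {
    aa_peak <- (nb - max(nb %/% 5, 2) + 1L) - 1L + which.max(y[(nb - max(nb %/% 5, 2) + 1L):nb])
    right <- mins[mins < aa_peak & mins > left]
    right <- if (length(right)) right[length(right)] else min(aa_peak - 1L, nb - 1L)
  }
  region <- seq_len(nb) >= left & seq_len(nb) <= right
  peak <- max(y[region])
  out$raw <- y
  out$density <- if (peak > 0) y / peak else y
  out$fit_region <- region
  out$boundaries <- mins
  out
}

# Peak models fitted to the scaled central BAF distribution. The
# contamination (CN4-pattern) model carries, besides the central peak and
# the host-heterozygote side peaks at 0.5 +/- delta, the two outer peaks
# produced by host-homozygote/contaminant-heterozygote sites: at mixture
# fraction f = 2*delta these sit at f/2 = delta and 1 - delta. They fall
# inside the modelled region once f > ~0.3 and would otherwise drag the
# side-peak fit toward a merged compromise.
.peak_model <- function(par, x, cn_state) {
  switch(cn_state,
    CN2 = par["m1"] * exp(-(x - 0.5)^2 / par["w"]^2),
    CN3 = par["m1"] * (exp(-(x - 0.5 + par["delta"])^2 / par["w"]^2) +
                       exp(-(x - 0.5 - par["delta"])^2 / par["w"]^2)),
    CN4 = par["mc"] * exp(-(x - 0.5)^2 / par["w"]^2) +
          par["m1"] * exp(-(x - 0.5 + par["delta"])^2 / par["w"]^2) +
          par["m2"] * exp(-(x - 0.5 - par["delta"])^2 / par["w"]^2) +
          par["mo1"] * exp(-(x - par["delta"])^2 / par["w"]^2) +
          par["mo2"] * exp(-(x - 1 + par["delta"])^2 / par["w"]^2))
}

#' Fit the expected BAF peak model for one copy-number state
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of a constrained
#' Gaussian-sum model to the scaled central region of a BAF distribution.
#' The diploid model is a single peak fixed at 0.5; the trisomy model has
#' two peaks at `0.5 +/- delta` with equal magnitudes; the contamination
#' (CN4-pattern) model has a central peak and two side peaks at
#' `0.5 +/- delta` whose magnitudes may differ. One shared width per fit,
#' bounded in `[0.01, 0.15]`. To avoid local minima, side-peak models are
#' restarted from several initial shifts and the best (lowest mean absolute
#' deviation, then smallest shift) is kept.
#'
#' @param dist A [build_baf_distribution()] result.
#' @param cn_state One of `"CN2"`, `"CN3"`, `"CN4"`.
#' @param config A [polysomy_config()].
#' @return A list of class `"peak_fit"`: `cn_state`, `delta`, `width`,
#'   `magnitudes`, `abs_dev` (mean |fit - data| over fitted bins),
#'   `converged`.
#' @export
fit_baf_peaks <- function(dist, cn_state = c("CN2", "CN3", "CN4"),
                          config = polysomy_config()) {
  cn_state <- match.arg(cn_state)
  x <- dist$bin_centers[dist$fit_region]
  y <- dist$density[dist$fit_region]
  starts <- switch(cn_state,
    CN2 = list(c(m1 = 1, w = 0.05)),
    CN3 = lapply(c(0.05, 0.1, 0.17, 0.25), function(d0)
      c(m1 = 1, w = 0.05, delta = d0)),
    CN4 = lapply(c(0.05, 0.1, 0.17, 0.25), function(d0)
      c(mc = 1, m1 = 0.5, m2 = 0.5, mo1 = 0.2, mo2 = 0.2,
        w = 0.05, delta = d0)))
  lower <- switch(cn_state,
    CN2 = c(m1 = 0, w = 0.01),
    CN3 = c(m1 = 0, w = 0.01, delta = 0),
    CN4 = c(mc = 0, m1 = 0, m2 = 0, mo1 = 0, mo2 = 0, w = 0.01,
            delta = 0))
  upper <- switch(cn_state,
    CN2 = c(m1 = Inf, w = 0.15),
    CN3 = c(m1 = Inf, w = 0.15, delta = 0.49),
    CN4 = c(mc = Inf, m1 = Inf, m2 = Inf, mo1 = Inf, mo2 = Inf,
            w = 0.15, delta = 0.49))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(par) .peak_model(par, x, cn_state) - y,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    par <- stats::coef(fit)
    dev <- mean(abs(.peak_model(par, x, cn_state) - y))
    cand <- list(par = par, abs_dev = dev,
                 converged = fit$info %in% 1:4)
    if (is.null(best) || dev < best$abs_dev - 1e-12 ||
        (abs(dev - best$abs_dev) <= 1e-12 && !is.na(par["delta"]) &&
         isTRUE(par["delta"] < best$par["delta"])))
      best <- cand
  }
  if (is.null(best))
    best <- list(par = starts[[1]], abs_dev = Inf, converged = FALSE)
  structure(list(cn_state = cn_state,
                 delta = if (cn_state == "CN2") 0 else
                   unname(best$par["delta"]),
                 width = unname(best$par["w"]),
                 magnitudes = unname(best$par[grep("^m", names(best$par))]),
                 abs_dev = best$abs_dev,
                 converged = best$converged),
            class = "peak_fit")
}

#' Aberrant-cell fraction from the fitted peak shift
#'
#' For a trisomy present in a fraction `f` of cells the heterozygous peaks
#' sit at `1/(2+f)` and `(1+f)/(2+f)`, i.e. at shift
#' `delta = f / (2 (2+f))` from 0.5; inverting gives
#' `f = 4 delta / (1 - 2 delta)`. For contamination the side peaks of the
#' two-genome mixture sit at `(1 -/+ f)/2`, so `f = 2 delta`.
#'
#' @param cn_state `"CN3"` (trisomy) or `"CN4"` (contamination pattern).
#' @param delta Fitted peak shift, `0 <= delta < 0.5`.
#' @return Estimated fraction of aberrant/contaminating cells.
#' @examples
#' fraction_from_delta("CN3", 1/6)  # 1: all cells trisomic
#' fraction_from_delta("CN4", 0.1)  # 0.2: 20% contamination
#' @export
fraction_from_delta <- function(cn_state, delta) {
  if (any(delta < 0 | delta >= 0.5)) stop("delta must lie in [0, 0.5)")
  switch(cn_state,
         CN3 = 4 * delta / (1 - 2 * delta),
         CN4 = 2 * delta,
         stop("cn_state must be CN3 or CN4"))
}

#' Select the copy-number state from the candidate fits
#'
#' Because more peaks always fit at least as well, an aberrant state is
#' accepted only when its fit deviation is below `fit_gate` times the
#' diploid single-peak deviation AND the implied aberrant-cell fraction is
#' at least `min_fraction`. Among accepted aberrant fits the one with the
#' lowest deviation wins (ties to the smaller shift). When no aberrant
#' model is accepted and the diploid fit itself failed to converge or
#' deviates more than the absolute cap, the chromosome is reported FAIL.
#'
#' @param fits Named list of [fit_baf_peaks()] results with elements
#'   `CN2`, `CN3`, `CN4`.
#' @param config A [polysomy_config()].
#' @return A list of class `"chromosome_call"`: `state` (`"CN2"`, `"CN3"`,
#'   `"CN4"` or `"FAIL"`), `fraction`, `delta`, `fit_ratio`
#'   (best-aberrant deviation / diploid deviation).
#' @export
select_cn_state <- function(fits, config = polysomy_config()) {
  cn2 <- fits$CN2
  cand <- list()
  for (st in c("CN3", "CN4")) {
    ft <- fits[[st]]
    if (is.null(ft) || !ft$converged || !is.finite(ft$abs_dev)) next
    if (st == "CN4" && ft$magnitudes[1] < config$min_central_peak)
      next  # no central heterozygous peak: not a contamination pattern
    delta <- min(ft$delta, 0.499)
    # a two-genome mixture at fractions f and 1-f produces the same peak
    # set (which genome is "the" contaminant is arbitrary); report the
    # minor component
    if (st == "CN4") delta <- min(delta, 0.5 - delta)
    fr <- fraction_from_delta(st, delta)
    gate_ok <- is.finite(cn2$abs_dev) &&
      ft$abs_dev < config$fit_gate * cn2$abs_dev
    # noise can push the full-trisomy shift slightly past 1/6 (implied
    # fraction just above 1); tolerate the overshoot and clamp the report
    if (gate_ok && fr >= config$min_fraction && fr <= 1.25)
      cand[[st]] <- list(state = st, fraction = min(fr, 1), delta = delta,
                         abs_dev = ft$abs_dev)
  }
  # nested-model guard, as for the CN2-vs-aberrant gate: the richer
  # contamination model displaces the trisomy model only when it is
  # markedly better, not merely no worse
  if (!is.null(cand$CN3) && !is.null(cand$CN4) &&
      cand$CN4$abs_dev >= config$fit_gate * cand$CN3$abs_dev)
    cand$CN4 <- NULL
  if (length(cand)) {
    devs <- vapply(cand, `[[`, numeric(1), "abs_dev")
    deltas <- vapply(cand, `[[`, numeric(1), "delta")
    pick <- cand[[order(devs, deltas)[1]]]
    out <- list(state = pick$state, fraction = pick$fraction,
                delta = pick$delta,
                fit_ratio = pick$abs_dev / cn2$abs_dev)
  } else if (!cn2$converged || !is.finite(cn2$abs_dev) ||
             cn2$abs_dev > config$fail_dev) {
    out <- list(state = "FAIL", fraction = NA_real_, delta = NA_real_,
                fit_ratio = NA_real_)
  } else {
    best_ab <- suppressWarnings(
      min(c(fits$CN3$abs_dev, fits$CN4$abs_dev), na.rm = TRUE))
    out <- list(state = "CN2", fraction = 0, delta = 0,
                fit_ratio = if (is.finite(best_ab))
                  best_ab / cn2$abs_dev else NA_real_)
  }
  class(out) <- "chromosome_call"
  out
}

#' Screen a chromosome's BAF values for aneuploidy or contamination
#'
#' Convenience wrapper: builds the distribution, fits all candidate
#' states, and selects one.
#'
#' @param bafs BAF values of one chromosome.
#' @param config A [polysomy_config()].
#' @return A `"chromosome_call"` (see [select_cn_state()]), with the fits
#'   attached as attribute `"fits"`.
#' @export
call_chromosome <- function(bafs, config = polysomy_config()) {
  dist <- build_baf_distribution(bafs, config)
  if (isTRUE(dist$too_few)) {
    out <- list(state = "FAIL", fraction = NA_real_, delta = NA_real_,
                fit_ratio = NA_real_)
    class(out) <- "chromosome_call"
    return(out)
  }
  fits <- list(CN2 = fit_baf_peaks(dist, "CN2", config),
               CN3 = fit_baf_peaks(dist, "CN3", config),
               CN4 = fit_baf_peaks(dist, "CN4", config))
  out <- select_cn_state(fits, config)
  attr(out, "fits") <- fits
  out
}

#' Screen a whole sample for aneuploidy and contamination
#'
#' Calls each chromosome's state from its BAF distribution and then forms
#' a sample-level verdict: when more than half of the chromosomes (by
#' default) carry side peaks at mutually consistent shifts, the pattern is
#' interpreted as contamination of the whole sample rather than as
#' independent trisomies, because a contaminating second genome affects
#' every chromosome in the same way, and the per-chromosome calls are
#' relabelled accordingly.
#'
#' @param tracks Named list of [marker_track()]s (one per chromosome), or a
#'   named list of numeric BAF vectors.
#' @param config A [polysomy_config()].
#' @return A list with `calls` (data.frame: `chrom`, `state`, `fraction`,
#'   `delta`, `fit_ratio`, `n_sites`), `contaminated` (logical verdict)
#'   and `contamination_fraction` (estimate when contaminated).
#' @export
call_polysomy <- function(tracks, config = polysomy_config()) {
  stopifnot(length(tracks) >= 1)
  res <- lapply(tracks, function(tr) {
    baf <- if (inherits(tr, "marker_track") || is.data.frame(tr)) tr$baf else tr
    c0 <- call_chromosome(baf, config)
    c0$n_sites <- sum(!is.na(baf))
    c0
  })
  calls <- data.frame(
    chrom = names(tracks),
    state = vapply(res, `[[`, character(1), "state"),
    fraction = vapply(res, `[[`, numeric(1), "fraction"),
    delta = vapply(res, `[[`, numeric(1), "delta"),
    fit_ratio = vapply(res, `[[`, numeric(1), "fit_ratio"),
    n_sites = vapply(res, `[[`, numeric(1), "n_sites"),
    stringsAsFactors = FALSE)
  # Per-chromosome contamination signature: a converged side-peak fit with
  # a central peak that beats the diploid fit by the gate, regardless of
  # the per-chromosome minimum-fraction gate — a sub-threshold signature on
  # one chromosome means little, but the same shift recurring on most
  # chromosomes is the pattern a contaminating genome produces.
  sig <- vapply(res, function(c0) {
    fits <- attr(c0, "fits")
    if (is.null(fits)) return(NA_real_)
    cn2 <- fits$CN2
    cn4 <- fits$CN4
    if (is.null(cn4) || !cn4$converged || !is.finite(cn4$abs_dev) ||
        !is.finite(cn2$abs_dev) ||
        cn4$abs_dev >= config$fit_gate * cn2$abs_dev ||
        cn4$magnitudes[1] < config$min_central_peak)
      return(NA_real_)
    d <- min(cn4$delta, 0.499)
    min(d, 0.5 - d)
  }, numeric(1))
  contaminated <- FALSE
  cfrac <- NA_real_
  ok <- !is.na(sig)
  if (sum(ok) > config$contamination_min_chroms * nrow(calls) &&
      diff(range(sig[ok])) < config$contamination_delta_spread) {
    contaminated <- TRUE
    cfrac <- fraction_from_delta("CN4", stats::median(sig[ok]))
    relabel <- ok | calls$state %in% c("CN3", "CN4")
    calls$state[relabel] <- "contamination"
    calls$delta[ok] <- sig[ok]
    calls$fraction[relabel] <-
      fraction_from_delta("CN4", calls$delta[relabel])
  }
  list(calls = calls, contaminated = contaminated,
       contamination_fraction = cfrac)
}
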