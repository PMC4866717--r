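#' Simulation configuration
#'
#' Describes the synthetic genotyping-array experiment the generator
#' emulates: marker spacing with a 2 kb median (right-skewed, exponential
#' gaps), ~15% heterozygous genotypes, per-experiment BAF noise drawn
#' uniformly from `[0.03, 0.08]` and LRR noise from `[0.13, 0.26]`, and
#' copy-number aberrations (CN1 losses and CN3 gains with equal
#' probability) whose lengths follow a two-piece log-normal hitting the
#' 18 kb / 1.7 Mb / 4 Mb (1st percentile / median / 99th percentile)
#' targets by construction.
#'
#' @param chrom_length Simulated chromosome length in bp, default 40 Mb.
#' @param median_spacing Median inter-marker gap in bp, default 2000.
#' @param het_fraction Expected fraction of heterozygous genotypes,
#'   default 0.15.
#' @param baf_sd Range (length-2) of per-experiment BAF noise sd.
#' @param lrr_sd Range (length-2) of per-experiment LRR noise sd.
#' @param length_quantiles Aberration length targets in bp: 1st percentile,
#'   median, 99th percentile.
#' @param aberrant_fraction Fraction of cells carrying each aberration,
#'   default 1 (clonal).
#' @param rate_aberrations Mean of the (zero-truncated) Poisson number of
#'   aberrations per experiment, chosen so ~2.3 regions are produced per
#'   experiment.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(chrom_length = 4e7, median_spacing = 2000,
                       het_fraction = 0.15, baf_sd = c(0.03, 0.08),
                       lrr_sd = c(0.13, 0.26),
                       length_quantiles = c(18e3, 1.7e6, 4e6),
                       aberrant_fraction = 1, rate_aberrations = 2) {
  stopifnot(het_fraction > 0, het_fraction < 0.5,
            length(baf_sd) == 2, length(lrr_sd) == 2,
            length(length_quantiles) == 3,
            aberrant_fraction > 0, aberrant_fraction <= 1)
  structure(list(chrom_length = chrom_length,
                 median_spacing = median_spacing,
                 het_fraction = het_fraction, baf_sd = baf_sd,
                 lrr_sd = lrr_sd, length_quantiles = length_quantiles,
                 aberrant_fraction = aberrant_fraction,
                 rate_aberrations = rate_aberrations),
            class = "sim_config")
}

#' Simulate marker positions
#'
#' Inter-marker gaps are exponential (right-skewed) with the configured
#' median; positions are their cumulative sums, strictly increasing.
#'
#' @param n Number of markers.
#' @param median_spacing Median gap in bp.
#' @return Integer vector of positions.
#' @export
simulate_positions <- function(n, median_spacing = 2000) {
  gaps <- pmax(1, round(stats::rexp(n, rate = log(2) / median_spacing)))
  cumsum(as.integer(gaps))
}

#' Simulate genotypes and allele frequencies
#'
#' Per-marker alternate allele frequencies are drawn from a U-shaped
#' Beta(a, a) site-frequency distribution with `a` chosen so the expected
#' Hardy-Weinberg heterozygosity equals `het_fraction`; genotypes are then
#' drawn from the per-marker Hardy-Weinberg proportions.
#'
#' @param n Number of markers.
#' @param het_fraction Expected heterozygous fraction, in (0, 0.5).
#' @return A list with `gt` (character RR/RA/AA) and `alt_freq`.
#' @export
simulate_genotypes <- function(n, het_fraction = 0.15) {
  stopifnot(het_fraction > 0, het_fraction < 0.5)
  # E[2q(1-q)] = 0.5 - 1/(2(2a+1)) for q ~ Beta(a, a)
  a <- het_fraction / (1 - 2 * het_fraction)
  q <- stats::rbeta(n, a, a)
  u <- stats::runif(n)
  p_rr <- (1 - q)^2
  p_het <- 2 * q * (1 - q)
  gt <- ifelse(u < p_rr, "RR", ifelse(u < p_rr + p_het, "RA", "AA"))
  list(gt = gt, alt_freq = q)
}

# two-piece log-normal hitting (q01, q50, q99) exactly
.rlength <- function(n, quantiles) {
  z99 <- stats::qnorm(0.99)
  lm <- log(quantiles[2])
  s_lo <- (lm - log(quantiles[1])) / z99
  s_hi <- (log(quantiles[3]) - lm) / z99
  z <- stats::rnorm(n)
  exp(lm + ifelse(z < 0, s_lo, s_hi) * z)
}

#' Inject copy-number aberrations into a clean track and add noise
#'
#' Starting from noise-free diploid BAF/LRR implied by the genotypes,
#' overwrites the regions in `regions` with the aberrant expectations:
#' within a CN1 loss, heterozygous markers lose one allele at random
#' (clonally, so all aberrant cells lose the same allele) and the BAF
#' expectation becomes `(1-f)/(2-f)` or `1/(2-f)`; within a CN3 gain the
#' heterozygous clusters move to `1/(2+f)` and `(1+f)/(2+f)`; LRR
#' expectations are `-0.45` and `0.3` scaled by the aberrant-cell fraction
#' `f`. Gaussian noise of the given sds is then added everywhere and BAF is
#' clipped to `[0, 1]`.
#'
#' @param track A [marker_track()] (its `gt`/`alt_freq` are kept; `baf` and
#'   `lrr` are regenerated).
#' @param regions Data.frame with columns `start`, `end` (bp, inclusive)
#'   and `cn` (1 or 3); regions must not overlap.
#' @param fraction Aberrant-cell fraction `f` in (0, 1].
#' @param baf_sd,lrr_sd Noise standard deviations (0 allowed).
#' @return A list with the modified `track` and a `truth` data.frame
#'   (`chrom`, `start`, `end`, `cn`, `n_markers`, `n_het_markers`), where
#'   start/end are the first/last marker positions inside each region;
#'   regions containing no marker are dropped from the truth.
#' @export
inject_aberrations <- function(track, regions, fraction = 1,
                               baf_sd = 0, lrr_sd = 0) {
  if (nrow(regions) > 1) {
    r <- regions[order(regions$start), ]
    if (any(r$start[-1] <= r$end[-nrow(r)]))
      stop("aberration regions must not overlap")
  }
  f <- fraction
  gt <- track$gt
  n <- nrow(track)
  baf <- ifelse(gt == "RR", 0, ifelse(gt == "AA", 1, 0.5))
  lrr <- numeric(n)
  truth <- NULL
  for (k in seq_len(nrow(regions))) {
    m <- track$pos >= regions$start[k] & track$pos <= regions$end[k]
    het <- m & gt == "RA"
    if (regions$cn[k] == 1) {
      lose_b <- stats::runif(1) < 0.5   # clonal: one allele lost throughout
      baf[het] <- if (lose_b) (1 - f) / 2 / (1 - f / 2) else
        1 / (2 - f)
      lrr[m] <- -0.45 * f
    } else if (regions$cn[k] == 3) {
      upper <- stats::runif(sum(het)) < 0.5
      baf[het] <- ifelse(upper, (1 + f) / (2 + f), 1 / (2 + f))
      lrr[m] <- 0.3 * f
    } else stop("regions$cn must be 1 or 3")
    if (any(m))
      truth <- rbind(truth, data.frame(
        chrom = track$chrom[1],
        start = min(track$pos[m]), end = max(track$pos[m]),
        cn = regions$cn[k], n_markers = sum(m),
        n_het_markers = sum(het)))
  }
  if (baf_sd > 0) baf <- pmin(pmax(baf + stats::rnorm(n, 0, baf_sd), 0), 1)
  if (lrr_sd > 0) lrr <- lrr + stats::rnorm(n, 0, lrr_sd)
  track$baf <- baf
  track$lrr <- lrr
  if (is.null(truth))
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), cn = integer(0),
                        n_markers = integer(0), n_het_markers = integer(0))
  list(track = track, truth = truth)
}

#' Simulate one array experiment with embedded aberrations
#'
#' Generates one chromosome of markers under `config`: positions,
#' genotypes, per-experiment noise levels drawn from the configured
#' ranges, and a zero-truncated Poisson number of non-overlapping CN1/CN3
#' aberrations with two-piece log-normal lengths.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name for the track.
#' @return A list with `track` and `truth` as in [inject_aberrations()],
#'   plus the realized `baf_sd` and `lrr_sd`.
#' @export
simulate_experiment <- function(config = sim_config(), chrom = "1") {
  L <- config$chrom_length
  n0 <- ceiling(L / config$median_spacing)
  pos <- simulate_positions(n0, config$median_spacing)
  pos <- pos[pos <= L]
  n <- length(pos)
  g <- simulate_genotypes(n, config$het_fraction)
  track <- marker_track(chrom, pos, baf = rep(0.5, n), lrr = rep(0, n),
                        gt = g$gt, alt_freq = g$alt_freq)
  n_ab <- 0
  while (n_ab < 1) n_ab <- stats::rpois(1, config$rate_aberrations)
  regions <- NULL
  for (k in seq_len(n_ab)) {
    for (try in 1:50) {
      len <- .rlength(1, config$length_quantiles)
      start <- floor(stats::runif(1, 1, max(L - len, 2)))
      end <- min(start + len, L)
      ok <- is.null(regions) ||
        all(end < regions$start - 1 | start > regions$end + 1)
      if (ok) {
        regions <- rbind(regions,
                         data.frame(start = start, end = end,
                                    cn = sample(c(1, 3), 1)))
        break
      }
    }
  }
  baf_sd <- stats::runif(1, config$baf_sd[1], config$baf_sd[2])
  lrr_sd <- stats::runif(1, config$lrr_sd[1], config$lrr_sd[2])
  out <- inject_aberrations(track, regions, config$aberrant_fraction,
                            baf_sd, lrr_sd)
  out$baf_sd <- baf_sd
  out$lrr_sd <- lrr_sd
  out
}

#' Simulate a set of experiments
#'
#' @param n_experiments Number of independent experiments.
#' @param config A [sim_config()].
#' @param seed Optional integer seed; when given, the RNG state is set
#'   locally so the dataset is fully reproducible and the caller's RNG
#'   stream is restored afterwards.
#' @return A list of experiments, each as returned by
#'   [simulate_experiment()]; experiment `k` uses chromosome name `k`.
#' @export
simulate_experiment_set <- function(n_experiments, config = sim_config(),
                                    seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(n_experiments), function(k)
    simulate_experiment(config, chrom = as.character(k)))
}

#' Simulate whole-chromosome BAF data for the aneuploidy screen
#'
#' Generates the BAF values of a whole chromosome in a diploid, trisomic or
#' contaminated state. Trisomy in a fraction `f` of cells puts the
#' heterozygous clusters at `1/(2+f)` and `(1+f)/(2+f)`. Contamination by a
#' second individual at mixture fraction `f` mixes the host's and the
#' contaminant's allelic dosage at every marker (both genotypes drawn from
#' the same site allele frequency), producing the characteristic symmetric
#' side peaks at `(1-f)/2` and `(1+f)/2` around the central heterozygous
#' peak, plus shifted homozygous clusters.
#'
#' @param n Number of markers.
#' @param state One of `"CN2"`, `"CN3"`, `"contamination"`.
#' @param fraction Aberrant or contaminating cell fraction in (0, 1].
#' @param baf_sd BAF noise sd.
#' @param het_fraction Expected heterozygosity of the array.
#' @return A list with `baf`, `gt` and `alt_freq`.
#' @export
simulate_polysomy_baf <- function(n, state = c("CN2", "CN3", "contamination"),
                                  fraction = 1, baf_sd = 0.04,
                                  het_fraction = 0.15) {
  state <- match.arg(state)
  g <- simulate_genotypes(n, het_fraction)
  dose <- c(RR = 0, RA = 0.5, AA = 1)[g$gt]
  f <- fraction
  if (state == "CN2") {
    baf <- dose
  } else if (state == "CN3") {
    het <- g$gt == "RA"
    extra_b <- stats::runif(n) < 0.5      # which allele gained
    b0 <- 1 / (2 + f)
    baf <- dose
    baf[het] <- ifelse(extra_b[het], 1 - b0, b0)
  } else {
    q <- g$alt_freq
    u <- stats::runif(n)
    p_rr <- (1 - q)^2
    p_het <- 2 * q * (1 - q)
    dose2 <- ifelse(u < p_rr, 0, ifelse(u < p_rr + p_het, 0.5, 1))
    baf <- (1 - f) * dose + f * dose2
  }
  baf <- pmin(pmax(baf + stats::rnorm(n, 0, baf_sd), 0), 1)
  list(baf = baf, gt = g$gt, alt_freq = g$alt_freq)
}
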