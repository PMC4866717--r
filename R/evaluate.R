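#' Match called segments against simulated truth regions
#'
#' A truth region counts as detected if at least one called segment of the
#' matching direction overlaps it by at least one base pair (losses match
#' CN0/CN1 calls, gains match CN3 calls). A non-diploid call is a false
#' positive if it overlaps no truth region of matching direction. Diploid
#' (CN2) calls are ignored.
#'
#' @param calls Data.frame of calls with columns `chrom`, `start`, `end`,
#'   `cn` (integers 0..3), e.g. from [call_cnv()].
#' @param truth Data.frame of truth regions with `chrom`, `start`, `end`,
#'   `cn` (1 or 3), e.g. from [simulate_experiment()].
#' @return A list with `truth` (input plus logical `detected`), `calls`
#'   (non-diploid calls plus logical `fp`), and for each truth region the
#'   indices of the matching calls (`matches`).
#' @export
match_overlaps <- function(calls, truth) {
  for (df in list(calls, truth))
    for (ch in unique(df$chrom)) {
      s <- df$start[df$chrom == ch]
      if (is.unsorted(s)) stop("segments must be sorted by start")
    }
  calls <- calls[calls$cn != 2, , drop = FALSE]
  dir_call <- ifelse(calls$cn < 2, "loss", "gain")
  dir_truth <- ifelse(truth$cn < 2, "loss", "gain")
  nt <- nrow(truth)
  detected <- logical(nt)
  matches <- vector("list", nt)
  fp <- rep(TRUE, nrow(calls))
  for (ch in unique(truth$chrom)) {
    for (dr in c("loss", "gain")) {
      ti <- which(truth$chrom == ch & dir_truth == dr)
      ci <- which(calls$chrom == ch & dir_call == dr)
      if (!length(ti) || !length(ci)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(truth$start[ti], truth$end[ti]),
        IRanges::IRanges(calls$start[ci], calls$end[ci]))
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      detected[ti[unique(qh)]] <- TRUE
      fp[ci[unique(sh)]] <- FALSE
      for (k in unique(qh))
        matches[[ti[k]]] <- ci[sh[qh == k]]
    }
  }
  truth$detected <- detected
  calls$fp <- fp
  list(truth = truth, calls = calls, matches = matches)
}

#' Boundary errors of detected regions
#'
#' For each detected truth region, `missed_length` is the truth length not
#' covered by its matching calls and `added_length` the called length
#' outside the truth (summed over all matching calls, so two calls
#' covering one truth region both contribute).
#'
#' @param matching Result of [match_overlaps()].
#' @return Data.frame, one row per detected truth region: `cn`, `length`,
#'   `missed_length`, `added_length`.
#' @export
boundary_errors <- function(matching) {
  truth <- matching$truth
  calls <- matching$calls
  det <- which(truth$detected)
  out <- lapply(det, function(i) {
    ci <- matching$matches[[i]]
    tr <- IRanges::IRanges(truth$start[i], truth$end[i])
    cr <- IRanges::IRanges(calls$start[ci], calls$end[ci])
    cov <- sum(IRanges::width(IRanges::intersect(tr, IRanges::reduce(cr))))
    added <- sum(IRanges::width(cr)) -
      sum(IRanges::width(IRanges::intersect(cr, tr)))
    data.frame(cn = truth$cn[i], length = IRanges::width(tr),
               missed_length = IRanges::width(tr) - cov,
               added_length = added)
  })
  if (!length(out))
    return(data.frame(cn = integer(0), length = integer(0),
                      missed_length = integer(0), added_length = integer(0)))
  do.call(rbind, out)
}

#' Summarize an evaluation into error rates
#'
#' @param matching Result of [match_overlaps()] (may be pooled across
#'   experiments by rbinding truths/calls before matching per experiment;
#'   see [evaluate_calls()] for the convenient path).
#' @param length_bins Breakpoints (bp) for the length-stratified error
#'   rates.
#' @return A list of class `"eval_report"`: `n_truth`, `n_called`,
#'   `miss_rate`, `fdr` (with `fdr_defined` flag), `dup_fraction_of_fn`,
#'   `dup_fraction_of_fp`, `by_length` (per-bin counts and miss rates),
#'   `boundary` (from [boundary_errors()]), `missed_markers` (marker and
#'   het-marker counts of missed regions, when the truth carries them).
#' @export
summarize_eval <- function(matching,
                           length_bins = c(0, 5e4, 1e5, 2e5, 5e5, 1e6,
                                           2e6, Inf)) {
  truth <- matching$truth
  calls <- matching$calls
  n_truth <- nrow(truth)
  n_called <- nrow(calls)
  n_missed <- sum(!truth$detected)
  miss_rate <- if (n_truth) n_missed / n_truth else 0
  n_fp <- sum(calls$fp)
  fdr_defined <- n_called > 0
  fdr <- if (fdr_defined) n_fp / n_called else 0
  dup_fn <- if (n_missed) mean(truth$cn[!truth$detected] == 3) else NA_real_
  dup_fp <- if (n_fp) mean(calls$cn[calls$fp] == 3) else NA_real_
  len <- truth$end - truth$start + 1
  bin <- cut(len, length_bins, include.lowest = TRUE)
  by_length <- data.frame(
    bin = levels(bin),
    n = as.vector(table(bin)),
    n_missed = as.vector(table(bin[!truth$detected])))
  by_length$miss_rate <- ifelse(by_length$n > 0,
                                by_length$n_missed / by_length$n, NA)
  missed_markers <- NULL
  if (all(c("n_markers", "n_het_markers") %in% names(truth)))
    missed_markers <- truth[!truth$detected,
                            c("cn", "n_markers", "n_het_markers")]
  structure(list(n_truth = n_truth, n_called = n_called,
                 miss_rate = miss_rate, fdr = fdr,
                 fdr_defined = fdr_defined,
                 dup_fraction_of_fn = dup_fn,
                 dup_fraction_of_fp = dup_fp,
                 by_length = by_length,
                 boundary = boundary_errors(matching),
                 missed_markers = missed_markers),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation of", x$n_called, "calls against", x$n_truth,
      "truth regions\n")
  cat(sprintf("  miss rate: %.2f%%   FDR: %.2f%%%s\n",
              100 * x$miss_rate, 100 * x$fdr,
              if (!x$fdr_defined) " (no calls; FDR undefined)" else ""))
  cat(sprintf("  duplications among FN: %s   among FP: %s\n",
              if (is.na(x$dup_fraction_of_fn)) "-" else
                sprintf("%.0f%%", 100 * x$dup_fraction_of_fn),
              if (is.na(x$dup_fraction_of_fp)) "-" else
                sprintf("%.0f%%", 100 * x$dup_fraction_of_fp)))
  invisible(x)
}

#' Evaluate pooled calls from a set of experiments
#'
#' Matches calls to truth within each experiment (chromosome names keep
#' experiments apart) and pools the counts.
#'
#' @param calls Data.frame of calls across experiments (`chrom`, `start`,
#'   `end`, `cn`).
#' @param truth Data.frame of truth regions across experiments.
#' @param ... Passed to [summarize_eval()].
#' @return An `"eval_report"`.
#' @export
evaluate_calls <- function(calls, truth, ...) {
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  summarize_eval(match_overlaps(calls, truth), ...)
}
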