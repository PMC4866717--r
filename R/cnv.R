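#' Re-estimate the heterozygous BAF shift of the gain state
#'
#' When only a fraction `f` of cells carries a single-copy gain, the
#' heterozygous BAF clusters sit at `1/(2+f)` and `(1+f)/(2+f)` rather than
#' 1/3 and 2/3, and a gain model assuming `f = 1` can miss the region
#' entirely. This routine iteratively re-estimates the expected shifted BAF
#' `beta0` from the data: each round runs the forward-backward algorithm and
#' forms the posterior-weighted average of the folded BAF
#' `0.5 - |0.5 - beta|` over heterozygous markers, weighting by the gain
#' posterior. By symmetry only the lower cluster needs to be considered.
#' Iteration stops on convergence (`|beta0' - beta0| < tol`), after
#' `max_iter` rounds, or when the candidate shift gets too close to 0.5 to
#' keep 95% of normally distributed BAF values below 0.5
#' (`0.5 - beta0' < 1.645 d / sqrt(2)`), in which case the last acceptable
#' value is kept — this guard adapts itself to the noise level and prevents
#' collapse onto the diploid model. If there is essentially no gain
#' posterior mass, `beta0` is returned unchanged.
#'
#' @param track A [marker_track()].
#' @param params An [emission_params()]; `params$beta0_het` is the starting
#'   value.
#' @param trans A transition model from [build_transitions()].
#' @param tol Convergence tolerance, default 1e-4.
#' @param max_iter Maximum iterations, default 20.
#' @return The updated `beta0_het` (numeric scalar) with attribute
#'   `"n_iter"`.
#' @export
optimize_beta0 <- function(track, params = emission_params(),
                           trans = build_transitions(), tol = 1e-4,
                           max_iter = 20) {
  guard <- stats::qnorm(0.95) * params$d / sqrt(2)
  beta0 <- params$beta0_het
  n_iter <- 0L
  repeat {
    p <- params
    p$beta0_het <- beta0
    post <- hmm_forward_backward(track, p, trans)
    pos <- attr(post, "pos")
    het <- track$gt[match(pos, track$pos)] == "RA"
    het[is.na(het)] <- FALSE
    w <- post[het, 4]                      # P(s = 3) at heterozygous sites
    # essentially no gain posterior mass anywhere: nothing to estimate
    if (sum(w) < 1e-3) break
    bfold <- 0.5 - abs(0.5 - track$baf[match(pos, track$pos)][het])
    new0 <- sum(bfold * w) / sum(w)
    n_iter <- n_iter + 1L
    if (0.5 - new0 < guard) break          # separation guard: keep old value
    done <- abs(new0 - beta0) < tol
    beta0 <- new0
    if (done || n_iter >= max_iter) break
  }
  attr(beta0, "n_iter") <- n_iter
  beta0
}

.runs_to_segments <- function(states, pos, chrom, quality_site) {
  n <- length(pos)
  if (n == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cn = integer(0),
                      quality = numeric(0), n_markers = integer(0)))
  key <- if (is.matrix(states)) paste(states[, 1], states[, 2]) else states
  r <- rle(as.vector(key))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(chrom = chrom,
                    start = pos[starts], end = pos[ends],
                    n_markers = r$lengths)
  if (is.matrix(states)) {
    seg$cn_query <- states[starts, 1]
    seg$cn_control <- states[starts, 2]
  } else {
    seg$cn <- states[starts]
  }
  seg$quality <- vapply(seq_along(starts), function(k)
    mean(quality_site[starts[k]:ends[k]]), numeric(1))
  cn_cols <- intersect(c("cn", "cn_query", "cn_control"), names(seg))
  seg[, c("chrom", "start", "end", cn_cols, "quality", "n_markers")]
}

#' Call copy-number segments in a single sample
#'
#' Decodes the most likely copy-number path with [hmm_viterbi()], merges
#' runs of equal state into segments, and attaches a quality score: the
#' mean posterior probability (from [hmm_forward_backward()]) of the
#' assigned state over the segment's markers. A Phred-scaled version
#' `-10 log10(1 - q)` capped at 99 is also reported.
#'
#' @param track A [marker_track()].
#' @param params An [emission_params()].
#' @param trans A transition model.
#' @param optimize If `TRUE`, first re-estimate the gain-state BAF shift
#'   with [optimize_beta0()] (recommended when only a fraction of cells may
#'   be aberrant).
#' @return A data.frame of segments: `chrom`, `start`, `end`, `cn` (0..3),
#'   `quality`, `n_markers`, `phred`. Attribute `"beta0_het"` records the
#'   shift actually used.
#' @export
call_cnv <- function(track, params = emission_params(),
                     trans = build_transitions(), optimize = FALSE) {
  if (optimize)
    params$beta0_het <- as.numeric(optimize_beta0(track, params, trans))
  prep <- .decode_prep(track, params, trans, NULL, 0.5)
  if (prep$n == 0) {
    seg <- .runs_to_segments(integer(0), integer(0), track$chrom[1],
                             numeric(0))
    seg$phred <- numeric(0)
    attr(seg, "beta0_het") <- params$beta0_het
    return(seg)
  }
  path <- .viterbi_core(log(prep$emis), log(prep$arr), log(prep$init),
                        prep$pref) - 1L
  pos <- prep$tr$pos
  post <- .fb_core(prep)
  qual <- post[cbind(seq_along(path), as.vector(path) + 1L)]
  seg <- .runs_to_segments(as.vector(path), pos, track$chrom[1], qual)
  seg$phred <- pmin(-10 * log10(pmax(1 - seg$quality, 1e-10)), 99)
  attr(seg, "beta0_het") <- params$beta0_het
  seg
}

#' Call copy-number differences between a query and a control sample
#'
#' Runs the 16-state paired HMM over two tracks on the same marker grid.
#' The shared-state prior `sigma` suppresses spurious discordant calls and
#' makes copy-number variation present in both samples (for example
#' inherited CNVs) come out as a concordant non-diploid state pair rather
#' than a difference. At `sigma = 0` the two samples are decoded
#' independently; at `sigma = 1` no discordant segment can be produced.
#'
#' @param track Query-sample [marker_track()].
#' @param control Control-sample track (same chromosome; markers are
#'   intersected on position).
#' @param sigma Shared-state prior in `[0, 1]`, default 0.5.
#' @param params An [emission_params()].
#' @param trans Single-sample transition model (the paired matrix is built
#'   internally).
#' @param optimize If `TRUE`, re-estimate the gain BAF shift from the query
#'   sample before decoding.
#' @return A list with components `segments` (runs of constant state pair:
#'   `chrom`, `start`, `end`, `cn_query`, `cn_control`, `quality`,
#'   `n_markers`), `diff` (the subset with `cn_query != cn_control`), and
#'   `query`/`control` (per-sample segment tables as in [call_cnv()]).
#' @export
call_cnv_pair <- function(track, control, sigma = 0.5,
                          params = emission_params(),
                          trans = build_transitions(), optimize = FALSE) {
  if (optimize)
    params$beta0_het <- as.numeric(optimize_beta0(track, params, trans))
  prep <- .decode_prep(track, params, trans, control, sigma)
  raw <- .viterbi_core(log(prep$emis), log(prep$arr), log(prep$init),
                       prep$pref)
  path <- cbind(query = (raw - 1L) %/% 4L, control = (raw - 1L) %% 4L)
  pos <- prep$tr$pos
  post <- .fb_core(prep)
  pair_idx <- path[, 1] * 4L + path[, 2] + 1L
  qual <- post[cbind(seq_along(pair_idx), pair_idx)]
  seg <- .runs_to_segments(path, pos, track$chrom[1], qual)
  qs <- .runs_to_segments(path[, 1], pos, track$chrom[1], qual)
  cs <- .runs_to_segments(path[, 2], pos, track$chrom[1], qual)
  list(segments = seg,
       diff = seg[seg$cn_query != seg$cn_control, , drop = FALSE],
       query = qs, control = cs)
}
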