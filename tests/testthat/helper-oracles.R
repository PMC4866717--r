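# Independent oracles used across tests. These deliberately avoid the
# package's decoding code paths: decoding is checked against exhaustive
# path enumeration, matrix powers against repeated multiplication, and
# overlap matching against a double loop.

# exhaustive decode over all S^n paths; returns the argmax path and the
# per-site posterior matrix computed by summing path probabilities
enumerate_decode <- function(emis, arr, init) {
  n <- nrow(emis)
  S <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  lp <- log(init[paths[, 1]]) + log(emis[cbind(1, paths[, 1])])
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + log(arr[cbind(paths[, t - 1], paths[, t], t - 1)]) +
        log(emis[cbind(t, paths[, t])])
    }
  }
  p <- exp(lp - max(lp))
  post <- matrix(0, n, S)
  for (t in 1:n)
    for (s in 1:S)
      post[t, s] <- sum(p[paths[, t] == s])
  post <- post / rowSums(post)
  list(best = unname(paths[which.max(lp), ]), post = post, logp = lp)
}

# naive repeated multiplication
matpow_naive <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

# naive overlap matcher: double loop, direction-matched
match_naive <- function(calls, truth) {
  calls <- calls[calls$cn != 2, , drop = FALSE]
  det <- logical(nrow(truth))
  fp <- rep(TRUE, nrow(calls))
  dirc <- ifelse(calls$cn < 2, "loss", "gain")
  dirt <- ifelse(truth$cn < 2, "loss", "gain")
  for (i in seq_len(nrow(truth))) for (j in seq_len(nrow(calls))) {
    if (truth$chrom[i] == calls$chrom[j] && dirt[i] == dirc[j] &&
        truth$start[i] <= calls$end[j] && truth$end[i] >= calls$start[j]) {
      det[i] <- TRUE
      fp[j] <- FALSE
    }
  }
  list(detected = det, fp = fp)
}

# small random marker track for decoder tests
random_track <- function(n, seed, chrom = "1") {
  set.seed(seed)
  pos <- cumsum(1 + stats::rpois(n, 1500))
  g <- simulate_genotypes(n, 0.3)
  marker_track(chrom, pos, baf = stats::runif(n),
               lrr = stats::rnorm(n, 0, 0.3), gt = g$gt,
               alt_freq = g$alt_freq)
}

# clean diploid track with exact BAF/LRR from genotypes
diploid_track <- function(n, seed, baf_sd = 0, lrr_sd = 0, chrom = "1",
                          het = 0.15, spacing = 2000) {
  set.seed(seed)
  pos <- simulate_positions(n, spacing)
  g <- simulate_genotypes(n, het)
  trk <- marker_track(chrom, pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  out <- inject_aberrations(trk, data.frame(start = integer(0),
                                            end = integer(0),
                                            cn = integer(0)),
                            1, baf_sd, lrr_sd)
  out$track
}
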