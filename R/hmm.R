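#' Emission model parameters for the CNV HMM
#'
#' Bundles the tunable parameters of the per-site emission model. BAF values
#' are modelled as truncated Gaussian peaks of scale `d` around the expected
#' value for each genotype and copy-number state; LRR as a Gaussian of scale
#' `lam` around a state-specific mean. The weights `b` and `l` moderate the
#' relative contribution of the two signals: LRR is empirically much noisier
#' than BAF across array runs, hence its default down-weighting.
#'
#' @param d BAF peak scale (the `d` in `exp(-(beta-beta0)^2/d^2)`),
#'   default 0.04.
#' @param lam LRR scale, default 0.2.
#' @param mu LRR means for copy-number states 1, 2, 3; default
#'   `c(-0.45, 0, 0.3)`.
#' @param b BAF weight in `[0, 1]`, default 1.
#' @param l LRR weight in `[0, 1]`, default 0.2.
#' @param p_err Uniform error floor added to every emission, default 1e-4.
#' @param beta0_het Expected BAF of the shifted heterozygous cluster under a
#'   single-copy gain; `1/3` when every cell carries the gain, and
#'   `1/(2+f)` when only a fraction `f` of cells does. See
#'   [optimize_beta0()].
#' @return A list of class `"emission_params"`.
#' @export
emission_params <- function(d = 0.04, lam = 0.2, mu = c(-0.45, 0, 0.3),
                            b = 1, l = 0.2, p_err = 1e-4, beta0_het = 1/3) {
  stopifnot(d > 0, lam > 0, length(mu) == 3,
            b >= 0, b <= 1, l >= 0, l <= 1,
            p_err >= 0, beta0_het > 0, beta0_het <= 0.5)
  structure(list(d = d, lam = lam, mu = mu, b = b, l = l, p_err = p_err,
                 beta0_het = beta0_het),
            class = "emission_params")
}

#' Truncated Gaussian BAF peak density
#'
#' Density of observing BAF `beta` when the expected value is `beta0`,
#' `c * exp(-(beta-beta0)^2/d^2)` with `c` chosen so the integral over
#' `[0, 1]` is 1. Truncation matters for boundary peaks: for `beta0 = 0` or
#' `1` the normalizer is twice that of an interior peak (half the mass would
#' fall outside the unit interval). For an interior peak the mode is
#' `1/(d*sqrt(pi))`.
#'
#' @param beta Observed BAF value(s) in `[0, 1]`.
#' @param beta0 Expected BAF value(s) in `[0, 1]`.
#' @param d Peak scale, positive.
#' @return Density values, same length as `beta`.
#' @export
gaussian_peak <- function(beta, beta0, d) {
  if (any(d <= 0)) stop("d must be positive")
  # integral of exp(-(x-beta0)^2/d^2) over [0,1]; Gaussian sd is d/sqrt(2)
  z <- sqrt(2) / d
  area <- d * sqrt(pi) *
    (stats::pnorm((1 - beta0) * z) - stats::pnorm(-beta0 * z))
  exp(-(beta - beta0)^2 / d^2) / area
}

#' BAF emission density for one copy-number state
#'
#' Mixture of genotype peaks weighted by the genotype priors. For the
#' diploid state the heterozygous peak sits at 0.5; under a single-copy gain
#' it splits into two peaks at `beta0_het` and `1 - beta0_het` (1/3 and 2/3
#' when all cells carry the gain). State 0 (homozygous loss) has no BAF
#' distribution and returns 0.
#'
#' @param beta Observed BAF value(s).
#' @param s Copy-number state, one of 0, 1, 2, 3.
#' @param priors Genotype priors from [genotype_priors()]; components may be
#'   vectors parallel to `beta`.
#' @param params An [emission_params()] object.
#' @return Density values; integrates to 1 over `[0, 1]` for `s` in 1..3.
#' @export
baf_emission <- function(beta, s, priors, params = emission_params()) {
  if (!s %in% 0:3) stop("state must be one of 0, 1, 2, 3")
  d <- params$d
  if (s == 0) return(rep(0, length(beta)))
  if (s == 1)
    return(gaussian_peak(beta, 0, d) * (priors$f_rr + 0.5 * priors$f_ra) +
           gaussian_peak(beta, 1, d) * (priors$f_aa + 0.5 * priors$f_ra))
  if (s == 2)
    return(gaussian_peak(beta, 0, d) * priors$f_rr +
           gaussian_peak(beta, 1, d) * priors$f_aa +
           gaussian_peak(beta, 0.5, d) * priors$f_ra)
  b0 <- params$beta0_het
  gaussian_peak(beta, 0, d) * priors$f_rr +
    gaussian_peak(beta, 1, d) * priors$f_aa +
    (gaussian_peak(beta, b0, d) + gaussian_peak(beta, 1 - b0, d)) *
      0.5 * priors$f_ra
}

#' LRR emission for one copy-number state
#'
#' Gaussian in the LRR value around the state mean, normalized to 1 at the
#' mode, `exp(-(lambda - mu_s)^2 / lam^2)`.
#'
#' @param lambda_val Observed LRR value(s).
#' @param s Copy-number state, one of 1, 2, 3.
#' @param params An [emission_params()] object.
#' @return Values in `(0, 1]`.
#' @export
lrr_emission <- function(lambda_val, s, params = emission_params()) {
  if (!s %in% 1:3) stop("LRR emission is defined for states 1, 2, 3")
  mu <- params$mu[s]
  exp(-(lambda_val - mu)^2 / params$lam^2)
}

#' Combined per-site emission probability
#'
#' Blends the BAF and LRR signals with their weights and adds the uniform
#' error floor: `P_err + (1 - b (1 - Pb)) (1 - l (1 - Pl))`. The BAF density
#' is rescaled by its maximum attainable interior-peak mode `1/(d sqrt(pi))`
#' so the weighted factor is an order-1 quantity; the LRR term is already
#' mode-normalized. State 0 carries no BAF or LRR model and emits the error
#' floor alone. A missing LRR drops the LRR factor for that site; a site
#' with missing genotype/BAF emits the missing-call probabilities
#' `(0.5, 1/6, 1/6, 1/6)` used in paired calling.
#'
#' @param beta,lambda_val Observed BAF and LRR (may be `NA`).
#' @param s Copy-number state 0..3.
#' @param priors Genotype priors ([genotype_priors()]).
#' @param params An [emission_params()] object.
#' @return Emission probabilities, same length as `beta`.
#' @export
site_emission <- function(beta, lambda_val, s, priors,
                          params = emission_params()) {
  em <- .emission_matrix(beta, lambda_val, priors, params)
  em[, s + 1L]
}

# n x 4 emission matrix over states 0..3, vectorized over sites
.emission_matrix <- function(beta, lambda_val, priors, params) {
  n <- length(beta)
  scale <- params$d * sqrt(pi)  # 1 / interior-peak mode
  miss <- is.na(beta)
  bafv <- ifelse(miss, 0.5, beta)
  lrr_ok <- !is.na(lambda_val)
  lrrv <- ifelse(lrr_ok, lambda_val, 0)
  l_eff <- params$l * lrr_ok  # missing LRR: weight 0 at that site
  out <- matrix(params$p_err, n, 4)
  for (s in 1:3) {
    pb <- baf_emission(bafv, s, priors, params) * scale
    pl <- lrr_emission(lrrv, s, params)
    out[, s + 1L] <- params$p_err +
      (1 - params$b * (1 - pb)) * (1 - l_eff * (1 - pl))
  }
  if (any(miss)) {
    out[miss, ] <- rep(c(0.5, 1/6, 1/6, 1/6), each = sum(miss))
  }
  out
}

#' Paired-sample emission probability
#'
#' In two-sample mode the emission for the state pair `(s1, s2)` is the
#' product of the two single-sample emissions.
#'
#' @param beta1,lambda1 Query-sample BAF and LRR.
#' @param beta2,lambda2 Control-sample BAF and LRR.
#' @param s1,s2 Copy-number states 0..3 for the two samples.
#' @param priors Genotype priors at the site(s).
#' @param params An [emission_params()] object.
#' @return Emission probabilities.
#' @export
pair_emission <- function(beta1, lambda1, beta2, lambda2, s1, s2, priors,
                          params = emission_params()) {
  site_emission(beta1, lambda1, s1, priors, params) *
    site_emission(beta2, lambda2, s2, priors, params)
}

#' Build the HMM transition model
#'
#' The single-sample transition matrix is symmetric with all off-diagonal
#' entries `p` and diagonal `1 - (n-1) p`. To account for uneven marker
#' spacing, the matrix applied between two markers `i` and `j` is the matrix
#' power `T^(j-i)` of the per-base-pair matrix; powers up to `cache_n` are
#' precomputed and longer gaps are computed on demand by
#' exponentiation-by-squaring (capped at `cap` base pairs, beyond which the
#' chain has effectively forgotten its state).
#'
#' @param p Per-step off-diagonal transition probability, `0 < p < 1/3`
#'   for the 4-state model. Default `1e-9`.
#' @param n_states Number of states (4 for single-sample calling).
#' @param cache_n Number of precomputed powers, default 10000.
#' @param cap Maximum distance in base pairs used for powering, default
#'   1e7.
#' @return A list of class `"trans_model"` with the base matrix `T`, the
#'   power cache, and the cap.
#' @export
build_transitions <- function(p = 1e-9, n_states = 4, cache_n = 10000,
                              cap = 1e7) {
  if (p <= 0 || p >= 1 / (n_states - 1))
    stop("p must satisfy 0 < p < 1/(n_states - 1)")
  T_ <- matrix(p, n_states, n_states)
  diag(T_) <- 1 - (n_states - 1) * p
  .trans_model(T_, cache_n = cache_n, cap = cap)
}

.trans_model <- function(T_, cache_n = 10000, cap = 1e7) {
  S <- nrow(T_)
  cache <- array(NA_real_, c(S, S, cache_n))
  cache[, , 1] <- T_
  if (cache_n > 1)
    for (k in 2:cache_n) cache[, , k] <- cache[, , k - 1] %*% T_
  structure(list(T = T_, cache = cache, cache_n = cache_n, cap = cap,
                 n_states = S),
            class = "trans_model")
}

#' Matrix power of the transition matrix
#'
#' @param tm A transition model from [build_transitions()] or
#'   [pair_transitions()].
#' @param k Non-negative integer exponent (in base pairs of marker
#'   distance). `k = 0` gives the identity.
#' @return The `k`-th power of the transition matrix.
#' @export
trans_power <- function(tm, k) {
  S <- tm$n_states
  k <- min(k, tm$cap)
  if (k == 0) return(diag(S))
  if (k <= tm$cache_n) return(tm$cache[, , k])
  # exponentiation by squaring
  out <- diag(S)
  base <- tm$T
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2
  }
  out
}

#' Paired-sample transition model
#'
#' Builds the 16-state transition matrix for two-sample calling. The
#' shared-state prior `sigma` interpolates between fully independent
#' samples (`sigma = 0`, the Kronecker product of the single-sample
#' matrices) and fully coupled samples (`sigma = 1`, under which no
#' transition may create a discordant state pair). With `0 < sigma < 1`
#' transitions that keep the two samples in the same state are favoured, so
#' copy-number variation shared by both samples (for example inherited
#' CNVs) is not reported as a difference.
#'
#' @param tm Single-sample transition model from [build_transitions()].
#' @param sigma Shared-state prior in `[0, 1]`.
#' @param cache_n,cap As in [build_transitions()].
#' @return A 16-state `"trans_model"`; the underlying matrix is
#'   row-stochastic (rows are normalized over destination pairs).
#' @export
pair_transitions <- function(tm, sigma, cache_n = 10000, cap = 1e7) {
  stopifnot(sigma >= 0, sigma <= 1)
  T_ <- tm$T
  S <- nrow(T_)
  M <- matrix(0, S * S, S * S)
  for (i in 1:S) for (x in 1:S) for (j in 1:S) for (y in 1:S) {
    base <- T_[i, j] * T_[x, y]
    v <- if (j == y && i == x) (1 - sigma) * base + sigma * T_[i, j]
         else if (j == y) base
         else (1 - sigma) * base
    M[(i - 1) * S + x, (j - 1) * S + y] <- v
  }
  M <- M / rowSums(M)
  .trans_model(M, cache_n = cache_n, cap = cap)
}

# per-gap linear-space transition array [S, S, length(gaps)]
.trans_array <- function(tm, gaps) {
  S <- tm$n_states
  g <- pmin(gaps, tm$cap)
  g[g < 1] <- 1
  arr <- array(NA_real_, c(S, S, length(g)))
  small <- g <= tm$cache_n
  if (any(small)) arr[, , small] <- tm$cache[, , g[small], drop = FALSE]
  if (any(!small)) {
    for (gk in unique(g[!small])) {
      Pk <- trans_power(tm, gk)
      arr[, , which(g == gk)] <- Pk
    }
  }
  arr
}

#' Most likely copy-number path (Viterbi decoding)
#'
#' Runs Viterbi decoding of the copy-number HMM over one marker track (4
#' states) or a pair of tracks (16 states). Initial state probabilities
#' prefer the diploid state (`P(s=2) = 0.5`, `0.5/3` for each other state;
#' the product of these in paired mode). Arithmetic is in log space; ties
#' are broken toward the diploid state and then toward the lower state
#' index, so output is deterministic.
#'
#' @param track A [marker_track()] for the query sample. Sites with missing
#'   genotype/BAF are ignored in single-sample mode and use the
#'   missing-call emissions in paired mode.
#' @param params An [emission_params()] object.
#' @param trans A transition model ([build_transitions()]).
#' @param track2 Optional control-sample track for paired decoding; must
#'   share marker positions with `track` (tracks are intersected on
#'   position).
#' @param sigma Shared-state prior used when `track2` is given.
#' @return An integer vector of copy-number states (0..3) per retained
#'   marker in single-sample mode, or a two-column matrix
#'   (`query`, `control`) in paired mode, with attribute `"pos"` giving
#'   marker positions.
#' @export
hmm_viterbi <- function(track, params = emission_params(),
                        trans = build_transitions(), track2 = NULL,
                        sigma = 0.5) {
  prep <- .decode_prep(track, params, trans, track2, sigma)
  if (prep$n == 0) {
    out <- if (is.null(track2)) integer(0) else
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("query", "control")))
    attr(out, "pos") <- integer(0)
    return(out)
  }
  path <- .viterbi_core(log(prep$emis), log(prep$arr), log(prep$init),
                        prep$pref)
  .decode_path(path, prep, track2)
}

.decode_prep <- function(track, params, trans, track2, sigma) {
  if (is.null(track2)) {
    keep <- !is.na(track$baf) & !is.na(track$gt)
    tr <- track[keep, , drop = FALSE]
    n <- nrow(tr)
    pr <- genotype_priors(tr$alt_freq)
    emis <- .emission_matrix(tr$baf, tr$lrr, pr, params)
    init <- c(0.5 / 3, 0.5 / 3, 0.5, 0.5 / 3)
    tmodel <- trans
    pref <- c(3L, 1L, 2L, 4L)
  } else {
    common <- intersect(track$pos, track2$pos)
    t1 <- track[match(common, track$pos), , drop = FALSE]
    t2 <- track2[match(common, track2$pos), , drop = FALSE]
    n <- length(common)
    pr <- genotype_priors(t1$alt_freq)
    e1 <- .emission_matrix(t1$baf, t1$lrr, pr, params)
    e2 <- .emission_matrix(t2$baf, t2$lrr, pr, params)
    # per-site outer product -> 16 columns indexed (s1-1)*4 + s2
    emis <- matrix(NA_real_, n, 16)
    for (s1 in 1:4) for (s2 in 1:4)
      emis[, (s1 - 1) * 4 + s2] <- e1[, s1] * e2[, s2]
    i4 <- c(0.5 / 3, 0.5 / 3, 0.5, 0.5 / 3)
    init <- as.vector(t(outer(i4, i4)))  # (s1-1)*4+s2 ordering
    tmodel <- pair_transitions(trans, sigma,
                               cache_n = min(trans$cache_n, 10000),
                               cap = trans$cap)
    # prefer diploid/diploid, then lower pair index
    pref <- c(11L, setdiff(1:16, 11L))
    tr <- t1
  }
  gaps <- if (n > 1) diff(tr$pos) else integer(0)
  arr <- .trans_array(tmodel, gaps)
  list(n = n, tr = tr, emis = emis, init = init, arr = arr, pref = pref)
}

.decode_path <- function(path, prep, track2) {
  if (is.null(track2)) {
    out <- path - 1L
  } else {
    s1 <- (path - 1L) %/% 4L
    s2 <- (path - 1L) %% 4L
    out <- cbind(query = s1, control = s2)
  }
  attr(out, "pos") <- prep$tr$pos
  out
}

# log-space Viterbi; emis_log n x S, arr_log S x S x (n-1).
# The inner maximization walks states in preference order (diploid first,
# then lower index) and keeps the incumbent on ties, which implements the
# deterministic tie-break.
.viterbi_core <- function(emis_log, arr_log, init_log, pref) {
  n <- nrow(emis_log)
  S <- ncol(emis_log)
  ptr <- matrix(NA_integer_, n, S)
  delta <- init_log + emis_log[1, ]
  rest <- pref[-1]
  if (n > 1) {
    for (t in 2:n) {
      tmp <- delta + arr_log[, , t - 1]       # tmp[i, j] = delta[i] + logT[i, j]
      best <- tmp[pref[1], ]
      idx <- rep.int(pref[1], S)
      for (i in rest) {
        row <- tmp[i, ]
        gt <- row > best
        if (any(gt)) {
          best[gt] <- row[gt]
          idx[gt] <- i
        }
      }
      ptr[t, ] <- idx
      delta <- best + emis_log[t, ]
    }
  }
  path <- integer(n)
  # final-state tie-break with the same preference order
  fin <- delta[pref]
  path[n] <- pref[which.max(fin)]
  if (n > 1) for (t in n:2) path[t - 1] <- ptr[t, path[t]]
  path
}

#' Per-site state posteriors (forward-backward)
#'
#' Computes the posterior probability of each copy-number state at each
#' marker with the scaled forward-backward algorithm, under the same model
#' as [hmm_viterbi()]. Segment qualities in [call_cnv()] are mean
#' posteriors from this matrix.
#'
#' @inheritParams hmm_viterbi
#' @return A numeric matrix (markers x states) of posteriors; each row sums
#'   to 1. States are 0..3 in single-sample mode and the 16 ordered state
#'   pairs in paired mode. Attribute `"pos"` gives marker positions;
#'   attribute `"loglik"` the data log-likelihood.
#' @export
hmm_forward_backward <- function(track, params = emission_params(),
                                 trans = build_transitions(), track2 = NULL,
                                 sigma = 0.5) {
  prep <- .decode_prep(track, params, trans, track2, sigma)
  .fb_core(prep)
}

.fb_core <- function(prep) {
  n <- prep$n
  S <- length(prep$init)
  if (n == 0) {
    out <- matrix(numeric(0), 0, S)
    attr(out, "pos") <- integer(0)
    return(out)
  }
  emis <- prep$emis
  arr <- prep$arr
  alpha <- matrix(NA_real_, n, S)
  cc <- numeric(n)
  a <- prep$init * emis[1, ]
  cc[1] <- sum(a)
  alpha[1, ] <- a / cc[1]
  if (n > 1) {
    for (t in 2:n) {
      A <- arr[, , t - 1]
      a0 <- alpha[t - 1, ]
      a <- .colSums(a0 * A, S, S) * emis[t, ]
      cc[t] <- sum(a)
      alpha[t, ] <- a / cc[t]
    }
  }
  beta <- matrix(NA_real_, n, S)
  beta[n, ] <- 1
  if (n > 1) {
    for (t in (n - 1):1) {
      v <- emis[t + 1, ] * beta[t + 1, ]
      b <- .rowSums(arr[, , t] * rep(v, each = S), S, S)
      beta[t, ] <- b / cc[t + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  attr(post, "pos") <- prep$tr$pos
  attr(post, "loglik") <- sum(log(cc))
  post
}
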