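test_that("BAF peaks are unit-area densities, including boundary truncation", {
  d <- 0.04
  for (b0 in c(0, 0.25, 0.5, 2/3, 1)) {
    area <- integrate(gaussian_peak, 0, 1, beta0 = b0, d = d,
                      rel.tol = 1e-10)$value
    expect_equal(area, 1, tolerance = 1e-8)
  }
  # interior mode equals 1/(d sqrt(pi)); boundary normalizer doubles it
  expect_equal(gaussian_peak(0.5, 0.5, d), 1 / (d * sqrt(pi)),
               tolerance = 1e-9)
  expect_equal(gaussian_peak(0, 0, d), 2 / (d * sqrt(pi)),
               tolerance = 1e-9)
  expect_error(gaussian_peak(0.5, 0.5, 0), "positive")
})

test_that("BAF state emissions integrate to one and rank states correctly", {
  set.seed(2)
  for (q in c(0.1, 0.5, 0.8)) {
    pr <- genotype_priors(q)
    for (s in 1:3) {
      area <- integrate(baf_emission, 0, 1, s = s, priors = pr,
                        rel.tol = 1e-9)$value
      expect_equal(area, 1, tolerance = 1e-7)
    }
    expect_equal(baf_emission(0.3, 0, pr), 0)
  }
  # single-component reduction: all-heterozygous prior at the mode
  pr1 <- list(f_rr = 0, f_ra = 1, f_aa = 0)
  expect_equal(baf_emission(0.5, 2, pr1),
               gaussian_peak(0.5, 0.5, emission_params()$d))
  # a BAF at 1/3 favours the gain state over diploid
  pr <- genotype_priors(0.5)
  expect_gt(baf_emission(1/3, 3, pr), baf_emission(1/3, 2, pr))
  expect_error(baf_emission(0.5, 5, pr), "state")
})

test_that("LRR emission is mode-normalized and symmetric", {
  p <- emission_params()
  expect_equal(lrr_emission(0, 2, p), 1)
  expect_equal(lrr_emission(0.3, 3, p), 1)
  expect_equal(lrr_emission(0.3, 2, p), exp(-0.09 / 0.04))
  x <- 0.17
  for (s in 1:3)
    expect_equal(lrr_emission(p$mu[s] + x, s, p),
                 lrr_emission(p$mu[s] - x, s, p))
})

test_that("site emission honours the BAF/LRR weights and missing data", {
  pr <- genotype_priors(0.4)
  p0 <- emission_params(b = 1, l = 0)
  # l = 0: LRR ignored entirely
  expect_equal(site_emission(0.5, -3, 2, pr, p0),
               site_emission(0.5, 10, 2, pr, p0))
  # b = 0, l = 0: no information beyond the error floor
  pno <- emission_params(b = 0, l = 0)
  for (s in 1:3)
    expect_equal(site_emission(0.77, 0.5, s, pr, pno), pno$p_err + 1)
  # missing LRR behaves like l = 0 at that site
  pl <- emission_params()
  expect_equal(site_emission(0.5, NA, 2, pr, pl),
               site_emission(0.5, 0, 2, pr, emission_params(l = 0)))
  # missing genotype/BAF: the paired-mode no-call emissions
  expect_equal(site_emission(NA, 0, 0, pr, pl), 0.5)
  for (s in 1:3) expect_equal(site_emission(NA, 0, s, pr, pl), 0.5 / 3)
  # state 0 at an observed site emits only the error floor
  expect_equal(site_emission(0.5, 0, 0, pr, pl), pl$p_err)
})

test_that("paired emissions factor into the two single-sample emissions", {
  pr <- genotype_priors(0.3)
  p <- emission_params()
  for (s1 in 0:3) for (s2 in 0:3) {
    e <- pair_emission(0.45, 0.1, 0.9, -0.2, s1, s2, pr, p)
    expect_equal(e, site_emission(0.45, 0.1, s1, pr, p) *
                    site_emission(0.9, -0.2, s2, pr, p))
    # swapping samples together with states is symmetric
    expect_equal(e, pair_emission(0.9, -0.2, 0.45, 0.1, s2, s1, pr, p))
  }
})

test_that("transition powers are stochastic and multiply correctly", {
  tm <- build_transitions(p = 1e-4, cache_n = 300)
  expect_equal(trans_power(tm, 0), diag(4))
  expect_equal(trans_power(tm, 1), tm$T)
  # cached and dynamically squared powers equal brute-force multiplication
  for (k in c(2, 57, 200, 301, 1024, 2049)) {
    expect_equal(trans_power(tm, k), matpow_naive(tm$T, k),
                 tolerance = 1e-12)
  }
  for (k in c(1, 10, 100, 300))
    expect_equal(rowSums(trans_power(tm, k)), rep(1, 4), tolerance = 1e-9)
  # semigroup property T^(a+b) = T^a T^b
  expect_equal(trans_power(tm, 450),
               trans_power(tm, 200) %*% trans_power(tm, 250),
               tolerance = 1e-12)
  expect_error(build_transitions(p = 0.5), "p must")
})

test_that("paired transitions interpolate between independence and lockstep", {
  tm <- build_transitions(p = 1e-3, cache_n = 2)
  # sigma = 0: exactly the Kronecker product of the single-sample matrix
  p0 <- pair_transitions(tm, 0, cache_n = 2)
  expect_equal(p0$T, kronecker(tm$T, tm$T), tolerance = 1e-12)
  # sigma = 1: no transition may create a discordant pair
  p1 <- pair_transitions(tm, 1, cache_n = 2)
  # destination discordance mask in (j-1)*4+y ordering
  mask <- logical(16)
  for (j in 1:4) for (y in 1:4) mask[(j - 1) * 4 + y] <- j != y
  expect_true(all(p1$T[, mask] == 0))
  for (sg in c(0, 0.3, 0.7, 1))
    expect_equal(rowSums(pair_transitions(tm, sg, cache_n = 2)$T),
                 rep(1, 16), tolerance = 1e-9)
})

test_that("Viterbi and forward-backward match exhaustive enumeration", {
  tm <- build_transitions(p = 1e-3, cache_n = 50)
  p <- emission_params()
  for (seed in 1:12) {
    n <- sample(4:8, 1)
    trk <- random_track(n, seed = 100 + seed)
    path <- hmm_viterbi(trk, p, tm)
    post <- hmm_forward_backward(trk, p, tm)
    # rebuild the model ingredients independently of the decoder internals
    pr <- genotype_priors(trk$alt_freq)
    emis <- sapply(0:3, function(s)
      site_emission(trk$baf, trk$lrr, s, pr, p))
    gaps <- diff(trk$pos)
    arr <- array(NA_real_, c(4, 4, n - 1))
    for (t in seq_len(n - 1)) arr[, , t] <- trans_power(tm, gaps[t])
    init <- c(0.5 / 3, 0.5 / 3, 0.5, 0.5 / 3)
    oracle <- enumerate_decode(emis, arr, init)
    expect_equal(as.vector(path), oracle$best - 1L)
    expect_equal(unclass(post), oracle$post, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(rowSums(post), rep(1, n), tolerance = 1e-12)
  }
})

test_that("single-site posteriors reduce to prior times emission", {
  tm <- build_transitions(p = 1e-3, cache_n = 2)
  p <- emission_params()
  trk <- random_track(1, seed = 77)
  post <- hmm_forward_backward(trk, p, tm)
  pr <- genotype_priors(trk$alt_freq)
  e <- sapply(0:3, function(s) site_emission(trk$baf, trk$lrr, s, pr, p))
  expected <- e * c(0.5 / 3, 0.5 / 3, 0.5, 0.5 / 3)
  expect_equal(as.vector(post), expected / sum(expected), tolerance = 1e-12)
})

test_that("paired decoding at sigma = 0 factorizes into single-sample runs", {
  tm <- build_transitions(p = 1e-3, cache_n = 50)
  p <- emission_params()
  t1 <- random_track(7, seed = 301)
  t2 <- random_track(7, seed = 302)
  t2$pos <- t1$pos  # same marker grid
  t2$alt_freq <- t1$alt_freq
  post_pair <- hmm_forward_backward(t1, p, tm, track2 = t2, sigma = 0)
  p1 <- hmm_forward_backward(t1, p, tm)
  p2 <- hmm_forward_backward(t2, p, tm)
  for (s1 in 1:4) for (s2 in 1:4)
    expect_equal(post_pair[, (s1 - 1) * 4 + s2], p1[, s1] * p2[, s2],
                 tolerance = 1e-9, ignore_attr = TRUE)
  v <- hmm_viterbi(t1, p, tm, track2 = t2, sigma = 0)
  expect_equal(v[, "query"], as.vector(hmm_viterbi(t1, p, tm)))
  expect_equal(v[, "control"], as.vector(hmm_viterbi(t2, p, tm)))
})
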