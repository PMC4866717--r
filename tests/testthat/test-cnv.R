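# one transition model for the whole file; building the power cache is the
# expensive part
tm <- build_transitions()

test_that("a clean diploid chromosome yields a single CN2 segment", {
  trk <- diploid_track(400, seed = 21, baf_sd = 0.03, lrr_sd = 0.15)
  seg <- call_cnv(trk, trans = tm)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$cn, 2)
  expect_equal(seg$start, trk$pos[1])
  expect_equal(seg$end, trk$pos[nrow(trk)])
  expect_equal(seg$n_markers, nrow(trk))
  expect_true(seg$quality > 0.9 && seg$quality <= 1)
})

test_that("a median-size deletion is called as one overlapping CN1 segment", {
  set.seed(31)
  n <- 3000
  pos <- simulate_positions(n, 2000)
  g <- simulate_genotypes(n, 0.15)
  trk <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  mid <- pos[1200]
  out <- inject_aberrations(trk, data.frame(start = mid, end = mid + 1.7e6,
                                            cn = 1),
                            1, 0.04, 0.2)
  seg <- call_cnv(out$track, trans = tm)
  hits <- seg[seg$cn == 1 & seg$start <= out$truth$end &
              seg$end >= out$truth$start, ]
  expect_equal(nrow(hits), 1)
  # boundaries within a handful of markers of the truth
  expect_lt(abs(hits$start - out$truth$start), 5e4)
  expect_lt(abs(hits$end - out$truth$end), 5e4)
  expect_true(all(seg$quality >= 0 & seg$quality <= 1))
})

test_that("a two-marker deletion is not called at default settings", {
  set.seed(32)
  n <- 800
  pos <- simulate_positions(n, 2000)
  g <- simulate_genotypes(n, 0.15)
  trk <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  out <- inject_aberrations(trk, data.frame(start = pos[400],
                                            end = pos[401], cn = 1),
                            1, 0.04, 0.2)
  seg <- call_cnv(out$track, trans = tm)
  expect_true(all(seg$cn == 2))
})

test_that("segment qualities are mean state posteriors with a Phred transform", {
  trk <- diploid_track(100, seed = 33, baf_sd = 0.03, lrr_sd = 0.13)
  seg <- call_cnv(trk, trans = tm)
  post <- hmm_forward_backward(trk, trans = tm)
  expect_equal(seg$quality, mean(post[, 3]))
  expect_equal(seg$phred, min(-10 * log10(1 - seg$quality), 99))
})

test_that("gain-shift re-estimation recovers 1/(2+f) for partial trisomies", {
  for (f in c(0.5, 1.0)) {
    set.seed(410 + round(10 * f))
    n <- 4000
    pos <- simulate_positions(n, 2000)
    g <- simulate_genotypes(n, 0.2)
    trk <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
    out <- inject_aberrations(trk, data.frame(start = pos[1], end = pos[n],
                                              cn = 3),
                              fraction = f, baf_sd = 0.03, lrr_sd = 0.15)
    b0 <- optimize_beta0(out$track, emission_params(), tm)
    expect_equal(as.numeric(b0), 1 / (2 + f), tolerance = 0.02)
  }
})

test_that("gain-shift re-estimation leaves diploid data at the default", {
  trk <- diploid_track(2000, seed = 55, baf_sd = 0.04, lrr_sd = 0.15)
  b0 <- optimize_beta0(trk, emission_params(), tm)
  expect_equal(as.numeric(b0), 1/3)
})

test_that("re-estimation rescues a low-fraction gain missed at beta0 = 1/3", {
  set.seed(61)
  n <- 3000
  pos <- simulate_positions(n, 2000)
  g <- simulate_genotypes(n, 0.2)
  trk <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  out <- inject_aberrations(trk, data.frame(start = pos[500],
                                            end = pos[2500], cn = 3),
                            fraction = 0.35, baf_sd = 0.03, lrr_sd = 0.15)
  seg_opt <- call_cnv(out$track, trans = tm, optimize = TRUE)
  hit <- any(seg_opt$cn == 3 & seg_opt$start <= out$truth$end &
             seg_opt$end >= out$truth$start)
  expect_true(hit)
  expect_equal(attr(seg_opt, "beta0_het"), 1 / 2.35, tolerance = 0.03)
})

test_that("identical tracks produce no difference segments in paired mode", {
  trk <- diploid_track(500, seed = 71, baf_sd = 0.04, lrr_sd = 0.2)
  res <- call_cnv_pair(trk, trk, sigma = 0.5, trans = tm)
  expect_equal(nrow(res$diff), 0)
})

test_that("a CNV shared by query and control is concordant, not a difference", {
  set.seed(72)
  n <- 2000
  pos <- simulate_positions(n, 2000)
  g <- simulate_genotypes(n, 0.15)
  base <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  reg <- data.frame(start = pos[800], end = pos[1400], cn = 3)
  q <- inject_aberrations(base, reg, 1, 0.03, 0.15)
  c0 <- inject_aberrations(base, reg, 1, 0.03, 0.15)
  res <- call_cnv_pair(q$track, c0$track, sigma = 0.5, trans = tm)
  conc <- res$segments[res$segments$cn_query == 3 &
                       res$segments$cn_control == 3, ]
  expect_gte(nrow(conc), 1)
  expect_true(any(conc$start <= q$truth$end & conc$end >= q$truth$start))
  expect_equal(nrow(res$diff), 0)
})

test_that("a query-only CNV appears as a difference segment", {
  set.seed(73)
  n <- 2000
  pos <- simulate_positions(n, 2000)
  g <- simulate_genotypes(n, 0.15)
  base <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  reg <- data.frame(start = pos[800], end = pos[1400], cn = 1)
  q <- inject_aberrations(base, reg, 1, 0.03, 0.15)
  c0 <- inject_aberrations(base, reg[0, ], 1, 0.03, 0.15)
  res <- call_cnv_pair(q$track, c0$track, sigma = 0.5, trans = tm)
  expect_gte(nrow(res$diff), 1)
  expect_true(any(res$diff$cn_query == 1 & res$diff$cn_control == 2 &
                  res$diff$start <= q$truth$end &
                  res$diff$end >= q$truth$start))
})

test_that("difference length is non-increasing in sigma and zero at sigma = 1", {
  set.seed(74)
  n <- 1200
  pos <- simulate_positions(n, 2000)
  g <- simulate_genotypes(n, 0.15)
  base <- marker_track("1", pos, rep(0.5, n), rep(0, n), g$gt, g$alt_freq)
  reg <- data.frame(start = pos[500], end = pos[800], cn = 3)
  q <- inject_aberrations(base, reg, 1, 0.06, 0.22)
  c0 <- inject_aberrations(base, reg[0, ], 1, 0.06, 0.22)
  diff_len <- vapply(c(0, 0.5, 1), function(sg) {
    d <- call_cnv_pair(q$track, c0$track, sigma = sg, trans = tm)$diff
    sum(pmax(d$end - d$start + 1, 0))
  }, numeric(1))
  expect_true(all(diff(diff_len) <= 0))
  expect_equal(diff_len[3], 0)
})
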