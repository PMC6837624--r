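stim1s <- step_stimulus(100, onset = 100, duration = 1000)

test_that("feature arithmetic matches the definitions", {
  fs <- extract_features(100 + c(100, 150, 210), stim1s)
  expect_equal(fs$fsl, 100)
  expect_equal(fs$isis, c(50, 60))
  expect_equal(fs$n_isis, 2L)
  expect_equal(fs$pss, 790)
  expect_equal(fs$delay_factor, 100 / 55)
})

test_that("undefined features stay NA instead of fabricated zeros", {
  fs0 <- extract_features(numeric(0), stim1s)
  expect_equal(fs0$n_spikes, 0)
  expect_true(is.na(fs0$fsl) && is.na(fs0$pss) && is.na(fs0$sfa))
  fs1 <- extract_features(150, stim1s)
  expect_equal(fs1$fsl, 50)
  expect_length(fs1$isis, 0)
  expect_true(is.na(fs1$sfa))
  expect_true(is.na(fs1$delay_factor))
})

test_that("perfectly periodic trains have zero adaptation", {
  fs <- extract_features(100 + seq(50, 950, by = 50), stim1s)
  expect_equal(fs$sfa, 0)
  expect_false(fs$trend_significant)
})

test_that("reconstruction identity: fsl + sum(ISIs) + pss = duration", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    st <- sort(runif(n, 100, 1100))
    fs <- extract_features(st, stim1s)
    expect_equal(fs$fsl + sum(fs$isis) + fs$pss, 1000)
  }
})

test_that("sfa is invariant to rescaling all ISIs", {
  isis <- c(40, 44, 48, 52, 56)
  expect_equal(adaptation_stats(isis)$sfa,
               adaptation_stats(isis * 7.3)$sfa)
  expect_equal(adaptation_stats(isis)$sfa,
               adaptation_stats(isis * 0.01)$sfa)
})

test_that("adaptation trend test agrees with the closed-form regression", {
  isis <- c(40, 44, 48, 52, 56)
  ad <- adaptation_stats(isis)
  expect_gt(ad$sfa, 0)
  expect_true(ad$trend_significant)
  # independent route: lm() on the same sequence
  fit <- suppressWarnings(summary(lm(isis ~ seq_along(isis))))
  expect_equal(ad$slope_pvalue, fit$coefficients[2, 4], tolerance = 1e-8)
  noisy <- c(50, 48, 53, 47, 52, 50)
  ad2 <- adaptation_stats(noisy)
  fit2 <- summary(lm(noisy ~ seq_along(noisy)))
  expect_equal(ad2$slope_pvalue, fit2$coefficients[2, 4], tolerance = 1e-8)
  expect_false(ad2$trend_significant)
})

test_that("rapid adaptation is detected only when confined to the head", {
  expect_true(adaptation_stats(c(10, 30, 31, 32, 33))$rapid_component)
  expect_false(adaptation_stats(c(40, 44, 48, 52, 56))$rapid_component)
  expect_false(adaptation_stats(c(50, 50, 50, 50))$rapid_component)
  expect_true(is.na(adaptation_stats(c(50))$sfa))
})

test_that("burst segmentation matches brute-force rule application", {
  seg <- segment_bursts(c(0, 10, 20, 300, 310, 320))
  expect_equal(seg$n_bursts, 2)
  expect_equal(seg$bursts$bw, c(20, 20))
  expect_equal(seg$pbi, 280)
  expect_equal(seg$bursts$b_n_isis, c(2L, 2L))
  # burst of two plus an isolated spike: one burst
  seg2 <- segment_bursts(c(0, 5, 500))
  expect_equal(seg2$n_bursts, 1)
  expect_equal(seg2$bursts$b_n_isis, 1L)
  # uniform train: a single cluster, no post-burst interval
  seg3 <- segment_bursts(seq(0, 900, by = 100))
  expect_equal(length(seg3$clusters), 1)
  expect_length(seg3$pbi, 0)
  # property: agreement with the loop-based oracle on random stutters
  set.seed(42)
  for (i in 1:10) {
    nb <- sample(2:4, 1)
    st <- sort(unlist(lapply(seq_len(nb) * 300, function(o)
      o + cumsum(runif(sample(2:5, 1), 5, 15)))))
    seg <- segment_bursts(st)
    expect_equal(lengths(seg$clusters), lengths(brute_clusters(st)))
  }
})

test_that("burst segmentation is shift-invariant and idempotent", {
  st <- c(0, 10, 20, 300, 310, 320)
  a <- segment_bursts(st)
  b <- segment_bursts(st + 137.5)
  expect_equal(a$n_bursts, b$n_bursts)
  expect_equal(a$bursts$bw, b$bursts$bw)
  expect_equal(a$pbi, b$pbi)
  expect_equal(segment_bursts(st), segment_bursts(st))
})

test_that("an adapting train is not split into spurious bursts", {
  # smoothly lengthening intervals must remain one cluster even though the
  # last ISI exceeds three times the median
  st <- cumsum(c(100, 50, 90, 150, 240, 380))
  seg <- segment_bursts(st)
  expect_equal(length(seg$clusters), 1)
})

test_that("spikes after the stimulus offset are not part of the pattern", {
  fs <- extract_features(c(200, 300, 400, 1150), stim1s)
  expect_equal(fs$n_spikes, 3)
  expect_equal(fs$pss, 700)
})
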