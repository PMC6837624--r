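test_that("the feature-weighted log error is zero exactly at a match", {
  t <- list(fsl = 20, pss = 100, sfa = 0.1, n_isis = 7)
  expect_equal(pattern_error(t, t), 0)
  expect_equal(pattern_error(list(fsl = 20), list(fsl = 30),
                             family = "fsl"), log(11))
  expect_equal(pattern_error(list(n_bursts = 3), list(n_bursts = 1),
                             family = "n_bursts"), log(3))
})

test_that("the error grows monotonically in each feature discrepancy", {
  t <- list(fsl = 50)
  errs <- vapply(c(55, 60, 80, 150), function(v)
    pattern_error(t, list(fsl = v), family = "fsl"), numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("equal weights make the error symmetric in target and model", {
  a <- list(fsl = 20, pss = 100, sfa = 0.10, n_isis = 7)
  b <- list(fsl = 35, pss = 80, sfa = 0.15, n_isis = 9)
  expect_equal(pattern_error(a, b), pattern_error(b, a))
})

test_that("list features align with zero padding and penalize missing bursts", {
  t <- list(bw = c(20, 25), pbi = 300)
  m_same <- list(bw = c(20, 25), pbi = 300)
  m_short <- list(bw = 20, pbi = 300)
  expect_equal(pattern_error(t, m_same, family = c("bw", "pbi")), 0)
  expect_equal(pattern_error(t, m_short, family = c("bw", "pbi")),
               log(1 + 25))
})

test_that("undefined model features draw a large finite penalty", {
  t <- list(sfa = 0.1)
  e <- pattern_error(t, list(sfa = NA_real_), family = "sfa")
  expect_true(is.finite(e))
  expect_gt(e, pattern_error(t, list(sfa = 0.9), family = "sfa"))
})

test_that("dynamic weights boost exactly the mismatched class aspects", {
  w0 <- dynamic_weights("ASP.SLN", "ASP.SLN")
  expect_true(all(w0 == 1))
  w1 <- dynamic_weights("ASP.SLN", "ASP.")
  expect_equal(unname(w1["pss"]), 10)
  expect_equal(unname(w1[c("sfa", "n_isis", "fsl")]), c(1, 1, 1))
  w2 <- dynamic_weights("D.NASP", "NASP")
  expect_equal(unname(w2["fsl"]), 10)
  expect_equal(unname(w2[c("sfa", "pss", "n_isis")]), c(1, 1, 1))
  w3 <- dynamic_weights("ASP.", NULL)
  expect_true(all(w3 == 10))
})

test_that("class families pick the published feature sets", {
  expect_setequal(feature_family("ASP.SLN"),
                  c("fsl", "pss", "sfa", "n_isis"))
  expect_setequal(feature_family("TSWB.SLN"),
                  c("fsl", "pss", "bw", "pbi", "n_bursts", "b_n_isis"))
  expect_setequal(feature_family("PSTUT"),
                  c("fsl", "pss", "bw", "pbi", "n_bursts", "b_n_isis"))
})

test_that("constraint errors are zero inside the constraints and log outside", {
  ce <- constraint_errors(0.10, 0.15, -10, -12, R = 1, epsp = 0.5)
  expect_true(all(ce == 0))
  # violated rheobase ordering
  ce2 <- constraint_errors(0.15, 0.10, -10, -12, R = 1, epsp = 0.5)
  expect_equal(ce2$rheo, log1p(0.05))
  # propagation below one
  expect_equal(constraint_errors(0.1, 0.1, -1, -1, R = 0.5, epsp = 0.5)$prop,
               log(1.5))
  # EPSP window branches
  expect_equal(constraint_errors(0.1, 0.1, -1, -1, R = 1, epsp = 0.05)$epsp,
               log(1.05))
  expect_equal(constraint_errors(0.1, 0.1, -1, -1, R = 1, epsp = 1.2)$epsp,
               log1p(0.3))
  expect_error(constraint_errors(0.1, 0.1, -1, -1, R = 1.5, epsp = 0.5),
               "propagation")
})

test_that("each constraint error is continuous at its boundary", {
  eps <- 1e-9
  expect_lt(constraint_errors(0.1, 0.1 - eps, -1, -1, 1, 0.5)$rheo, 1e-8)
  expect_lt(constraint_errors(0.1, 0.1, -1 - eps, -1, 1, 0.5)$vdef, 1e-8)
  expect_lt(constraint_errors(0.1, 0.1, -1, -1, 1 - eps, 0.5)$prop, 1e-8)
  expect_lt(constraint_errors(0.1, 0.1, -1, -1, 1, 0.1 - eps)$epsp, 1e-8)
  expect_lt(constraint_errors(0.1, 0.1, -1, -1, 1, 0.9 + eps)$epsp, 1e-8)
})
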