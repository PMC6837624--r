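test_that("sign and tertile encodings follow their definitions", {
  expect_equal(categorize_values(c(-2, -1, 3), "sign"),
               c("neg", "neg", "pos"))
  expect_equal(categorize_values(c(-1, 0, 2), "sign"),
               c("neg", "pos", "pos"))
  out <- categorize_values(c(5, 1, 9, 3, 7, 2, 8, 4, 6), "tertile")
  expect_equal(sum(out == "high", na.rm = TRUE), 3)
  expect_equal(sum(out == "low", na.rm = TRUE), 3)
  expect_equal(sum(is.na(out)), 3)
  expect_equal(out[c(2, 6, 4)], rep("low", 3))
})

test_that("tertile ties break deterministically and drops stay near n/3", {
  x <- c(1, 2, 2, 2, 3, 9, 9, 10, 11)
  expect_identical(categorize_values(x, "tertile"),
                   categorize_values(x, "tertile"))
  for (n in 3:20) {
    set.seed(n)
    dropped <- sum(is.na(categorize_values(rnorm(n), "tertile")))
    expect_gte(dropped, floor(n / 3) - 0L)
    expect_lte(dropped, ceiling(n / 3))
  }
  expect_warning(out <- categorize_values(rep(1, 6), "tertile"), "dropped")
  expect_true(all(is.na(out)))
})

test_that("Barnard p-values match the exhaustive enumeration oracle", {
  tables <- list(matrix(c(5, 0, 0, 5), 2),
                 matrix(c(3, 1, 0, 4), 2),
                 matrix(c(4, 4, 1, 6), 2),
                 matrix(c(2, 2, 2, 2), 2),
                 matrix(c(6, 2, 1, 7), 2))
  for (tab in tables) {
    expect_lte(abs(barnard_test(tab)$p_value - barnard_oracle(tab)), 1e-3)
  }
})

test_that("identical row proportions give p = 1", {
  res <- barnard_test(matrix(c(3, 3, 3, 3), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("transposing a table with matched margins leaves p unchanged", {
  for (tab in list(matrix(c(5, 0, 0, 5), 2), matrix(c(4, 2, 2, 1), 2),
                   matrix(c(1, 3, 3, 6), 2))) {
    expect_equal(barnard_test(tab)$p_value, barnard_test(t(tab))$p_value,
                 tolerance = 1e-12)
  }
})

test_that("refining the nuisance grid never decreases the p-value", {
  tab <- matrix(c(4, 1, 1, 5), 2)
  p_coarse <- barnard_test(tab, grid_step = 0.01)$p_value
  p_fine <- barnard_test(tab, grid_step = 0.001)$p_value
  expect_gte(p_fine, p_coarse - 1e-12)
})

test_that("degenerate margins are flagged with p = 1", {
  res <- barnard_test(matrix(c(0, 3, 0, 4), 2))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("the association suite covers its standard cases", {
  r <- associate(1:10, (1:10)^3, kind = "spearman")
  expect_equal(r$statistic, 1)
  g <- rep(c("a", "b"), each = 8)
  x_same <- rep(1:8, 2)
  expect_gte(associate(x_same, g, kind = "wilcoxon")$p_value, 0.5)
  x_shift <- c(rnorm(10) + 10, rnorm(10))
  set.seed(5)
  r2 <- associate(c(rnorm(10) + 10, rnorm(10)),
                  rep(c("hi", "lo"), each = 10), kind = "ttest")
  expect_lt(r2$p_value, 0.05)
  expect_error(associate(1:2, 2:3, kind = "spearman"), "complete pairs")
})

test_that("BH discovery flags match the definitional scan", {
  expect_false(any(fdr_control(rep(1, 10), q = 0.25)))
  expect_true(fdr_control(c(0.01), q = 0.25))
  set.seed(11)
  for (i in 1:5) {
    p <- runif(20)^2
    expect_equal(fdr_control(p, q = 0.25), bh_oracle(p, 0.25))
    expect_equal(fdr_control(p, q = 0.05), bh_oracle(p, 0.05))
  }
})

test_that("the association screen wires tests and FDR together", {
  set.seed(9)
  n <- 24
  latent <- rnorm(n)
  params <- data.frame(b = latent + rnorm(n, sd = 0.2),
                       noise = rnorm(n))
  params[] <- lapply(params, categorize_values, mode = "tertile")
  props <- data.frame(marker = ifelse(latent > 0, "yes", "no"))
  out <- association_screen(params, props, q = 0.25)
  expect_equal(nrow(out), 2)
  expect_true(out$discovery[out$parameter == "b"])
  expect_lt(out$p_value[out$parameter == "b"],
            out$p_value[out$parameter == "noise"])
})
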