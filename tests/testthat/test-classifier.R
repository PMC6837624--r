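stim1s <- step_stimulus(100, onset = 100, duration = 1000)

classify_spikes <- function(st, stim = stim1s, ...) {
  classify_pattern(extract_features(st, stim), ...)
}

test_that("label grammar round-trips over all elements and compositions", {
  labels <- c("D", "ASP", "RASP", "TSTUT", "TSWB") |>
    lapply(function(t) c(paste0(t, "."),
                         paste0(t, ".", c("SLN", "NASP", "PSTUT", "PSWB")))) |>
    unlist() |>
    c("SLN", "NASP", "PSTUT", "PSWB", "RASP.ASP.", "D.ASP.SLN", "TSWB.SLN")
  for (s in labels) {
    expect_equal(format(parse_label(s)), s)
    expect_equal(parse_label(s)$complete, !endsWith(s, "."))
  }
  expect_error(parse_label("ASP"), "steady-state")
  expect_error(parse_label("FOO."), "transient")
  expect_error(class_label("ASP", "XYZ"), "steady-state")
})

test_that("canonical trains get their canonical labels", {
  # uniform filling train, no trend, short pss
  expect_equal(format(classify_spikes(100 + seq(50, 990, by = 50))), "NASP")
  # increasing ISIs up to the stimulus end: incomplete adapting pattern
  st_asp <- 100 + cumsum(c(50, 55, 62, 70, 80, 92, 106, 122, 140, 160))
  expect_equal(format(classify_spikes(st_asp)), "ASP.")
  # increasing ISIs then long silence: adapting into silence
  st_sln <- 100 + cumsum(c(50, 60, 75, 95, 120))
  expect_equal(format(classify_spikes(st_sln)), "ASP.SLN")
  # long first latency then uniform: delayed non-adapting
  st_d <- 100 + 400 + c(0, cumsum(rep(60, 8)))
  expect_equal(format(classify_spikes(st_d)), "D.NASP")
  # repeated clusters until the end: persistent stuttering
  st_ps <- 100 + sort(unlist(lapply(c(0, 250, 500, 750), function(o)
    o + seq(0, 40, by = 10))))
  expect_equal(format(classify_spikes(st_ps)), "PSTUT")
  # early cluster then long silence: transient burst into silence
  st_tb <- 100 + c(0, 8, 16, 24)
  expect_equal(format(classify_spikes(st_tb)), "TSTUT.SLN")
  expect_equal(format(classify_spikes(st_tb, slow_ahp = TRUE)), "TSWB.SLN")
})

test_that("fewer than two spikes yields no label", {
  expect_null(classify_spikes(numeric(0)))
  expect_null(classify_spikes(500))
})

test_that("classifier is total and deterministic on random spike trains", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:40, 1)
    st <- sort(runif(n, 100, 1100))
    l1 <- classify_spikes(st)
    l2 <- classify_spikes(st)
    expect_s3_class(l1, "class_label")
    expect_identical(format(l1), format(l2))
    els <- c(l1$transients, if (!is.na(l1$steady)) l1$steady)
    expect_true(all(els %in% c(izhifit:::TRANSIENT_ELEMENTS,
                               izhifit:::STEADY_ELEMENTS)))
  }
})

test_that("lengthening the silence can add SLN but never remove it", {
  base <- cumsum(c(50, 60, 75, 95, 120))
  got_sln <- FALSE
  for (shift in seq(0, 500, by = 100)) {
    # same ISIs, earlier in the window -> progressively longer pss
    st <- 100 + base + (500 - shift)
    st <- st[st <= 1100]
    lab <- classify_spikes(st)
    if (!is.na(lab$steady) && lab$steady == "SLN") got_sln <- TRUE
    if (got_sln)
      expect_equal(lab$steady, "SLN")
  }
  expect_true(got_sln)
})

test_that("label matching is exact except the rapid-adapting exception", {
  expect_true(label_match("ASP.", "ASP."))
  expect_false(label_match("NASP", "ASP."))
  expect_true(label_match("RASP.NASP", "RASP.ASP."))
  expect_false(label_match("RASP.NASP", "RASP.ASP.",
                           allow_rasp_exception = FALSE))
  # the exception is one-directional
  expect_false(label_match("RASP.ASP.", "RASP.NASP"))
  expect_false(label_match(NULL, "ASP."))
})

test_that("contradictory threshold configuration is rejected", {
  expect_error(class_thresholds(alpha = 1.2), "alpha")
  expect_error(class_thresholds(delay_factor = -1), "non-negative")
})
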