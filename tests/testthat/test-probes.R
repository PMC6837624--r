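test_that("rheobase sits just above the closed-form saddle-node current", {
  # b = 0: saddle-node at k (Vt - Vr)^2 / 4 = 0.7 * 400 / 4 = 70 pA
  p <- rs_params(b = 0)
  r <- find_rheobase(p)
  expect_gte(r, 0.070)
  expect_lt(r, 0.070 * 1.10)
  # doubling k approximately doubles the bifurcation current
  p2 <- izhi_params(100, 1.4, -60, -40, 35, -50, 0.03, 0, 100)
  expect_equal(find_rheobase(p2) / r, 2, tolerance = 0.1)
})

test_that("rheobase is monotone in the quadratic gain k", {
  lo <- izhi_params(100, 0.5, -60, -40, 35, -50, 0.03, 0, 100)
  hi <- izhi_params(100, 1.0, -60, -40, 35, -50, 0.03, 0, 100)
  expect_gt(find_rheobase(hi), find_rheobase(lo))
})

test_that("rheobase errors when the bracket cannot elicit a spike", {
  expect_error(find_rheobase(rs_params(), lo = 0, hi = 0.001), "no spike")
})

test_that("voltage deflection is zero at zero and grows with the current", {
  p <- rs_params()
  expect_equal(voltage_deflection(p, 0), 0)
  d1 <- abs(voltage_deflection(p, -0.01))
  d2 <- abs(voltage_deflection(p, -0.03))
  d3 <- abs(voltage_deflection(p, -0.06))
  expect_true(d1 < d2 && d2 < d3)
})

two_comp <- function(G, P, dend = NULL) {
  soma <- rs_params(b = 0, d = 60)
  if (is.null(dend))
    dend <- izhi_params(50, 0.35, -60, -30, 35, -45, 0.03, 0, 40)
  compartment_model(list(soma = soma, dend = dend),
                    data.frame(prox = 1, dist = 2, G = G, P = P))
}

test_that("propagation ratio: decoupled gives 0, strong coupling gives 1", {
  expect_equal(propagation_ratio(two_comp(0, 0.5)), 0)
  expect_equal(propagation_ratio(two_comp(25, 0.4)), 1)
  # source that cannot spike: undefined, distinct from zero
  quiet <- izhi_params(50, 0.35, -60, -30, 35, -45, 0.03, 0, 40)
  m <- compartment_model(list(soma = rs_params(), dend = quiet),
                         data.frame(prox = 1, dist = 2, G = 1, P = 0.5))
  expect_true(is.na(propagation_ratio(m, n_synapses = 1, weight = 0.01)))
})

test_that("EPSP amplitude is zero at zero weight and monotone below threshold", {
  m <- two_comp(25, 0.4)
  expect_equal(epsp_amplitude(m, weight = 0), 0)
  amps <- vapply(c(2, 6, 10), function(w) epsp_amplitude(m, weight = w),
                 numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("decoupled probes reproduce single-compartment values exactly", {
  dend <- izhi_params(50, 0.35, -60, -30, 35, -45, 0.03, 0, 40)
  m0 <- two_comp(0, 0.5, dend = dend)
  expect_equal(find_rheobase(m0$compartments$dend), find_rheobase(dend))
  expect_equal(voltage_deflection(m0$compartments$dend, -0.05),
               voltage_deflection(dend, -0.05))
})

test_that("back-propagating spikes attenuate, more so down a chain", {
  p <- rs_params(d = 60)
  # symmetric strong coupling between identical compartments: ~no attenuation
  twin <- compartment_model(list(soma = p, dend = p),
                            data.frame(prox = 1, dist = 2, G = 60, P = 0.5))
  att_twin <- backprop_attenuation(twin, 0.15)
  expect_lt(att_twin[["dend"]], 0.1)
  # passive dendrite: attenuation decreases as backward coupling increases
  quiet <- izhi_params(50, 0.35, -60, -30, 35, -45, 0.03, 0, 40)
  att <- vapply(c(3, 10, 30), function(G) {
    m <- compartment_model(list(soma = p, dend = quiet),
                           data.frame(prox = 1, dist = 2, G = G, P = 0.5))
    backprop_attenuation(m, 0.15)[["dend"]]
  }, numeric(1))
  expect_true(all(diff(att) < 0))
  expect_true(all(att >= 0 & att <= 1))
  # chain: distal attenuation at least proximal attenuation
  chain <- compartment_model(
    list(soma = p, mid = quiet, tip = quiet),
    data.frame(prox = c(1, 2), dist = c(2, 3), G = c(10, 10), P = c(0.5, 0.5)))
  att_chain <- backprop_attenuation(chain, 0.15)
  expect_gte(att_chain[["tip"]], att_chain[["mid"]])
})

test_that("rebound spiking requires b > 0 and grows easier with b", {
  # integrator (b < 0): no rebound up to the search bound
  expect_true(is.na(rebound_rheobase(rs_params(b = -2))))
  # sweep: no b <= 0 model rebounds, across parameter variations
  set.seed(3)
  for (i in 1:10) {
    p <- izhi_params(runif(1, 50, 150), runif(1, 0.5, 1.2), -60,
                     runif(1, -45, -38), 35, runif(1, -55, -45),
                     runif(1, 0.01, 0.1), runif(1, -8, 0),
                     runif(1, 0, 150))
    expect_true(is.na(rebound_rheobase(p)))
  }
  # increasing b from +5 to +50 makes rebound no harder
  rr <- vapply(c(5, 20, 50), function(b)
    rebound_rheobase(rs_params(b = b)), numeric(1))
  rr[is.na(rr)] <- Inf
  expect_true(all(diff(rr) <= 0))
  # plateau: beyond +50 the rebound rheobase changes little (qualitative)
  r50 <- rebound_rheobase(rs_params(b = 50))
  r100 <- rebound_rheobase(rs_params(b = 100))
  expect_lt(abs(r100 - r50) / r50, 0.3)
})

test_that("proximal depolarization gates distal-to-somatic propagation", {
  p <- rs_params(b = 0, d = 60)
  quiet <- izhi_params(60, 0.5, -60, -35, 35, -45, 0.03, 0, 40)
  m <- compartment_model(
    list(soma = p, prox = quiet, dist = quiet),
    data.frame(prox = c(1, 2), dist = c(2, 3), G = c(10, 20), P = c(0.45, 0.45)))
  counts <- gating_probe(m, distal = 3, proximal = 2, depol_pA = 70)
  expect_equal(counts[["without"]], 0)
  expect_gte(counts[["with"]], 1)
  expect_error(gating_probe(m, distal = 3, proximal = 2, depol_pA = 70,
                            n_synapses = 1, weight = 0.01), "subthreshold")
})

test_that("probe reports are deterministic", {
  m <- two_comp(25, 0.4)
  expect_equal(probe_model(m), probe_model(m))
})
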