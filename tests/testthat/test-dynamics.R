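test_that("resting state is an equilibrium: zero input holds V at Vr", {
  p <- rs_params()
  tr <- simulate_model(p, step = NULL, total_time = 500)
  expect_equal(max(abs(tr$V[, 1] - p$Vr)), 0)
  expect_equal(max(abs(tr$U[, 1])), 0)
  expect_length(spike_times(tr), 0)
})

test_that("coupling currents follow the asymmetric coupling law", {
  cs <- coupling_spec(10, 0.5)
  expect_equal(coupling_currents(cs, -50, -60),
               c(Iprox = 50, Idist = -50))
  expect_equal(coupling_currents(cs, -55, -55), c(Iprox = 0, Idist = 0))
  # backward-dominant coupling: much weaker toward the soma
  asym <- coupling_currents(coupling_spec(10, 0.1), -50, -60)
  expect_equal(unname(asym), c(10, -90))
  expect_gt(abs(asym["Idist"]), abs(asym["Iprox"]))
})

test_that("symmetric twin compartments stay identical with zero net coupling", {
  p <- rs_params()
  m <- compartment_model(list(soma = p, dend = p),
                         data.frame(prox = 1, dist = 2, G = 10, P = 0.5))
  st1 <- step_stimulus(70, 100, 500, total_time = 700, target = 1)
  st2 <- step_stimulus(70, 100, 500, total_time = 700, target = 2)
  tr <- simulate_model(m, list(st1, st2))
  expect_equal(tr$V[, 1], tr$V[, 2])
  # P = 0.5 means the interaction currents cancel edge-wise at every step
  expect_equal(tr$spikes[[1]], tr$spikes[[2]])
})

test_that("spike count matches the independent high-resolution integrator", {
  p <- rs_params()
  tr <- simulate_model(p, step_stimulus(70, 100, 1000), dt = 0.1)
  ref <- euler_reference(p, 70, 100, 1000, 1200, dt = 0.001)
  expect_lte(abs(length(spike_times(tr)) - length(ref)), 1)
})

test_that("reset contract: V = Vmin after each spike and U jumps by d", {
  p <- rs_params()
  tr <- simulate_model(p, step_stimulus(120, 100, 1000), dt = 0.1)
  spikes <- spike_times(tr)
  expect_gt(length(spikes), 3)
  idx <- match(round(spikes, 10), round(tr$time, 10))
  expect_false(anyNA(idx))
  expect_true(all(tr$V[idx, 1] == p$Vmin))
  # U immediately after the spike exceeds U just before by at least d's order
  jumps <- tr$U[idx, 1] - tr$U[idx - 1, 1]
  expect_true(all(jumps > 0.9 * p$d))
})

test_that("halving dt moves canonical spike times by less than 1 ms", {
  p <- rs_params()
  s1 <- spike_times(simulate_model(p, step_stimulus(70, 100, 1000), dt = 0.1))
  s2 <- spike_times(simulate_model(p, step_stimulus(70, 100, 1000),
                                   dt = 0.05))
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 1)
})

test_that("steady-state deflection approaches the linearized closed form", {
  # small hyperpolarizing steps: dV = I / (k (Vt - Vr) + b), within 5%
  p <- rs_params()  # k = 0.7, Vt - Vr = 20, b = -2 -> denominator 12 nS
  for (I in c(-2, -5)) {
    predicted <- I / (p$k * (p$Vt - p$Vr) + p$b)
    measured <- voltage_deflection(p, I / 1000)
    expect_lt(abs(measured - predicted) / abs(predicted), 0.05)
  }
})

test_that("interaction currents sum to zero over every edge when P = 0.5", {
  cs <- coupling_spec(8, 0.5)
  set.seed(4)
  for (i in 1:20) {
    v <- runif(2, -80, 30)
    cc <- coupling_currents(cs, v[1], v[2])
    expect_equal(unname(cc[["Iprox"]] + cc[["Idist"]]), 0)
  }
})

test_that("divergent parameters abort with a diagnostic, not garbage", {
  # recovery rate far above the stability limit of the step: U oscillates
  # with growing amplitude until the state overflows
  p <- izhi_params(100, 0.7, -60, -40, 35, -50, 5, -2, 100)
  expect_error(simulate_model(p, step_stimulus(70, 0, 1000), dt = 1),
               "diverged")
})

test_that("stimuli referencing missing compartments are rejected", {
  expect_error(simulate_model(rs_params(),
                              step_stimulus(50, 100, 100, target = 3)),
               "non-existent")
})

test_that("model construction enforces the parameter invariants", {
  expect_error(izhi_params(-1, 0.7, -60, -40, 35, -50, 0.03, -2, 100), "C")
  expect_error(izhi_params(100, 0.7, -40, -60, 35, -50, 0.03, -2, 100),
               "Vr < Vt")
  expect_error(compartment_model(list(
    soma = rs_params(),
    dend = izhi_params(100, 0.7, -55, -40, 35, -50, 0.03, -2, 100)),
    data.frame(prox = 1, dist = 2, G = 5, P = 0.5)), "single Vr")
  expect_error(coupling_spec(-1, 0.5), "G")
  expect_error(coupling_spec(1, 1.5), "P")
})
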