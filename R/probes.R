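# Standardized in-silico experiments on a model: rheobase, input resistance
# (voltage deflection), spike propagation, EPSP amplitude, back-propagation
# attenuation, rebound excitability, and dendro-somatic gating. All probes are
# deterministic given dt; currents are quoted in nA at this interface.

probe_step <- function(amp_nA, duration = 1000, onset = 100, target = 1L) {
  step_stimulus(amp_nA, onset = onset, duration = duration,
                total_time = onset + duration + 100, target = target,
                units = "nA")
}

#' Rheobase of a decoupled compartment
#'
#' Minimum depolarizing step current eliciting at least one spike, found by
#' bisection on the amplitude of a 1-s step. For `b = 0` the saddle-node
#' current `k (Vt - Vr)^2 / 4` is a closed-form lower bound the measured value
#' approaches from above.
#'
#' @param params An [izhi_params()] (probes run on decoupled compartments).
#' @param lo,hi Search bracket (nA); `hi` must elicit a spike.
#' @param tol Bisection tolerance (nA).
#' @param dt Integration step (ms).
#' @param duration Step duration (ms).
#' @return Rheobase (nA).
#' @examples
#' p <- izhi_params(100, 0.7, -60, -40, 35, -50, 0.03, 0, 100)
#' find_rheobase(p)  # close to 0.07 nA
#' @export
find_rheobase <- function(params, lo = 0, hi = 1, tol = 0.001, dt = 0.1,
                          duration = 1000) {
  stopifnot(inherits(params, "izhi_params"), hi > lo, tol > 0)
  model <- point_model(params)
  spikes_at <- function(a) {
    tr <- simulate_model(model, probe_step(a, duration), dt = dt,
                         record = FALSE)
    length(spike_times(tr))
  }
  if (spikes_at(hi) == 0)
    stop("no spike at the upper search bound ", hi, " nA", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Steady-state voltage deflection under hyperpolarization
#'
#' The steady-state displacement of V from rest for a long hyperpolarizing
#' step in a decoupled compartment; the in-silico input-resistance probe. In
#' the linear regime the closed form is `I / (k (Vt - Vr) + b)`.
#'
#' @param params An [izhi_params()].
#' @param I_hyp Step amplitude (nA), negative.
#' @param dt Integration step (ms).
#' @param duration Step duration (ms), long enough to settle.
#' @return Deflection (mV, negative for hyperpolarizing input).
#' @export
voltage_deflection <- function(params, I_hyp, dt = 0.1, duration = 1000) {
  stopifnot(inherits(params, "izhi_params"), I_hyp <= 0)
  if (I_hyp == 0) return(0)
  st <- probe_step(I_hyp, duration)
  tr <- simulate_model(point_model(params), st, dt = dt)
  if (length(spike_times(tr)))
    stop("hyperpolarizing probe elicited a spike; invalid probe",
         call. = FALSE)
  i_end <- max(which(tr$time <= st$onset + st$duration))
  tr$V[i_end, 1] - params$Vr
}

adjacent_proximal <- function(model, idx) {
  e <- model$edges
  hit <- which(e$dist == idx)
  if (length(hit)) return(e$prox[hit[1]])
  NA_integer_
}

#' Forward spike-propagation ratio
#'
#' A synaptic volley (many co-active AMPA synapses) drives a dendritic
#' compartment to spike; `R` is the ratio of spike counts at the adjacent
#' proximal compartment to those at the source over the stimulation window.
#'
#' @param model A [compartment_model()] with at least 2 compartments.
#' @param source Dendritic compartment index.
#' @param n_synapses,weight Synaptic drive (defaults: 100 synapses, weight 10).
#' @param events Presynaptic event times (ms); default a 5-event volley.
#' @param dt Integration step (ms).
#' @return `R` in `[0, Inf)` (capped quantities upstream keep it in `[0, 1]`
#'   for tree layouts), or `NA` when the source fails to spike (distinct from
#'   a true `R = 0`).
#' @export
propagation_ratio <- function(model, source = 2L, n_synapses = 100,
                              weight = 10, events = seq(200, 600, by = 100),
                              dt = 0.1) {
  stopifnot(inherits(model, "compartment_model"), n_compartments(model) >= 2)
  dest <- adjacent_proximal(model, source)
  if (is.na(dest)) stop("source has no proximal neighbour", call. = FALSE)
  syn <- syn_stimulus(source, events, weight = weight,
                      n_synapses = n_synapses)
  tr <- simulate_model(model, step = NULL, syn = syn,
                       total_time = max(events) + 400, dt = dt,
                       record = FALSE)
  ns <- length(tr$spikes[[source]])
  if (ns == 0) return(NA_real_)
  length(tr$spikes[[dest]]) / ns
}

#' Somatic EPSP amplitude for a single dendritic synapse
#'
#' One AMPA synapse is activated once at a dendritic compartment; the probe
#' reports the peak somatic depolarization above the pre-event baseline. The
#' stimulation must stay subthreshold everywhere.
#'
#' @param model A [compartment_model()].
#' @param target Dendritic compartment index.
#' @param weight Synaptic weight (10 by convention).
#' @param dt Integration step (ms).
#' @return EPSP amplitude at the soma (mV).
#' @export
epsp_amplitude <- function(model, target = 2L, weight = 10, dt = 0.1) {
  stopifnot(inherits(model, "compartment_model"))
  if (weight == 0) return(0)
  t_ev <- 200
  syn <- syn_stimulus(target, t_ev, weight = weight, n_synapses = 1)
  tr <- simulate_model(model, syn = syn, total_time = t_ev + 300, dt = dt)
  if (any(lengths(tr$spikes) > 0))
    stop("EPSP probe elicited a spike; invalid probe", call. = FALSE)
  i0 <- which(tr$time >= t_ev)[1]
  soma <- model$soma
  max(tr$V[i0:nrow(tr$V), soma]) - tr$V[i0, soma]
}

#' Back-propagation attenuation of the first somatic spike
#'
#' A somatic step elicits spiking; spike amplitude in each compartment is
#' measured as `max(V) - Vmin` within a +/-2 ms window around the first
#' somatic spike, and attenuation is one minus the ratio to the somatic
#' amplitude.
#'
#' @param model A [compartment_model()].
#' @param amp_nA Somatic step amplitude (nA).
#' @param dt Integration step (ms).
#' @param window Half-width (ms) of the first-spike window.
#' @return Named vector of attenuation fractions for non-somatic
#'   compartments, capped at 1 (a compartment whose excursion never exceeds
#'   its own reset baseline is fully attenuated).
#' @export
backprop_attenuation <- function(model, amp_nA, dt = 0.1, window = 2) {
  stopifnot(inherits(model, "compartment_model"), n_compartments(model) >= 2)
  st <- probe_step(amp_nA, duration = 1000, target = model$soma)
  tr <- simulate_model(model, st, dt = dt)
  soma_spikes <- spike_times(tr)
  if (!length(soma_spikes))
    stop("no somatic spike at ", amp_nA, " nA; attenuation undefined",
         call. = FALSE)
  t1 <- soma_spikes[1]
  idx <- which(tr$time >= t1 - window & tr$time <= t1 + window)
  par <- model_par_matrix(model)
  amps <- vapply(seq_len(n_compartments(model)), function(j)
    max(tr$V[idx, j]) - par[j, "Vmin"], numeric(1))
  soma_amp <- amps[model$soma]
  out <- 1 - pmax(amps, 0) / soma_amp
  names(out) <- names(model$compartments)
  out[-model$soma]
}

#' Rebound rheobase
#'
#' Minimum-magnitude hyperpolarizing step (500 ms) whose release elicits at
#' least one spike within the following 500 ms. Only resonator-type models
#' (`b > 0`) can rebound; integrators return `NA`.
#'
#' @param model A [compartment_model()] or [izhi_params()].
#' @param max_amp Search bound on `|I|` (nA).
#' @param tol Bisection tolerance (nA).
#' @param dt Integration step (ms).
#' @return Rebound rheobase (nA, magnitude), or `NA` if none up to `max_amp`.
#' @export
rebound_rheobase <- function(model, max_amp = 1, tol = 0.001, dt = 0.1) {
  if (inherits(model, "izhi_params")) model <- point_model(model)
  rebound_spikes <- function(a) {
    st <- step_stimulus(-a, onset = 100, duration = 500, total_time = 1100,
                        target = model$soma, units = "nA")
    tr <- tryCatch(simulate_model(model, st, dt = dt, record = FALSE),
                   error = function(e) NULL)
    if (is.null(tr)) return(0L)
    sum(spike_times(tr) > 600)
  }
  if (rebound_spikes(max_amp) == 0) return(NA_real_)
  lo <- 0; hi <- max_amp
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rebound_spikes(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Dendro-somatic gating probe
#'
#' A distal synaptic volley initiates dendritic spikes; the probe counts
#' somatic spikes without and with an additional subthreshold depolarizing
#' step at the proximal compartment. Gating is demonstrated when the volley
#' alone fails to fire the soma but succeeds with the proximal depolarization.
#'
#' @param model A [compartment_model()] with a chain layout (soma, proximal,
#'   distal ...).
#' @param distal Distal compartment index.
#' @param proximal Proximal compartment index receiving the depolarization.
#' @param depol_pA Proximal depolarization amplitude (pA), subthreshold alone.
#' @param n_synapses,weight,events Distal synaptic volley.
#' @param dt Integration step (ms).
#' @return Named integer vector `c(without =, with =)` of somatic spikes.
#' @export
gating_probe <- function(model, distal, proximal, depol_pA,
                         n_synapses = 100, weight = 10,
                         events = seq(200, 600, by = 100), dt = 0.1) {
  stopifnot(inherits(model, "compartment_model"))
  syn <- syn_stimulus(distal, events, weight = weight,
                      n_synapses = n_synapses)
  total <- max(events) + 400
  run <- function(dep) {
    st <- if (dep != 0)
      list(step_stimulus(dep, onset = 100, duration = total - 100,
                         total_time = total, target = proximal)) else NULL
    simulate_model(model, step = st, syn = syn, total_time = total, dt = dt,
                   record = FALSE)
  }
  tr0 <- run(0)
  if (!length(tr0$spikes[[distal]]))
    stop("distal stimulation is subthreshold; gating probe invalid",
         call. = FALSE)
  tr1 <- run(depol_pA)
  c(without = length(tr0$spikes[[model$soma]]),
    with = length(tr1$spikes[[model$soma]]))
}

#' Full constraint-probe report for a model
#'
#' Runs the decoupled rheobase and voltage-deflection probes on every
#' compartment, the forward propagation ratio and somatic EPSP amplitude for
#' every dendritic compartment, and assembles the per-dendrite constraint
#' errors.
#'
#' @param model A [compartment_model()].
#' @param I_hyp Hyperpolarizing probe current (nA).
#' @param dt Integration step (ms).
#' @return A tibble, one row per dendritic compartment, with probe values and
#'   the four constraint errors (all zero for an accepted model). For a point
#'   neuron, a zero-row tibble.
#' @export
probe_model <- function(model, I_hyp = -0.05, dt = 0.1) {
  stopifnot(inherits(model, "compartment_model"))
  nc <- n_compartments(model)
  if (nc == 1)
    return(tibble::tibble(compartment = character(0), rheobase_nA = numeric(0),
                          vdef_mV = numeric(0), R = numeric(0),
                          epsp_mV = numeric(0), rheo = numeric(0),
                          vdef = numeric(0), prop = numeric(0),
                          epsp = numeric(0)))
  rheo <- vapply(model$compartments, function(p)
    find_rheobase(p, dt = dt), numeric(1))
  vdef <- vapply(model$compartments, function(p)
    voltage_deflection(p, I_hyp, dt = dt), numeric(1))
  dend <- setdiff(seq_len(nc), model$soma)
  R <- vapply(dend, function(j) {
    r <- propagation_ratio(model, j, dt = dt)
    if (is.na(r)) 0 else min(r, 1)
  }, numeric(1))
  ep <- vapply(dend, function(j)
    tryCatch(epsp_amplitude(model, j, dt = dt),
             error = function(e) NA_real_), numeric(1))
  ep_filled <- ifelse(is.na(ep), 10, ep)  # spiking EPSP probe: out of window
  ce <- constraint_errors(rheo[model$soma], rheo[dend],
                          vdef[model$soma], vdef[dend], R, ep_filled)
  dplyr::bind_cols(
    tibble::tibble(compartment = names(model$compartments)[dend],
                   rheobase_nA = rheo[dend], vdef_mV = vdef[dend],
                   R = R, epsp_mV = ep),
    ce
  )
}
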