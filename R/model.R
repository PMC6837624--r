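#' Izhikevich model parameters for one compartment
#'
#' The nine-parameter quadratic integrate-and-fire formulation with a linear
#' recovery variable. The membrane equation is
#' \deqn{C\,dV/dt = k (V - V_r)(V - V_t) - U + I}
#' \deqn{dU/dt = a (b (V - V_r) - U)}
#' with the reset rule: when \eqn{V \ge V_{peak}}, \eqn{V \leftarrow V_{min}}
#' and \eqn{U \leftarrow U + d}.
#'
#' Internal units are mV, ms, pA, pF and nS throughout; stimulus amplitudes
#' quoted in nA (the convention of the experimental literature) are converted
#' at the user interface.
#'
#' @param C Membrane capacitance (pF), positive.
#' @param k Quadratic gain (pA/mV^2), positive. Larger `k` sharpens the
#'   spike upstroke and raises the current needed to spike.
#' @param Vr Resting potential (mV).
#' @param Vt Instantaneous threshold potential (mV), must exceed `Vr`.
#' @param Vpeak Spike cutoff (mV); reaching it registers a spike.
#' @param Vmin Post-spike reset voltage (mV), below `Vpeak`.
#' @param a Recovery time-scale (1/ms); small values give slow adaptation.
#' @param b Recovery sensitivity to voltage (nS); `b > 0` makes the model a
#'   resonator capable of rebound spiking, `b < 0` an integrator.
#' @param d Recovery increment at each spike (pA); large values produce
#'   strong spike-frequency adaptation or bursting.
#'
#' @return An object of class `izhi_params` (a named list of the nine values).
#' @examples
#' rs <- izhi_params(C = 100, k = 0.7, Vr = -60, Vt = -40, Vpeak = 35,
#'                   Vmin = -50, a = 0.03, b = -2, d = 100)
#' rs
#' @export
izhi_params <- function(C, k, Vr, Vt, Vpeak, Vmin, a, b, d) {
  p <- list(C = C, k = k, Vr = Vr, Vt = Vt, Vpeak = Vpeak, Vmin = Vmin,
            a = a, b = b, d = d)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                   logical(1)))
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (!(Vr < Vt && Vt < Vpeak)) stop("need Vr < Vt < Vpeak", call. = FALSE)
  if (!(Vmin < Vpeak)) stop("need Vmin < Vpeak", call. = FALSE)
  structure(p, class = "izhi_params")
}

#' @export
print.izhi_params <- function(x, ...) {
  cat("<izhi_params> ", paste(names(x), unlist(x), sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.izhi_params <- function(x, ...) as.data.frame(unclass(x))

param_names <- c("C", "k", "Vr", "Vt", "Vpeak", "Vmin", "a", "b", "d")

#' Electrical coupling between two compartments
#'
#' Asymmetric resistive coupling. For an edge joining a proximal and a distal
#' compartment the interaction currents are
#' \deqn{I_{prox} = G P (V_{prox} - V_{dist}), \quad
#'       I_{dist} = G (1-P) (V_{dist} - V_{prox}),}
#' each subtracted from its compartment's current balance, so current flow
#' always reduces the voltage difference. `G*P` is the forward (dendrite to
#' soma) coupling strength and `G*(1-P)` the backward strength; `P < 0.5`
#' therefore means weaker coupling toward the soma than away from it.
#'
#' @param G Coupling strength (nS), non-negative.
#' @param P Asymmetry fraction in `[0, 1]`.
#' @return An object of class `coupling_spec`.
#' @examples
#' coupling_currents(coupling_spec(10, 0.1), Vprox = -50, Vdist = -60)
#' @export
coupling_spec <- function(G, P) {
  stopifnot(is.numeric(G), is.numeric(P), length(G) == 1, length(P) == 1)
  if (G < 0) stop("G must be >= 0", call. = FALSE)
  if (P < 0 || P > 1) stop("P must lie in [0, 1]", call. = FALSE)
  structure(list(G = G, P = P), class = "coupling_spec")
}

#' Interaction currents across one coupling edge
#'
#' @param c A [coupling_spec()].
#' @param Vprox,Vdist Membrane potentials (mV) of the proximal and distal
#'   compartments.
#' @return Named numeric vector `c(Iprox =, Idist =)` in pA.
#' @export
coupling_currents <- function(c, Vprox, Vdist) {
  stopifnot(inherits(c, "coupling_spec"))
  c(Iprox = c$G * c$P * (Vprox - Vdist),
    Idist = c$G * (1 - c$P) * (Vdist - Vprox))
}

#' Single- or compact multi-compartment model
#'
#' A tree of up to four Izhikevich compartments joined by asymmetric electrical
#' coupling. Every compartment carries its own parameter set except the
#' resting potential `Vr`, which is shared (enforced at construction). With a
#' single compartment the object degenerates to a point neuron.
#'
#' @param compartments A named list of [izhi_params()]; names are layer labels
#'   (e.g. `"soma"`, `"SR"`, `"SLM"`).
#' @param edges `NULL` for a point neuron, otherwise a data frame with columns
#'   `prox`, `dist` (compartment indices), `G`, `P` describing a tree rooted at
#'   the soma.
#' @param soma Index of the somatic compartment (default 1).
#' @return An object of class `compartment_model`.
#' @examples
#' soma <- izhi_params(100, 0.7, -60, -40, 35, -50, 0.03, -2, 100)
#' point_model(soma)
#' @export
compartment_model <- function(compartments, edges = NULL, soma = 1L) {
  stopifnot(is.list(compartments), length(compartments) >= 1)
  if (length(compartments) > 4)
    stop("at most 4 compartments are supported", call. = FALSE)
  if (is.null(names(compartments)) || anyNA(names(compartments)) ||
      any(names(compartments) == ""))
    stop("compartments must be a named list (layer labels)", call. = FALSE)
  lapply(compartments, function(p) stopifnot(inherits(p, "izhi_params")))
  vr <- vapply(compartments, `[[`, numeric(1), "Vr")
  if (diff(range(vr)) > 1e-9)
    stop("all compartments must share a single Vr", call. = FALSE)
  nc <- length(compartments)
  if (is.null(edges)) {
    edges <- data.frame(prox = integer(), dist = integer(),
                        G = numeric(), P = numeric())
  }
  edges <- as.data.frame(edges)
  stopifnot(all(c("prox", "dist", "G", "P") %in% names(edges)))
  if (nrow(edges) != nc - 1)
    stop("a tree on ", nc, " compartments needs ", nc - 1, " edges",
         call. = FALSE)
  if (nrow(edges)) {
    idx <- c(edges$prox, edges$dist)
    if (any(idx < 1 | idx > nc)) stop("edge index out of range", call. = FALSE)
    if (any(edges$G < 0) || any(edges$P < 0 | edges$P > 1))
      stop("edge coupling must have G >= 0 and P in [0, 1]", call. = FALSE)
    # connectivity check: n-1 edges + connected => tree
    reach <- soma
    repeat {
      grow <- unique(c(edges$dist[edges$prox %in% reach],
                       edges$prox[edges$dist %in% reach]))
      grow <- setdiff(grow, reach)
      if (!length(grow)) break
      reach <- c(reach, grow)
    }
    if (length(reach) != nc)
      stop("edges must form a tree rooted at the soma", call. = FALSE)
  }
  structure(list(compartments = compartments, edges = edges,
                 soma = as.integer(soma)),
            class = "compartment_model")
}

#' @rdname compartment_model
#' @param params An [izhi_params()] for the single compartment.
#' @param layer Layer label for the single compartment.
#' @export
point_model <- function(params, layer = "soma") {
  compartment_model(setNames(list(params), layer))
}

#' @export
print.compartment_model <- function(x, ...) {
  cat("<compartment_model> ", length(x$compartments), " compartment(s): ",
      paste(names(x$compartments), collapse = ", "), "\n", sep = "")
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  edge %d->%d  G=%g nS  P=%g\n", x$edges$prox[i],
                  x$edges$dist[i], x$edges$G[i], x$edges$P[i]))
  }
  invisible(x)
}

n_compartments <- function(model) length(model$compartments)

model_par_matrix <- function(model) {
  m <- t(vapply(model$compartments, function(p) unlist(p[param_names]),
                numeric(9)))
  dimnames(m) <- list(names(model$compartments), param_names)
  m
}

#' Step-current stimulus
#'
#' @param amplitude Signed step amplitude.
#' @param onset Stimulus onset (ms). A settling window before onset (100 ms by
#'   default in the fixtures) lets the state relax from its initial value.
#' @param duration Step duration (ms).
#' @param total_time Total simulated time (ms); must cover the step.
#' @param target Compartment index receiving the current.
#' @param units `"pA"` or `"nA"` for `amplitude`.
#' @return An object of class `step_stimulus`; amplitude stored in pA.
#' @examples
#' step_stimulus(70, onset = 100, duration = 1000)
#' @export
step_stimulus <- function(amplitude, onset = 100, duration = 1000,
                          total_time = onset + duration + 100, target = 1L,
                          units = c("pA", "nA")) {
  units <- match.arg(units)
  amp <- if (units == "nA") amplitude * 1000 else amplitude
  stopifnot(onset >= 0, duration >= 0)
  if (onset + duration > total_time + 1e-9)
    stop("onset + duration must not exceed total_time", call. = FALSE)
  structure(list(amplitude = amp, onset = onset, duration = duration,
                 total_time = total_time, target = as.integer(target)),
            class = "step_stimulus")
}

#' Synaptic (AMPA-like) stimulus
#'
#' Instantaneous-rise, single-exponential conductance synapse. Each event adds
#' `weight * g_unit * n_synapses` nS to the conductance, which decays with time
#' constant `tau` and drives current `g * (E_rev - V)`.
#'
#' @param target Compartment index.
#' @param event_times Event (presynaptic spike) times, ms.
#' @param weight Dimensionless synaptic weight (10 by convention).
#' @param n_synapses Number of co-activated synapses (1 for EPSP probes,
#'   50-200 for spike-initiation probes).
#' @param tau Conductance decay time constant (ms).
#' @param E_rev Reversal potential (mV); 0 for AMPA.
#' @param g_unit Conductance per unit weight per synapse (nS).
#' @return An object of class `syn_stimulus`.
#' @export
syn_stimulus <- function(target, event_times, weight = 10, n_synapses = 1,
                         tau = 5, E_rev = 0, g_unit = 0.1) {
  stopifnot(n_synapses >= 1, weight >= 0, tau > 0)
  structure(list(target = as.integer(target),
                 events = as.numeric(event_times),
                 g_inc = weight * g_unit * n_synapses,
                 tau = tau, erev = E_rev),
            class = "syn_stimulus")
}
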