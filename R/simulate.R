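#' Simulate a compartment model
#'
#' Forward-Euler integration at a fixed step of the coupled Izhikevich
#' equations with the spike-reset rule. The initial state is `(Vr, 0)` in
#' every compartment unless overridden; spikes are stamped at the first step
#' whose voltage reaches `Vpeak` of the compartment.
#'
#' @param model A [compartment_model()] (or a bare [izhi_params()], promoted to
#'   a point neuron).
#' @param step A [step_stimulus()], a list of them, or `NULL`.
#' @param syn A [syn_stimulus()], a list of them, or empty.
#' @param dt Integration step (ms). The default 0.1 ms resolves the spike
#'   upstroke for the parameter magnitudes typical of hippocampal fits.
#' @param total_time Total simulated time (ms); defaults to the largest
#'   stimulus `total_time`, or 1000 ms with no stimulus.
#' @param V0,U0 Optional initial state vectors (per compartment).
#' @param record Keep the full V/U series (`TRUE`) or only spike times
#'   (`FALSE`, used in the inner loop of the evolutionary search).
#' @return A `voltage_trace`: list with `dt`, `time`, matrices `V`, `U`
#'   (time by compartment; `NULL` when `record = FALSE`), `spikes` (list of
#'   spike-time vectors per compartment), and the stimuli used.
#' @examples
#' rs <- izhi_params(100, 0.7, -60, -40, 35, -50, 0.03, -2, 100)
#' tr <- simulate_model(rs, step_stimulus(70, 100, 1000))
#' length(spike_times(tr))
#' @export
simulate_model <- function(model, step = NULL, syn = list(), dt = 0.1,
                           total_time = NULL, V0 = NULL, U0 = NULL,
                           record = TRUE) {
  if (inherits(model, "izhi_params")) model <- point_model(model)
  stopifnot(inherits(model, "compartment_model"), dt > 0)
  nc <- n_compartments(model)
  if (inherits(step, "step_stimulus")) step <- list(step)
  if (inherits(syn, "syn_stimulus")) syn <- list(syn)
  stopifnot(all(vapply(step, inherits, logical(1), "step_stimulus")),
            all(vapply(syn, inherits, logical(1), "syn_stimulus")))
  targets <- c(vapply(step, `[[`, integer(1), "target"),
               vapply(syn, `[[`, integer(1), "target"))
  if (any(targets < 1 | targets > nc))
    stop("stimulus targets a non-existent compartment", call. = FALSE)
  if (is.null(total_time)) {
    total_time <- if (length(step))
      max(vapply(step, `[[`, numeric(1), "total_time")) else 1000
  }
  par <- model_par_matrix(model)
  stepm <- if (length(step)) {
    do.call(rbind, lapply(step, function(s)
      c(s$target, s$amplitude, s$onset, s$duration)))
  } else matrix(numeric(0), 0, 4)
  synl <- lapply(syn, unclass)
  if (is.null(V0)) V0 <- par[, "Vr"]
  if (is.null(U0)) U0 <- rep(0, nc)
  out <- sim_izhi_cpp(par, as.integer(model$edges$prox),
                      as.integer(model$edges$dist),
                      as.numeric(model$edges$G), as.numeric(model$edges$P),
                      stepm, synl, dt, total_time,
                      as.numeric(V0), as.numeric(U0), record)
  if (!out$ok)
    stop("simulation diverged (non-finite state) at t = ",
         format(out$bad_step * dt), " ms; parameters are dynamically unstable",
         call. = FALSE)
  spikes <- lapply(out$spikes, as.numeric)
  names(spikes) <- names(model$compartments)
  structure(list(dt = dt,
                 time = if (record) seq(0, total_time, by = dt),
                 V = out$V, U = out$U, spikes = spikes,
                 layers = names(model$compartments), soma = model$soma,
                 step = step, syn = syn),
            class = "voltage_trace")
}

#' Spike times from a trace
#'
#' @param trace A `voltage_trace`.
#' @param compartment Index or layer name (default: the soma).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
spike_times <- function(trace, compartment = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.null(compartment)) compartment <- trace$soma
  trace$spikes[[compartment]]
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace> ", length(x$time) - 1, " steps of ", x$dt, " ms, ",
      length(x$layers), " compartment(s)\n", sep = "")
  for (j in seq_along(x$layers))
    cat(sprintf("  %s: %d spikes\n", x$layers[j], length(x$spikes[[j]])))
  invisible(x)
}

#' Tidy a voltage trace into a long tibble
#'
#' @param x A `voltage_trace`.
#' @param ... Unused.
#' @return A tibble with columns `time_ms`, `compartment`, `V_mV`, `U_pA`.
#' @export
as_tibble.voltage_trace <- function(x, ...) {
  if (is.null(x$V))
    stop("trace was simulated with record = FALSE; no series stored",
         call. = FALSE)
  tibble::tibble(
    time_ms = rep(x$time, times = length(x$layers)),
    compartment = rep(x$layers, each = length(x$time)),
    V_mV = as.vector(x$V),
    U_pA = as.vector(x$U)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plot a voltage trace
#'
#' One panel per compartment, membrane potential against time, with the
#' stimulus window shaded.
#'
#' @param object A `voltage_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voltage_trace <- function(object, ...) {
  df <- as_tibble(object)
  df$compartment <- factor(df$compartment, levels = object$layers)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$V_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
  if (length(object$step)) {
    s <- object$step[[1]]
    p <- p + ggplot2::annotate("rect", xmin = s$onset,
                               xmax = s$onset + s$duration,
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p
}
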