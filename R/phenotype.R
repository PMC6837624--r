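# Fitting targets: a phenotype is a set of per-stimulus target patterns
# (class label plus any quantitative features printed for that trace), an
# optional rebound-spiking requirement, and the compartment layout to fit.

#' One target pattern of a phenotype
#'
#' @param amplitude_nA Injected step current (nA), or `NA` when the
#'   experimental amplitude is unknown (then `bracket_nA` is searched as an
#'   extra gene).
#' @param label Target class label (dot notation string).
#' @param features Named list of quantitative targets (any of `fsl`, `pss`,
#'   `sfa`, `n_isis`, `bw`, `pbi`, `n_bursts`, `b_n_isis`); empty for
#'   class-only targets.
#' @param bracket_nA Search bracket `c(lo, hi)` (nA) for an unknown amplitude.
#' @param onset,duration Stimulus timing (ms).
#' @param current_window Half-width (nA) of the admissible window around
#'   `amplitude_nA`: the model is driven at a current within +/- this value
#'   of the experimental one (20 pA total range by convention).
#' @return A `pattern_target`.
#' @export
pattern_target <- function(amplitude_nA, label, features = list(),
                           bracket_nA = NULL, onset = 100, duration = 1000,
                           current_window = 0.01) {
  lab <- parse_label(label)
  amplitude_nA <- as.numeric(amplitude_nA)
  if (is.na(amplitude_nA) && is.null(bracket_nA))
    stop("unknown amplitude needs a bracket_nA", call. = FALSE)
  known <- c("fsl", "pss", "sfa", "n_isis", "bw", "pbi", "n_bursts",
             "b_n_isis")
  if (length(features) && !all(names(features) %in% known))
    stop("unknown feature name(s): ",
         paste(setdiff(names(features), known), collapse = ", "),
         call. = FALSE)
  structure(list(amplitude_nA = amplitude_nA, bracket_nA = bracket_nA,
                 label = lab, features = features, onset = onset,
                 duration = duration, current_window = current_window),
            class = "pattern_target")
}

#' A firing-pattern phenotype to fit
#'
#' @param name Phenotype (neuron type) name.
#' @param patterns List of [pattern_target()]s, at least one.
#' @param n_compartments 1 (point neuron) to 4 (compact multi-compartment
#'   chain: soma, then successively more distal compartments).
#' @param rebound_nA Hyperpolarizing current (nA, negative) at which the
#'   model must produce rebound spikes, or `NULL` for no requirement.
#' @param thresholds Classifier thresholds used for both target parsing and
#'   model verification.
#' @param experimental_features Optional list mirroring `patterns` with the
#'   features of the recorded traces when those differ from the model
#'   constraints (kept for reporting, not used by the fit).
#' @param source Free-text provenance note.
#' @return A `phenotype_spec`.
#' @export
phenotype_spec <- function(name, patterns, n_compartments = 1L,
                           rebound_nA = NULL,
                           thresholds = class_thresholds(),
                           experimental_features = NULL, source = NULL) {
  stopifnot(length(patterns) >= 1,
            all(vapply(patterns, inherits, logical(1), "pattern_target")),
            n_compartments >= 1, n_compartments <= 4)
  if (!is.null(rebound_nA)) stopifnot(rebound_nA < 0)
  structure(list(name = name, patterns = patterns,
                 n_compartments = as.integer(n_compartments),
                 rebound_nA = rebound_nA, thresholds = thresholds,
                 experimental_features = experimental_features,
                 source = source),
            class = "phenotype_spec")
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat("<phenotype_spec> ", x$name, " (", x$n_compartments,
      " compartment(s), ", length(x$patterns), " pattern(s))\n", sep = "")
  for (p in x$patterns) {
    amp <- if (is.na(p$amplitude_nA))
      sprintf("* in [%g, %g]", p$bracket_nA[1], p$bracket_nA[2])
    else sprintf("%+g", p$amplitude_nA)
    cat(sprintf("  %s nA -> %s %s\n", amp, format(p$label),
                if (length(p$features))
                  paste0("{", paste(names(p$features), collapse = ","), "}")
                else "(class only)"))
  }
  if (!is.null(x$rebound_nA))
    cat("  rebound spiking required at", x$rebound_nA, "nA\n")
  invisible(x)
}

#' Acceptance tolerances for quantitative features
#'
#' Counts (`n_isis`, `n_bursts`, `b_n_isis`) must match exactly; times
#' (`fsl`, `pss`, `bw`, `pbi`) within 10 percent or 5 ms, whichever is
#' larger; `sfa` within 0.01 absolute.
#'
#' @param time_frac,time_abs_ms,sfa_abs The three tolerance knobs.
#' @return Named list.
#' @export
accept_tolerances <- function(time_frac = 0.1, time_abs_ms = 5,
                              sfa_abs = 0.01) {
  list(time_frac = time_frac, time_abs_ms = time_abs_ms, sfa_abs = sfa_abs)
}

feature_within_tol <- function(name, target, model, tol) {
  if (is.null(target) || all(is.na(target))) return(TRUE)
  if (is.null(model) || all(is.na(model))) return(FALSE)
  if (name %in% c("n_isis", "n_bursts")) return(isTRUE(model == target))
  if (name == "b_n_isis") {
    return(length(model) == length(target) && all(model == target))
  }
  if (name == "sfa") return(isTRUE(abs(model - target) <= tol$sfa_abs))
  # time-valued (possibly list-valued) features
  if (length(model) != length(target)) return(FALSE)
  all(abs(model - target) <= pmax(tol$time_frac * abs(target),
                                  tol$time_abs_ms))
}

#' Verify a model against a phenotype from scratch
#'
#' Re-simulates the model on every target stimulus and checks: class match
#' for every pattern (with the rapidly-adapting exception for
#' single-compartment models), quantitative features within tolerance,
#' rebound spiking if required, and -- for multi-compartment models -- all
#' four dendritic constraint errors exactly zero.
#'
#' @param model A [compartment_model()].
#' @param spec A [phenotype_spec()].
#' @param currents_pA Amplitudes (pA) to use per pattern; defaults to the
#'   target amplitudes (required for patterns with unknown amplitude).
#' @param tol See [accept_tolerances()].
#' @param dt Integration step (ms).
#' @param details Return the per-pattern diagnosis instead of a single flag.
#' @return Logical, or a list when `details = TRUE`.
#' @export
accept_model <- function(model, spec, currents_pA = NULL,
                         tol = accept_tolerances(), dt = 0.1,
                         details = FALSE) {
  if (inherits(model, "izhi_params")) model <- point_model(model)
  stopifnot(inherits(model, "compartment_model"),
            inherits(spec, "phenotype_spec"))
  if (is.null(currents_pA)) {
    currents_pA <- vapply(spec$patterns, function(p) p$amplitude_nA * 1000,
                          numeric(1))
    if (anyNA(currents_pA))
      stop("patterns with unknown amplitude need explicit currents_pA",
           call. = FALSE)
  }
  allow_rasp <- n_compartments(model) == 1
  rows <- vector("list", length(spec$patterns))
  ok <- TRUE
  for (i in seq_along(spec$patterns)) {
    p <- spec$patterns[[i]]
    st <- step_stimulus(currents_pA[i], onset = p$onset,
                        duration = p$duration, target = model$soma)
    res <- tryCatch({
      tr <- simulate_model(model, st, dt = dt)
      classify_trace(tr, st, spec$thresholds)
    }, error = function(e) NULL)
    if (is.null(res)) {
      ok <- FALSE
      rows[[i]] <- list(label_ok = FALSE, features_ok = FALSE, label = NULL)
      next
    }
    lab_ok <- label_match(res$label, p$label,
                          allow_rasp_exception = allow_rasp)
    feat_ok <- all(vapply(names(p$features), function(f)
      feature_within_tol(f, p$features[[f]],
                         feature_value(res$features, f), tol), logical(1)))
    if (!lab_ok || !feat_ok) ok <- FALSE
    rows[[i]] <- list(label_ok = lab_ok, features_ok = feat_ok,
                      label = res$label, features = res$features)
  }
  rebound_ok <- TRUE
  if (!is.null(spec$rebound_nA)) {
    st <- step_stimulus(spec$rebound_nA, onset = 100, duration = 500,
                        total_time = 1100, target = model$soma, units = "nA")
    tr <- tryCatch(simulate_model(model, st, dt = dt, record = FALSE),
                   error = function(e) NULL)
    rebound_ok <- !is.null(tr) && any(spike_times(tr) > 600)
    if (!rebound_ok) ok <- FALSE
  }
  constraints_ok <- TRUE
  if (n_compartments(model) > 1) {
    pr <- tryCatch(probe_model(model, dt = dt), error = function(e) NULL)
    constraints_ok <- !is.null(pr) &&
      all(c(pr$rheo, pr$vdef, pr$prop, pr$epsp) == 0)
    if (!constraints_ok) ok <- FALSE
  }
  if (!details) return(ok)
  list(ok = ok, patterns = rows, rebound_ok = rebound_ok,
       constraints_ok = constraints_ok)
}
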