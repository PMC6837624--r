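# Built-in reference phenotypes transcribed from published hippocampal
# exemplars (Hippocampome.org neuron types), plus a synthetic-spec generator
# that turns any known model into a fitting target with ground truth.
# Stimulus durations are not printed with the published traces (calibration
# bars only); all fixtures adopt a 1000 ms step with 100 ms onset.

#' Built-in reference phenotypes
#'
#' Fitting targets for six hippocampal neuron types with published exemplar
#' firing patterns. Quantitative features are included where printed with the
#' source traces; the remaining patterns are class-only constraints. The
#' DG Total Molecular Layer entry carries both the experimentally recorded
#' feature values and the (slightly different) values the published models
#' were constrained to; the fit targets the model-constraint values.
#'
#' @return Named list of [phenotype_spec()]s:
#' \describe{
#' \item{dg_total_molecular_layer}{Three adapting (ASP.) patterns with ISI
#'   counts 5/9/19 and adaptation magnitudes 0.142/0.082/0.032 at
#'   +0.073/+0.102/+0.205 nA (experimental traces: 0.142/0.114/0.056 at
#'   +0.075/+0.100/+0.200 nA).}
#' \item{ca1_trilaminar}{Adapting-then-silent at +0.025 nA, adapting with 22
#'   spikes and adaptation 0.038 at +0.05 nA, rebound spiking at -0.1 nA.}
#' \item{ca1_basket}{Non-adapting spiking at +0.15 and +0.31 nA.}
#' \item{mec_lvvi_pyramidal_polymorphic}{Delayed non-adapting spiking just
#'   above rheobase (unknown amplitude) and adapting at +0.2 nA.}
#' \item{ca1_bistratified}{Persistent stuttering at +0.4 nA, adapting at
#'   +0.6 nA.}
#' \item{dg_granule}{Transient slow-wave burst then silence at +0.2 and
#'   +0.4 nA.}
#' }
#' @examples
#' hippocampome_phenotypes()$dg_total_molecular_layer
#' @export
hippocampome_phenotypes <- function() {
  list(
    dg_total_molecular_layer = phenotype_spec(
      name = "DG Total Molecular Layer",
      patterns = list(
        pattern_target(0.073, "ASP.", features = list(n_isis = 5L,
                                                      sfa = 0.142)),
        pattern_target(0.102, "ASP.", features = list(n_isis = 9L,
                                                      sfa = 0.082)),
        pattern_target(0.205, "ASP.", features = list(n_isis = 19L,
                                                      sfa = 0.032))
      ),
      experimental_features = list(
        list(amplitude_nA = 0.075, n_isis = 5L, sfa = 0.142),
        list(amplitude_nA = 0.100, n_isis = 9L, sfa = 0.114),
        list(amplitude_nA = 0.200, n_isis = 19L, sfa = 0.056)
      ),
      source = "Hippocampome.org exemplar: simple adapting phenotype"),
    ca1_trilaminar = phenotype_spec(
      name = "CA1 Trilaminar",
      patterns = list(
        pattern_target(0.025, "ASP.SLN"),
        pattern_target(0.05, "ASP.", features = list(n_isis = 21L,
                                                     sfa = 0.038))
      ),
      rebound_nA = -0.1,
      source = "Hippocampome.org exemplar: complex phenotype with rebound"),
    ca1_basket = phenotype_spec(
      name = "CA1 Basket",
      patterns = list(
        pattern_target(0.15, "NASP"),
        pattern_target(0.31, "NASP")
      ),
      source = "Hippocampome.org exemplar: fast-spiking interneuron"),
    mec_lvvi_pyramidal_polymorphic = phenotype_spec(
      name = "MEC LV-VI Pyramidal-Polymorphic",
      patterns = list(
        pattern_target(NA, "D.NASP", bracket_nA = c(0.07, 0.17)),
        pattern_target(0.2, "ASP.")
      ),
      source = "Hippocampome.org exemplar: delayed spiking near rheobase"),
    ca1_bistratified = phenotype_spec(
      name = "CA1 Bistratified",
      patterns = list(
        pattern_target(0.4, "PSTUT"),
        pattern_target(0.6, "ASP.")
      ),
      source = "Hippocampome.org exemplar: stuttering interneuron"),
    dg_granule = phenotype_spec(
      name = "DG Granule",
      patterns = list(
        pattern_target(0.2, "TSWB.SLN"),
        pattern_target(0.4, "TSWB.SLN")
      ),
      source = "Hippocampome.org exemplar: transient slow-wave bursting")
  )
}

#' Exemplar parameter sets for the main firing-pattern families
#'
#' One hand-picked [izhi_params()] per family, each lying inside the
#' corresponding [default_class_boxes()] subregion and producing its family's
#' label at the quoted probe current. `currents_nA` records a current at
#' which the exemplar expresses the family cleanly (used by the synthetic
#' recovery fixtures).
#'
#' @return Named list (`NASP`, `ASP`, `D`, `TSWB`, `PSTUT`), each with
#'   elements `params`, `currents_nA` and `label`.
#' @examples
#' ex <- family_exemplars()$ASP
#' st <- step_stimulus(ex$currents_nA[1], units = "nA")
#' classify_trace(simulate_model(ex$params, st), st)$label
#' @export
family_exemplars <- function() {
  list(
    NASP = list(params = izhi_params(100, 0.7, -60, -40, 35, -60, 0.3, 0, 0),
                currents_nA = 0.1, label = "NASP"),
    ASP = list(params = izhi_params(100, 0.7, -60, -40, 35, -50, 0.002, -2,
                                    30),
               currents_nA = 0.205, label = "ASP."),
    D = list(params = izhi_params(100, 0.7, -60, -40, 35, -44, 0.05, 0, 30),
             currents_nA = 0.075, label = "D.NASP"),
    TSWB = list(params = izhi_params(63, 0.89, -60, -44.5, 25.8, -37.7,
                                     5e-4, 7.9, 162),
                currents_nA = 0.2, label = "TSWB.SLN"),
    PSTUT = list(params = izhi_params(50, 1.5, -60, -40, 25, -40, 0.02, 1,
                                      150),
                 currents_nA = 0.3, label = "PSTUT")
  )
}

#' Synthesize a phenotype spec from a known model
#'
#' Simulates `model` at the given currents, extracts features, classifies,
#' and packages the results as a [phenotype_spec()] whose targets are the
#' generator's own outputs. The generating model therefore passes
#' [accept_model()] on the returned spec by construction, which makes these
#' specs ground-truthed recovery targets for the evolutionary search.
#'
#' @param model A [compartment_model()] (or [izhi_params()]).
#' @param currents_nA Step amplitudes (nA); each must elicit at least two
#'   spikes.
#' @param name Spec name.
#' @param dt Integration step (ms).
#' @param onset,duration Stimulus timing (ms).
#' @param thresholds Classifier thresholds.
#' @param features Which feature names to carry as quantitative targets;
#'   defaults to the class family's feature set restricted to defined values.
#' @return List with `spec` (the [phenotype_spec()]) and `truth` (the
#'   generating model and its per-current features).
#' @export
synth_spec <- function(model, currents_nA, name = "synthetic", dt = 0.1,
                       onset = 100, duration = 1000,
                       thresholds = class_thresholds(), features = NULL) {
  if (inherits(model, "izhi_params")) model <- point_model(model)
  stopifnot(inherits(model, "compartment_model"), length(currents_nA) >= 1)
  patterns <- vector("list", length(currents_nA))
  truth_feats <- vector("list", length(currents_nA))
  for (i in seq_along(currents_nA)) {
    st <- step_stimulus(currents_nA[i], onset = onset, duration = duration,
                        target = model$soma, units = "nA")
    tr <- simulate_model(model, st, dt = dt)
    res <- classify_trace(tr, st, thresholds)
    if (res$features$n_spikes < 2)
      stop("current ", currents_nA[i],
           " nA elicits fewer than 2 spikes; cannot define a pattern",
           call. = FALSE)
    fam <- feature_family(res$label)
    want <- if (is.null(features)) fam else intersect(features, fam)
    fv <- list()
    for (f in want) {
      v <- feature_value(res$features, f)
      if (!is.null(v) && !all(is.na(v)) && length(v)) fv[[f]] <- v
    }
    patterns[[i]] <- pattern_target(currents_nA[i], format(res$label),
                                    features = fv, onset = onset,
                                    duration = duration)
    truth_feats[[i]] <- res$features
  }
  spec <- phenotype_spec(name, patterns,
                         n_compartments = n_compartments(model),
                         thresholds = thresholds,
                         source = "synthetic (generated from known model)")
  list(spec = spec, truth = list(model = model, features = truth_feats))
}
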