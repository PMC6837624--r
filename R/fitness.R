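# The scalar objective of the fit: a feature-weighted log error over the
# class-dependent feature set, plus four dendritic constraint errors for
# compact multi-compartment models. Unit convention inside every log term is
# fixed: times in ms, currents in nA, voltages in mV.

SPIKING_FEATURES <- c("fsl", "pss", "sfa", "n_isis")
BURSTING_FEATURES <- c("fsl", "pss", "bw", "pbi", "n_bursts", "b_n_isis")
LIST_FEATURES <- c("bw", "pbi", "b_n_isis")

#' Feature set of a class family
#'
#' Spiking-class patterns are scored on `fsl, pss, sfa, nISIs`;
#' bursting/stuttering patterns on `fsl, pss, bw, pbi, n_bursts, b_nISIs`.
#'
#' @param label A `class_label` or label string.
#' @return Character vector of feature names.
#' @export
feature_family <- function(label) {
  lab <- parse_label(label)
  els <- c(lab$transients, if (!is.na(lab$steady)) lab$steady)
  if (any(els %in% c("TSTUT", "TSWB", "PSTUT", "PSWB")))
    BURSTING_FEATURES else SPIKING_FEATURES
}

feature_value <- function(fs, name) {
  switch(name,
         fsl = fs$fsl, pss = fs$pss, sfa = fs$sfa,
         n_isis = fs$n_isis, n_bursts = fs$n_bursts,
         bw = fs$bursts$bw, pbi = fs$pbi, b_n_isis = fs$bursts$b_n_isis,
         stop("unknown feature: ", name, call. = FALSE))
}

# pad the shorter list with zeros so missing entries contribute their
# full magnitude to the error
align_lists <- function(a, b) {
  n <- max(length(a), length(b))
  list(a = c(a, rep(0, n - length(a))), b = c(b, rep(0, n - length(b))))
}

#' Feature-weighted log error between target and model patterns
#'
#' The error is `sum over f in S of W_f * log(1 + |exp_f - model_f|)` with S
#' the class family's feature set (natural log). List-valued features (burst
#' widths, post-burst intervals, per-burst ISI counts) are compared
#' element-wise after zero-padding to equal length. A feature the model does
#' not define (e.g. `sfa` of a single-spike response) contributes
#' `W_f * log(1 + penalty)`; features absent from the target are skipped, so
#' class-only targets score zero here and are driven by the class-mismatch
#' weighting instead.
#'
#' @param target,model `feature_set`s (target may be a plain named list of
#'   feature values).
#' @param weights Named numeric weights `W_f`; see [dynamic_weights()].
#'   Features not named default to weight 1.
#' @param family Feature set to score, from [feature_family()] of the target
#'   class.
#' @param penalty Magnitude charged for an undefined model feature.
#' @return Non-negative scalar; zero exactly when all scored features match.
#' @examples
#' pattern_error(list(fsl = 20), list(fsl = 30), family = "fsl")  # log(11)
#' @export
pattern_error <- function(target, model, weights = NULL,
                          family = SPIKING_FEATURES, penalty = 1000) {
  total <- 0
  for (f in family) {
    tv <- if (inherits(target, "feature_set")) feature_value(target, f)
          else target[[f]]
    if (is.null(tv) || all(is.na(tv))) next   # not constrained by the target
    mv <- if (inherits(model, "feature_set")) feature_value(model, f)
          else model[[f]]
    w <- if (!is.null(weights) && f %in% names(weights)) weights[[f]] else 1
    if (f %in% LIST_FEATURES) {
      if (is.null(mv)) mv <- numeric(0)
      al <- align_lists(as.numeric(tv), as.numeric(mv))
      total <- total + w * sum(log1p(abs(al$a - al$b)))
    } else if (is.null(mv) || is.na(mv)) {
      total <- total + w * log1p(penalty)
    } else {
      total <- total + w * log1p(abs(tv - mv))
    }
  }
  total
}

# which taxonomy elements define each feature (for the dynamic weighting)
FEATURE_ELEMENTS <- list(
  fsl = "D",
  sfa = c("ASP", "RASP"),
  pss = "SLN",
  n_isis = "NASP",
  bw = c("TSTUT", "TSWB", "PSTUT", "PSWB"),
  pbi = c("TSTUT", "TSWB", "PSTUT", "PSWB"),
  n_bursts = c("TSTUT", "TSWB", "PSTUT", "PSWB"),
  b_n_isis = c("TSTUT", "TSWB", "PSTUT", "PSWB")
)

label_elements <- function(label) {
  if (is.null(label)) return(character(0))
  lab <- parse_label(label)
  c(lab$transients, if (!is.na(lab$steady)) lab$steady)
}

#' Class-mismatch feature weighting
#'
#' During the evolutionary search each feature weight is set by comparing the
#' target class with the model's current class: a feature whose defining
#' taxonomy element is present in one label but not the other gets its base
#' weight multiplied by `boost`, steering the search toward expressing the
#' missing element before fine-tuning magnitudes. An unclassifiable model
#' (fewer than two spikes) boosts every feature.
#'
#' @param target,model `class_label`s or strings; `model` may be `NULL`.
#' @param base Named base weights (default 1 for every feature).
#' @param boost Multiplier applied on mismatch.
#' @return Named numeric vector over all features.
#' @examples
#' dynamic_weights("ASP.SLN", "ASP.")["pss"]  # boosted
#' @export
dynamic_weights <- function(target, model, base = NULL, boost = 10) {
  feats <- names(FEATURE_ELEMENTS)
  w <- setNames(rep(1, length(feats)), feats)
  if (!is.null(base)) w[names(base)] <- unlist(base)
  if (is.null(model)) return(w * boost)
  te <- label_elements(target)
  me <- label_elements(model)
  for (f in feats) {
    def <- FEATURE_ELEMENTS[[f]]
    if (!setequal(intersect(def, te), intersect(def, me)))
      w[f] <- w[f] * boost
  }
  w
}

#' Dendritic constraint errors
#'
#' Four zero-when-satisfied penalties computed per dendritic compartment from
#' probe results (units: currents in nA, voltages in mV):
#' \itemize{
#' \item rheobase: dendrites must be no more excitable than the soma
#'   (`I_dend_rheo >= I_soma_rheo`), else `log(1 + (I_soma - I_dend))`;
#' \item voltage deflection: dendritic input resistance at least somatic
#'   (`|V_dend_def| >= |V_soma_def|`), else the log of the shortfall;
#' \item propagation: forward spike-propagation ratio `R = 1`, else
#'   `log(1 + (1 - R))`;
#' \item EPSP: somatic EPSP amplitude inside `[0.1, 0.9]` mV, else the log
#'   of the distance to the violated bound.
#' }
#' Each error is continuous at its constraint boundary.
#'
#' @param rheo_soma,rheo_dend Rheobases (nA) of the decoupled compartments.
#' @param vdef_soma,vdef_dend Steady-state voltage deflections (mV, signed or
#'   absolute) under a hyperpolarizing step in decoupled compartments.
#' @param R Forward spike-propagation ratio in `[0, 1]`.
#' @param epsp Somatic EPSP amplitude (mV) for a single dendritic synapse.
#' @return A tibble with columns `rheo`, `vdef`, `prop`, `epsp`.
#' @examples
#' constraint_errors(0.10, 0.15, -10, -12, R = 1, epsp = 0.5)  # all zero
#' @export
constraint_errors <- function(rheo_soma, rheo_dend, vdef_soma, vdef_dend,
                              R, epsp) {
  if (any(is.na(R)) || any(R < 0 | R > 1 + 1e-9))
    stop("propagation ratio must lie in [0, 1]", call. = FALSE)
  rheo <- ifelse(rheo_dend >= rheo_soma, 0, log1p(rheo_soma - rheo_dend))
  vdef <- ifelse(abs(vdef_dend) >= abs(vdef_soma), 0,
                 log1p(abs(vdef_soma) - abs(vdef_dend)))
  prop <- ifelse(R >= 1, 0, log1p(1 - R))
  epsp_err <- ifelse(epsp < 0.1, log1p(0.1 - epsp),
                     ifelse(epsp > 0.9, log1p(epsp - 0.9), 0))
  tibble::tibble(rheo = rheo, vdef = vdef, prop = prop, epsp = epsp_err)
}
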