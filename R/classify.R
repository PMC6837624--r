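# Firing-pattern taxonomy: transient elements D, ASP, RASP, TSTUT, TSWB and
# steady-state elements SLN, NASP, PSTUT, PSWB, composed in dot notation
# ("ASP.SLN", "D.NASP", "RASP.ASP."). A trailing dot marks an incomplete
# pattern: the stimulus ended before a steady-state element was expressed.

TRANSIENT_ELEMENTS <- c("D", "ASP", "RASP", "TSTUT", "TSWB")
STEADY_ELEMENTS <- c("SLN", "NASP", "PSTUT", "PSWB")

#' Firing-pattern class label
#'
#' @param transients Character vector of transient elements, in order, from
#'   `D, ASP, RASP, TSTUT, TSWB`.
#' @param steady A single steady-state element from `SLN, NASP, PSTUT, PSWB`,
#'   or `NA` for an incomplete pattern.
#' @return An object of class `class_label`.
#' @examples
#' format(class_label("ASP", "SLN"))
#' parse_label("RASP.ASP.")
#' @export
class_label <- function(transients = character(0), steady = NA_character_) {
  transients <- as.character(transients)
  if (!all(transients %in% TRANSIENT_ELEMENTS))
    stop("unknown transient element(s): ",
         paste(setdiff(transients, TRANSIENT_ELEMENTS), collapse = ", "),
         call. = FALSE)
  if (!is.na(steady) && !steady %in% STEADY_ELEMENTS)
    stop("unknown steady-state element: ", steady, call. = FALSE)
  if (is.na(steady) && !length(transients))
    stop("a label needs at least one element", call. = FALSE)
  structure(list(transients = transients, steady = steady,
                 complete = !is.na(steady)),
            class = "class_label")
}

#' @export
format.class_label <- function(x, ...) {
  trans <- if (length(x$transients))
    paste0(x$transients, ".", collapse = "") else ""
  paste0(trans, if (!is.na(x$steady)) x$steady else "")
}

#' @export
print.class_label <- function(x, ...) {
  cat("<class_label> ", format(x),
      if (!x$complete) "  (incomplete)", "\n", sep = "")
  invisible(x)
}

#' @rdname class_label
#' @param s A label string in dot notation, e.g. `"ASP.SLN"` or `"TSTUT."`.
#' @export
parse_label <- function(s) {
  if (inherits(s, "class_label")) return(s)
  stopifnot(is.character(s), length(s) == 1, nzchar(s))
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (any(!nzchar(parts))) stop("malformed label: ", s, call. = FALSE)
  incomplete <- endsWith(s, ".")
  if (incomplete) {
    trans <- parts
    steady <- NA_character_
  } else {
    steady <- parts[length(parts)]
    trans <- parts[-length(parts)]
  }
  if (!is.na(steady) && !steady %in% STEADY_ELEMENTS)
    stop("label must end in a steady-state element or a '.': ", s,
         call. = FALSE)
  class_label(trans, steady)
}

#' Classification thresholds
#'
#' Central knob set for [classify_pattern()]. The defaults implement the
#' published taxonomy's qualitative definitions with declared numeric cutoffs.
#'
#' @param delay_factor Minimum `fsl / mean(first two ISIs)` for a Delay
#'   transient.
#' @param gap_ratio Burst segmentation threshold ([segment_bursts()]).
#' @param pss_factor `pss > pss_factor * max(ISI)` declares the Silence
#'   steady state.
#' @param alpha Significance level for the adaptation trend test.
#' @param rapid_min,rapid_tail_frac Rapid-adaptation detection, see
#'   [adaptation_stats()].
#' @param ahp_drop Voltage drop (mV) below resting baseline after a burst
#'   that flags a slow after-hyperpolarization (selects slow-wave bursting
#'   over stuttering) when derived from a trace.
#' @return A named list of thresholds.
#' @export
class_thresholds <- function(delay_factor = 2, gap_ratio = 3, pss_factor = 2,
                             alpha = 0.05, rapid_min = 0.1,
                             rapid_tail_frac = 0.25, ahp_drop = 2) {
  thr <- list(delay_factor = delay_factor, gap_ratio = gap_ratio,
              pss_factor = pss_factor, alpha = alpha, rapid_min = rapid_min,
              rapid_tail_frac = rapid_tail_frac, ahp_drop = ahp_drop)
  if (any(vapply(thr, function(v) !is.numeric(v) || v < 0, logical(1))))
    stop("thresholds must be non-negative numbers", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  thr
}

# pss "sufficiently long" rule shared by several branches
pss_long <- function(fs, thr, isis = fs$isis) {
  length(isis) > 0 && fs$pss > thr$pss_factor * max(isis)
}

#' Classify a feature set into the firing-pattern taxonomy
#'
#' Applies, in order: Delay (delay factor at least `delay_factor`); burst
#' transients / persistent stuttering by cluster structure (slow-wave
#' bursting instead of stuttering when a slow AHP is flagged); rapid and
#' sustained adaptation; then the steady-state element (Silence for long
#' post-spike silence, non-adapting spiking for an uninterrupted flat tail).
#' A pattern whose stimulus ended mid-transient gets an incomplete label
#' (trailing dot). Responses with fewer than two spikes are not classified.
#'
#' @param features A `feature_set` from [extract_features()].
#' @param thresholds See [class_thresholds()].
#' @param slow_ahp Logical: slow after-hyperpolarization present after bursts
#'   (supplied per trace, or derived via [detect_slow_ahp()]).
#' @return A `class_label`, or `NULL` for fewer than two spikes.
#' @examples
#' st <- step_stimulus(100, 100, 1000)
#' fs <- extract_features(100 + seq(50, 950, by = 50), st)
#' format(classify_pattern(fs))
#' @export
classify_pattern <- function(features, thresholds = class_thresholds(),
                             slow_ahp = FALSE) {
  stopifnot(inherits(features, "feature_set"))
  thr <- thresholds
  fs <- features
  if (fs$n_spikes < 2) return(NULL)

  trans <- character(0)
  steady <- NA_character_
  if (!is.na(fs$delay_factor) && fs$delay_factor >= thr$delay_factor)
    trans <- c(trans, "D")

  clusters <- fs$clusters
  n_clusters <- length(clusters)
  burst_el <- if (isTRUE(slow_ahp)) c("TSWB", "PSWB") else c("TSTUT", "PSTUT")
  offset <- fs$onset + fs$duration
  window_mid <- fs$onset + fs$duration / 2

  if (!is.na(fs$n_bursts) && fs$n_bursts >= 1 && n_clusters >= 2) {
    last_cl <- clusters[[n_clusters]]
    if (fs$n_bursts >= 2 && last_cl[1] > window_mid) {
      # clustering persists through the response
      steady <- burst_el[2]
      return(class_label(trans, steady))
    }
    # clustering confined to the start: transient burst element, then the tail
    burst_cl <- which(lengths(clusters) >= 2)
    last_burst <- max(burst_cl)
    trans <- c(trans, burst_el[1])
    tail_spikes <- if (last_burst < n_clusters)
      unlist(clusters[(last_burst + 1):n_clusters]) else numeric(0)
    if (length(tail_spikes) >= 3) {
      tail_isis <- diff(tail_spikes)
      ad <- adaptation_stats(tail_isis, alpha = thr$alpha,
                             rapid_min = thr$rapid_min,
                             rapid_tail_frac = thr$rapid_tail_frac)
      if (isTRUE(ad$trend_significant)) {
        trans <- c(trans, "ASP")
        steady <- if (pss_long(fs, thr, tail_isis)) "SLN" else NA_character_
      } else {
        steady <- if (pss_long(fs, thr, tail_isis)) "SLN" else "NASP"
      }
    } else {
      intra <- unlist(lapply(clusters[burst_cl], diff))
      steady <- if (fs$pss > thr$pss_factor * max(fs$pbi, intra))
        "SLN" else NA_character_
    }
    return(class_label(trans, steady))
  }

  # a single high-frequency cluster confined to the response onset followed
  # by dominant silence is a transient burst with a Silence steady state
  if (n_clusters == 1 && fs$n_spikes >= 3) {
    last_spike <- max(clusters[[1]])
    if (last_spike - fs$onset < fs$duration / 4 &&
        max(fs$isis) < fs$duration / 20 && pss_long(fs, thr)) {
      return(class_label(c(trans, burst_el[1]), "SLN"))
    }
  }

  # single uninterrupted cluster: adaptation logic
  if (fs$n_isis < 2) {
    steady <- if (pss_long(fs, thr)) "SLN" else "NASP"
    return(class_label(trans, steady))
  }
  rapid <- isTRUE(fs$rapid_component)
  sustained <- isTRUE(fs$trend_significant)
  if (rapid) {
    trans <- c(trans, "RASP")
    if (isTRUE(fs$tail_trend_significant)) {
      trans <- c(trans, "ASP")
      steady <- if (pss_long(fs, thr)) "SLN" else NA_character_
    } else {
      steady <- if (pss_long(fs, thr)) "SLN" else "NASP"
    }
  } else if (sustained) {
    trans <- c(trans, "ASP")
    steady <- if (pss_long(fs, thr)) "SLN" else NA_character_
  } else {
    steady <- if (pss_long(fs, thr)) "SLN" else "NASP"
  }
  class_label(trans, steady)
}

#' Detect a slow after-hyperpolarization in a voltage trace
#'
#' Heuristic proxy used to distinguish slow-wave bursting from stuttering:
#' after the first burst the membrane potential must drop at least `ahp_drop`
#' mV below the resting baseline (the pre-stimulus voltage).
#'
#' @param trace A `voltage_trace` with stored series.
#' @param features The matching `feature_set`.
#' @param thresholds See [class_thresholds()].
#' @param compartment Compartment to inspect (default soma).
#' @return Logical.
#' @export
detect_slow_ahp <- function(trace, features, thresholds = class_thresholds(),
                            compartment = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.null(trace$V)) stop("trace has no stored series", call. = FALSE)
  if (is.null(compartment)) compartment <- trace$soma
  if (is.na(features$n_bursts) || features$n_bursts < 1) return(FALSE)
  cl_sizes <- lengths(features$clusters)
  first_burst <- which(cl_sizes >= 2)[1]
  burst_end <- max(features$clusters[[first_burst]])
  nxt <- if (first_burst < length(features$clusters))
    min(features$clusters[[first_burst + 1]]) else
    features$onset + features$duration
  i0 <- which(trace$time >= burst_end + 2)[1]
  i1 <- max(which(trace$time <= nxt))
  if (is.na(i0) || i0 >= i1) return(FALSE)
  baseline_idx <- max(1, which(trace$time >= features$onset)[1] - 1)
  baseline <- trace$V[baseline_idx, compartment]
  min(trace$V[i0:i1, compartment]) < baseline - thresholds$ahp_drop
}

#' Compare a model label with a target label
#'
#' Exact label equality, with one published exception: a single-compartment
#' model cannot sustain weak adaptation after a rapid component, so a target
#' `RASP.ASP.` may be satisfied by a model `RASP.NASP` when
#' `allow_rasp_exception` is on.
#'
#' @param model,target `class_label`s or label strings.
#' @param allow_rasp_exception Accept `RASP.NASP` for a `RASP.ASP.` target.
#' @return Logical.
#' @examples
#' label_match("RASP.NASP", "RASP.ASP.")
#' @export
label_match <- function(model, target, allow_rasp_exception = TRUE) {
  if (is.null(model)) return(FALSE)
  m <- format(parse_label(model))
  t <- format(parse_label(target))
  if (m == t) return(TRUE)
  isTRUE(allow_rasp_exception) && t == "RASP.ASP." && m == "RASP.NASP"
}

#' Classify a simulated trace end-to-end
#'
#' @param trace A `voltage_trace`.
#' @param stim The [step_stimulus()] used.
#' @param thresholds See [class_thresholds()].
#' @param slow_ahp `NULL` to derive the slow-AHP flag from the trace (when a
#'   series is stored), or an explicit logical.
#' @return List with `label` (a `class_label` or `NULL`) and `features`.
#' @export
classify_trace <- function(trace, stim, thresholds = class_thresholds(),
                           slow_ahp = NULL) {
  fs <- extract_features(spike_times(trace), stim,
                         gap_ratio = thresholds$gap_ratio,
                         alpha = thresholds$alpha,
                         rapid_min = thresholds$rapid_min,
                         rapid_tail_frac = thresholds$rapid_tail_frac)
  if (is.null(slow_ahp)) {
    slow_ahp <- if (!is.null(trace$V))
      detect_slow_ahp(trace, fs, thresholds) else FALSE
  }
  list(label = classify_pattern(fs, thresholds, slow_ahp = slow_ahp),
       features = fs)
}
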