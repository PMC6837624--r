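# Quantitative spike-pattern features: first-spike latency, inter-spike
# intervals, adaptation, post-spike silence, burst structure. These are the
# quantities the classifier and the fitting error operate on.

# closed-form OLS slope + two-sided t-test; hot path of the EA, so no lm()
ols_slope_test <- function(y) {
  n <- length(y)
  if (n < 3) return(list(slope = NA_real_, p = NA_real_))
  x <- seq_len(n)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - my - slope * (x - mx)
  s2 <- sum(res^2) / (n - 2)
  if (s2 <= 0) {                       # exact fit: slope sign decides
    p <- if (abs(slope) > 1e-12) 0 else 1
    return(list(slope = slope, p = p))
  }
  tt <- slope / sqrt(s2 / sxx)
  list(slope = slope, p = 2 * pt(-abs(tt), n - 2))
}

pairwise_sfa <- function(isis) {
  if (length(isis) < 2) return(NA_real_)
  num <- diff(isis)
  den <- isis[-1] + isis[-length(isis)]
  mean(num / den)
}

#' Adaptation statistics of an ISI sequence
#'
#' The adaptation magnitude `sfa` is the mean over consecutive ISI pairs of
#' `(ISI[i+1] - ISI[i]) / (ISI[i+1] + ISI[i])`, a pairwise-normalized index
#' that is zero for a perfectly periodic train, positive when intervals
#' lengthen, and invariant to rescaling all intervals. A sustained trend is
#' assessed by ordinary least squares of ISI against index (two-sided t-test
#' on the slope). A rapid component -- strong adaptation confined to the first
#' two or three ISIs -- is detected by a two-segment comparison: the pairwise
#' index over the first `s` intervals (`s` in 2:3) must reach `rapid_min`
#' while the remainder stays below `rapid_tail_frac` of it.
#'
#' @param isis Inter-spike intervals (ms), at least 2.
#' @param alpha Significance level for the trend test.
#' @param rapid_min Minimum head adaptation index to call a rapid component.
#' @param rapid_tail_frac Maximum tail/head adaptation ratio for the tail to
#'   count as flat.
#' @return List with `sfa`, `slope`, `slope_pvalue`, `trend_significant`,
#'   `rapid_component`, `rapid_split` (number of head ISIs, NA if none),
#'   `tail_sfa`, `tail_slope_pvalue`, `tail_trend_significant`.
#' @examples
#' adaptation_stats(c(10, 30, 31, 32, 33))$rapid_component
#' adaptation_stats(c(40, 44, 48, 52, 56))$trend_significant
#' @export
adaptation_stats <- function(isis, alpha = 0.05, rapid_min = 0.1,
                             rapid_tail_frac = 0.25) {
  isis <- as.numeric(isis)
  if (length(isis) < 2)
    return(list(sfa = NA_real_, slope = NA_real_, slope_pvalue = NA_real_,
                trend_significant = NA, rapid_component = NA,
                rapid_split = NA_integer_, tail_sfa = NA_real_,
                tail_slope_pvalue = NA_real_, tail_trend_significant = NA))
  sfa <- pairwise_sfa(isis)
  fit <- ols_slope_test(isis)
  trend <- isTRUE(fit$p < alpha && fit$slope > 0)
  rapid <- FALSE
  split <- NA_integer_
  tail_sfa <- NA_real_
  tail_fit <- list(slope = NA_real_, p = NA_real_)
  for (s in 2:3) {
    if (length(isis) < s + 2) break
    head_sfa <- pairwise_sfa(isis[seq_len(s)])
    rest <- isis[(s + 1):length(isis)]
    rest_sfa <- pairwise_sfa(rest)
    if (is.na(rest_sfa)) rest_sfa <- 0
    if (head_sfa >= rapid_min && rest_sfa <= rapid_tail_frac * head_sfa) {
      rapid <- TRUE
      split <- s
      tail_sfa <- rest_sfa
      tail_fit <- ols_slope_test(rest)
      break
    }
  }
  if (!rapid && length(isis) >= 4) {
    rest <- isis[3:length(isis)]
    tail_sfa <- pairwise_sfa(rest)
    tail_fit <- ols_slope_test(rest)
  }
  list(sfa = sfa, slope = fit$slope, slope_pvalue = fit$p,
       trend_significant = trend, rapid_component = rapid,
       rapid_split = split, tail_sfa = tail_sfa,
       tail_slope_pvalue = tail_fit$p,
       tail_trend_significant = isTRUE(tail_fit$p < alpha && tail_fit$slope > 0))
}

#' Segment a spike train into bursts
#'
#' Spikes are grouped into clusters split at quiescent gaps. An ISI counts as
#' a gap when it exceeds `gap_ratio` times a robust intra-cluster interval
#' estimate (the median of the ISIs not exceeding the mean ISI; with few,
#' widely split intervals the plain median is dominated by the gaps
#' themselves) *and* `gap_ratio` times the preceding ISI (the following ISI
#' for the first interval). The second condition distinguishes genuine
#' quiescence between clusters of high-frequency spikes from the smooth
#' interval growth of an adapting train, which never jumps by that ratio in
#' one step. A burst is a cluster of at least two spikes; its width `bw` is
#' last minus first spike, and the post-burst interval `pbi` is the gap that
#' follows it.
#'
#' @param spike_times Sorted spike times (ms), at least 2.
#' @param gap_ratio Multiplier on the intra-cluster ISI estimate.
#' @return List with `clusters` (list of spike-time vectors), `bursts` (list
#'   with `bw`, `b_n_isis`), `pbi` (gaps following each non-final cluster),
#'   and `n_bursts` (clusters with >= 2 spikes).
#' @examples
#' segment_bursts(c(0, 10, 20, 300, 310, 320))
#' @export
segment_bursts <- function(spike_times, gap_ratio = 3) {
  st <- as.numeric(spike_times)
  stopifnot(length(st) >= 2, !is.unsorted(st, strictly = TRUE))
  isis <- diff(st)
  intra <- isis[isis <= mean(isis) + 1e-12]
  thr <- gap_ratio * median(intra)
  neighbor <- c(if (length(isis) > 1) isis[2] else isis[1],
                isis[-length(isis)])
  splits <- which(isis > thr & isis > gap_ratio * neighbor)
  bounds <- c(0, splits, length(st))
  clusters <- lapply(seq_len(length(bounds) - 1), function(i)
    st[(bounds[i] + 1):bounds[i + 1]])
  sizes <- lengths(clusters)
  keep <- sizes >= 2
  bursts <- list(
    bw = vapply(clusters[keep], function(cl) cl[length(cl)] - cl[1],
                numeric(1)),
    b_n_isis = sizes[keep] - 1L
  )
  list(clusters = clusters, bursts = bursts,
       pbi = isis[splits], n_bursts = sum(keep))
}

#' Extract spike-pattern features for one stimulus
#'
#' Decomposes a spike-time list into the features used throughout the fitting
#' pipeline: first-spike latency `fsl`, the ISIs and their count, adaptation
#' magnitude `sfa`, post-spike silence `pss`, the burst structure, and the
#' delay factor (`fsl` over the mean of the first two ISIs). Whenever the last
#' spike falls inside the stimulus window the identity
#' `fsl + sum(ISIs) + pss = duration` holds to within one integration step.
#'
#' @param spike_times Sorted spike times (ms), all at or after stimulus onset.
#' @param stim The [step_stimulus()] that evoked the train.
#' @param gap_ratio Burst segmentation threshold, see [segment_bursts()].
#' @param ... Passed to [adaptation_stats()].
#' @return A `feature_set`: list with `n_spikes`, `fsl`, `isis`, `n_isis`,
#'   `sfa`, `pss`, `delay_factor`, `bursts`, `pbi`, `n_bursts`, the adaptation
#'   test results, and the stimulus metadata. Quantities that are undefined
#'   for the spike count at hand are `NA`, never fabricated zeros.
#' @examples
#' st <- step_stimulus(100, onset = 100, duration = 1000)
#' extract_features(100 + c(100, 150, 210), st)
#' @export
extract_features <- function(spike_times, stim, gap_ratio = 3, ...) {
  stopifnot(inherits(stim, "step_stimulus"))
  st <- as.numeric(spike_times)
  if (length(st) && (is.unsorted(st) || any(st < stim$onset - 1e-9)))
    stop("spike times must be sorted and at/after stimulus onset",
         call. = FALSE)
  # the pattern is the response during current injection; spikes after the
  # stimulus offset (e.g. rebound activity) are not part of it
  st <- st[st <= stim$onset + stim$duration + 1e-9]
  fs <- list(n_spikes = length(st), fsl = NA_real_, isis = numeric(0),
             n_isis = 0L, sfa = NA_real_, pss = NA_real_,
             delay_factor = NA_real_,
             bursts = list(bw = numeric(0), b_n_isis = integer(0)),
             pbi = numeric(0), n_bursts = NA_integer_,
             slope_pvalue = NA_real_, trend_significant = NA,
             rapid_component = NA, rapid_split = NA_integer_,
             tail_sfa = NA_real_, tail_trend_significant = NA,
             onset = stim$onset, duration = stim$duration,
             amplitude_pA = stim$amplitude)
  class(fs) <- "feature_set"
  if (!length(st)) return(fs)
  offset <- stim$onset + stim$duration
  fs$fsl <- st[1] - stim$onset
  fs$isis <- diff(st)
  fs$n_isis <- length(fs$isis)
  fs$pss <- max(0, offset - st[length(st)])
  if (fs$n_isis >= 2) {
    fs$delay_factor <- fs$fsl / mean(fs$isis[1:2])
    ad <- adaptation_stats(fs$isis, ...)
    fs$sfa <- ad$sfa
    fs$slope_pvalue <- ad$slope_pvalue
    fs$trend_significant <- ad$trend_significant
    fs$rapid_component <- ad$rapid_component
    fs$rapid_split <- ad$rapid_split
    fs$tail_sfa <- ad$tail_sfa
    fs$tail_trend_significant <- ad$tail_trend_significant
  }
  if (length(st) >= 2) {
    seg <- segment_bursts(st, gap_ratio = gap_ratio)
    fs$bursts <- seg$bursts
    fs$pbi <- seg$pbi
    fs$n_bursts <- seg$n_bursts
    fs$clusters <- seg$clusters
  }
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>", x$n_spikes, "spikes | fsl", signif(x$fsl, 4),
      "| nISIs", x$n_isis, "| sfa", signif(x$sfa, 4),
      "| pss", signif(x$pss, 4), "| bursts", x$n_bursts, "\n")
  invisible(x)
}

#' One-row tibble view of a feature set
#' @param x A `feature_set`.
#' @param ... Unused.
#' @export
as_tibble.feature_set <- function(x, ...) {
  tibble::tibble(
    n_spikes = x$n_spikes, fsl = x$fsl, n_isis = x$n_isis, sfa = x$sfa,
    pss = x$pss, delay_factor = x$delay_factor, n_bursts = x$n_bursts,
    isis = list(x$isis), bw = list(x$bursts$bw),
    b_n_isis = list(x$bursts$b_n_isis), pbi = list(x$pbi)
  )
}

#' Feature table for a set of traces
#'
#' Convenience wrapper: simulate-or-take traces, extract features per
#' stimulus, return one tidy row each.
#'
#' @param traces A list of `voltage_trace` objects (somatic spikes are used).
#' @param stims The matching list of [step_stimulus()] objects.
#' @param ... Passed to [extract_features()].
#' @return A tibble, one row per trace, with an `amplitude_nA` column.
#' @export
feature_table <- function(traces, stims, ...) {
  stopifnot(length(traces) == length(stims))
  purrr::map2_dfr(traces, stims, function(tr, st) {
    fs <- extract_features(spike_times(tr), st, ...)
    dplyr::bind_cols(tibble::tibble(amplitude_nA = st$amplitude / 1000),
                     as_tibble(fs))
  })
}
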