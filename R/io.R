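# Readers and writers for the package's interchange artifacts: the model
# parameter CSV (dialect "izhifit-csv-1"), voltage-trace CSV, the XPP .ode
# export for single-compartment models, and the JSON fit-file pairing
# experimental with simulated feature values. All writers are deterministic:
# stable column/key order and 6-significant-digit float formatting, so
# write -> read -> write is byte-identical.

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Write models to the parameter CSV
#'
#' One row per compartment: model id, type name, layer label, the nine
#' parameters, then the coupling (`G`, `P`, proximal layer) of the edge
#' joining the compartment to its proximal neighbour (empty for the soma).
#' The first line is a comment naming the schema version.
#'
#' @param models A [compartment_model()], a list of them, or an `izhi_fit`
#'   (its accepted models are written).
#' @param path Output file.
#' @param type_name Type name column (recycled).
#' @return `path`, invisibly.
#' @export
write_param_csv <- function(models, path, type_name = "model") {
  if (inherits(models, "izhi_fit"))
    models <- lapply(models$accepted, `[[`, "model")
  if (inherits(models, "compartment_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "compartment_model")))
  type_name <- rep_len(type_name, length(models))
  rows <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    pm <- model_par_matrix(m)
    for (j in seq_len(nrow(pm))) {
      e <- m$edges[m$edges$dist == j, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        model_id = i, type_name = type_name[i],
        layer = rownames(pm)[j],
        as.list(pm[j, ]),
        G = if (nrow(e)) e$G else NA_real_,
        P = if (nrow(e)) e$P else NA_real_,
        prox_layer = if (nrow(e)) rownames(pm)[e$prox] else "")
    }
  }
  df <- do.call(rbind, rows)
  num_cols <- c(param_names, "G", "P")
  for (cc in num_cols) df[[cc]] <- fmt_num(df[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# izhifit-csv-1", con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read models from the parameter CSV
#'
#' @param path A file written by [write_param_csv()].
#' @return A list of [compartment_model()]s (named by `type_name` when
#'   unique), with `model_id` ordering preserved.
#' @export
read_param_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# izhifit-csv"))
    stop("not an izhifit parameter CSV (missing schema header)",
         call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(split(df, df$model_id), function(d) {
    comps <- list()
    for (j in seq_len(nrow(d)))
      comps[[d$layer[j]]] <- do.call(izhi_params,
                                     as.list(d[j, param_names]))
    edges <- d[!is.na(d$G), , drop = FALSE]
    e <- if (nrow(edges)) {
      data.frame(prox = match(edges$prox_layer, d$layer),
                 dist = match(edges$layer, d$layer),
                 G = edges$G, P = edges$P)
    } else NULL
    compartment_model(comps, e)
  })
}

#' Write a voltage trace as CSV
#'
#' Columns: `time_ms`, then `V_<layer>` per compartment. Spike times are
#' appended as comment lines (one per compartment) so the file remains a
#' plain rectangular CSV.
#'
#' @param trace A `voltage_trace` with stored series.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.null(trace$V)) stop("trace has no stored series", call. = FALSE)
  df <- data.frame(time_ms = fmt_num(trace$time))
  for (j in seq_along(trace$layers))
    df[[paste0("V_", trace$layers[j])]] <- fmt_num(trace$V[, j])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# izhifit-trace-1", con)
  for (j in seq_along(trace$layers))
    writeLines(paste0("# spikes_", trace$layers[j], ": ",
                      paste(fmt_num(trace$spikes[[j]]), collapse = " ")),
               con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voltage-trace CSV
#'
#' @param path A file written by [write_trace_csv()].
#' @return A list with `time`, `V` (matrix), `spikes` (list per layer).
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# izhifit-trace"))
    stop("not an izhifit trace CSV", call. = FALSE)
  spk_lines <- grep("^# spikes_", lines, value = TRUE)
  spikes <- lapply(spk_lines, function(l) {
    as.numeric(strsplit(sub("^# spikes_[^:]+: ?", "", l), " ")[[1]])
  })
  names(spikes) <- sub("^# spikes_([^:]+):.*$", "\\1", spk_lines)
  df <- read.csv(path, comment.char = "#")
  V <- as.matrix(df[, -1, drop = FALSE])
  colnames(V) <- sub("^V_", "", colnames(V))
  list(time = df$time_ms, V = V, spikes = spikes)
}

#' Export a single-compartment model as an XPP .ode script
#'
#' Emits the two model equations with the reset rule as a global flag, the
#' parameters substituted, and the step current as a time-gated term, ready
#' to run in XPP. Multi-compartment models are refused (this export is
#' defined for point neurons only).
#'
#' @param model A single-compartment [compartment_model()] or
#'   [izhi_params()].
#' @param stim A [step_stimulus()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xpp_ode <- function(model, stim, path) {
  if (inherits(model, "izhi_params")) model <- point_model(model)
  stopifnot(inherits(model, "compartment_model"),
            inherits(stim, "step_stimulus"))
  if (n_compartments(model) > 1)
    stop("XPP export is defined for single-compartment models only",
         call. = FALSE)
  p <- model$compartments[[1]]
  lines <- c(
    "# izhifit XPP export v1",
    sprintf("par C=%s k=%s vr=%s vt=%s vpeak=%s vmin=%s a=%s b=%s d=%s",
            fmt_num(p$C), fmt_num(p$k), fmt_num(p$Vr), fmt_num(p$Vt),
            fmt_num(p$Vpeak), fmt_num(p$Vmin), fmt_num(p$a), fmt_num(p$b),
            fmt_num(p$d)),
    sprintf("par iamp=%s ton=%s toff=%s", fmt_num(stim$amplitude),
            fmt_num(stim$onset), fmt_num(stim$onset + stim$duration)),
    "v'=(k*(v-vr)*(v-vt)-u+iamp*heav(t-ton)*heav(toff-t))/C",
    "u'=a*(b*(v-vr)-u)",
    "global 1 v-vpeak {v=vmin;u=u+d}",
    sprintf("init v=%s u=0", fmt_num(p$Vr)),
    sprintf("@ total=%s, dt=0.1, maxstor=2000000, bounds=100000",
            fmt_num(stim$total_time)),
    "done")
  writeLines(lines, path)
  invisible(path)
}

#' Recover the parameters from an XPP export
#'
#' Parses the `par` line of a script written by [write_xpp_ode()] back into
#' an [izhi_params()] (the round-trip check for the exporter).
#'
#' @param path An .ode file from [write_xpp_ode()].
#' @return An [izhi_params()].
#' @export
read_xpp_ode <- function(path) {
  lines <- readLines(path)
  par_line <- grep("^par C=", lines, value = TRUE)
  if (!length(par_line)) stop("no parameter line found", call. = FALSE)
  kv <- strsplit(sub("^par ", "", par_line[1]), " ")[[1]]
  vals <- as.numeric(sub("^[^=]+=", "", kv))
  names(vals) <- sub("=.*$", "", kv)
  izhi_params(C = vals[["C"]], k = vals[["k"]], Vr = vals[["vr"]],
              Vt = vals[["vt"]], Vpeak = vals[["vpeak"]],
              Vmin = vals[["vmin"]], a = vals[["a"]], b = vals[["b"]],
              d = vals[["d"]])
}

feature_or_null <- function(fs, f) {
  if (is.null(fs)) return(NULL)
  v <- if (inherits(fs, "feature_set")) feature_value(fs, f) else fs[[f]]
  if (is.null(v) || !length(v) || all(is.na(v))) NULL else unname(v)
}

#' Write the JSON fit-file
#'
#' For each pattern of a spec, the fit-file pairs the experimental
#' (target) feature values with the simulated ones and reports their ratio
#' (the goodness-of-fit convention: simulated over experimental). Undefined
#' features are encoded as `null`, never as zeros.
#'
#' @param spec A [phenotype_spec()].
#' @param model The fitted [compartment_model()].
#' @param path Output file.
#' @param currents_pA Currents used per pattern (defaults to the targets').
#' @param dt Integration step (ms).
#' @return `path`, invisibly. The JSON schema is `izhifit-fit-1`.
#' @export
write_fit_file <- function(spec, model, path, currents_pA = NULL, dt = 0.1) {
  if (inherits(model, "izhi_params")) model <- point_model(model)
  stopifnot(inherits(spec, "phenotype_spec"))
  if (is.null(currents_pA))
    currents_pA <- vapply(spec$patterns, function(p) p$amplitude_nA * 1000,
                          numeric(1))
  if (anyNA(currents_pA))
    stop("patterns with unknown amplitude need explicit currents_pA",
         call. = FALSE)
  pats <- vector("list", length(spec$patterns))
  for (i in seq_along(spec$patterns)) {
    p <- spec$patterns[[i]]
    st <- step_stimulus(currents_pA[i], onset = p$onset,
                        duration = p$duration, target = model$soma)
    res <- classify_trace(simulate_model(model, st, dt = dt), st,
                          spec$thresholds)
    if (res$features$n_spikes == 0)
      stop("model produces no simulated pattern at ",
           currents_pA[i] / 1000, " nA", call. = FALSE)
    feats <- list()
    for (f in union(names(p$features),
                    feature_family(p$label))) {
      ev <- feature_or_null(p$features, f)
      sv <- feature_or_null(res$features, f)
      ratio <- if (!is.null(ev) && !is.null(sv) &&
                   length(ev) == length(sv) && all(ev != 0))
        signif(sv / ev, 6) else NULL
      feats[[f]] <- list(exp = ev, sim = sv, ratio = ratio)
    }
    pats[[i]] <- list(
      amplitude_nA = signif(currents_pA[i] / 1000, 6),
      label_exp = format(p$label),
      label_sim = if (is.null(res$label)) NULL else format(res$label),
      features = feats)
  }
  out <- list(schema = "izhifit-fit-1", phenotype = spec$name,
              patterns = pats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON fit-file
#'
#' @param path A file written by [write_fit_file()].
#' @return The parsed list; stops if the schema tag is missing.
#' @export
read_fit_file <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$schema) || !startsWith(x$schema, "izhifit-fit"))
    stop("not an izhifit fit-file", call. = FALSE)
  x
}
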