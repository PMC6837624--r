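# YAML serialization for phenotype specs: the on-disk format for fitting
# targets (and their provenance notes).

#' Write / read a phenotype spec as YAML
#'
#' @param spec A [phenotype_spec()].
#' @param path File path.
#' @return `path` (writer) or a [phenotype_spec()] (reader).
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_phenotype_yaml(hippocampome_phenotypes()$ca1_basket, f)
#' read_phenotype_yaml(f)
#' @export
write_phenotype_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "phenotype_spec"))
  pat <- lapply(spec$patterns, function(p) {
    out <- list(label = format(p$label), onset = p$onset,
                duration = p$duration, current_window = p$current_window)
    if (is.na(p$amplitude_nA)) out$bracket_nA <- as.list(p$bracket_nA)
    else out$amplitude_nA <- p$amplitude_nA
    if (length(p$features)) out$features <- p$features
    out
  })
  obj <- list(schema = "izhifit-spec-1", name = spec$name,
              n_compartments = spec$n_compartments, patterns = pat)
  if (!is.null(spec$rebound_nA)) obj$rebound_nA <- spec$rebound_nA
  if (!is.null(spec$source)) obj$source <- spec$source
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_phenotype_yaml
#' @export
read_phenotype_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema) || !startsWith(x$schema, "izhifit-spec"))
    stop("not an izhifit phenotype YAML", call. = FALSE)
  patterns <- lapply(x$patterns, function(p) {
    feats <- if (is.null(p$features)) list() else
      lapply(p$features, function(v) if (is.list(v)) unlist(v) else v)
    if (!is.null(feats$n_isis)) feats$n_isis <- as.integer(feats$n_isis)
    if (!is.null(feats$n_bursts)) feats$n_bursts <- as.integer(feats$n_bursts)
    if (!is.null(feats$b_n_isis)) feats$b_n_isis <- as.integer(feats$b_n_isis)
    pattern_target(
      amplitude_nA = if (is.null(p$amplitude_nA)) NA_real_ else p$amplitude_nA,
      label = p$label, features = feats,
      bracket_nA = if (is.null(p$bracket_nA)) NULL else unlist(p$bracket_nA),
      onset = p$onset, duration = p$duration,
      current_window = p$current_window)
  })
  phenotype_spec(x$name, patterns, n_compartments = x$n_compartments,
                 rebound_nA = x$rebound_nA, source = x$source)
}
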