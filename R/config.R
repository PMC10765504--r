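#' Analysis options
#'
#' One structured key-value tree holding every tunable threshold of the
#' pipeline, with the study's values as defaults. Pass the whole list to
#' [run_pipeline()] or individual values to the stage functions.
#'
#' @param ... Named overrides for any default (nested lists are merged
#'   shallowly at the top level).
#' @return A named list of options, class `"ol_options"`.
#' @export
#' @examples
#' opts <- analysis_options(doc_percentile = 95)
#' opts$doc_percentile
analysis_options <- function(...) {
  defaults <- list(
    # core_io / QC
    doc_percentile = 90,          # DOC contamination screen, percent
    doc_min_group = 5,            # min obs per group for the percentile rule
    doc_group_vars = c("treatment", "bottle"),
    filtrate_fraction = 0.70,     # filtrate volume fraction per bottle
    # growth kinetics
    fg_per_cell = 20,             # fg C per cell conversion factor
    growth_analyte = "PA",
    doc_analyte = "DOC",
    # diagenesis
    di_reference = NULL,          # NULL = packaged synthetic reference table
    # metabolomics
    ai_modified = TRUE,           # modified aromaticity index (AI_mod)
    weighted_over_classified_only = FALSE,
    # qPCR
    qpcr_merge = "mean_cq",       # replicate merging before quantification
    # community
    asv_min_samples = 4,          # prevalence filter ("in less than four")
    rarefaction_depth = 10000,
    filter_before_rarefy = TRUE,
    asv_plot_threshold = 0.0015,  # >0.15% of total for per-ASV plots
    family_other_threshold = 0.01,# <1% of total pooled into "other"
    copy_number_renormalize = FALSE,
    # statistics
    replicate_test = "t",         # "t" or "permutation"
    anova_scope = "timepoint",    # or "pooled"
    p_adjust = "none"             # optional BH across analytes
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown option(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "ol_options")
}

#' Read / write analysis options as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_options()` returns an `"ol_options"` list;
#'   `write_options()` returns `path` invisibly.
#' @rdname options-io
#' @export
read_options <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_options, vals)
}

#' @param opts An `"ol_options"` list.
#' @rdname options-io
#' @export
write_options <- function(opts, path) {
  yaml::write_yaml(unclass(opts), path)
  invisible(path)
}
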