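stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on an experiment bundle (or a directory written by
#' [write_bundle()]): DOC QC flagging, growth fits and specific growth rates,
#' bacterial growth efficiency, amino-acid diagenesis (TDAA, yield, DI),
#' metabolome indices and compound-class fractions, qPCR standard curves and
#' normalized gene copies, community filtering/rarefaction/diversity/
#' aggregation with copy-number adjustment, and treatment comparisons. Any
#' stage failure aborts with the stage name. The report is a pure function
#' of (inputs, options, seed); [report_checksum()] hashes it for
#' reproducibility checks.
#'
#' @param input An `"experiment_bundle"` or a directory path.
#' @param opts An [analysis_options()] list.
#' @param seed Integer seed (used by rarefaction).
#' @param stages Character vector of stages to run; default all of
#'   `"qc"`, `"growth"`, `"diagenesis"`, `"metabolome"`, `"qpcr"`,
#'   `"community"`, `"comparisons"`.
#' @return A list of class `"ol_report"` with one element per stage (tidy
#'   tibbles) plus `options` and `seed`.
#' @export
run_pipeline <- function(input, opts = analysis_options(), seed = 1,
                         stages = c("qc", "growth", "diagenesis",
                                    "metabolome", "qpcr", "community",
                                    "comparisons")) {
  bundle <- if (is.character(input)) read_bundle(input) else input
  if (!inherits(bundle, "experiment_bundle")) {
    abort("`input` must be an experiment_bundle or a bundle directory.")
  }
  report <- list(options = unclass(opts), seed = seed)

  series <- bundle$timeseries
  if ("qc" %in% stages) {
    report$timeseries <- stage_run("qc", flag_doc_outliers(
      series, analyte = opts$doc_analyte, percentile = opts$doc_percentile,
      min_group = opts$doc_min_group, group_vars = opts$doc_group_vars))
    series <- report$timeseries
  }

  fits <- NULL
  if ("growth" %in% stages) {
    report$growth <- stage_run("growth", {
      fits <- fit_growth(series, analyte = opts$growth_analyte)
      select(fits, -"fit")
    })
    report$bge <- stage_run("growth", bge_table(
      series, fits, pa_analyte = opts$growth_analyte,
      doc_analyte = opts$doc_analyte, fg_per_cell = opts$fg_per_cell))
  }

  if ("diagenesis" %in% stages) {
    report$diagenesis <- stage_run("diagenesis", {
      if (is.null(bundle$aa_profiles)) abort("input table missing")
      reference <- if (is.null(opts$di_reference)) read_aa_reference()
        else read_aa_reference(opts$di_reference)
      doc_all <- series |>
        filter(.data$analyte == opts$doc_analyte) |>
        group_by(.data$treatment, .data$time_days) |>
        summarise(
          # prefer unflagged observations; fall back to the flagged ones
          # when QC suspected every measurement at a timepoint
          doc_umol_l = if (any(.data$qc_flag == "ok"))
            mean(.data$value[.data$qc_flag == "ok"]) else mean(.data$value),
          .groups = "drop")
      doc_at <- bundle$aa_profiles |>
        distinct(.data$sample_id, .data$treatment, .data$time_days) |>
        left_join(doc_all, by = c("treatment", "time_days"))
      diagenesis_table(bundle$aa_profiles,
                       select(doc_at, "sample_id", "doc_umol_l"),
                       reference) |>
        left_join(distinct(bundle$aa_profiles, .data$sample_id,
                           .data$treatment, .data$time_days),
                  by = "sample_id")
    })
  }

  if ("metabolome" %in% stages) {
    report$metabolome <- stage_run("metabolome", {
      if (!length(bundle$feature_tables)) abort("input table missing")
      rules <- read_class_rules()
      purrr::imap(bundle$feature_tables, function(tbl, nm) {
        ann <- annotate_features(tbl, rules, modified_ai = opts$ai_modified)
        idx <- magnitude_weighted_indices(
          ann, classified_only = opts$weighted_over_classified_only)
        cnt <- element_class_counts(ann)
        frac <- class_peak_area_fractions(ann) |>
          mutate(sample_id = nm, .before = 1)
        list(summary = dplyr::bind_cols(tibble(sample_id = nm), cnt, idx),
             fractions = frac)
      }) |>
        (\(x) list(summary = bind_rows(purrr::map(x, "summary")),
                   class_fractions = bind_rows(purrr::map(x, "fractions"))))()
    })
  }

  if ("qpcr" %in% stages) {
    report$qpcr <- stage_run("qpcr", {
      if (is.null(bundle$qpcr_plate)) abort("input table missing")
      res <- analyze_qpcr_plate(bundle$qpcr_plate,
                                merge_replicates =
                                  if (opts$qpcr_merge == "mean_cq")
                                    "mean_cq" else "none")
      list(curves = select(res$curves, -"curve"), unknowns = res$unknowns)
    })
  }

  if ("community" %in% stages) {
    report$community <- stage_run("community", {
      if (is.null(bundle$asv_counts)) abort("input table missing")
      counts <- bundle$asv_counts
      if (opts$filter_before_rarefy) {
        counts <- filter_low_prevalence(counts, opts$asv_min_samples)
        counts <- rarefy_counts(counts, opts$rarefaction_depth, seed = seed)
      } else {
        counts <- rarefy_counts(counts, opts$rarefaction_depth, seed = seed)
        counts <- filter_low_prevalence(counts, opts$asv_min_samples)
      }
      div <- diversity_indices(counts)
      fam <- aggregate_taxa(counts, bundle$asv_taxonomy, rank = "family",
                            other_threshold = opts$family_other_threshold)
      adj <- fam |>
        mutate(fraction_pct = 100 * .data$fraction) |>
        rename(taxon = "group") |>
        group_by(.data$sample_id) |>
        dplyr::group_modify(~ copy_number_adjust(
          select(.x, "taxon", "fraction_pct"), bundle$copy_map,
          renormalize = opts$copy_number_renormalize)) |>
        ungroup()
      list(rarefied_counts = counts, diversity = div,
           family_fractions = fam, copy_number_adjusted = adj)
    })
  }

  if ("comparisons" %in% stages) {
    report$comparisons <- stage_run("comparisons", {
      analytes <- intersect(c(opts$growth_analyte, opts$doc_analyte),
                            unique(series$analyte))
      anova_tbl <- purrr::map(analytes, function(a) {
        cmp <- treatment_anova(series, a, scope = "pooled")
        glance(cmp)
      }) |> bind_rows()
      if (opts$p_adjust == "BH") {
        anova_tbl$p_adjusted <- stats::p.adjust(anova_tbl$p_value, "BH")
      }
      repl <- purrr::map(analytes, function(a) {
        replicate_equivalence(series, a, method = opts$replicate_test,
                              seed = seed, on_unpaired = "drop")
      }) |> bind_rows()
      list(anova = anova_tbl, replicates = repl)
    })
  }

  structure(report, class = "ol_report")
}

#' @export
print.ol_report <- function(x, ...) {
  cat("overturnlab pipeline report; stages: ",
      paste(setdiff(names(x), c("options", "seed")), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$growth)) {
    cat("\nGrowth fits:\n"); print(x$growth)
  }
  if (!is.null(x$bge)) {
    cat("\nBGE:\n"); print(x$bge)
  }
  invisible(x)
}

#' Hash a pipeline report
#'
#' Stable content hash of an [run_pipeline()] report (128-bit xxHash),
#' used to verify that identical inputs, options and seed reproduce an
#' identical report.
#'
#' @param report An `"ol_report"`.
#' @return A hash string.
#' @export
report_checksum <- function(report) {
  rlang::hash(report)
}

#' Write a report's tables to a directory
#'
#' Flattens the report into delimited tables (one CSV per tibble) plus a
#' YAML run log with the options and the report checksum.
#'
#' @param report An `"ol_report"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, name) {
    if (is.data.frame(x)) {
      readr::write_csv(x, file.path(dir, paste0(name, ".csv")),
                       progress = FALSE)
    } else if (is.matrix(x)) {
      readr::write_csv(as_tibble(x, rownames = "sample_id"),
                       file.path(dir, paste0(name, ".csv")), progress = FALSE)
    } else if (is.list(x)) {
      for (nm in names(x)) emit(x[[nm]], paste0(name, "_", nm))
    }
  }
  for (nm in setdiff(names(report), c("options", "seed"))) {
    emit(report[[nm]], nm)
  }
  yaml::write_yaml(list(options = report$options, seed = report$seed,
                        checksum = report_checksum(report)),
                   file.path(dir, "run_log.yaml"))
  invisible(dir)
}
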