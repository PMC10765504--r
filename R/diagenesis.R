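#' Amino-acid reference table for the degradation index
#'
#' Loads the per-amino-acid reference used by the degradation index (DI):
#' mean and standard deviation of the molar percentage across a calibration
#' set of DOM samples, the first-principal-component factor coefficient, and
#' the carbon atom count of each amino acid.
#'
#' The packaged default (`aa_reference_synthetic.csv`) is an explicitly
#' *synthetic* stand-in: its means sum to 100 and its coefficient signs follow
#' the published fresh-versus-degraded pattern (protein amino acids such as
#' leucine, isoleucine and phenylalanine positive; glycine, serine and
#' threonine negative), but the numbers are not transcribed from the original
#' calibration. Replace it with a transcription of the published table (via
#' `path`) for production use; every DI property used by this package (zero at
#' the reference composition, linearity in single-acid z-score perturbations,
#' scale invariance) holds for any valid reference.
#'
#' @param path Optional path to a user CSV with columns `amino_acid`,
#'   `abbrev`, `mean_molpct`, `sd_molpct`, `factor_coef`, `carbon_atoms`,
#'   `in_di_set`.
#' @return A tibble, one row per amino acid.
#' @export
read_aa_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_reference_synthetic.csv",
                        package = "overturnlab", mustWork = TRUE)
  }
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("amino_acid", "mean_molpct", "sd_molpct", "factor_coef",
            "carbon_atoms", "in_di_set")
  missing_cols <- setdiff(need, names(ref))
  if (length(missing_cols)) {
    abort(paste0("amino-acid reference is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(ref$sd_molpct[ref$in_di_set] <= 0)) {
    abort("sd_molpct must be > 0 for every amino acid in the DI set.")
  }
  if (any(ref$carbon_atoms < 1)) abort("carbon_atoms must be >= 1.")
  ref
}

#' Molar fractions of an amino-acid profile
#'
#' Converts per-amino-acid concentrations (nmol L^-1) to molar percentages
#' per sample; percentages sum to 100 within each sample.
#'
#' @param profiles Long tibble with columns `sample_id`, `amino_acid`,
#'   `conc_nmol_l`.
#' @return The input with an added `molpct` column.
#' @export
molar_fractions <- function(profiles) {
  check_profiles(profiles)
  out <- profiles |>
    group_by(.data$sample_id) |>
    mutate(total = sum(.data$conc_nmol_l)) |>
    ungroup()
  if (any(out$total <= 0)) {
    bad <- unique(out$sample_id[out$total <= 0])
    abort(paste0("all-zero amino-acid profile for sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  out |>
    mutate(molpct = 100 * .data$conc_nmol_l / .data$total) |>
    select(-"total")
}

check_profiles <- function(profiles) {
  need <- c("sample_id", "amino_acid", "conc_nmol_l")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols)) {
    abort(paste0("amino-acid profiles are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(profiles$conc_nmol_l < 0)) {
    abort("amino-acid concentrations must be >= 0.")
  }
  invisible(profiles)
}

#' Total dissolved amino acids in carbon units
#'
#' TDAA-C is the concentration-weighted sum of carbon atoms:
#' `sum_i conc_i * carbon_atoms_i`, in nmol C L^-1 per sample.
#'
#' @param profiles Long tibble (`sample_id`, `amino_acid`, `conc_nmol_l`).
#' @param reference Amino-acid reference table ([read_aa_reference()]).
#' @return Tibble with `sample_id`, `tdaa_nmol_l` (molar sum) and
#'   `tdaa_c_nmol_l`.
#' @export
#' @examples
#' p <- tibble::tibble(sample_id = "x", amino_acid = "glycine",
#'                     conc_nmol_l = 100)
#' tdaa_carbon(p)  # glycine has 2 carbons -> 200 nmol C L-1
tdaa_carbon <- function(profiles, reference = read_aa_reference()) {
  check_profiles(profiles)
  unknown <- setdiff(unique(profiles$amino_acid), reference$amino_acid)
  if (length(unknown)) {
    abort(paste0("amino acid(s) not in the reference: ",
                 paste(unknown, collapse = ", ")))
  }
  profiles |>
    left_join(select(reference, "amino_acid", "carbon_atoms"),
              by = "amino_acid") |>
    group_by(.data$sample_id) |>
    summarise(tdaa_nmol_l = sum(.data$conc_nmol_l),
              tdaa_c_nmol_l = sum(.data$conc_nmol_l * .data$carbon_atoms),
              .groups = "drop")
}

#' TDAA yield: amino-acid carbon as a percent of DOC
#'
#' `yield = (TDAA-C in nmol C L^-1 / 1000) / DOC in umol C L^-1 * 100`.
#' Higher yields indicate fresher, less diagenetically altered DOM.
#'
#' @param tdaa_c_nmol_l TDAA carbon, nmol C L^-1.
#' @param doc_umol_l DOC, umol C L^-1 (> 0).
#' @return Yield in percent.
#' @export
#' @examples
#' tdaa_yield(940, 94)  # 1%
tdaa_yield <- function(tdaa_c_nmol_l, doc_umol_l) {
  if (any(doc_umol_l <= 0)) abort("DOC must be > 0 to compute a yield.")
  (tdaa_c_nmol_l / 1000) / doc_umol_l * 100
}

#' Degradation index from molar percentages
#'
#' The degradation index is the factor-coefficient-weighted sum of
#' standardized molar-percentage anomalies over the reference's DI set:
#' \deqn{DI = \sum_i \frac{var_i - AVG var_i}{STD var_i} \cdot fac.coef_i}
#' A profile matching the reference means gives DI = 0; DI is linear in each
#' amino acid's z-score. Lower (especially < 1) indicates more degraded,
#' refractory material; higher indicates fresher DOM.
#'
#' `degradation_index_molpct()` takes molar percentages as given (one named
#' vector or a tibble with `amino_acid` and `molpct`);
#' `degradation_index()` computes them from concentrations per sample.
#'
#' @param molpct Named numeric vector of molar percentages, or a tibble with
#'   columns `amino_acid`, `molpct`.
#' @param reference Reference table ([read_aa_reference()]).
#' @return A single DI value.
#' @rdname degradation_index
#' @export
degradation_index_molpct <- function(molpct, reference = read_aa_reference()) {
  if (is.data.frame(molpct)) {
    molpct <- setNames(molpct$molpct, molpct$amino_acid)
  }
  di_set <- reference[reference$in_di_set, ]
  if (any(di_set$sd_molpct <= 0)) abort("reference sd_molpct must be > 0.")
  missing_aa <- setdiff(names(molpct), reference$amino_acid)
  if (length(missing_aa)) {
    abort(paste0("no reference entry for: ", paste(missing_aa, collapse = ", ")))
  }
  # acids absent from the profile contribute their 0-concentration mol%
  v <- setNames(rep(0, nrow(di_set)), di_set$amino_acid)
  shared <- intersect(names(molpct), di_set$amino_acid)
  v[shared] <- molpct[shared]
  sum((v - di_set$mean_molpct) / di_set$sd_molpct * di_set$factor_coef)
}

#' @param profiles Long tibble (`sample_id`, `amino_acid`, `conc_nmol_l`).
#' @return `degradation_index()` returns a tibble `sample_id`, `di`.
#' @rdname degradation_index
#' @export
degradation_index <- function(profiles, reference = read_aa_reference()) {
  molar_fractions(profiles) |>
    group_by(.data$sample_id) |>
    summarise(
      di = degradation_index_molpct(
        setNames(.data$molpct, .data$amino_acid), reference),
      .groups = "drop")
}

#' Per-sample diagenesis summary
#'
#' Convenience wrapper producing, per sample: total TDAA, TDAA carbon, TDAA
#' yield against a supplied DOC concentration, and the degradation index.
#'
#' @param profiles Long tibble (`sample_id`, `amino_acid`, `conc_nmol_l`).
#' @param doc Tibble with `sample_id`, `doc_umol_l`.
#' @param reference Reference table.
#' @return Tibble with `sample_id`, `tdaa_nmol_l`, `tdaa_c_nmol_l`,
#'   `tdaa_yield_pct`, `di`.
#' @export
diagenesis_table <- function(profiles, doc, reference = read_aa_reference()) {
  tdaa_carbon(profiles, reference) |>
    left_join(doc, by = "sample_id") |>
    mutate(tdaa_yield_pct = tdaa_yield(.data$tdaa_c_nmol_l, .data$doc_umol_l)) |>
    left_join(degradation_index(profiles, reference), by = "sample_id") |>
    select("sample_id", "tdaa_nmol_l", "tdaa_c_nmol_l", "tdaa_yield_pct", "di")
}
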