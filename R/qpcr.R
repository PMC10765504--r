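#' Gene copies in a qPCR standard
#'
#' Converts the DNA mass of a standard of known length to gene copies:
#' \deqn{GCN = \frac{DNA (ng) \times 6.0221\times10^{23}}{length (bp) \times 10^{9} (ng/g) \times 660 (g/mol\,bp)}}
#' with 660 g per mole of base pair for double-stranded DNA.
#'
#' @param dna_ng DNA mass in ng (>= 0).
#' @param standard_length_bp Standard (amplicon/plasmid) length in bp (> 0).
#' @return Gene copies.
#' @export
#' @examples
#' standard_copies(1, 1000)  # ~9.124e8 copies
standard_copies <- function(dna_ng, standard_length_bp) {
  if (any(standard_length_bp <= 0)) abort("standard length must be > 0 bp.")
  if (any(dna_ng < 0)) abort("DNA mass must be >= 0 ng.")
  dna_ng * 6.0221e23 / (standard_length_bp * 1e9 * 660)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a standard dilution
#' series (conventionally 10^6 down to 10^1 copies). Amplification efficiency
#' is `E = 10^(-1/slope) - 1`; a slope of -3.3219 corresponds to perfect
#' per-cycle doubling (100%).
#'
#' @param standards Tibble with columns `copies` (> 0) and `cq`, spanning at
#'   least 3 distinct copy levels.
#' @return An object of class `"standard_curve"`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency` (fraction),
#'   `efficiency_percent`, `cq_range`, `valid` (FALSE for a non-negative
#'   slope), and the standards used.
#' @export
#' @examples
#' s <- tibble::tibble(copies = 10^(6:1), cq = 10 - (-2.93) * 0 + -2.93 * (6:1) + 30)
#' fit_standard_curve(tibble::tibble(copies = 10^(6:1), cq = 38 - 2.93 * (6:1)))
fit_standard_curve <- function(standards) {
  if (!all(c("copies", "cq") %in% names(standards))) {
    abort("standards need 'copies' and 'cq' columns.")
  }
  if (any(standards$copies <= 0)) abort("standard copies must be > 0.")
  if (dplyr::n_distinct(standards$copies) < 3) {
    abort("standard curve needs >= 3 distinct copy levels.")
  }
  m <- lm(cq ~ log10(copies), data = standards)
  slope <- unname(coef(m)[2]); intercept <- unname(coef(m)[1])
  ss_res <- sum(resid(m)^2)
  ss_tot <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  valid <- slope < 0
  if (!valid) warn("standard curve has a non-negative slope; flagged invalid.")
  eff <- if (valid) 10^(-1 / slope) - 1 else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = eff, efficiency_percent = 100 * eff,
         cq_range = range(standards$cq), valid = valid,
         standards = as_tibble(standards)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  Cq = %.4f + %.4f x log10(copies)\n", x$intercept, x$slope))
  cat(sprintf("  R^2 = %.4f, efficiency = %.1f%%%s\n", x$r_squared,
              x$efficiency_percent, if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         unit = c("Cq", "Cq per log10(copies)"))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, efficiency = x$efficiency,
         efficiency_percent = x$efficiency_percent, valid = x$valid,
         n = nrow(x$standards))
}

#' Quantify unknowns from a standard curve
#'
#' Inverts the fitted curve, `copies = 10^((Cq - intercept) / slope)`. Cq
#' values outside the standards' observed Cq range are still converted but
#' flagged out-of-range.
#'
#' @param curve A [fit_standard_curve()] result (must be valid).
#' @param cq Numeric vector of Cq values.
#' @return Tibble `cq`, `copies`, `out_of_range`.
#' @export
quantify_unknowns <- function(curve, cq) {
  if (!inherits(curve, "standard_curve")) abort("`curve` must be a standard_curve.")
  if (!curve$valid) abort("cannot quantify from an invalid standard curve.")
  tibble(
    cq = cq,
    copies = 10^((cq - curve$intercept) / curve$slope),
    out_of_range = cq < curve$cq_range[1] | cq > curve$cq_range[2]
  )
}

#' Normalize gene copies by DNA mass
#'
#' @param copies Gene copies (>= 0).
#' @param dna_ng DNA mass in ng (> 0).
#' @return Copies per ng of DNA.
#' @export
normalize_gcn <- function(copies, dna_ng) {
  if (any(dna_ng <= 0)) abort("DNA mass must be > 0 ng to normalize.")
  copies / dna_ng
}

#' Analyze a qPCR plate
#'
#' Full plate workflow per gene: fit the standard curve from `role ==
#' "standard"` wells, check negative controls (any detected Cq in a negative
#' raises a plate-level warning), merge replicate unknowns by mean Cq per
#' (sample, gene), quantify, and normalize per ng of template DNA.
#'
#' @param plate Tibble with columns `well`, `gene`, `role`
#'   (`standard`/`unknown`/`negative`), `copies` (standards), `cq`, `dna_ng`
#'   (unknowns), `sample_id` (unknowns), `replicate`.
#' @param merge_replicates `"mean_cq"` (default) merges replicates by mean Cq
#'   before quantification; `"none"` quantifies each replicate.
#' @return List with `curves` (tibble of per-gene curve summaries, fitted
#'   objects in a list-column) and `unknowns` (tibble with `gene`,
#'   `sample_id`, `cq`, `copies`, `gcn_per_ng`, `out_of_range`).
#' @export
analyze_qpcr_plate <- function(plate, merge_replicates = c("mean_cq", "none")) {
  merge_replicates <- match.arg(merge_replicates)
  need <- c("gene", "role", "cq")
  missing_cols <- setdiff(need, names(plate))
  if (length(missing_cols)) {
    abort(paste0("plate is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  negs <- filter(plate, .data$role == "negative", is.finite(.data$cq))
  if (nrow(negs)) {
    warn(paste0("amplification detected in ", nrow(negs),
                " negative control well(s)."))
  }
  genes <- unique(plate$gene[plate$role == "standard"])
  curves <- purrr::map(genes, function(g) {
    st <- filter(plate, .data$gene == g, .data$role == "standard")
    fit_standard_curve(st)
  })
  names(curves) <- genes
  curve_tbl <- purrr::map2(genes, curves, function(g, cv) {
    glance(cv) |> mutate(gene = g, slope = cv$slope,
                         intercept = cv$intercept, .before = 1)
  }) |> bind_rows()
  curve_tbl$curve <- curves

  unk <- filter(plate, .data$role == "unknown")
  res <- NULL
  if (nrow(unk)) {
    if (!all(c("sample_id", "dna_ng") %in% names(unk))) {
      abort("unknown wells need 'sample_id' and 'dna_ng' columns.")
    }
    if (merge_replicates == "mean_cq") {
      unk <- unk |>
        group_by(.data$gene, .data$sample_id) |>
        summarise(cq = mean(.data$cq), dna_ng = mean(.data$dna_ng),
                  .groups = "drop")
    }
    res <- unk |>
      filter(.data$gene %in% genes) |>
      group_by(.data$gene) |>
      dplyr::group_modify(function(d, key) {
        q <- quantify_unknowns(curves[[key$gene]], d$cq)
        mutate(d, copies = q$copies, out_of_range = q$out_of_range,
               gcn_per_ng = normalize_gcn(q$copies, d$dna_ng))
      }) |>
      ungroup()
  }
  list(curves = curve_tbl, unknowns = res)
}
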