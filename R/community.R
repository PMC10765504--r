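asv_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

check_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("ASV counts need sample rownames and ASV colnames.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("ASV counts must be non-negative integers.")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Remove low-prevalence ASVs
#'
#' Drops amplicon sequence variants with nonzero counts in fewer than
#' `min_samples` samples (the conventional "present in less than four
#' samples" screen); an ASV present in exactly `min_samples` samples is
#' retained.
#'
#' @param counts Integer matrix, samples x ASVs, with dimnames.
#' @param min_samples Minimum number of samples an ASV must occur in;
#'   default 4.
#' @return The filtered count matrix.
#' @export
filter_low_prevalence <- function(counts, min_samples = 4) {
  counts <- check_counts(counts)
  prevalence <- colSums(counts > 0)
  counts[, prevalence >= min_samples, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (seeded, reproducible); samples with fewer than `depth` total reads
#' are dropped with a notice so all retained samples are comparable.
#'
#' @param counts Integer matrix, samples x ASVs.
#' @param depth Rarefaction depth in reads; default 10000.
#' @param seed Integer seed.
#' @return The rarefied count matrix (row sums all equal `depth`).
#' @export
rarefy_counts <- function(counts, depth = 10000, seed = 1) {
  counts <- check_counts(counts)
  if (depth < 1) abort("rarefaction depth must be >= 1.")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (any(!keep)) {
    inform(paste0("dropping ", sum(!keep), " sample(s) below ", depth,
                  " reads: ", paste(rownames(counts)[!keep], collapse = ", ")))
  }
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) return(counts)
  # vegan heuristically warns about large "observed counts"; counts were
  # already validated as non-negative integers above
  out <- withr::with_seed(seed,
                          suppressWarnings(vegan::rrarefy(counts, depth)))
  storage.mode(out) <- "integer"
  out
}

#' Alpha-diversity indices per sample
#'
#' Shannon index `H = -sum(p_i log p_i)` (natural log) and the Gini–Simpson
#' index `1 - sum(p_i^2)`; both are maximal on uniform compositions and zero
#' for a single-taxon sample.
#'
#' @param counts Integer matrix, samples x ASVs, every row sum > 0.
#' @return Tibble `sample_id`, `shannon`, `simpson`.
#' @export
#' @examples
#' m <- matrix(25L, 1, 4, dimnames = list("s1", paste0("asv", 1:4)))
#' diversity_indices(m)  # shannon = log(4), simpson = 0.75
diversity_indices <- function(counts) {
  counts <- check_counts(counts)
  if (any(rowSums(counts) == 0)) abort("every sample must have > 0 reads.")
  tibble(
    sample_id = rownames(counts),
    shannon = as.numeric(vegan::diversity(counts, index = "shannon")),
    simpson = as.numeric(vegan::diversity(counts, index = "simpson"))
  )
}

#' Aggregate ASVs at a taxonomic rank
#'
#' Sums per-sample relative abundances within groups at the requested rank of
#' the lineage strings (`domain;phylum;class;order;family;genus`), pooling
#' groups whose share of the experiment-wide total is below `other_threshold`
#' into `"other"`. ASVs with no name at the rank are grouped as
#' `"unclassified"`. Per-sample fractions sum to 1.
#'
#' @param counts Integer matrix, samples x ASVs.
#' @param taxonomy Tibble with columns `asv`, `lineage`.
#' @param rank One of `r paste0('"', asv_ranks, '"', collapse = ", ")`.
#' @param other_threshold Pooling threshold as a fraction of total reads;
#'   default 0.01 (groups under 1% pooled).
#' @return Long tibble `sample_id`, `group`, `fraction`.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = "family",
                           other_threshold = 0.01) {
  counts <- check_counts(counts)
  if (!rank %in% asv_ranks) {
    abort(paste0("`rank` must be one of: ", paste(asv_ranks, collapse = ", ")))
  }
  if (!all(c("asv", "lineage") %in% names(taxonomy))) {
    abort("taxonomy needs 'asv' and 'lineage' columns.")
  }
  pos <- match(rank, asv_ranks)
  fields <- strsplit(taxonomy$lineage, ";", fixed = TRUE)
  if (!any(lengths(fields) >= pos)) {
    abort(paste0("rank '", rank, "' is absent from every lineage string."))
  }
  grp <- vapply(fields, function(f) {
    if (length(f) >= pos && nzchar(trimws(f[pos]))) trimws(f[pos])
    else "unclassified"
  }, character(1))
  names(grp) <- taxonomy$asv
  missing_tax <- setdiff(colnames(counts), taxonomy$asv)
  if (length(missing_tax)) {
    abort(paste0("ASV(s) without taxonomy: ",
                 paste(head(missing_tax, 5), collapse = ", ")))
  }
  groups <- grp[colnames(counts)]
  agg <- t(rowsum(t(counts), groups))  # samples x groups
  share <- colSums(agg) / sum(agg)
  pooled <- names(share)[share < other_threshold]
  if (length(pooled)) {
    other <- rowSums(agg[, pooled, drop = FALSE])
    agg <- cbind(agg[, setdiff(colnames(agg), pooled), drop = FALSE],
                 other = other)
  }
  rel <- agg / rowSums(agg)
  as_tibble(rel, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "group",
                        values_to = "fraction")
}

#' Adjust relative abundances for 16S rRNA copy number
#'
#' Multi-copy taxa are over-represented in amplicon data in proportion to
#' their rRNA operon count. Each taxon's percent of total ASVs is divided by
#' its copy number; with `renormalize = FALSE` (the reporting convention this
#' package follows by default) the adjusted value is still expressed against
#' the original total, so a family at 75% with 3 copies becomes 25% of total
#' ASVs. With `renormalize = TRUE` the divided fractions are rescaled to sum
#' to 100, which is the statistically preferable composition.
#'
#' @param fractions Tibble with columns `taxon` and `fraction_pct`
#'   (percent of total, in `[0, 100]`).
#' @param copy_map Tibble with columns `taxon`, `copies` (>= 1); taxa absent
#'   from the map default to 1 copy.
#' @param renormalize Rescale adjusted fractions to sum to 100; default
#'   `FALSE`.
#' @return The input with added `copies` and `adjusted_pct`.
#' @export
#' @examples
#' fr <- tibble::tibble(taxon = c("Chlorobiales", "rest"),
#'                      fraction_pct = c(75, 25))
#' cm <- tibble::tibble(taxon = "Chlorobiales", copies = 3)
#' copy_number_adjust(fr, cm)  # Chlorobiales: 25% of total ASVs
copy_number_adjust <- function(fractions, copy_map, renormalize = FALSE) {
  if (!all(c("taxon", "fraction_pct") %in% names(fractions))) {
    abort("`fractions` needs 'taxon' and 'fraction_pct' columns.")
  }
  if (any(fractions$fraction_pct < 0 | fractions$fraction_pct > 100)) {
    abort("fractions must lie in [0, 100] percent.")
  }
  if (!all(c("taxon", "copies") %in% names(copy_map))) {
    abort("`copy_map` needs 'taxon' and 'copies' columns.")
  }
  if (any(copy_map$copies < 1)) abort("copy numbers must be >= 1.")
  out <- fractions |>
    left_join(copy_map, by = "taxon") |>
    mutate(copies = dplyr::coalesce(.data$copies, 1),
           adjusted_pct = .data$fraction_pct / .data$copies)
  if (renormalize) {
    out <- mutate(out,
                  adjusted_pct = 100 * .data$adjusted_pct /
                    sum(.data$adjusted_pct))
  }
  out
}
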