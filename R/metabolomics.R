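#' Parse an elemental formula string
#'
#' Accepts formulas over the CHNOSP alphabet ("C6H12O6", "CH4", ...); an
#' omitted count means 1. Vectorized; empty strings or `NA` yield all-zero
#' counts with `formula_assigned = FALSE`.
#'
#' @param text Character vector of formula strings.
#' @return A tibble with integer columns `C`, `H`, `N`, `O`, `S`, `P` and a
#'   logical `formula_assigned`.
#' @export
#' @examples
#' parse_formula(c("C6H12O6", "CH4", ""))
parse_formula <- function(text) {
  elements <- c("C", "H", "N", "O", "S", "P")
  out <- matrix(0L, nrow = length(text), ncol = length(elements),
                dimnames = list(NULL, elements))
  assigned <- !is.na(text) & nzchar(text)
  for (i in which(assigned)) {
    s <- text[i]
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(s)) {
      abort(paste0("cannot parse formula: '", s, "'"))
    }
    for (tok in toks) {
      sym <- gsub("[0-9]", "", tok)
      if (!sym %in% elements) {
        abort(paste0("unknown element symbol '", sym, "' in formula '", s, "'"))
      }
      cnt <- gsub("[A-Za-z]", "", tok)
      out[i, sym] <- out[i, sym] + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
  }
  res <- as_tibble(out)
  res$formula_assigned <- assigned
  res
}

#' Double-bond equivalents of a molecular formula
#'
#' `DBE = (2 + 2C - H + N + P) / 2`, a count of rings plus double bonds.
#' Half-integral values (nitrogen-rule parity violations) are returned as-is;
#' callers may flag them.
#'
#' @param C,H,N,P Element counts (vectorized).
#' @return DBE values.
#' @export
#' @examples
#' double_bond_equivalents(C = 6, H = 6)  # benzene: 4
double_bond_equivalents <- function(C, H, N = 0, P = 0) {
  (2 + 2 * C - H + N + P) / 2
}

#' Aromaticity index of a molecular formula
#'
#' The modified aromaticity index
#' `AI_mod = (1 + C - 0.5 O - S - 0.5 (N + P + H)) / (C - 0.5 O - N - S - P)`
#' treats half the oxygen as carbonyl-like; the unmodified variant
#' (`modified = FALSE`) counts all oxygen:
#' `AI = (1 + C - O - S - 0.5 H) / (C - O - N - S - P)`.
#' By convention the index is clamped to 0 when the numerator is negative or
#' the denominator is non-positive.
#'
#' @param C,H,N,O,S,P Element counts (vectorized).
#' @param modified Use AI_mod (default) or the unmodified AI.
#' @return Aromaticity index values in `[0, Inf)`.
#' @export
#' @examples
#' aromaticity_index(C = 6, H = 6)        # benzene: 2/3
#' aromaticity_index(C = 6, H = 12, O = 6)  # glucose: clamped to 0
aromaticity_index <- function(C, H, N = 0, O = 0, S = 0, P = 0,
                              modified = TRUE) {
  if (modified) {
    num <- 1 + C - 0.5 * O - S - 0.5 * (N + P + H)
    den <- C - 0.5 * O - N - S - P
  } else {
    num <- 1 + C - O - S - 0.5 * H
    den <- C - O - N - S - P
  }
  ai <- ifelse(den <= 0 | num < 0, 0, num / den)
  ai
}

#' Compound-class rule table
#'
#' Loads the priority-ordered van Krevelen / aromaticity rule table used to
#' bin molecular formulas into DOM compound classes (black carbon,
#' carbohydrates, condensed hydrocarbons, highly unsaturated compounds,
#' lignin, lipids, peptides, proteins, protein maya, polyphenols, unsaturated
#' aliphatic compounds, sugars, saturated fatty acids, CRAM). Each rule is a
#' conjunction of closed-interval bounds on element counts, H/C, O/C, the
#' aromaticity index and DBE ratios; `NA` bounds are unconstrained. The first
#' matching rule in priority order wins; features matching none are
#' `"unassigned"`. The packaged defaults are literature-conventional bounds
#' and are meant to be edited.
#'
#' @param path Optional path to a user rule CSV with the same columns as the
#'   packaged `compound_classes.csv`.
#' @return A tibble of rules sorted by `priority`.
#' @export
read_class_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_classes.csv",
                        package = "overturnlab", mustWork = TRUE)
  }
  rules <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("priority", "class") %in% names(rules))) {
    abort("class rule table must have 'priority' and 'class' columns.")
  }
  if (anyDuplicated(rules$priority)) abort("rule priorities must be unique.")
  arrange(rules, .data$priority)
}

rule_bounds <- list(
  c_min = c("C", "min"), c_max = c("C", "max"),
  hc_min = c("hc", "min"), hc_max = c("hc", "max"),
  oc_min = c("oc", "min"), oc_max = c("oc", "max"),
  ai_min = c("ai", "min"), ai_max = c("ai", "max"),
  n_min = c("N", "min"), n_max = c("N", "max"),
  s_min = c("S", "min"), s_max = c("S", "max"),
  p_min = c("P", "min"), p_max = c("P", "max"),
  dbec_min = c("dbe_c", "min"), dbec_max = c("dbe_c", "max"),
  dbeh_min = c("dbe_h", "min"), dbeh_max = c("dbe_h", "max"),
  dbeo_min = c("dbe_o", "min"), dbeo_max = c("dbe_o", "max")
)

# logical matrix: features x rules, TRUE where all of a rule's bounds hold
match_rules <- function(ann, rules) {
  vals <- list(
    C = ann$C, N = ann$N, S = ann$S, P = ann$P,
    hc = ann$hc, oc = ann$oc, ai = ann$ai,
    dbe_c = ann$dbe / ann$C,
    dbe_h = ann$dbe / ann$H,
    dbe_o = ifelse(ann$O > 0, ann$dbe / ann$O, Inf)
  )
  sapply(seq_len(nrow(rules)), function(j) {
    hit <- rep(TRUE, nrow(ann))
    for (b in names(rule_bounds)) {
      if (!b %in% names(rules)) next
      bound <- rules[[b]][j]
      if (is.na(bound)) next
      v <- vals[[rule_bounds[[b]][1]]]
      hit <- hit & if (rule_bounds[[b]][2] == "min") v >= bound else v <= bound
    }
    hit
  })
}

#' Annotate an mzRT feature table with molecular indices and classes
#'
#' Parses assigned formulas and adds element counts, H/C, O/C, DBE, the
#' aromaticity index, a nitrogen-rule parity flag (`half_integer_dbe`) and
#' the compound class (first matching rule; `"unassigned"` when no rule
#' matches or no formula is assigned).
#'
#' @param features Tibble with columns `mz`, `rt`, `magnitude` and `formula`
#'   (empty string or `NA` = no assigned formula).
#' @param rules Rule table ([read_class_rules()]).
#' @param modified_ai Use the modified aromaticity index; default `TRUE`.
#' @return The feature table with added columns `C`,`H`,`N`,`O`,`S`,`P`,
#'   `formula_assigned`, `hc`, `oc`, `dbe`, `half_integer_dbe`, `ai`,
#'   `class`.
#' @export
annotate_features <- function(features, rules = read_class_rules(),
                              modified_ai = TRUE) {
  need <- c("mz", "rt", "magnitude", "formula")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(features$magnitude < 0, na.rm = TRUE)) {
    abort("peak magnitudes must be >= 0.")
  }
  counts <- parse_formula(features$formula)
  ann <- dplyr::bind_cols(as_tibble(features), counts)
  bad <- ann$formula_assigned & (ann$C < 1 | ann$H < 1)
  if (any(bad)) {
    abort(paste0("assigned formulas must contain C and H (rows ",
                 paste(head(which(bad), 5), collapse = ", "), ")."))
  }
  ann <- ann |>
    mutate(
      hc = ifelse(.data$formula_assigned, .data$H / .data$C, NA_real_),
      oc = ifelse(.data$formula_assigned, .data$O / .data$C, NA_real_),
      dbe = ifelse(.data$formula_assigned,
                   double_bond_equivalents(.data$C, .data$H, .data$N, .data$P),
                   NA_real_),
      half_integer_dbe = !is.na(.data$dbe) & .data$dbe %% 1 != 0,
      ai = ifelse(.data$formula_assigned,
                  aromaticity_index(.data$C, .data$H, .data$N, .data$O,
                                    .data$S, .data$P, modified = modified_ai),
                  NA_real_)
    )
  ann$class <- "unassigned"
  idx <- which(ann$formula_assigned)
  if (length(idx)) {
    hits <- match_rules(ann[idx, ], rules)
    hits <- matrix(hits, nrow = length(idx))
    first <- apply(hits, 1, function(h) if (any(h)) which(h)[1] else NA_integer_)
    ann$class[idx] <- ifelse(is.na(first), "unassigned", rules$class[first])
  }
  ann
}

#' Magnitude-weighted molecular indices
#'
#' Per-sample bulk indices: each of O/C, H/C and DBE averaged over
#' formula-assigned features with weights proportional to peak magnitude,
#' `index_w = sum(magnitude_i * index_i) / sum(magnitude_i)`. The weighted
#' index always lies between the per-feature extremes and is invariant to a
#' uniform rescaling of magnitudes.
#'
#' @param annotated An [annotate_features()] table.
#' @param classified_only Average over classified (non-"unassigned") features
#'   only, instead of all assigned formulas; default `FALSE`.
#' @return One-row tibble `oc_w`, `hc_w`, `dbe_w`, `n_used`.
#' @export
magnitude_weighted_indices <- function(annotated, classified_only = FALSE) {
  x <- filter(annotated, .data$formula_assigned)
  if (classified_only) x <- filter(x, .data$class != "unassigned")
  if (!nrow(x) || sum(x$magnitude) <= 0) {
    abort("no assigned features with positive total magnitude.")
  }
  w <- x$magnitude / sum(x$magnitude)
  tibble(oc_w = sum(w * x$oc), hc_w = sum(w * x$hc),
         dbe_w = sum(w * x$dbe), n_used = nrow(x))
}

#' Feature and heteroatom-class counts
#'
#' Counts features, assigned formulas, and the disjoint CHO (no N, S or P),
#' CHON (N but no S) and CHOS (S but no N) heteroatom classes; formulas with
#' both N and S are reported separately as `n_chons`.
#'
#' @param annotated An [annotate_features()] table.
#' @return One-row tibble `n_features`, `n_formulas`, `n_cho`, `n_chon`,
#'   `n_chos`, `n_chons`.
#' @export
element_class_counts <- function(annotated) {
  a <- filter(annotated, .data$formula_assigned)
  tibble(
    n_features = nrow(annotated),
    n_formulas = nrow(a),
    n_cho = sum(a$N == 0 & a$S == 0 & a$P == 0),
    n_chon = sum(a$N > 0 & a$S == 0),
    n_chos = sum(a$S > 0 & a$N == 0),
    n_chons = sum(a$N > 0 & a$S > 0)
  )
}

#' Peak-area fraction of each compound class
#'
#' Per-class total magnitude divided by the total magnitude of all classified
#' (non-"unassigned") features; fractions sum to 1.
#'
#' @param annotated An [annotate_features()] table.
#' @return Tibble `class`, `magnitude`, `fraction`, sorted by fraction.
#' @export
class_peak_area_fractions <- function(annotated) {
  x <- filter(annotated, .data$class != "unassigned")
  if (!nrow(x)) abort("no classified features.")
  x |>
    group_by(.data$class) |>
    summarise(magnitude = sum(.data$magnitude), .groups = "drop") |>
    mutate(fraction = .data$magnitude / sum(.data$magnitude)) |>
    arrange(dplyr::desc(.data$fraction))
}
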