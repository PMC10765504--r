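rules <- read_class_rules()

feature_row <- function(formula, magnitude = 1) {
  tibble::tibble(mz = 100, rt = 60, magnitude = magnitude, formula = formula)
}

test_that("formula parsing handles implicit counts and rejects unknown symbols", {
  out <- parse_formula(c("C6H12O6", "CH4", ""))
  expect_equal(out$C, c(6L, 1L, 0L))
  expect_equal(out$H, c(12L, 4L, 0L))
  expect_equal(out$O, c(6L, 0L, 0L))
  expect_equal(out$formula_assigned, c(TRUE, TRUE, FALSE))
  expect_error(parse_formula("X2Y"), "unknown element")
})

test_that("DBE follows the half-of-(2 + 2C - H + N + P) rule", {
  expect_equal(double_bond_equivalents(C = 6, H = 12), 1)  # glucose
  expect_equal(double_bond_equivalents(C = 1, H = 4), 0)   # methane
  expect_equal(double_bond_equivalents(C = 6, H = 6), 4)   # benzene
  expect_equal(double_bond_equivalents(C = 5, H = 9, N = 1), 2)
  # parity violation gives a half-integer, not an error
  expect_equal(double_bond_equivalents(C = 2, H = 5), 0.5)
})

test_that("aromaticity index evaluates and clamps by convention", {
  expect_equal(aromaticity_index(C = 6, H = 6), 4 / 6)
  expect_equal(aromaticity_index(C = 6, H = 12, O = 6), 0)  # negative numerator
  expect_equal(aromaticity_index(C = 2, H = 2, O = 6), 0)   # denominator <= 0
  # unmodified variant counts all oxygen
  expect_equal(aromaticity_index(C = 10, H = 6, O = 2, modified = FALSE),
               (1 + 10 - 2 - 3) / (10 - 2))
})

test_that("compound-class assignment follows the priority rule table", {
  ann <- annotate_features(dplyr::bind_rows(
    feature_row("C6H6"),      # AI 0.667 -> condensed hydrocarbons
    feature_row("C6H12O6"),   # H/C 2, O/C 1 -> sugars branch
    feature_row("C20H10"),    # aromatic, C >= 15 -> black carbon
    feature_row("C5H20N2S2"), # matches no rule
    feature_row("")), rules)
  expect_equal(ann$class,
               c("condensed hydrocarbons", "sugars", "black carbon",
                 "unassigned", "unassigned"))
})

test_that("classification agrees with a brute-force all-rules oracle on random formulas", {
  set.seed(99)
  n <- 300
  C <- sample(4:40, n, TRUE)
  H <- pmax(1L, as.integer(round(C * runif(n, 0.3, 2.4))))
  O <- as.integer(round(C * runif(n, 0, 1.2)))
  N <- ifelse(runif(n) < 0.4, sample(0:3, n, TRUE), 0L)
  S <- ifelse(runif(n) < 0.1, 1L, 0L)
  P <- ifelse(runif(n) < 0.05, 1L, 0L)
  formulas <- paste0("C", C, "H", H,
                     ifelse(N > 0, paste0("N", N), ""),
                     ifelse(O > 0, paste0("O", O), ""),
                     ifelse(P > 0, paste0("P", P), ""),
                     ifelse(S > 0, paste0("S", S), ""))
  tbl <- tibble::tibble(mz = 1, rt = 1, magnitude = 1, formula = formulas)
  ann <- annotate_features(tbl, rules)

  in_bound <- function(v, lo, hi) {
    (is.na(lo) | v >= lo) & (is.na(hi) | v <= hi)
  }
  for (i in seq_len(nrow(ann))) {
    dbe <- ann$dbe[i]
    matches <- character(0)
    for (j in seq_len(nrow(rules))) {
      r <- rules[j, ]
      ok <- in_bound(ann$C[i], r$c_min, r$c_max) &&
        in_bound(ann$hc[i], r$hc_min, r$hc_max) &&
        in_bound(ann$oc[i], r$oc_min, r$oc_max) &&
        in_bound(ann$ai[i], r$ai_min, r$ai_max) &&
        in_bound(ann$N[i], r$n_min, r$n_max) &&
        in_bound(ann$S[i], r$s_min, r$s_max) &&
        in_bound(ann$P[i], r$p_min, r$p_max) &&
        in_bound(dbe / ann$C[i], r$dbec_min, r$dbec_max) &&
        in_bound(dbe / ann$H[i], r$dbeh_min, r$dbeh_max) &&
        in_bound(if (ann$O[i] > 0) dbe / ann$O[i] else Inf,
                 r$dbeo_min, r$dbeo_max)
      if (ok) matches <- c(matches, r$class)
    }
    expected <- if (length(matches)) matches[1] else "unassigned"
    expect_identical(ann$class[i], expected)
    # where exactly one rule matches, order of the rules cannot matter
    if (length(matches) == 1) expect_identical(ann$class[i], matches)
  }
})

test_that("magnitude-weighted indices interpolate between per-feature values", {
  tbl <- dplyr::bind_rows(feature_row("C10H12O2", 1),
                          feature_row("C10H12O6", 1))
  ann <- annotate_features(tbl, rules)
  idx <- magnitude_weighted_indices(ann)
  expect_equal(idx$oc_w, mean(c(0.2, 0.6)))  # equal weights: plain mean

  # 3:1 weights on DBE 2 and 6 -> 3
  dbe_pair <- dplyr::bind_rows(feature_row("C6H10", 3),  # DBE 2
                               feature_row("C8H6", 1))   # DBE 6
  annp <- annotate_features(dbe_pair, rules)
  expect_equal(magnitude_weighted_indices(annp)$dbe_w, 3)

  single <- annotate_features(feature_row("C6H12O6"), rules)
  s <- magnitude_weighted_indices(single)
  expect_equal(s$oc_w, 1); expect_equal(s$hc_w, 2)
})

test_that("weighted indices are bounded by extremes and scale-invariant", {
  set.seed(17)
  C <- sample(5:30, 40, TRUE)
  H <- pmax(1L, as.integer(round(C * runif(40, 0.5, 2.2))))
  O <- as.integer(round(C * runif(40, 0, 1)))
  tbl <- tibble::tibble(mz = 1, rt = 1,
                        magnitude = stats::rlnorm(40),
                        formula = paste0("C", C, "H", H,
                                         ifelse(O > 0, paste0("O", O), "")))
  ann <- annotate_features(tbl, rules)
  idx <- magnitude_weighted_indices(ann)
  expect_gte(idx$oc_w, min(ann$oc)); expect_lte(idx$oc_w, max(ann$oc))
  expect_gte(idx$hc_w, min(ann$hc)); expect_lte(idx$hc_w, max(ann$hc))
  expect_gte(idx$dbe_w, min(ann$dbe)); expect_lte(idx$dbe_w, max(ann$dbe))
  ann10 <- dplyr::mutate(ann, magnitude = magnitude * 10)
  expect_equal(magnitude_weighted_indices(ann10), idx)
})

test_that("heteroatom counts partition assigned formulas", {
  tbl <- dplyr::bind_rows(feature_row("C6H12O6"), feature_row("C5H9NO4"),
                          feature_row("C2H6OS"), feature_row("C5H11NO2S"),
                          feature_row(""))
  cnt <- element_class_counts(annotate_features(tbl, rules))
  expect_equal(cnt$n_features, 5L)
  expect_equal(cnt$n_formulas, 4L)
  expect_equal(cnt$n_cho, 1L)
  expect_equal(cnt$n_chon, 1L)
  expect_equal(cnt$n_chos, 1L)
  expect_equal(cnt$n_chons, 1L)
  empty <- element_class_counts(
    annotate_features(feature_row("")[0, ], rules))
  expect_true(all(unlist(empty) == 0))
})

test_that("class peak-area fractions sum to one", {
  tbl <- dplyr::bind_rows(feature_row("C6H6", 2), feature_row("C10H8", 2),
                          feature_row("C6H12O6", 4))
  fr <- class_peak_area_fractions(annotate_features(tbl, rules))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  expect_equal(fr$fraction[fr$class == "condensed hydrocarbons"], 0.5)
  expect_equal(fr$fraction[fr$class == "sugars"], 0.5)
  one <- class_peak_area_fractions(annotate_features(feature_row("C6H6"),
                                                     rules))
  expect_equal(one$fraction, 1)
})
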