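# in-code fixtures shared across test files

toy_series <- function(values, treatment = "S/S", bottle = "A",
                       analyte = "DOC", unit = "umol C L-1",
                       times = seq_along(values) - 1) {
  tibble::tibble(treatment = treatment, bottle = bottle, time_days = times,
                 analyte = analyte, value = values, unit = unit,
                 qc_flag = "ok")
}

# logistic trajectory used by growth-fit tests
logistic_curve <- function(t, K, N0, r) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

# small ASV count matrix with dimnames
toy_counts <- function(mat, samples = NULL, asvs = NULL) {
  m <- as.matrix(mat)
  rownames(m) <- samples %||% rownames(m) %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- asvs %||% colnames(m) %||% paste0("asv", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent one-way-ANOVA F statistic from sums (oracle helper)
f_oracle <- function(values, groups) {
  n <- length(values)
  k <- length(unique(groups))
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}
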