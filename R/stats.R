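#' One-way ANOVA across treatments with Tukey HSD
#'
#' Compares an analyte across treatments, either within a single timepoint
#' (`scope = "timepoint"`, `at` giving the day) or pooling all timepoints
#' (`scope = "pooled"`). Pairwise treatment contrasts use Tukey's honest
#' significant difference on the fitted ANOVA. QC-flagged observations are
#' excluded.
#'
#' @param series An incubation series tibble.
#' @param analyte Analyte label to compare.
#' @param scope `"timepoint"` or `"pooled"`.
#' @param at Day to compare when `scope = "timepoint"`.
#' @return A list of class `"treatment_comparison"`: `analyte`, `scope`,
#'   `f_statistic`, `p_value`, and `pairwise` (tibble with `pair`, `diff`,
#'   `p_adj` — one row per treatment pair).
#' @export
treatment_anova <- function(series, analyte, scope = c("timepoint", "pooled"),
                            at = NULL) {
  scope <- match.arg(scope)
  series <- validate_timeseries(series)
  dat <- filter(series, .data$analyte == !!analyte, .data$qc_flag == "ok")
  if (scope == "timepoint") {
    if (is.null(at)) abort("supply `at` (the day) for scope = 'timepoint'.")
    dat <- filter(dat, .data$time_days == at)
  }
  sizes <- dat |> dplyr::count(.data$treatment)
  small <- sizes$treatment[sizes$n < 2]
  if (length(small) || nrow(sizes) < 2) {
    abort(paste0("each of >= 2 treatment groups needs >= 2 observations",
                 if (length(small)) paste0("; too small: ",
                                           paste(small, collapse = ", "))))
  }
  dat$treatment <- factor(dat$treatment)
  fit <- aov(value ~ treatment, data = dat)
  tab <- summary(fit)[[1]]
  fstat <- tab[1, "F value"]
  pval <- tab[1, "Pr(>F)"]
  if (is.na(fstat)) { fstat <- 0; pval <- 1 }  # zero between-group variance
  tk <- TukeyHSD(fit)$treatment
  pairwise <- tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    p_adj = ifelse(is.nan(tk[, "p adj"]), 1, tk[, "p adj"])
  )
  structure(
    list(analyte = analyte, scope = scope, at = at,
         f_statistic = unname(fstat), p_value = unname(pval),
         pairwise = pairwise, n = nrow(dat)),
    class = "treatment_comparison"
  )
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("ANOVA: %s (%s%s)  F = %.3g, p = %.3g, n = %d\n",
              x$analyte, x$scope,
              if (!is.null(x$at)) paste0(" day ", x$at) else "",
              x$f_statistic, x$p_value, x$n))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.treatment_comparison <- function(x, ...) {
  mutate(x$pairwise, analyte = x$analyte, .before = 1)
}

#' @export
glance.treatment_comparison <- function(x, ...) {
  tibble(analyte = x$analyte, scope = x$scope,
         f_statistic = x$f_statistic, p_value = x$p_value, n = x$n)
}

#' Replicate-bottle equivalence test
#'
#' Tests whether duplicate bottles of each treatment track each other: for
#' every treatment the two bottles are paired by timepoint, and the pooled
#' per-timepoint differences (bottle 1 minus bottle 2, across treatments) are
#' tested against zero. `method = "t"` uses a paired two-sided t test;
#' `method = "permutation"` uses a sign-flip permutation of the differences
#' (exhaustive when there are at most `2^20` sign patterns, otherwise
#' `n_perm` Monte Carlo draws).
#'
#' @param series An incubation series tibble with exactly 2 bottles per
#'   treatment for `analyte`.
#' @param analyte Analyte label.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Monte Carlo permutations when not exhaustive; default 10000.
#' @param seed Seed for Monte Carlo permutation.
#' @param on_unpaired `"error"` (default) reports timepoints present in only
#'   one bottle; `"drop"` silently pairs on the shared timepoints (used by
#'   the pipeline, where QC flagging can thin one bottle's series).
#' @return Tibble `analyte`, `method`, `statistic`, `p_value`, `n`
#'   (number of paired timepoints).
#' @export
replicate_equivalence <- function(series, analyte,
                                  method = c("t", "permutation"),
                                  n_perm = 10000, seed = 1,
                                  on_unpaired = c("error", "drop")) {
  method <- match.arg(method)
  on_unpaired <- match.arg(on_unpaired)
  series <- validate_timeseries(series)
  dat <- filter(series, .data$analyte == !!analyte, .data$qc_flag == "ok")
  diffs <- c()
  for (tr in unique(dat$treatment)) {
    d <- filter(dat, .data$treatment == tr)
    bottles <- sort(unique(d$bottle))
    if (length(bottles) != 2) {
      abort(paste0("treatment ", tr, " has ", length(bottles),
                   " bottle(s); exactly 2 required."))
    }
    a <- filter(d, .data$bottle == bottles[1])
    b <- filter(d, .data$bottle == bottles[2])
    shared <- intersect(a$time_days, b$time_days)
    unpaired <- c(setdiff(a$time_days, b$time_days),
                  setdiff(b$time_days, a$time_days))
    if (length(unpaired) && on_unpaired == "error") {
      abort(paste0("unpaired timepoint(s) in treatment ", tr, ": ",
                   paste(sort(unpaired), collapse = ", ")))
    }
    diffs <- c(diffs,
               a$value[match(shared, a$time_days)] -
                 b$value[match(shared, b$time_days)])
  }
  n <- length(diffs)
  if (method == "t") {
    if (all(diffs == 0)) {
      stat <- 0; p <- 1  # identical bottles: no evidence of difference
    } else {
      tt <- t.test(diffs)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
  } else {
    stat <- mean(diffs)
    p <- sign_flip_p(diffs, n_perm = n_perm, seed = seed)
  }
  tibble(analyte = analyte, method = method, statistic = stat,
         p_value = p, n = n)
}

# two-sided sign-flip permutation p-value for mean(diffs) == 0
sign_flip_p <- function(diffs, n_perm = 10000, seed = 1) {
  n <- length(diffs)
  obs <- abs(mean(diffs))
  if (n <= 20) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% diffs / n)
    mean(stats >= obs - 1e-12)
  } else {
    withr::with_seed(seed, {
      stats <- replicate(n_perm,
                         abs(mean(sample(c(-1, 1), n, replace = TRUE) * diffs)))
      (sum(stats >= obs - 1e-12) + 1) / (n_perm + 1)
    })
  }
}
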