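#' Default synthetic-experiment configuration
#'
#' Builds the configuration for [generate_experiment()], whose defaults
#' encode the three-treatment overturn-incubation design: a surface control
#' (S/S), surface cells in deep filtrate (S/D) and deep cells in surface
#' filtrate (D/S), each 30% whole-water inoculum + 70% filtrate, sampled
#' densely over days 0–6 and then on days 8, 9, 12 and 21.
#'
#' Per treatment the growth block carries the initial abundance (30% of the
#' source-water abundance: 17.6e8 cells L^-1 surface, 70.0e8 deep), the
#' target specific growth rate (0.03 / 0.19 / 0.11 d^-1) and the exponential
#' growth duration (10.1 / 4.9 / 2.8 d); D/S additionally carries an initial
#' die-off (25.5% over the first day) before regrowth. The logistic rate and
#' carrying capacity are *calibrated* from these targets (see
#' [calibrate_logistic_growth()]) so that the downstream estimators — ln-slope
#' over the exponential window, stationary onset at twice the half-capacity
#' time — recover the configured values exactly on noiseless data. DOC starts
#' at the conservative-mixing expectation of the 94.8 (surface) and 110.1
#' (deep) umol C L^-1 end-members and declines piecewise linearly (S/S: 2-day
#' lag then 0.79 umol C L^-1 d^-1; S/D: 2.7 for two days then 0.64; D/S: 0.68
#' with a ~5 umol C L^-1 production pulse between days 9 and 12).
#'
#' @param noise_scale Multiplier on every observation-noise SD; `0` gives a
#'   noiseless bundle. Default 1.
#' @return A nested list of class `"experiment_config"`.
#' @export
default_config <- function(noise_scale = 1) {
  surface_pa <- 17.6e8; deep_pa <- 70.0e8
  surface_doc <- 94.8; deep_doc <- 110.1
  frac <- 0.70
  mix <- function(filtrate_src) {
    expected_mixture_concentration(surface_doc, deep_doc, frac,
                                   filtrate_src)$expected
  }
  cfg <- list(
    design = treatment_design(),
    sampling_days = c(0, 1, 2, 3, 4, 5, 6, 8, 9, 12, 21),
    treatments = list(
      "S/S" = list(
        growth = list(initial_abundance = 0.30 * surface_pa,
                      specific_growth_rate = 0.03,
                      exponential_duration = 10.1,
                      carrying_capacity = NA,
                      die_off_fraction = 0, die_off_duration = 0),
        doc = list(initial = mix("surface"), lag = 2,
                   drawdown_rate = 0.79,
                   fast = NULL, production_pulse = NULL),
        aa = list(tdaa0 = 1600, decay = 0.06, drift_rate = -0.04)
      ),
      "S/D" = list(
        growth = list(initial_abundance = 0.30 * surface_pa,
                      specific_growth_rate = 0.19,
                      exponential_duration = 4.9,
                      carrying_capacity = NA,
                      die_off_fraction = 0, die_off_duration = 0),
        doc = list(initial = mix("deep"), lag = 0,
                   drawdown_rate = 0.64,
                   fast = list(duration = 2, rate = 2.7),
                   production_pulse = NULL),
        aa = list(tdaa0 = 2000, decay = 0.10, drift_rate = -0.10)
      ),
      "D/S" = list(
        growth = list(initial_abundance = 0.30 * deep_pa,
                      specific_growth_rate = 0.11,
                      exponential_duration = 2.8,
                      carrying_capacity = NA,
                      die_off_fraction = 0.255, die_off_duration = 1),
        doc = list(initial = mix("deep"), lag = 0,
                   drawdown_rate = 0.68,
                   fast = NULL,
                   production_pulse = list(start = 9, peak = 12, end = 18,
                                           magnitude = 5)),
        aa = list(tdaa0 = 1800, decay = 0.14, drift_rate = -0.25)
      )
    ),
    doc_floor = 40,
    aa_days = c(0, 2, 6, 12, 21),
    qpcr = list(
      slope = -2.93, intercept = 38, replicate_sd = 0.15 * noise_scale,
      levels = 10^(6:1), n_replicates = 2,
      genes = list(
        amoA = list(standard_length_bp = 635, base_gcn = 15,
                    late_rise = 10000),
        cbbL = list(standard_length_bp = 1400, base_gcn = 9000,
                    late_rise = 0)
      ),
      dna_ng = 20,
      days = c(0, 2, 6, 12, 21)
    ),
    features = list(
      n_features = 5456,
      days = c(0, 8, 21),
      magnitude_meanlog = 10, magnitude_sdlog = 1
    ),
    asv = list(
      n_per_family = 4,
      days = c(0, 2, 6, 12, 21),
      library_meanlog = log(80000), library_sdlog = 0.25,
      library_min = 12000,
      deep_dominant_family = "Chlorobiaceae",
      deep_dominant_copies = 3,
      deep_dominant_fraction = 0.75
    ),
    noise = list(pa_sdlog = 0.03 * noise_scale,
                 doc_sd = 0.5 * noise_scale,
                 aa_sdlog = 0.05 * noise_scale)
  )
  structure(cfg, class = "experiment_config")
}

validate_config <- function(config) {
  if (!inherits(config, "experiment_config") && !is.list(config)) {
    abort("`config` must be an experiment_config list.")
  }
  for (code in names(config$treatments)) {
    g <- config$treatments[[code]]$growth
    if (g$initial_abundance <= 0) abort(paste0(code, ": initial abundance must be > 0."))
    if (g$specific_growth_rate <= 0) abort(paste0(code, ": growth rate must be > 0."))
    if (g$die_off_fraction < 0 || g$die_off_fraction >= 1) {
      abort(paste0(code, ": die_off_fraction must lie in [0, 1)."))
    }
    if (g$exponential_duration <= g$die_off_duration) {
      abort(paste0(code, ": exponential_duration must exceed die_off_duration."))
    }
  }
  if (any(config$sampling_days < 0)) abort("sampling days must be >= 0.")
  invisible(config)
}

#' Calibrate logistic parameters to a target growth rate and duration
#'
#' The analysis stage estimates mu as the OLS ln-slope over the exponential
#' window and places the stationary onset at `2 * t_mid`. For a logistic
#' curve those two observables do not equal `r` and an arbitrary duration, so
#' the generator solves for the intrinsic rate `r` (and hence the carrying
#' capacity `K`) such that, at the configured sampling days, the noiseless
#' trajectory yields exactly the configured `mu` and exponential duration:
#' the half-capacity time (relative to the window start `t_start`) is fixed
#' at `(duration - t_start)/2` and `r` is found by root-finding on the
#' window ln-slope.
#'
#' @param mu Target specific growth rate, d^-1.
#' @param duration Target exponential duration `t_stationary - t_start`, d.
#' @param n0 Abundance at the window start, cells L^-1.
#' @param days Sampling days.
#' @param t_start Window start (0, or the die-off bottom time).
#' @return List with `r`, `K`, `t_mid_rel` (half-capacity time after
#'   `t_start`).
#' @export
calibrate_logistic_growth <- function(mu, duration, n0, days, t_start = 0) {
  t_mid_rel <- (duration - t_start) / 2
  if (t_mid_rel <= 0) abort("duration must exceed t_start.")
  wdays <- days[days >= t_start & days <= t_start + duration]
  if (length(wdays) < 3) abort("fewer than 3 sampling days in the window.")
  slope_of <- function(r) {
    q <- exp(r * t_mid_rel)
    lnN <- log(n0 * (1 + q)) - log(1 + q * exp(-r * (wdays - t_start)))
    unname(coef(lm(lnN ~ wdays))[2])
  }
  lo <- mu  # window ln-slope of a logistic is strictly below r
  hi <- mu * 2
  while (slope_of(hi) < mu && hi < mu * 1e4) hi <- hi * 2
  r <- uniroot(function(r) slope_of(r) - mu, c(lo, hi), tol = 1e-12)$root
  q <- exp(r * t_mid_rel)
  list(r = r, K = n0 * (1 + q), t_mid_rel = t_mid_rel)
}

# noiseless abundance trajectory for one treatment at times t
growth_trajectory <- function(g, days) {
  d0 <- g$die_off_duration
  f <- g$die_off_fraction
  n0 <- g$initial_abundance
  n_start <- n0 * (1 - f)
  cal <- calibrate_logistic_growth(g$specific_growth_rate,
                                   g$exponential_duration,
                                   n_start, days, t_start = d0)
  K <- if (is.na(g$carrying_capacity)) cal$K else g$carrying_capacity
  r <- if (is.na(g$carrying_capacity)) cal$r else
    2 * log((K - n_start) / n_start) / (g$exponential_duration - d0)
  q <- (K - n_start) / n_start
  ifelse(days < d0 & d0 > 0,
         n0 * exp(log1p(-f) / d0 * days),
         K / (1 + q * exp(-r * (days - d0))))
}

# noiseless DOC trajectory
doc_trajectory <- function(dcfg, days, floor = 40) {
  base <- numeric(length(days))
  for (i in seq_along(days)) {
    t <- days[i]
    drawn <- 0
    t_eff <- max(0, t - dcfg$lag)
    if (!is.null(dcfg$fast)) {
      fast_t <- min(t_eff, dcfg$fast$duration)
      drawn <- drawn + dcfg$fast$rate * fast_t
      t_eff <- t_eff - fast_t
    }
    drawn <- drawn + dcfg$drawdown_rate * t_eff
    base[i] <- max(floor, dcfg$initial - drawn)
  }
  if (!is.null(dcfg$production_pulse)) {
    p <- dcfg$production_pulse
    bump <- ifelse(days <= p$start | days >= p$end, 0,
                   ifelse(days <= p$peak,
                          p$magnitude * (days - p$start) / (p$peak - p$start),
                          p$magnitude * (p$end - days) / (p$end - p$peak)))
    base <- base + bump
  }
  base
}

# amino-acid mol% trajectory: DI(t) = drift_rate * t exactly, by moving the
# composition along a zero-sum direction scaled to unit DI response
aa_molpct <- function(reference, drift_rate, t) {
  di_set <- reference[reference$in_di_set, ]
  w <- di_set$factor_coef * di_set$sd_molpct
  u <- w - mean(w)
  unit_di <- sum(u / di_set$sd_molpct * di_set$factor_coef)
  u <- u / unit_di
  setNames(pmax(0, di_set$mean_molpct + drift_rate * t * u),
           di_set$amino_acid)
}

asv_families <- function() {
  tibble(
    family = c("Chlorobiaceae", "Synechococcales", "SAR11",
               "Rhodospirillales", "Rhodobacterales", "Pseudomonadales",
               "Flavobacteriales", "SAR202", "Nitrosopumilales",
               "Planctomycetales", "Actinomarinales", "Marine Group II",
               "Chitinophagales"),
    order = c("Chlorobiales", "Synechococcales", "Pelagibacterales",
              "Rhodospirillales", "Rhodobacterales", "Pseudomonadales",
              "Flavobacteriales", "SAR202 clade", "Nitrosopumilales",
              "Planctomycetales", "Actinomarinales", "Marine Group II",
              "Chitinophagales"),
    surface = c(0.001, 0.17, 0.20, 0.10, 0.10, 0.14, 0.13, 0.005, 0.004,
                0.02, 0.05, 0.05, 0.02),
    deep = c(0.75, 0.01, 0.03, 0.04, 0.04, 0.02, 0.03, 0.035, 0.015,
             0.01, 0.005, 0.025, 0.005),
    late = c(0.0005, 0.01, 0.10, 0.06, 0.07, 0.05, 0.10, 0.14, 0.15,
             0.10, 0.12, 0.13, 0.07)
  )
}

#' Generate a complete synthetic experiment bundle
#'
#' Produces, for one seeded realization of the configured study conditions:
#' the incubation time series (prokaryotic abundance with logistic growth,
#' optional initial die-off, and lognormal observation noise; DOC with lagged
#' piecewise-linear drawdown, optional production pulse, and zero-truncated
#' Gaussian noise), per-sample amino-acid profiles whose composition drifts
#' away from the packaged reference (so the degradation index moves linearly
#' in time), a qPCR plate (standard dilution series on the configured line
#' plus treatment/day unknowns), per-sample mzRT feature tables with
#' elemental formulas, and a treatment-structured ASV count table with a
#' dominant multi-copy taxon in the deep inoculum. The same `(config, seed)`
#' pair always returns an identical bundle.
#'
#' @param config An `"experiment_config"` (see [default_config()]).
#' @param seed Integer seed for all randomness.
#' @return A list of class `"experiment_bundle"`: `timeseries`,
#'   `aa_profiles`, `qpcr_plate`, `feature_tables` (named list of tibbles),
#'   `asv_counts` (matrix), `asv_taxonomy`, `copy_map`, `manifest`.
#' @export
generate_experiment <- function(config = default_config(), seed = 1) {
  validate_config(config)
  bundle <- withr::with_seed(seed, {
    days <- config$sampling_days
    design <- config$design
    bottles <- list("S/S" = c("A", "B"), "S/D" = c("C", "D"),
                    "D/S" = c("E", "F"))

    ## time series -------------------------------------------------------
    ts <- purrr::map(names(config$treatments), function(code) {
      tc <- config$treatments[[code]]
      pa_true <- growth_trajectory(tc$growth, days)
      doc_true <- doc_trajectory(tc$doc, days, config$doc_floor)
      purrr::map(bottles[[code]] %||% c("A", "B"), function(bo) {
        pa_obs <- pa_true *
          if (config$noise$pa_sdlog > 0)
            rlnorm(length(days), -config$noise$pa_sdlog^2 / 2,
                   config$noise$pa_sdlog) else 1
        doc_obs <- pmax(0, doc_true +
                          if (config$noise$doc_sd > 0)
                            rnorm(length(days), 0, config$noise$doc_sd)
                          else 0)
        bind_rows(
          tibble(treatment = code, bottle = bo, time_days = days,
                 analyte = "PA", value = pa_obs, unit = "cells L-1"),
          tibble(treatment = code, bottle = bo, time_days = days,
                 analyte = "DOC", value = doc_obs, unit = "umol C L-1")
        )
      }) |> bind_rows()
    }) |> bind_rows()
    ts$qc_flag <- "ok"
    ts <- validate_timeseries(ts)

    ## amino-acid profiles ----------------------------------------------
    reference <- read_aa_reference()
    aa <- purrr::map(names(config$treatments), function(code) {
      acfg <- config$treatments[[code]]$aa
      purrr::map(config$aa_days, function(d) {
        molpct <- aa_molpct(reference, acfg$drift_rate, d)
        total <- acfg$tdaa0 * exp(-acfg$decay * d)
        conc <- molpct / 100 * total
        if (config$noise$aa_sdlog > 0) {
          conc <- conc * rlnorm(length(conc), -config$noise$aa_sdlog^2 / 2,
                                config$noise$aa_sdlog)
        }
        tibble(sample_id = paste0(code, "_d", d), treatment = code,
               time_days = d, amino_acid = names(molpct),
               conc_nmol_l = unname(conc))
      }) |> bind_rows()
    }) |> bind_rows()

    ## qPCR plate --------------------------------------------------------
    qp <- config$qpcr
    plate <- purrr::map(names(qp$genes), function(g) {
      gcfg <- qp$genes[[g]]
      std <- tidyr::expand_grid(copies = qp$levels,
                                replicate = seq_len(qp$n_replicates)) |>
        mutate(
          gene = g, role = "standard", sample_id = NA_character_,
          dna_ng = NA_real_,
          cq = qp$intercept + qp$slope * log10(.data$copies) +
            if (qp$replicate_sd > 0)
              rnorm(dplyr::n(), 0, qp$replicate_sd) else 0)
      unk <- tidyr::expand_grid(treatment = names(config$treatments),
                                time_days = qp$days,
                                replicate = seq_len(qp$n_replicates)) |>
        mutate(
          gene = g, role = "unknown",
          sample_id = paste0(.data$treatment, "_d", .data$time_days),
          dna_ng = qp$dna_ng,
          true_gcn = gcfg$base_gcn *
            ifelse(.data$treatment == "S/S", 1,
                   ifelse(.data$treatment == "S/D", 1.2, 0.6)) +
            gcfg$late_rise * pmax(0, .data$time_days - 12) / 9,
          copies = NA_real_,
          cq = qp$intercept +
            qp$slope * log10(.data$true_gcn * .data$dna_ng) +
            if (qp$replicate_sd > 0)
              rnorm(dplyr::n(), 0, qp$replicate_sd) else 0) |>
        select(-"true_gcn", -"treatment", -"time_days")
      neg <- tibble(gene = g, role = "negative", copies = NA_real_,
                    cq = NA_real_, sample_id = NA_character_,
                    dna_ng = NA_real_, replicate = 1L)
      bind_rows(std, unk, neg)
    }) |> bind_rows() |>
      mutate(well = sprintf("W%03d", dplyr::row_number()), .before = 1)

    ## mzRT feature tables ----------------------------------------------
    fx <- config$features
    day_hc_shift <- c("0" = 0, "8" = 0.25, "21" = 0.1)
    feature_tables <- list()
    for (code in names(config$treatments)) {
      for (d in fx$days) {
        n <- fx$n_features
        C <- sample(5:40, n, replace = TRUE)
        hc <- pmin(2.4, pmax(0.3, stats::rbeta(n, 3, 2) * 2 +
                               (day_hc_shift[as.character(d)] %||% 0)))
        H <- pmax(1L, as.integer(round(C * hc)))
        O <- as.integer(round(C * pmin(1.2, stats::rbeta(n, 2, 3) * 1.2)))
        N <- ifelse(stats::runif(n) < 0.40, sample(1:3, n, replace = TRUE), 0L)
        S <- ifelse(stats::runif(n) < 0.08, 1L, 0L)
        P <- ifelse(stats::runif(n) < 0.03, 1L, 0L)
        assigned <- stats::runif(n) < 0.85
        formula <- ifelse(
          assigned,
          paste0("C", C, "H", H,
                 ifelse(N > 0, paste0("N", N), ""),
                 ifelse(O > 0, paste0("O", O), ""),
                 ifelse(P > 0, paste0("P", P), ""),
                 ifelse(S > 0, paste0("S", S), "")),
          "")
        mass <- 12 * C + 1.0078 * H + 14.0031 * N + 15.9949 * O +
          31.9721 * S + 30.9738 * P
        tbl <- tibble(
          mz = round(mass + stats::runif(n, -0.3, 0.3), 4),
          rt = round(stats::runif(n, 60, 1200), 1),
          magnitude = rlnorm(n, fx$magnitude_meanlog, fx$magnitude_sdlog),
          formula = formula)
        feature_tables[[paste0(code, "_d", d)]] <- tbl
      }
    }

    ## ASV table ---------------------------------------------------------
    av <- config$asv
    fams <- asv_families()
    npf <- av$n_per_family
    asv_ids <- paste0("ASV", sprintf("%03d", seq_len(nrow(fams) * npf)))
    taxonomy <- tibble(
      asv = asv_ids,
      family = rep(fams$family, each = npf),
      lineage = rep(paste("Bacteria", "phylum", "class", fams$order,
                          fams$family, sep = ";"), each = npf)
    )
    taxonomy$lineage <- paste0(taxonomy$lineage, ";genus_",
                               rep(seq_len(npf), nrow(fams)))
    # fixed within-family split of each family's weight across its ASVs
    split_w <- matrix(stats::rgamma(nrow(taxonomy), 2, 1), nrow = npf)
    split_w <- sweep(split_w, 2, colSums(split_w), "/")
    comp_at <- function(code, d) {
      inoc <- design$inoculum_source[design$treatment == code]
      base0 <- if (inoc == "deep") fams$deep else fams$surface
      w_surface <- if (inoc == "deep") pmin(1, d / 2) else 1
      base <- (1 - w_surface) * base0 + w_surface * fams$surface
      w_late <- pmax(0, pmin(1, (d - 6) / 15))
      w <- (1 - w_late) * base + w_late * fams$late
      w / sum(w)
    }
    samples <- tidyr::expand_grid(treatment = names(config$treatments),
                                  time_days = av$days,
                                  replicate = 1:2)
    counts <- matrix(0L, nrow = nrow(samples), ncol = nrow(taxonomy),
                     dimnames = list(
                       paste0(samples$treatment, "_d", samples$time_days,
                              "_r", samples$replicate),
                       taxonomy$asv))
    for (i in seq_len(nrow(samples))) {
      fam_w <- comp_at(samples$treatment[i], samples$time_days[i])
      asv_w <- as.numeric(sweep(split_w, 2, fam_w, "*"))
      lib <- max(av$library_min,
                 round(rlnorm(1, av$library_meanlog, av$library_sdlog)))
      counts[i, ] <- as.integer(rmultinom(1, lib, asv_w))
    }
    copy_map <- tibble(
      taxon = fams$family,
      copies = ifelse(fams$family == av$deep_dominant_family,
                      av$deep_dominant_copies, 1))

    list(timeseries = ts, aa_profiles = aa, qpcr_plate = plate,
         feature_tables = feature_tables, asv_counts = counts,
         asv_taxonomy = taxonomy, copy_map = copy_map)
  })
  bundle$manifest <- list(
    generator = "overturnlab",
    version = as.character(utils::packageVersion("overturnlab")),
    seed = seed,
    config = unclass(config)
  )
  structure(bundle, class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("Synthetic overturn-experiment bundle (seed ", x$manifest$seed, ")\n",
      sep = "")
  cat("  timeseries:    ", nrow(x$timeseries), " rows\n", sep = "")
  cat("  aa_profiles:   ", nrow(x$aa_profiles), " rows\n", sep = "")
  cat("  qpcr_plate:    ", nrow(x$qpcr_plate), " wells\n", sep = "")
  cat("  feature tables:", length(x$feature_tables), "samples\n")
  cat("  asv_counts:    ", nrow(x$asv_counts), " samples x ",
      ncol(x$asv_counts), " ASVs\n", sep = "")
  invisible(x)
}

#' Write / read a bundle as plain-text tables
#'
#' `write_bundle()` writes every table of the bundle as CSV plus a YAML
#' manifest (config + seed + version) sufficient to regenerate the bundle;
#' `read_bundle()` reads such a directory back.
#'
#' @param bundle An `"experiment_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` returns
#'   an `"experiment_bundle"`.
#' @rdname bundle-io
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$timeseries, file.path(dir, "timeseries.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$aa_profiles, file.path(dir, "aa_profiles.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$qpcr_plate, file.path(dir, "qpcr_plate.csv"),
                   progress = FALSE)
  fdir <- file.path(dir, "features")
  dir.create(fdir, showWarnings = FALSE)
  for (nm in names(bundle$feature_tables)) {
    readr::write_csv(bundle$feature_tables[[nm]],
                     file.path(fdir, paste0(gsub("/", "-", nm), ".csv")),
                     progress = FALSE)
  }
  counts <- as_tibble(bundle$asv_counts, rownames = "sample_id")
  readr::write_csv(counts, file.path(dir, "asv_counts.csv"), progress = FALSE)
  readr::write_csv(bundle$asv_taxonomy, file.path(dir, "asv_taxonomy.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$copy_map, file.path(dir, "copy_map.csv"),
                   progress = FALSE)
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname bundle-io
#' @export
read_bundle <- function(dir) {
  if (!file.exists(file.path(dir, "timeseries.csv"))) {
    abort("bundle directory is missing timeseries.csv")
  }
  # other tables are optional; the stage that needs a missing one aborts
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  counts_tbl <- rd("asv_counts.csv")
  counts <- NULL
  if (!is.null(counts_tbl)) {
    counts <- as.matrix(counts_tbl[, -1])
    rownames(counts) <- counts_tbl$sample_id
    storage.mode(counts) <- "integer"
  }
  fdir <- file.path(dir, "features")
  feature_tables <- list()
  if (dir.exists(fdir)) {
    for (f in sort(list.files(fdir, pattern = "\\.csv$"))) {
      nm <- gsub("-", "/", sub("\\.csv$", "", f))
      feature_tables[[nm]] <- readr::read_csv(file.path(fdir, f),
                                              show_col_types = FALSE,
                                              progress = FALSE)
    }
  }
  manifest <- if (file.exists(file.path(dir, "manifest.yaml"))) {
    yaml::read_yaml(file.path(dir, "manifest.yaml"))
  }
  structure(
    list(timeseries = validate_timeseries(rd("timeseries.csv")),
         aa_profiles = rd("aa_profiles.csv"),
         qpcr_plate = rd("qpcr_plate.csv"),
         feature_tables = feature_tables,
         asv_counts = counts,
         asv_taxonomy = rd("asv_taxonomy.csv"),
         copy_map = rd("copy_map.csv"),
         manifest = manifest),
    class = "experiment_bundle")
}
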