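#' Fit a logistic growth curve to prokaryotic abundance
#'
#' Least-squares fit of the three-parameter logistic
#' \deqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-r t})}
#' to abundance observations, by bounded Levenberg--Marquardt minimization
#' with a deterministic start (K from the largest observation, N0 from the
#' first, r from the log-slope of the first three points), so the same data
#' always give the same fit. The half-capacity time is
#' `t_mid = log((K - N0)/N0) / r` and the onset of stationary phase is taken
#' as `t_stationary = 2 * t_mid`.
#'
#' @param times Sampling times in days.
#' @param abundances Cell abundances (cells per liter), all positive.
#' @return An object of class `"growth_fit"`: a list with `K`, `r`, `N0`,
#'   `t_mid`, `t_stationary`, `rss`, and the data used.
#' @seealso [exponential_window()], [specific_growth_rate()], [fit_growth()]
#' @export
#' @examples
#' t <- 0:10
#' n <- 70e8 / (1 + ((70e8 - 5.28e8) / 5.28e8) * exp(-1.2 * t))
#' fit <- fit_logistic(t, n)
#' fit$t_mid  # log(64.72/5.28)/1.2
fit_logistic <- function(times, abundances) {
  ok <- is.finite(times) & is.finite(abundances)
  t <- times[ok]; y <- abundances[ok]
  o <- order(t); t <- t[o]; y <- y[o]
  if (length(t) < 5) abort("logistic fit needs at least 5 observations.")
  if (any(y <= 0)) abort("abundances must be positive for a logistic fit.")
  if (max(y) <= y[1]) {
    abort("no growth signal: series never rises above its first observation.")
  }
  K0 <- max(y)
  N00 <- y[1]
  r0 <- {
    s <- coef(lm(log(y[1:3]) ~ t[1:3]))[[2]]
    if (!is.finite(s) || s <= 0) 0.1 else s
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
      start = list(K = K0 * 1.05, N0 = N00, r = r0),
      lower = c(K = K0 * (1 + 1e-9), N0 = min(y) * 1e-3, r = 1e-9),
      upper = c(K = K0 * 10, N0 = K0, r = 50),
      control = minpack.lm::nls.lm.control(
        maxiter = 1024, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) {
      abort(paste0("logistic fit failed to converge (start K=", signif(K0, 4),
                   ", N0=", signif(N00, 4), ", r=", signif(r0, 4), "): ",
                   conditionMessage(e)))
    }
  )
  p <- as.list(coef(fit))
  t_mid <- log((p$K - p$N0) / p$N0) / p$r
  structure(
    list(K = p$K, r = p$r, N0 = p$N0, t_mid = t_mid,
         t_stationary = 2 * t_mid, rss = sum(resid(fit)^2),
         times = t, abundances = y),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Logistic growth fit\n")
  cat(sprintf("  K  = %.4g cells L-1\n  N0 = %.4g cells L-1\n  r  = %.4g d-1\n",
              x$K, x$N0, x$r))
  cat(sprintf("  t_mid = %.3g d, t_stationary = %.3g d, RSS = %.3g\n",
              x$t_mid, x$t_stationary, x$rss))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("K", "r", "N0"),
         estimate = c(x$K, x$r, x$N0),
         unit = c("cells L-1", "d-1", "cells L-1"))
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(t_mid = x$t_mid, t_stationary = x$t_stationary,
         rss = x$rss, n = length(x$times))
}

#' Delimit the exponential growth phase
#'
#' The window ends at the stationary onset `t_stationary = 2 * t_mid`
#' (capped at the last observation so the window stays within the sampled
#' range). The
#' window starts at the first timepoint unless an initial die-off is
#' detected: when the minimum observed abundance on `[0, t_mid]` falls more
#' than `die_off_threshold` below the first observation (as in a deep
#' inoculum dying back before regrowth), the window starts at that minimum,
#' so regrowth is measured from its true start. The threshold keeps mere
#' observation noise on a flat start from being mistaken for a die-off.
#'
#' @param times,abundances Observed series (full, untrimmed).
#' @param fit A [fit_logistic()] result.
#' @param die_off_threshold Minimum fractional drop below the first
#'   observation that counts as a die-off; default 0.1.
#' @return Numeric `c(t_start, t_end)` in days.
#' @export
exponential_window <- function(times, abundances, fit,
                               die_off_threshold = 0.1) {
  o <- order(times); times <- times[o]; abundances <- abundances[o]
  pre <- which(times <= fit$t_mid)
  t_start <- times[1]
  if (length(pre)) {
    imin <- pre[which.min(abundances[pre])]
    if (abundances[imin] < abundances[1] * (1 - die_off_threshold)) {
      t_start <- times[imin]
    }
  }
  t_end <- min(fit$t_stationary, max(times))
  n_in <- sum(times >= t_start & times <= t_end)
  if (n_in < 3) {
    abort(paste0("exponential window [", signif(t_start, 3), ", ",
                 signif(t_end, 3), "] contains only ", n_in,
                 " observation(s); supply a manual window."))
  }
  c(t_start, t_end)
}

#' Specific growth rate as the ln-slope over a window
#'
#' Ordinary least-squares slope of `log(abundance)` against time restricted
#' to `window`, the standard estimator of the specific growth rate mu (per
#' day) during exponential phase.
#'
#' @param times,abundances Observed series.
#' @param window Numeric `c(t_start, t_end)`; observations with
#'   `t_start <= t <= t_end` enter the regression.
#' @return mu in d^-1.
#' @export
#' @examples
#' t <- 0:4
#' specific_growth_rate(t, 2e8 * exp(0.19 * t), c(0, 4))  # 0.19
specific_growth_rate <- function(times, abundances, window) {
  sel <- times >= window[1] & times <= window[2] &
    is.finite(times) & is.finite(abundances)
  t <- times[sel]; y <- abundances[sel]
  if (length(t) < 2) abort("specific growth rate needs >= 2 points in window.")
  if (any(y <= 0)) abort("nonpositive abundance in window; cannot take log.")
  unname(coef(lm(log(y) ~ t))[2])
}

#' Linear interpolation within an observed series
#'
#' Used to evaluate, e.g., the DOC concentration at the modeled stationary
#' time when sampling did not coincide with it. Exact at the knots; requests
#' outside the observed range are an error, not an extrapolation.
#'
#' @param times,values Observed series.
#' @param t Time (days) at which to interpolate.
#' @return Interpolated value.
#' @export
interpolate_at <- function(times, values, t) {
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (t < min(times) || t > max(times)) {
    abort(paste0("t = ", t, " is outside the observed range [",
                 min(times), ", ", max(times), "]; refusing to extrapolate."))
  }
  approx(times, values, xout = t, ties = "ordered")$y
}

#' Trapezoidal integral of excess above/below a baseline
#'
#' Integrates `value - baseline` (sign `"above"`) or `baseline - value`
#' (`"below"`) over a time window by the trapezoid rule, with window
#' endpoints evaluated by linear interpolation so partial intervals are
#' handled exactly. With `normalize = TRUE` the integral is divided by the
#' window length, giving a time-normalized mean excess.
#'
#' @param times,values Observed series.
#' @param window Numeric `c(t0, t1)` within the observed range.
#' @param baseline Finite reference value subtracted before integration.
#' @param sign `"above"` or `"below"`.
#' @param normalize Divide by window length? Default `FALSE`.
#' @return Integral in value-units x days (or value-units if normalized).
#' @export
#' @examples
#' # linear rise 0 -> 1 over [0, 6]: triangle area 3
#' integrate_excess(c(0, 6), c(0, 1), c(0, 6), baseline = 0, sign = "above")
integrate_excess <- function(times, values, window, baseline,
                             sign = c("above", "below"), normalize = FALSE) {
  sign <- match.arg(sign)
  if (!is.finite(baseline)) abort("`baseline` must be finite.")
  if (window[2] <= window[1]) abort("empty or inverted integration window.")
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  o <- order(times); times <- times[o]; values <- values[o]
  inside <- times > window[1] & times < window[2]
  t <- c(window[1], times[inside], window[2])
  v <- c(interpolate_at(times, values, window[1]),
         values[inside],
         interpolate_at(times, values, window[2]))
  excess <- if (sign == "above") v - baseline else baseline - v
  out <- pracma::trapz(t, excess)
  if (normalize) out <- out / (window[2] - window[1])
  out
}

#' Convert cell abundance to biomass carbon
#'
#' Applies a per-cell carbon content (default 20 fg C per cell) and the molar
#' mass of carbon (12.011 g mol^-1) to express prokaryotic abundance as
#' biomass carbon in umol C L^-1.
#'
#' @param abundance Cells per liter (>= 0).
#' @param fg_per_cell Carbon per cell in femtograms; default 20.
#' @return Biomass carbon in umol C L^-1.
#' @export
#' @examples
#' bacterial_carbon(1e9)  # ~1.665 umol C L-1
bacterial_carbon <- function(abundance, fg_per_cell = 20) {
  if (any(abundance < 0, na.rm = TRUE)) abort("abundance must be >= 0.")
  abundance * fg_per_cell * 1e-15 / 12.011 * 1e6
}

#' Bacterial growth efficiency by curve integration
#'
#' BGE is the ratio of the time-integrated increase in biomass carbon above
#' its value at the window start (T0) to the time-integrated DOC drawdown
#' below its T0 value, both integrated from T0 to the stationary onset
#' `t_stationary = 2 * t_mid` of the logistic fit:
#' \deqn{BGE = \int_{T0}^{T_{stat}} \Delta BC\, dt \; / \; \int_{T0}^{T_{stat}} \Delta DOC\, dt}
#' Both integrals are time-normalized over the window (the normalization
#' cancels in the ratio). Adding a constant to the DOC series leaves BGE
#' unchanged, since only drawdown below the T0 value enters.
#'
#' @param pa_times,pa_values Prokaryotic abundance series (cells L^-1).
#' @param doc_times,doc_values DOC series (umol C L^-1).
#' @param fit A [fit_logistic()] result for the abundance series.
#' @param fg_per_cell Carbon conversion factor, fg C per cell; default 20.
#' @param window Optional `c(T0, T_end)` override; default is the
#'   [exponential_window()] of the fit.
#' @return A one-row tibble: `t0`, `t_stationary`, `integral_bc`,
#'   `integral_doc` (time-normalized, umol C L^-1), `bge` (fraction),
#'   `bge_percent`, and `flag` (`"ok"` or `"no net DOC removal"`, in which
#'   case `bge` is `NaN`).
#' @export
compute_bge <- function(pa_times, pa_values, doc_times, doc_values, fit,
                        fg_per_cell = 20, window = NULL) {
  if (is.null(window)) window <- exponential_window(pa_times, pa_values, fit)
  t0 <- window[1]; t1 <- window[2]
  bc <- bacterial_carbon(pa_values, fg_per_cell)
  bc0 <- interpolate_at(pa_times, bc, t0)
  doc0 <- interpolate_at(doc_times, doc_values, t0)
  int_bc <- integrate_excess(pa_times, bc, c(t0, t1), baseline = bc0,
                             sign = "above", normalize = TRUE)
  int_doc <- integrate_excess(doc_times, doc_values, c(t0, t1),
                              baseline = doc0, sign = "below",
                              normalize = TRUE)
  if (int_doc <= 0) {
    bge <- NaN
    flag <- "no net DOC removal"
  } else {
    bge <- int_bc / int_doc
    flag <- "ok"
  }
  tibble(t0 = t0, t_stationary = t1,
         integral_bc = int_bc, integral_doc = int_doc,
         bge = bge, bge_percent = 100 * bge, flag = flag)
}

#' OLS rate of change over a time window
#'
#' Slope (sign preserved) of value against time for observations inside
#' `[t0, t1]`; used to report, e.g., DOC removal rates over a phase of the
#' incubation in umol C L^-1 d^-1.
#'
#' @param times,values Observed series.
#' @param t0,t1 Window bounds (inclusive).
#' @return Slope in value-units per day.
#' @export
window_rate <- function(times, values, t0, t1) {
  sel <- times >= t0 & times <= t1 & is.finite(times) & is.finite(values)
  t <- times[sel]; v <- values[sel]
  if (length(t) < 2) abort("window rate needs >= 2 points in [t0, t1].")
  unname(coef(lm(v ~ t))[2])
}

#' Fit growth curves for every (treatment, bottle) in a series
#'
#' Data-frame front end to the growth-kinetics stage: for each (treatment,
#' bottle) slice of the abundance analyte it trims the series at its first
#' global minimum (so an initial die-off does not bias the logistic), fits
#' [fit_logistic()], delimits the [exponential_window()] on the full series,
#' and estimates mu as the ln-slope over that window. QC-flagged observations
#' are excluded throughout. When the stationary onset of a (noisy) fit falls
#' before the third sampled timepoint, the window end is extended to the
#' earliest timepoint giving three observations, so the ln-slope is always
#' identifiable.
#'
#' @param series An incubation series tibble.
#' @param analyte Abundance analyte label; default `"PA"`.
#' @return A tibble with one row per (treatment, bottle): logistic parameters,
#'   `t_mid`, `t_stationary`, window bounds, `exp_duration`
#'   (`t_end - t_start`), `mu`, and `rss`. The fitted objects are kept in a
#'   list-column `fit`.
#' @export
fit_growth <- function(series, analyte = "PA") {
  series <- validate_timeseries(series)
  dat <- series |>
    filter(.data$analyte == !!analyte, .data$qc_flag == "ok")
  if (!nrow(dat)) abort(paste0("no usable observations for analyte '", analyte, "'."))
  dat |>
    group_by(.data$treatment, .data$bottle) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(fit = purrr::map(.data$data, function(d) {
      d <- arrange(d, .data$time_days)
      i0 <- which.min(d$value)[1]
      if (d$value[i0] >= d$value[1] * 0.9) i0 <- 1  # no die-off detected
      f <- fit_logistic(d$time_days[i0:nrow(d)], d$value[i0:nrow(d)])
      w <- tryCatch(
        exponential_window(d$time_days, d$value, f),
        error = function(e) {
          # stationary onset fell before the 3rd sample: extend the window
          # end to the earliest timepoint that gives 3 observations
          t_start <- d$time_days[i0]
          later <- d$time_days[d$time_days >= t_start]
          if (length(later) < 3) abort(conditionMessage(e))
          c(t_start, max(later[3], f$t_stationary))
        })
      mu <- specific_growth_rate(d$time_days, d$value, w)
      list(fit = f, window = w, mu = mu)
    })) |>
    mutate(
      K = purrr::map_dbl(.data$fit, ~ .x$fit$K),
      N0 = purrr::map_dbl(.data$fit, ~ .x$fit$N0),
      r = purrr::map_dbl(.data$fit, ~ .x$fit$r),
      t_mid = purrr::map_dbl(.data$fit, ~ .x$fit$t_mid),
      t_stationary = purrr::map_dbl(.data$fit, ~ .x$fit$t_stationary),
      t_start = purrr::map_dbl(.data$fit, ~ .x$window[1]),
      t_end = purrr::map_dbl(.data$fit, ~ .x$window[2]),
      exp_duration = .data$t_end - .data$t_start,
      mu = purrr::map_dbl(.data$fit, ~ .x$mu),
      rss = purrr::map_dbl(.data$fit, ~ .x$fit$rss),
      fit = purrr::map(.data$fit, "fit")
    ) |>
    select(-"data")
}

#' Bacterial growth efficiency for every (treatment, bottle)
#'
#' Joins the growth fits of [fit_growth()] with the DOC series and computes
#' [compute_bge()] per bottle.
#'
#' @param series An incubation series tibble holding both analytes.
#' @param fits Result of [fit_growth()] on the same series.
#' @param pa_analyte,doc_analyte Analyte labels; defaults `"PA"`, `"DOC"`.
#' @param fg_per_cell fg C per cell; default 20.
#' @return A tibble, one row per (treatment, bottle), with the
#'   [compute_bge()] columns.
#' @export
bge_table <- function(series, fits, pa_analyte = "PA", doc_analyte = "DOC",
                      fg_per_cell = 20) {
  series <- validate_timeseries(series)
  ok <- filter(series, .data$qc_flag == "ok")
  purrr::pmap(
    list(fits$treatment, fits$bottle, fits$fit, fits$t_start, fits$t_end),
    function(tr, bo, f, t_start, t_end) {
      pa <- filter(ok, .data$treatment == tr, .data$bottle == bo,
                   .data$analyte == pa_analyte)
      doc <- filter(ok, .data$treatment == tr, .data$bottle == bo,
                    .data$analyte == doc_analyte)
      if (!nrow(doc)) abort(paste0("no DOC series for (", tr, ", ", bo, ")."))
      # if QC flagged the T0 observation (the percentile screen always
      # suspects a declining series' maximum), hold the earliest unflagged
      # DOC value constant back to T0 so the window is covered
      doc_t <- doc$time_days; doc_v <- doc$value
      if (min(doc_t) > t_start) {
        doc_v <- c(doc_v[which.min(doc_t)], doc_v)
        doc_t <- c(t_start, doc_t)
      }
      compute_bge(pa$time_days, pa$value, doc_t, doc_v, f,
                  fg_per_cell = fg_per_cell, window = c(t_start, t_end)) |>
        mutate(treatment = tr, bottle = bo, .before = 1)
    }
  ) |>
    bind_rows()
}
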