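# Unit convention: viable densities are cells/ml, concentrations g/l.
# The ml <-> l factor enters metabolite mass balances in exactly one place.
ML_PER_L <- 1000

#' Batch culture time series
#'
#' Container for sampled viable-cell density, optional metabolite
#' concentrations, and the partial medium-exchange schedule. Samples taken at
#' an exchange time are *pre*-exchange measurements (the spent medium is
#' sampled before replacement).
#'
#' @param times Sampling times in h; strictly increasing, starting at 0.
#' @param viable_density Viable cell density in cells/ml at each time (> 0).
#' @param glucose,lactate Optional concentration series in g/l (`NA` allowed
#'   for unmeasured points).
#' @param exchange_events Optional data.frame with columns `time_h`,
#'   `fraction` (replaced volume fraction in \[0, 1\]) and one
#'   `fresh_<metabolite>` column per metabolite giving the fresh-medium
#'   concentration in g/l (e.g. `fresh_glucose`, `fresh_lactate`).
#' @return An object of class `culture_series`.
#' @examples
#' culture_time_series(c(0, 72, 120, 168), 1e5 * exp(0.028 * c(0, 72, 120, 168)))
#' @export
culture_time_series <- function(times, viable_density, glucose = NULL,
                                lactate = NULL, exchange_events = NULL) {
  if (length(times) < 1L || any(!is.finite(times))) {
    stop("times must be finite", call. = FALSE)
  }
  if (times[1] != 0) stop("time series must start at t = 0 h", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (length(viable_density) != length(times)) {
    stop("viable_density and times must have the same length", call. = FALSE)
  }
  if (any(!is.finite(viable_density)) || any(viable_density <= 0)) {
    stop("viable densities must be finite and positive", call. = FALSE)
  }
  metabolites <- list()
  for (m in c("glucose", "lactate")) {
    v <- get(m)
    if (!is.null(v)) {
      if (length(v) != length(times)) {
        stop(sprintf("%s series length must match times", m), call. = FALSE)
      }
      metabolites[[m]] <- as.numeric(v)
    }
  }
  if (!is.null(exchange_events)) {
    exchange_events <- as.data.frame(exchange_events)
    if (!all(c("time_h", "fraction") %in% names(exchange_events))) {
      stop("exchange_events needs columns time_h and fraction", call. = FALSE)
    }
    if (any(exchange_events$fraction < 0 | exchange_events$fraction > 1)) {
      stop("exchange fractions must lie in [0, 1]", call. = FALSE)
    }
    if (any(exchange_events$time_h < times[1] |
            exchange_events$time_h > times[length(times)])) {
      stop("exchange events must fall within the sampled time range",
           call. = FALSE)
    }
    exchange_events <- exchange_events[order(exchange_events$time_h), ,
                                       drop = FALSE]
  }
  structure(
    list(times = as.numeric(times),
         viable_density = as.numeric(viable_density),
         metabolites = metabolites,
         exchange_events = exchange_events),
    class = "culture_series")
}

#' @export
print.culture_series <- function(x, ...) {
  cat(sprintf("Culture time series: %d samples over %g h", length(x$times),
              max(x$times)))
  if (length(x$metabolites)) {
    cat("; metabolites:", paste(names(x$metabolites), collapse = ", "))
  }
  if (!is.null(x$exchange_events)) {
    cat(sprintf("; %d medium exchanges", nrow(x$exchange_events)))
  }
  cat("\n")
  invisible(x)
}

#' Fit exponential batch growth
#'
#' Fits C_x(t) = C_x0 exp(mu t) by ordinary least squares on the log scale
#' (ln C_x vs t): mu is the slope and C_x0 the exponential of the intercept.
#' R-squared is reported on the log scale.
#'
#' @param series A [culture_time_series()] (or a numeric density vector
#'   together with `times`).
#' @param times Sampling times in h when `series` is a plain numeric vector.
#' @return An object of class `growth_fit` with fields `mu` (1/h),
#'   `initial_density` (cells/ml) and `r_squared`.
#' @examples
#' tt <- c(0, 72, 120, 168)
#' fit_growth(culture_time_series(tt, 1e5 * exp(0.028 * tt)))
#' @export
fit_growth <- function(series, times = NULL) {
  if (inherits(series, "culture_series")) {
    times <- series$times
    dens <- series$viable_density
  } else {
    dens <- series
  }
  if (length(times) < 2L || length(dens) != length(times)) {
    stop("need at least two matched time points", call. = FALSE)
  }
  if (any(!is.finite(dens)) || any(dens <= 0)) {
    stop("densities must be finite and positive", call. = FALSE)
  }
  fit <- stats::lm(log(dens) ~ times)
  ss_tot <- sum((log(dens) - mean(log(dens)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NaN
  structure(
    list(mu = unname(stats::coef(fit)[2]),
         initial_density = unname(exp(stats::coef(fit)[1])),
         r_squared = r2),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: mu = %.4g 1/h, C_x0 = %.4g cells/ml, R^2 = %.4f\n",
              x$mu, x$initial_density, x$r_squared))
  invisible(x)
}

#' Predict viable density from a growth fit
#'
#' C_x(t) = C_x0 exp(mu t).
#'
#' @param fit A [fit_growth()] result (or any list with `mu` and
#'   `initial_density`).
#' @param t Time(s) in h (>= 0).
#' @return Predicted density in cells/ml.
#' @export
predict_density <- function(fit, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  fit$initial_density * exp(fit$mu * t)
}

#' Fold expansion
#'
#' Final viable density divided by initial viable density.
#'
#' @param initial Initial density (> 0), cells/ml.
#' @param final Final density, cells/ml.
#' @return Dimensionless fold expansion.
#' @examples
#' fold_expansion(1e5, 2.74e6)  # 27.4
#' @export
fold_expansion <- function(initial, final) {
  if (any(!is.finite(initial)) || any(initial <= 0)) {
    stop("initial density must be finite and positive", call. = FALSE)
  }
  final / initial
}

# Time integral of the fitted exponential density over [u, v], cells.h/ml.
# expm1 keeps the mu -> 0 limit accurate; mu = 0 returns the linear form.
density_integral <- function(fit, u, v) {
  if (fit$mu == 0) {
    fit$initial_density * (v - u)
  } else {
    fit$initial_density * (expm1(fit$mu * v) - expm1(fit$mu * u)) / fit$mu
  }
}

#' Exchange-corrected cumulative metabolite change
#'
#' Separates the biological consumption/production of a metabolite from the
#' concentration jumps caused by partial medium exchanges. An exchange at
#' time tau replacing a fraction f of the medium with fresh concentration C_f
#' resets the concentration baseline to (1 - f) C(tau-) + f C_f; the
#' cumulative biological change is continuous across events.
#'
#' A sample taken exactly at an exchange time is treated as the pre-exchange
#' concentration. For events strictly inside a sampling interval, the
#' biological rate is assumed constant within that interval and the
#' pre-event concentration is recovered by affine propagation (exact when
#' events coincide with sampling times).
#'
#' @param series A [culture_time_series()] with the metabolite and (possibly
#'   `NULL`) exchange schedule.
#' @param metabolite Metabolite name, e.g. `"glucose"`.
#' @return A data.frame with columns `time_h`, `concentration` (the observed
#'   series) and `cumulative_change` (signed biological change in g/l since
#'   t\[1\]; negative = net consumption).
#' @export
apply_exchange_correction <- function(series, metabolite) {
  stopifnot(inherits(series, "culture_series"))
  conc <- series$metabolites[[metabolite]]
  if (is.null(conc)) {
    stop(sprintf("metabolite '%s' not present in series", metabolite),
         call. = FALSE)
  }
  keep <- !is.na(conc)
  tt <- series$times[keep]
  cc <- conc[keep]
  if (length(tt) < 2L) {
    stop("need at least two measured concentrations", call. = FALSE)
  }
  ev <- series$exchange_events
  fresh_col <- paste0("fresh_", metabolite)
  if (!is.null(ev) && !fresh_col %in% names(ev)) {
    stop(sprintf("exchange_events lacks column %s", fresh_col), call. = FALSE)
  }
  cum <- numeric(length(tt))
  for (i in seq_len(length(tt) - 1L)) {
    t0 <- tt[i]; t1 <- tt[i + 1L]
    # events applying inside (t0, t1]; an event at a sample time applies just
    # after that sample, so tau == t0 belongs to this interval, tau == t1 to
    # the next
    if (!is.null(ev)) {
      in_iv <- ev$time_h >= t0 & ev$time_h < t1
      evs <- ev[in_iv, , drop = FALSE]
    } else {
      evs <- NULL
    }
    if (is.null(evs) || nrow(evs) == 0L) {
      bio <- cc[i + 1L] - cc[i]
    } else {
      # propagate C = p + q * rho (rho = constant biological rate) through
      # the events, then solve for rho from the end-of-interval sample
      p <- cc[i]; q <- 0; cursor <- t0
      for (j in seq_len(nrow(evs))) {
        q <- q + (evs$time_h[j] - cursor)
        f <- evs$fraction[j]
        p <- (1 - f) * p + f * evs[[fresh_col]][j]
        q <- (1 - f) * q
        cursor <- evs$time_h[j]
      }
      q <- q + (t1 - cursor)
      if (q <= 0) {
        stop("degenerate exchange schedule: no residual medium carries information",
             call. = FALSE)
      }
      rho <- (cc[i + 1L] - p) / q
      bio <- rho * (t1 - t0)
    }
    cum[i + 1L] <- cum[i] + bio
  }
  data.frame(time_h = tt, concentration = cc, cumulative_change = cum)
}

#' Specific metabolite consumption/production rate
#'
#' Estimates the specific rate q_met of the batch mass balance
#' q_met C_x = dC_met/dt, after removing medium-exchange jumps with
#' [apply_exchange_correction()]. Two estimates are returned:
#' per-interval rates using the arithmetic mean of the endpoint densities,
#' and an overall rate equal to the exchange-corrected total concentration
#' change divided by the time integral of the fitted exponential density.
#'
#' @inheritParams apply_exchange_correction
#' @param fit Optional [fit_growth()] result; fitted from `series` when
#'   omitted.
#' @return An object of class `metabolic_rates`: a list with `metabolite`,
#'   `q` (positive magnitude, g cell^-1 h^-1), `direction` (`"consumption"`
#'   or `"production"`), `q_signed` (negative = consumption),
#'   `interval_rates` (data.frame `t_start`, `t_end`, `delta_conc`,
#'   `mean_density`, `q_signed`), `predicted` (model-predicted concentration
#'   at the measured times), `r_squared` (observed vs model prediction) and
#'   `growth_fit`.
#' @export
specific_metabolite_rate <- function(series, metabolite, fit = NULL) {
  corr <- apply_exchange_correction(series, metabolite)
  if (is.null(fit)) fit <- fit_growth(series)
  tt <- corr$time_h
  keep <- series$times %in% tt
  dens <- series$viable_density[keep]
  n <- length(tt)
  d_conc <- diff(corr$cumulative_change)
  d_t <- diff(tt)
  mean_dens <- (dens[-n] + dens[-1L]) / 2
  interval <- data.frame(
    t_start = tt[-n], t_end = tt[-1L], delta_conc = d_conc,
    mean_density = mean_dens,
    q_signed = d_conc / (d_t * mean_dens * ML_PER_L))
  total <- corr$cumulative_change[n]
  q_signed <- total / (density_integral(fit, tt[1L], tt[n]) * ML_PER_L)
  direction <- if (q_signed < 0) "consumption" else "production"
  pred <- predict_metabolite_profile(
    fit, abs(q_signed), corr$concentration[1L], tt,
    direction = direction, exchange_events = series$exchange_events,
    metabolite = metabolite)
  structure(
    list(metabolite = metabolite,
         q = abs(q_signed),
         direction = direction,
         q_signed = q_signed,
         interval_rates = interval,
         predicted = pred,
         r_squared = tryCatch(r_squared(corr$concentration, pred),
                              error = function(e) NA_real_),
         growth_fit = fit),
    class = "metabolic_rates")
}

#' @export
print.metabolic_rates <- function(x, ...) {
  cat(sprintf("Specific %s %s rate: q = %.3e g/cell/h (R^2 = %.3f)\n",
              x$metabolite, x$direction, x$q, x$r_squared))
  invisible(x)
}

#' Closed-form metabolite concentration profile
#'
#' Integrates the batch mass balance (+/- q C_x) V = d(C_met V)/dt with
#' exponential cell growth, giving
#' C(t) = C0 + s q m C_x0 (exp(mu t) - 1) / mu
#' between exchanges, where s = +1 for production, -1 for consumption and m
#' converts the cells/ml density to the per-litre concentration basis. The
#' mu = 0 limit is the linear form C0 + s q m C_x0 t. Each exchange event
#' resets the baseline to (1 - f) C(tau-) + f C_f using the model value of
#' C(tau-). Predicted concentrations are floored at 0 with a warning if
#' depletion is reached.
#'
#' @param fit A [fit_growth()] result (fields `mu`, `initial_density`).
#' @param q Specific rate magnitude, g cell^-1 h^-1 (>= 0).
#' @param C0 Concentration at t = 0, g/l (>= 0).
#' @param times Times (h) at which to evaluate the profile.
#' @param direction `"consumption"` or `"production"`.
#' @param exchange_events Optional exchange schedule as in
#'   [culture_time_series()].
#' @param metabolite Metabolite name used to pick the `fresh_<metabolite>`
#'   column of `exchange_events`.
#' @param conversion_ml_l Density-to-concentration basis factor (ml per l);
#'   default 1000.
#' @return Numeric vector of concentrations (g/l) at `times`.
#' @export
predict_metabolite_profile <- function(fit, q, C0, times,
                                       direction = c("consumption", "production"),
                                       exchange_events = NULL,
                                       metabolite = NULL,
                                       conversion_ml_l = ML_PER_L) {
  direction <- match.arg(direction)
  if (q < 0) stop("q is a magnitude; use `direction` for the sign", call. = FALSE)
  if (C0 < 0) stop("C0 must be non-negative", call. = FALSE)
  s <- if (direction == "consumption") -1 else 1
  rate <- function(u, v) {
    s * q * conversion_ml_l * density_integral(fit, u, v)
  }
  ev_t <- numeric(0); ev_f <- numeric(0); ev_c <- numeric(0)
  if (!is.null(exchange_events) && nrow(exchange_events) > 0L) {
    fresh_col <- if (!is.null(metabolite)) paste0("fresh_", metabolite) else "fresh"
    if (!fresh_col %in% names(exchange_events)) {
      stop(sprintf("exchange_events lacks column %s", fresh_col), call. = FALSE)
    }
    ord <- order(exchange_events$time_h)
    ev_t <- exchange_events$time_h[ord]
    ev_f <- exchange_events$fraction[ord]
    ev_c <- exchange_events[[fresh_col]][ord]
  }
  out <- numeric(length(times))
  ord_q <- order(times)
  base_t <- 0; base_c <- C0; next_ev <- 1L
  for (k in ord_q) {
    t_k <- times[k]
    # apply events up to (and excluding) t_k: a sample at an exchange time is
    # the pre-exchange concentration
    while (next_ev <= length(ev_t) && ev_t[next_ev] < t_k) {
      c_pre <- base_c + rate(base_t, ev_t[next_ev])
      base_c <- (1 - ev_f[next_ev]) * c_pre + ev_f[next_ev] * ev_c[next_ev]
      base_t <- ev_t[next_ev]
      next_ev <- next_ev + 1L
    }
    out[k] <- base_c + rate(base_t, t_k)
  }
  if (any(out < 0)) {
    warning("predicted metabolite depletion: concentrations floored at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot between an observed and a predicted series.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return R^2 (<= 1; can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("observed and predicted must be equal-length vectors (n >= 2)",
         call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: observed series has zero variance", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Lactate-to-glucose yield ratio
#'
#' Exchange-corrected lactate produced divided by exchange-corrected glucose
#' consumed over a time window: an index of overflow metabolism (values near
#' 2 mol/mol, here computed on a mass basis in g/g, indicate anaerobic waste
#' metabolism; lower values indicate respiratory glucose use).
#'
#' @inheritParams apply_exchange_correction
#' @param window Length-2 numeric `c(t_a, t_b)` in h, inside the sampled
#'   range; defaults to the full series. Cumulative changes are interpolated
#'   linearly at non-sample endpoints.
#' @return Dimensionless yield ratio.
#' @export
lactate_glucose_ratio <- function(series, window = NULL) {
  glc <- apply_exchange_correction(series, "glucose")
  lac <- apply_exchange_correction(series, "lactate")
  if (is.null(window)) window <- range(series$times)
  if (window[1] > window[2] || window[1] < series$times[1] ||
      window[2] > series$times[length(series$times)]) {
    stop("window must be an ordered interval inside the sampled range",
         call. = FALSE)
  }
  cum_at <- function(corr, t) {
    stats::approx(corr$time_h, corr$cumulative_change, xout = t)$y
  }
  consumed <- -(cum_at(glc, window[2]) - cum_at(glc, window[1]))
  produced <- cum_at(lac, window[2]) - cum_at(lac, window[1])
  if (consumed <= 0) {
    stop("yield ratio undefined: no net glucose consumption in window",
         call. = FALSE)
  }
  produced / consumed
}
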