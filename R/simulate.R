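#' Simulation configuration for synthetic culture data
#'
#' Collects every parameter of the synthetic-data generators with defaults
#' matching a 7-day suspension expansion run: seeding at 1e5 cells/ml,
#' exponential growth at 0.028 1/h (the low-shear agitation condition),
#' counts sampled on days 0/3/5/7 with 10% lognormal counting noise,
#' metabolites sampled daily with 50% medium exchanges on days 1/3/5
#' (fresh glucose 2 g/l), and micrographs of 100 non-overlapping elliptical
#' cells whose axis-ratio populations (round 0.85-0.98, stretched 0.40-0.70)
#' straddle the R_c = 0.8 classification threshold with a guard band.
#'
#' All generators consume the configuration `seed` through R's default
#' Mersenne-Twister stream (`set.seed(seed)` at entry), so equal
#' configurations give identical output on any platform.
#'
#' @param seed Integer RNG seed.
#' @param true_mu Specific growth rate, 1/h.
#' @param true_C_x0 Seeding density, cells/ml.
#' @param sampling_times Counting times in h.
#' @param count_noise_cv Lognormal sigma (log scale) of counting noise.
#' @param q_glucose,q_lactate Specific rate magnitudes, g cell^-1 h^-1
#'   (glucose consumed, lactate produced).
#' @param C_glc0,C_lac0 Initial concentrations, g/l.
#' @param fresh_glc,fresh_lac Fresh-medium concentrations at exchanges, g/l.
#' @param exchange_times Exchange times in h (50% replacement on days 1/3/5
#'   by default).
#' @param exchange_fraction Replaced volume fraction at each exchange.
#' @param metabolite_times Metabolite sampling times in h.
#' @param metabolite_noise_sd Additive Gaussian noise on concentrations, g/l.
#' @param n_cells Number of cells per synthetic image.
#' @param round_fraction_true Fraction of cells drawn from the round
#'   population.
#' @param round_ratio_range,stretched_ratio_range Minor/major axis-ratio
#'   ranges of the two populations; they must avoid the band 0.75-0.85 so
#'   rasterization error cannot flip a ground-truth class.
#' @param semi_major_range Cell semi-major axis range in px.
#' @param canvas_px Square image side length in px.
#' @param background,foreground Background/foreground intensities in \[0, 1\].
#' @param image_noise_sd Gaussian pixel noise sd.
#' @return An object of class `simulation_config` (a list of the above).
#' @export
simulation_config <- function(seed = 1L,
                              true_mu = 0.028,
                              true_C_x0 = 1e5,
                              sampling_times = c(0, 72, 120, 168),
                              count_noise_cv = 0.1,
                              q_glucose = 3.0e-12,
                              q_lactate = 2.7e-12,
                              C_glc0 = 2.0, C_lac0 = 0,
                              fresh_glc = 2.0, fresh_lac = 0,
                              exchange_times = c(24, 72, 120),
                              exchange_fraction = 0.5,
                              metabolite_times = seq(0, 168, by = 24),
                              metabolite_noise_sd = 0.05,
                              n_cells = 100L,
                              round_fraction_true = 0.67,
                              round_ratio_range = c(0.85, 0.98),
                              stretched_ratio_range = c(0.40, 0.70),
                              semi_major_range = c(10, 16),
                              canvas_px = 1024L,
                              background = 0.1, foreground = 0.85,
                              image_noise_sd = 0.02) {
  stopifnot(is.finite(true_mu), true_C_x0 > 0, count_noise_cv >= 0,
            q_glucose >= 0, q_lactate >= 0,
            metabolite_noise_sd >= 0, image_noise_sd >= 0,
            round_fraction_true >= 0, round_fraction_true <= 1,
            exchange_fraction >= 0, exchange_fraction <= 1)
  guard <- c(0.75, 0.85)
  for (rg in list(round_ratio_range, stretched_ratio_range)) {
    if (rg[1] < guard[2] && rg[2] > guard[1]) {
      stop("axis-ratio ranges must avoid the 0.75-0.85 guard band around the R_c threshold",
           call. = FALSE)
    }
  }
  structure(as.list(environment())[setdiff(ls(), c("guard", "rg"))],
            class = "simulation_config")
}

#' Simulate a viable-cell growth series
#'
#' C_x(t_i) = C_x0 exp(mu t_i) exp(e_i) with e_i ~ Normal(0, sigma^2) on the
#' log scale (lognormal counting noise: counts are positive and errors
#' multiplicative).
#'
#' @param config A [simulation_config()].
#' @return A [culture_time_series()] with the exchange schedule attached.
#' @examples
#' s <- simulate_growth(simulation_config(seed = 7))
#' fit_growth(s)$mu
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tt <- config$sampling_times
  dens <- config$true_C_x0 * exp(config$true_mu * tt) *
    exp(stats::rnorm(length(tt), 0, config$count_noise_cv))
  culture_time_series(tt, dens, exchange_events = exchange_schedule(config))
}

exchange_schedule <- function(config) {
  if (length(config$exchange_times) == 0L) return(NULL)
  data.frame(time_h = config$exchange_times,
             fraction = config$exchange_fraction,
             fresh_glucose = config$fresh_glc,
             fresh_lactate = config$fresh_lac)
}

#' Simulate glucose and lactate profiles
#'
#' Concentrations follow the closed-form batch mass balance with exponential
#' cell growth ([predict_metabolite_profile()]), with the baseline reset at
#' each partial medium exchange, additive Gaussian measurement noise, and a
#' floor at 0 g/l. Samples at exchange times are pre-exchange values.
#' Densities are sampled at `metabolite_times` (noise-free, so kinetics
#' round trips isolate metabolite noise).
#'
#' @param config A [simulation_config()].
#' @param noise_sd Overrides `config$metabolite_noise_sd` when not `NULL`.
#' @return A [culture_time_series()] with `glucose` and `lactate` series.
#' @export
simulate_metabolites <- function(config, noise_sd = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(noise_sd)) noise_sd <- config$metabolite_noise_sd
  set.seed(config$seed + 1L)
  tt <- config$metabolite_times
  fit <- list(mu = config$true_mu, initial_density = config$true_C_x0)
  ev <- exchange_schedule(config)
  glc <- predict_metabolite_profile(fit, config$q_glucose, config$C_glc0, tt,
                                    direction = "consumption",
                                    exchange_events = ev,
                                    metabolite = "glucose")
  lac <- predict_metabolite_profile(fit, config$q_lactate, config$C_lac0, tt,
                                    direction = "production",
                                    exchange_events = ev,
                                    metabolite = "lactate")
  if (noise_sd > 0) {
    glc <- glc + stats::rnorm(length(tt), 0, noise_sd)
    lac <- lac + stats::rnorm(length(tt), 0, noise_sd)
  }
  culture_time_series(tt, config$true_C_x0 * exp(config$true_mu * tt),
                      glucose = pmax(glc, 0), lactate = pmax(lac, 0),
                      exchange_events = ev)
}

#' Render a synthetic micrograph of elliptical cells
#'
#' Places `n_cells` non-overlapping ellipses with uniform random centres and
#' orientations on a square canvas. Exactly `round(n_cells *
#' round_fraction_true)` cells draw their minor/major axis ratio from the
#' round population, the rest from the stretched population, so the
#' ground-truth round fraction is known exactly. Gaussian pixel noise is
#' added and intensities clipped to \[0, 1\].
#'
#' Placement uses rejection sampling; if `max_attempts` proposals cannot
#' accommodate all cells, an error advises enlarging the canvas.
#'
#' @param config A [simulation_config()].
#' @param max_attempts Maximum centre proposals (default 20000).
#' @return A list with `image` (intensity matrix) and `truth` (data.frame
#'   `cell`, `center_x`, `center_y`, `semi_major`, `semi_minor`,
#'   `axis_ratio`, `angle`, `round` (logical ground-truth class)).
#' @export
render_cell_image <- function(config, max_attempts = 20000L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n <- config$n_cells
  n_round <- round(n * config$round_fraction_true)
  is_round <- c(rep(TRUE, n_round), rep(FALSE, n - n_round))
  a <- stats::runif(n, config$semi_major_range[1], config$semi_major_range[2])
  ratio <- ifelse(is_round,
                  stats::runif(n, config$round_ratio_range[1],
                               config$round_ratio_range[2]),
                  stats::runif(n, config$stretched_ratio_range[1],
                               config$stretched_ratio_range[2]))
  b <- a * ratio
  ang <- stats::runif(n, 0, pi)
  side <- config$canvas_px
  margin <- max(config$semi_major_range) + 4
  min_gap <- 2 * max(config$semi_major_range) + 4
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(paste0("could not place %d non-overlapping cells in %d ",
                          "attempts; increase canvas_px"), n, max_attempts),
           call. = FALSE)
    }
    px <- stats::runif(1, margin, side - margin)
    py <- stats::runif(1, margin, side - margin)
    if (placed == 0L ||
        all((cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2 >=
            min_gap^2)) {
      placed <- placed + 1L
      cx[placed] <- px; cy[placed] <- py
    }
  }
  img <- matrix(config$background, side, side)
  for (i in seq_len(n)) {
    r <- ceiling(a[i]) + 2
    xs <- max(1, floor(cx[i] - r)):min(side, ceiling(cx[i] + r))
    ys <- max(1, floor(cy[i] - r)):min(side, ceiling(cy[i] + r))
    dx <- outer(xs - cx[i], rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - cy[i])
    u <- dx * cos(ang[i]) + dy * sin(ang[i])
    v <- -dx * sin(ang[i]) + dy * cos(ang[i])
    inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
    img[xs, ys][inside] <- config$foreground
  }
  if (config$image_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(side * side, 0, config$image_noise_sd),
                        side, side)
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img,
       truth = data.frame(cell = seq_len(n), center_x = cx, center_y = cy,
                          semi_major = a, semi_minor = b, axis_ratio = ratio,
                          angle = ang, round = is_round))
}
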