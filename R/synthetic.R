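#' Stochastic climate specification for a central-German lowland site
#'
#' Defaults emulate the Kassel area: about 650 mm annual precipitation,
#' 9 degC mean air temperature, winter-skewed humidity. Precipitation
#' occurrence follows a first-order two-state Markov chain with seasonal
#' transition probabilities (DJF, MAM, JJA, SON); wet-day amounts are gamma
#' distributed, scaled so that the expected annual total matches
#' `annual_precip_mm`, with a multiplicative lognormal year factor of mean 1
#' providing interannual variability.
#'
#' @param annual_precip_mm Expected annual precipitation (mm).
#' @param interannual_cv Coefficient of variation of the annual year factor.
#' @param p_wet_given_dry,p_wet_given_wet Markov transition probabilities
#'   P(wet | dry) and P(wet | wet); scalars or length-4 seasonal vectors
#'   (DJF, MAM, JJA, SON).
#' @param gamma_shape Gamma shape of wet-day amounts.
#' @param t_mean_c,t_amplitude_c,t_phase_doy,t_noise_sd Temperature sinusoid:
#'   annual mean (degC), half-amplitude, coldest day of year, daily noise sd.
#' @param diurnal_range_c Mean diurnal temperature range (degC).
#' @param rad_mean,rad_amplitude Global-radiation sinusoid (MJ/m2/d).
#' @param rh_mean,rh_amplitude,rh_wet_bonus Relative-humidity sinusoid (%)
#'   and wet-day increment.
#' @param wind_mean_ms Mean wind speed (m/s, lognormal).
#' @return A list of class `pfas_climate`.
#' @export
climate_spec <- function(annual_precip_mm = 650, interannual_cv = 0.15,
                         p_wet_given_dry = c(0.30, 0.27, 0.26, 0.29),
                         p_wet_given_wet = c(0.65, 0.60, 0.58, 0.63),
                         gamma_shape = 0.75,
                         t_mean_c = 9, t_amplitude_c = 9, t_phase_doy = 15,
                         t_noise_sd = 2.5, diurnal_range_c = 8,
                         rad_mean = 11, rad_amplitude = 9.5,
                         rh_mean = 80, rh_amplitude = 8, rh_wet_bonus = 7,
                         wind_mean_ms = 2.2) {
  p01 <- rep_len(p_wet_given_dry, 4)
  p11 <- rep_len(p_wet_given_wet, 4)
  stopifnot(all(p01 >= 0 & p01 <= 1), all(p11 >= 0 & p11 <= 1),
            gamma_shape > 0, annual_precip_mm > 0, interannual_cv >= 0,
            t_noise_sd >= 0)
  structure(list(
    annual_precip_mm = annual_precip_mm, interannual_cv = interannual_cv,
    p_wet_given_dry = p01, p_wet_given_wet = p11, gamma_shape = gamma_shape,
    t_mean_c = t_mean_c, t_amplitude_c = t_amplitude_c,
    t_phase_doy = t_phase_doy, t_noise_sd = t_noise_sd,
    diurnal_range_c = diurnal_range_c, rad_mean = rad_mean,
    rad_amplitude = rad_amplitude, rh_mean = rh_mean,
    rh_amplitude = rh_amplitude, rh_wet_bonus = rh_wet_bonus,
    wind_mean_ms = wind_mean_ms
  ), class = "pfas_climate")
}

# stationary wet-day probability of the seasonal Markov chain
markov_stationary_wet <- function(spec) {
  spec$p_wet_given_dry / (1 - spec$p_wet_given_wet + spec$p_wet_given_dry)
}

season_of_month <- function(m) {
  c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)[m]
}

#' Generate a daily synthetic weather series
#'
#' @param spec A [climate_spec()].
#' @param start Start date.
#' @param years Number of calendar years to generate (>= 1).
#' @param seed Integer seed; a fixed seed reproduces the series exactly.
#' @return Weather tibble with columns `date`, `precip_mm`, `tmean_c`,
#'   `tmin_c`, `tmax_c`, `rad_mj_m2`, `rh_pct`, `wind_ms`.
#' @export
generate_weather <- function(spec = climate_spec(), start = "2006-01-01",
                             years = 10, seed = 1) {
  stopifnot(years >= 1)
  start <- as.Date(start)
  end <- seq(start, by = paste(years, "years"), length.out = 2)[2] - 1
  dates <- seq(start, end, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  seas <- season_of_month(mon)
  set.seed(seed)

  # occurrence: first-order Markov chain with seasonal persistence
  u <- runif(n)
  wet <- logical(n)
  p01 <- spec$p_wet_given_dry[seas]
  p11 <- spec$p_wet_given_wet[seas]
  state <- FALSE
  for (i in seq_len(n)) {
    state <- u[i] < if (state) p11[i] else p01[i]
    wet[i] <- state
  }

  # amounts: gamma, scaled to the expected annual total
  pi_wet <- markov_stationary_wet(spec)
  e_wet_days <- sum(c(90.25, 92, 92, 91) * pi_wet)
  scale <- spec$annual_precip_mm / (e_wet_days * spec$gamma_shape)
  precip <- numeric(n)
  precip[wet] <- rgamma(sum(wet), shape = spec$gamma_shape, scale = scale)
  if (spec$interannual_cv > 0) {
    s <- sqrt(log(1 + spec$interannual_cv^2))
    yfac <- setNames(rlnorm(length(unique(yr)), -s^2 / 2, s),
                     sort(unique(yr)))
    precip <- precip * yfac[as.character(yr)]
  }

  ang <- 2 * pi * (doy - spec$t_phase_doy) / 365.25
  tmean <- spec$t_mean_c - spec$t_amplitude_c * cos(ang) +
    rnorm(n, 0, spec$t_noise_sd)
  dr <- pmax(rnorm(n, spec$diurnal_range_c, 1.5), 1)
  rad0 <- spec$rad_mean + spec$rad_amplitude * sin(2 * pi * (doy - 81) / 365.25)
  rad <- rad0 * ifelse(wet, 0.75, 1.05) * (1 + rnorm(n, 0, 0.08))
  ra <- extraterrestrial_radiation(51.3, doy)
  rad <- pmin(pmax(rad, 0.5), 0.78 * ra)
  rh <- spec$rh_mean - spec$rh_amplitude * sin(2 * pi * (doy - 81) / 365.25) +
    ifelse(wet, spec$rh_wet_bonus, 0) + rnorm(n, 0, 4)
  rh <- pmin(pmax(rh, 35), 100)
  wind <- rlnorm(n, log(spec$wind_mean_ms) - 0.35^2 / 2, 0.35)

  tibble::tibble(
    date = dates, precip_mm = precip, tmean_c = tmean,
    tmin_c = tmean - dr / 2, tmax_c = tmean + dr / 2,
    rad_mj_m2 = rad, rh_pct = rh, wind_ms = wind
  )
}

#' Observation noise specification
#'
#' Multiplicative lognormal measurement error (mean 1) for each observation
#' type, plus a reporting limit below which leachate concentrations are
#' censored to missing.
#'
#' @param cv_q,cv_c,cv_u Coefficients of variation for monthly percolation
#'   volumes, monthly leachate concentrations and seasonal plant uptake.
#' @param detection_limit_ugl Concentration reporting limit (ug/l).
#' @return A list of class `pfas_noise`.
#' @export
noise_spec <- function(cv_q = 0.10, cv_c = 0.20, cv_u = 0.30,
                       detection_limit_ugl = 0.1) {
  stopifnot(cv_q >= 0, cv_c >= 0, cv_u >= 0, detection_limit_ugl >= 0)
  structure(list(cv_q = cv_q, cv_c = cv_c, cv_u = cv_u,
                 detection_limit_ugl = detection_limit_ugl),
            class = "pfas_noise")
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, -s^2 / 2, s)
}

#' Generate a complete synthetic lysimeter study
#'
#' Runs the simulator with a known ("truth") configuration and samples what
#' the real experiment measured: monthly percolation volumes, monthly
#' flux-averaged leachate concentrations per substance (only for months with
#' outflow; censored below the detection limit) and per-season plant uptake
#' per substance — each perturbed with multiplicative lognormal noise.
#'
#' @param config Truth configuration (see [default_config()]).
#' @param noise A [noise_spec()].
#' @param seed Integer seed for the observation noise.
#' @param from Date; observations start at this date (default the earliest
#'   application date, excluding warm-up).
#' @return A list with `observations` (tibble `date`, `variable`, `value`,
#'   `unit`), `truth` (config and seed), and `sim` (the truth `pfas_sim`).
#' @export
generate_study <- function(config, noise = noise_spec(), seed = 1,
                           from = NULL) {
  config <- as_config(config)
  sim <- simulate_column(config)
  if (is.null(from)) {
    from <- min(as.Date(vapply(config$substances,
                               function(s) as.character(s$application_date),
                               "")))
  }
  from <- as.Date(format(as.Date(from), "%Y-%m-01"))
  set.seed(seed)

  q <- sim$monthly_q |> dplyr::filter(.data$month >= from)
  obs <- tibble::tibble(
    date = q$month, variable = "Q",
    value = q$q_l * lognormal_factor(nrow(q), noise$cv_q),
    unit = "l/month"
  )
  for (nm in names(sim$substances)) {
    r <- sim$substances[[nm]]
    cm <- r$monthly |>
      dplyr::filter(.data$month >= from, .data$q_l > 0, !is.na(.data$c_ugl))
    cv <- cm$c_ugl * lognormal_factor(nrow(cm), noise$cv_c)
    keep <- cv >= noise$detection_limit_ugl
    obs <- dplyr::bind_rows(
      obs,
      tibble::tibble(date = cm$month[keep], variable = paste0("C_", nm),
                     value = cv[keep], unit = "ug/l"),
      tibble::tibble(
        date = as.Date(paste0(r$seasonal$season, "-08-01")),
        variable = paste0("U_", nm),
        value = r$seasonal$uptake_g *
          lognormal_factor(nrow(r$seasonal), noise$cv_u),
        unit = "g"
      ) |> dplyr::filter(.data$date >= from)
    )
  }
  list(observations = dplyr::arrange(obs, .data$variable, .data$date),
       truth = list(config = config, seed = seed),
       sim = sim)
}
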