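# Saturation vapour pressure (kPa) at air temperature t (degC), FAO-56 form.
svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

# Extraterrestrial radiation (MJ/m2/d) for a latitude (deg) and day of year.
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Penman-Monteith evapotranspiration from pre-computed surface terms
#'
#' Daily Penman-Monteith evaporation in the FAO-56 parameterisation,
#' generalised to an arbitrary bulk surface resistance: the reference-crop
#' constants 900 and 0.34 arise from an aerodynamic resistance of `208/u2`
#' s/m and a surface resistance of 70 s/m; here the surface-resistance term
#' is `rs * u2 / 208` so that the stomatal control of the actual canopy
#' enters the denominator.
#'
#' @param t_mean Mean air temperature (degC).
#' @param net_radiation Net radiation at the surface (MJ/m2/d).
#' @param vpd Vapour-pressure deficit `e_s - e_a` (kPa), >= 0.
#' @param wind Wind speed at 2 m (m/s), >= 0.
#' @param rs Bulk surface resistance (s/m).
#' @param g Soil heat flux (MJ/m2/d), 0 at daily resolution.
#' @param pressure_kpa Atmospheric pressure (kPa).
#' @return Potential evapotranspiration (mm/d, never negative).
#' @export
penman_monteith <- function(t_mean, net_radiation, vpd, wind, rs = 70,
                            g = 0, pressure_kpa = 101.3) {
  if (!is.finite(t_mean)) stop("`t_mean` must be finite", call. = FALSE)
  delta <- 4098 * svp(t_mean) / (t_mean + 237.3)^2
  gamma <- 0.000665 * pressure_kpa
  num <- 0.408 * delta * (net_radiation - g) +
    gamma * 900 / (t_mean + 273) * wind * vpd
  den <- delta + gamma * (1 + rs * wind / 208)
  max(num / den, 0)
}

#' Reference/potential evapotranspiration for one weather day
#'
#' Uses the Penman-Monteith form when radiation, relative humidity and wind
#' are available (albedo enters the net-radiation term, the crop's minimum
#' stomatal resistance the surface-resistance term); otherwise falls back to
#' the temperature-based Hargreaves estimate from `t_min`/`t_max`, which
#' ignores the stomatal resistance.
#'
#' @param day One weather record: a list or one-row data frame with at least
#'   `date` and `tmean_c`, optionally `tmin_c`, `tmax_c`, `rad_mj_m2`,
#'   `rh_pct`, `wind_ms`.
#' @param site Site description as from [site_params()]: `albedo`,
#'   `latitude`, `elevation_m`.
#' @param rsmin Minimum stomatal resistance of the active crop (s/m); the
#'   bulk surface resistance is `rsmin / 1.44` (an active leaf-area index of
#'   1.44, the FAO-56 reference canopy). Default 100 s/m reproduces the
#'   FAO-56 reference surface.
#' @return Potential evapotranspiration (mm/d).
#' @export
reference_et <- function(day, site, rsmin = 100) {
  t_mean <- day$tmean_c
  if (is.null(t_mean) || is.na(t_mean)) {
    stop("weather day is missing `tmean_c`", call. = FALSE)
  }
  doy <- as.integer(format(as.Date(day$date), "%j"))
  ra <- extraterrestrial_radiation(site$latitude, doy)
  has <- function(x) !is.null(day[[x]]) && !is.na(day[[x]])
  if (has("rad_mj_m2") && has("rh_pct") && has("wind_ms")) {
    rs_mj <- day$rad_mj_m2
    if (has("tmin_c") && has("tmax_c")) {
      es <- (svp(day$tmax_c) + svp(day$tmin_c)) / 2
      tk4 <- ((day$tmax_c + 273.16)^4 + (day$tmin_c + 273.16)^4) / 2
    } else {
      es <- svp(t_mean)
      tk4 <- (t_mean + 273.16)^4
    }
    ea <- day$rh_pct / 100 * es
    elev <- if (is.null(site$elevation_m)) 200 else site$elevation_m
    rso <- (0.75 + 2e-5 * elev) * ra
    rel <- if (rso > 0) pmin(rs_mj / rso, 1) else 0
    rnl <- 4.903e-9 * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) *
      (1.35 * rel - 0.35)
    rn <- (1 - site$albedo) * rs_mj - max(rnl, 0)
    pressure <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
    penman_monteith(t_mean, rn, vpd = max(es - ea, 0), wind = day$wind_ms,
                    rs = rsmin / 1.44, pressure_kpa = pressure)
  } else if (has("tmin_c") && has("tmax_c")) {
    max(0.0023 * 0.408 * ra * (t_mean + 17.8) *
          sqrt(max(day$tmax_c - day$tmin_c, 0)), 0)
  } else {
    stop("need either (rad_mj_m2, rh_pct, wind_ms) or (tmin_c, tmax_c) ",
         "in addition to tmean_c", call. = FALSE)
  }
}

#' Partition potential evapotranspiration by canopy cover
#'
#' Beer-law split of potential evapotranspiration into soil evaporation and
#' crop transpiration: the transpiration fraction is `1 - exp(-k * lai)`.
#'
#' @param pet Potential evapotranspiration (mm/d), >= 0.
#' @param lai Leaf-area index (dimensionless), >= 0.
#' @param k Canopy extinction coefficient (default 0.6).
#' @return Named numeric vector with `evaporation` and `transpiration`
#'   (mm/d), summing to `pet`.
#' @export
partition_et <- function(pet, lai, k = 0.6) {
  stopifnot(pet >= 0, lai >= 0, k >= 0)
  f_t <- 1 - exp(-k * lai)
  tr <- pet * f_t
  c(evaporation = pet - tr, transpiration = tr)
}
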