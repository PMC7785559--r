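# Vectorised potential-ET series; Penman-Monteith where radiation, humidity
# and wind are present, Hargreaves from the diurnal temperature range
# otherwise. reference_et() is the scalar interface over the same arithmetic.
pet_series <- function(weather, site, rsmin) {
  n <- nrow(weather)
  rsmin <- rep_len(rsmin, n)
  doy <- as.integer(format(weather$date, "%j"))
  ra <- extraterrestrial_radiation(site$latitude, doy)
  tmean <- weather$tmean_c
  if (any(is.na(tmean))) stop("weather has missing tmean_c", call. = FALSE)
  getcol <- function(nm) if (nm %in% names(weather)) weather[[nm]] else
    rep(NA_real_, n)
  tmin <- getcol("tmin_c"); tmax <- getcol("tmax_c")
  rad <- getcol("rad_mj_m2"); rh <- getcol("rh_pct"); wind <- getcol("wind_ms")

  pm_ok <- !is.na(rad) & !is.na(rh) & !is.na(wind)
  hg_ok <- !is.na(tmin) & !is.na(tmax)
  if (any(!pm_ok & !hg_ok)) {
    stop("weather day without (rad, rh, wind) or (tmin, tmax)", call. = FALSE)
  }
  elev <- if (is.null(site$elevation_m)) 200 else site$elevation_m
  pressure <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  gamma <- 0.000665 * pressure

  pet <- numeric(n)
  if (any(pm_ok)) {
    i <- which(pm_ok)
    have_ext <- !is.na(tmin[i]) & !is.na(tmax[i])
    es <- ifelse(have_ext, (svp(ifelse(have_ext, tmax[i], 0)) +
                              svp(ifelse(have_ext, tmin[i], 0))) / 2,
                 svp(tmean[i]))
    tk4 <- ifelse(have_ext,
                  ((tmax[i] + 273.16)^4 + (tmin[i] + 273.16)^4) / 2,
                  (tmean[i] + 273.16)^4)
    ea <- rh[i] / 100 * es
    rso <- (0.75 + 2e-5 * elev) * ra[i]
    rel <- ifelse(rso > 0, pmin(rad[i] / rso, 1), 0)
    rnl <- pmax(4.903e-9 * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) *
                  (1.35 * rel - 0.35), 0)
    rn <- (1 - site$albedo) * rad[i] - rnl
    vpd <- pmax(es - ea, 0)
    delta <- 4098 * svp(tmean[i]) / (tmean[i] + 237.3)^2
    num <- 0.408 * delta * rn + gamma * 900 / (tmean[i] + 273) * wind[i] * vpd
    den <- delta + gamma * (1 + (rsmin[i] / 1.44) * wind[i] / 208)
    pet[i] <- pmax(num / den, 0)
  }
  if (any(!pm_ok)) {
    i <- which(!pm_ok)
    pet[i] <- pmax(0.0023 * 0.408 * ra[i] * (tmean[i] + 17.8) *
                     sqrt(pmax(tmax[i] - tmin[i], 0)), 0)
  }
  pet
}

#' Daily layered water balance of a free-draining soil column
#'
#' Capacity-type ("tipping bucket") matrix flow with a single preferential
#' bypass store: rainfall (or snowmelt; snow accumulates below 0 degC and
#' melts degree-day at 2 mm/degC/d) infiltrates up to the topsoil's maximum
#' matrix percolation rate, the excess being routed to the macropore domain,
#' which discharges at the column bottom with a one-day travel time. Potential
#' evapotranspiration is split by canopy cover into soil evaporation (top
#' layer) and transpiration (extracted over the root zone weighted by an
#' exponential root distribution); water above field capacity cascades
#' downward at up to `k_matrix` per layer; the deepest layer drains freely.
#'
#' The daily water balance closes exactly:
#' `precip = delta(storage) + actual ET + bottom outflow`.
#'
#' @param weather Weather tibble (`date`, `precip_mm`, `tmean_c`, optional
#'   `tmin_c`, `tmax_c`, `rad_mj_m2`, `rh_pct`, `wind_ms`), daily, gap-free.
#' @param soil Soil profile tibble, see [soil_profile()].
#' @param rotation Crop rotation tibble, see [default_rotation()]; `NULL`
#'   for permanently bare soil.
#' @param site Site description, see [site_params()].
#' @param options Named list; recognised entries `snow_melt` (mm/degC/d,
#'   default 2), `extinction_k` (canopy extinction, default 0.6),
#'   `theta_init` (`"fc"` or numeric volumetric content).
#' @return An object of class `pfas_water`: a list with per-day vectors
#'   (`precip`, `pet`, `evap_actual`, `transp_actual`, `infiltration`,
#'   `macro_in`, `macro_out`, `bottom_matrix`, `bottom_outflow`, `closure`),
#'   matrices `w_mm`, `theta`, `perc` (interface fluxes), `transp_layer`
#'   (days x layers) and the inputs needed downstream.
#' @export
run_water_balance <- function(weather, soil, rotation, site,
                              options = list()) {
  validate_soil(soil)
  validate_weather(weather)
  opt <- modifyList(list(snow_melt = 2, extinction_k = 0.6,
                         theta_init = "fc"), options)
  n_day <- nrow(weather)
  nl <- nrow(soil)
  th_mm <- soil$thickness * 1000
  wmax <- soil$theta_sat * th_mm
  wfc <- soil$theta_fc * th_mm
  wwp <- soil$theta_wp * th_mm
  kmat <- soil$k_matrix
  mf_top <- soil$macropore_fraction[1]
  bounds <- cumsum(c(0, soil$thickness))

  crop <- if (is.null(rotation)) {
    tibble::tibble(date = weather$date, lai = 0, root_depth = 0, rsmin = 100,
                   root_shape = 3, season = NA_integer_)
  } else {
    crop_daily_state(rotation, weather$date)
  }
  pet <- pet_series(weather, site, crop$rsmin)
  ft <- 1 - exp(-opt$extinction_k * crop$lai)
  tp_pot <- pet * ft
  ep_pot <- pet - tp_pot
  rf <- matrix(0, n_day, nl)
  for (d in which(crop$root_depth > 0)) {
    rf[d, ] <- root_fractions(crop$root_depth[d], crop$root_shape[d], bounds)
  }

  w <- if (identical(opt$theta_init, "fc")) wfc else
    rep_len(opt$theta_init, nl) * th_mm
  snow <- 0; macro_store <- 0; pond <- 0

  w_out <- matrix(0, n_day, nl)
  perc <- matrix(0, n_day, nl)       # flux leaving layer i downward (mm/d)
  tr_l <- matrix(0, n_day, nl)
  ev <- numeric(n_day); tr <- numeric(n_day)
  infl <- numeric(n_day); m_in <- numeric(n_day); m_out <- numeric(n_day)
  bot_mat <- numeric(n_day); outflow <- numeric(n_day)
  closure <- numeric(n_day)
  precip <- weather$precip_mm
  if (any(!is.finite(precip)) || any(!is.finite(pet))) {
    stop("non-finite forcing (precip or PET)", call. = FALSE)
  }

  for (d in seq_len(n_day)) {
    s0 <- sum(w) + snow + macro_store + pond
    # macropore store from previous day reaches the bottom (1-day travel)
    mo <- macro_store; macro_store <- 0

    # snow partition and degree-day melt
    tm <- weather$tmean_c[d]
    if (tm < 0) { snow <- snow + precip[d]; rain <- 0 } else rain <- precip[d]
    melt <- if (tm > 0) min(snow, opt$snow_melt * tm) else 0
    snow <- snow - melt
    water_in <- rain + melt + pond; pond <- 0

    # infiltration-capacity excess -> bypass domain (or ponding if disabled);
    # the top layer may transiently exceed saturation until the drainage
    # cascade has run, after which leftover supersaturation is routed too
    excess_cap <- max(water_in - kmat[1], 0)
    inf <- water_in - excess_cap
    w[1] <- w[1] + inf

    # soil evaporation from the top layer, limited above wilting point
    ea <- min(ep_pot[d], max(w[1] - wwp[1], 0))
    w[1] <- w[1] - ea

    # transpiration over the root zone
    if (tp_pot[d] > 0 && crop$root_depth[d] > 0) {
      dem <- tp_pot[d] * rf[d, ]
      ta <- pmin(dem, pmax(w - wwp, 0))
      w <- w - ta
      tr_l[d, ] <- ta
      tr[d] <- sum(ta)
    }

    # matrix drainage cascade, top down; receivers may transiently exceed
    # saturation (they drain in turn within the same day)
    for (i in seq_len(nl)) {
      dr <- min(max(w[i] - wfc[i], 0), kmat[i])
      if (i < nl) w[i + 1] <- w[i + 1] + dr else bot_mat[d] <- dr
      w[i] <- w[i] - dr
      perc[d, i] <- dr
    }
    # saturation backup: leftover supersaturation perches upward
    for (i in rev(seq_len(nl))) {
      ex <- max(w[i] - wmax[i], 0)
      if (ex > 0) {
        w[i] <- w[i] - ex
        if (i > 1) {
          w[i - 1] <- w[i - 1] + ex
          perc[d, i - 1] <- perc[d, i - 1] - min(ex, perc[d, i - 1])
        } else {
          w[1] <- w[1] + ex  # handled as surface excess below
        }
      }
    }

    # supersaturation left in the top layer after drainage
    excess_sat <- max(w[1] - wmax[1], 0)
    w[1] <- w[1] - excess_sat
    bypass <- excess_cap + excess_sat
    if (mf_top > 0) macro_store <- macro_store + bypass else
      pond <- pond + bypass
    infl[d] <- inf - excess_sat
    m_in[d] <- if (mf_top > 0) bypass else 0

    ev[d] <- ea
    m_out[d] <- mo
    outflow[d] <- bot_mat[d] + mo
    w_out[d, ] <- w
    s1 <- sum(w) + snow + macro_store + pond
    closure[d] <- precip[d] - (s1 - s0) - ea - tr[d] - outflow[d]
  }

  structure(list(
    date = weather$date, precip = precip, pet = pet,
    evap_pot = ep_pot, transp_pot = tp_pot,
    evap_actual = ev, transp_actual = tr,
    infiltration = infl, macro_in = m_in, macro_out = m_out,
    bottom_matrix = bot_mat, bottom_outflow = outflow,
    closure = closure,
    w_mm = w_out, theta = sweep(w_out, 2, th_mm, "/"),
    perc = perc, transp_layer = tr_l,
    soil = soil, site = site, crop = crop
  ), class = "pfas_water")
}

validate_weather <- function(weather) {
  req <- c("date", "precip_mm", "tmean_c")
  miss <- setdiff(req, names(weather))
  if (length(miss)) {
    stop("weather is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- as.numeric(diff(as.Date(weather$date)))
  if (length(d) && any(d != 1)) {
    stop("weather dates must be strictly increasing with daily spacing",
         call. = FALSE)
  }
  if (any(weather$precip_mm < 0, na.rm = TRUE)) {
    stop("precip_mm must be >= 0", call. = FALSE)
  }
  invisible(weather)
}

#' @export
tidy.pfas_water <- function(x, ...) {
  tibble::tibble(
    date = x$date, precip_mm = x$precip, pet_mm = x$pet,
    evaporation_mm = x$evap_actual, transpiration_mm = x$transp_actual,
    macropore_mm = x$macro_out, bottom_outflow_mm = x$bottom_outflow
  )
}

#' @export
glance.pfas_water <- function(x, ...) {
  tibble::tibble(
    days = length(x$date),
    precip_mm = sum(x$precip),
    et_actual_mm = sum(x$evap_actual + x$transp_actual),
    outflow_mm = sum(x$bottom_outflow),
    max_abs_closure_mm = max(abs(x$closure))
  )
}

#' Aggregate a daily bottom-outflow series to monthly percolation volumes
#'
#' Calendar-month sums; with a column area of 1 m2, 1 mm of outflow equals
#' 1 litre, matching monthly leachate collection in a lysimeter.
#'
#' @param date Vector of consecutive daily dates (full calendar coverage).
#' @param outflow_mm Daily bottom outflow (mm/d).
#' @param column_area Column surface area (m2).
#' @return Tibble with `month` (first of month) and `q_l` (litres/month);
#'   months without outflow are reported as 0.
#' @export
aggregate_monthly <- function(date, outflow_mm, column_area = 1) {
  date <- as.Date(date)
  if (length(date) > 1 && any(as.numeric(diff(date)) != 1)) {
    stop("daily series has gaps; full calendar coverage required",
         call. = FALSE)
  }
  tibble::tibble(
    month = as.Date(format(date, "%Y-%m-01")),
    v = outflow_mm * column_area
  ) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(q_l = sum(.data$v), .groups = "drop")
}
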