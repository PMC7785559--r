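#' Construct one crop season
#'
#' @param name Crop name.
#' @param sowing,emergence,maturity,harvest Phenology dates (coerced with
#'   [as.Date()]); must satisfy `sowing < emergence < maturity <= harvest`.
#' @param max_root_depth Maximum rooting depth (m).
#' @param max_lai Maximum leaf-area index (dimensionless).
#' @param rsmin Minimum stomatal resistance (s/m).
#' @param root_shape Exponential root-distribution shape parameter
#'   (dimensionless); larger values concentrate roots near the surface.
#' @return A one-row tibble.
#' @export
crop_season <- function(name, sowing, emergence, maturity, harvest,
                        max_root_depth = 1.2, max_lai = 5, rsmin = 60,
                        root_shape = 3) {
  sowing <- as.Date(sowing); emergence <- as.Date(emergence)
  maturity <- as.Date(maturity); harvest <- as.Date(harvest)
  if (!(sowing < emergence && emergence < maturity && maturity <= harvest)) {
    stop("need sowing < emergence < maturity <= harvest for crop '", name,
         "'", call. = FALSE)
  }
  if (rsmin < 25 || rsmin > 100) {
    stop("rsmin must lie in [25, 100] s/m", call. = FALSE)
  }
  tibble::tibble(name = name, sowing = sowing, emergence = emergence,
                 maturity = maturity, harvest = harvest,
                 max_root_depth = max_root_depth, max_lai = max_lai,
                 rsmin = rsmin, root_shape = root_shape)
}

# genus-typical phenology offsets for central-European winter cereals/canola;
# harvest_year labels the season
crop_templates <- function() {
  list(
    `winter wheat` = list(sow = "-10-10", eme = "-11-01", mat = "-06-20",
                          har = "-08-01", rd = 1.2, lai = 5.0),
    `winter rye` = list(sow = "-09-25", eme = "-10-15", mat = "-06-15",
                        har = "-07-25", rd = 1.2, lai = 5.0),
    `winter barley` = list(sow = "-09-20", eme = "-10-10", mat = "-06-10",
                           har = "-07-15", rd = 1.0, lai = 4.5),
    canola = list(sow = "-08-25", eme = "-09-10", mat = "-06-25",
                  har = "-07-20", rd = 1.2, lai = 4.0)
  )
}

#' Nine-season crop rotation of the lysimeter experiment
#'
#' Winter wheat, winter rye, canola, winter wheat, winter barley, canola,
#' winter wheat, winter barley, winter rye, labelled by harvest year starting
#' at `start_year`. Winter crops are sown in the autumn of the preceding
#' year. The two canola seasons carry their own `rsmin`, mirroring the
#' separate stomatal-resistance parameter used for canola in calibration.
#'
#' @param start_year First harvest year (default 2007).
#' @param rsmin_crops Minimum stomatal resistance for the cereals (s/m).
#' @param rsmin_canola Minimum stomatal resistance for canola (s/m).
#' @return A tibble with one row per season (see [crop_season()]).
#' @export
default_rotation <- function(start_year = 2007, rsmin_crops = 60,
                             rsmin_canola = 60) {
  crops <- c("winter wheat", "winter rye", "canola", "winter wheat",
             "winter barley", "canola", "winter wheat", "winter barley",
             "winter rye")
  tmpl <- crop_templates()
  purrr::map2_dfr(crops, start_year + seq_along(crops) - 1, function(cr, yr) {
    tp <- tmpl[[cr]]
    crop_season(
      name = cr,
      sowing = paste0(yr - 1, tp$sow), emergence = paste0(yr - 1, tp$eme),
      maturity = paste0(yr, tp$mat), harvest = paste0(yr, tp$har),
      max_root_depth = tp$rd, max_lai = tp$lai,
      rsmin = if (cr == "canola") rsmin_canola else rsmin_crops
    )
  })
}

#' Daily crop state over a simulation period
#'
#' Linear development between fixed phenology dates: leaf-area index rises
#' from 0 at emergence to `max_lai` at maturity and stays there until
#' harvest; root depth grows from 0.05 m at emergence to `max_root_depth` at
#' maturity. Static, date-driven growth (no response to weather).
#'
#' @param rotation Tibble of crop seasons (see [default_rotation()]).
#' @param dates Vector of dates to evaluate.
#' @return Tibble with `date`, `lai`, `root_depth`, `rsmin`, `root_shape`,
#'   `season` (harvest-year label or `NA` outside any season).
#' @export
crop_daily_state <- function(rotation, dates) {
  dates <- as.Date(dates)
  lai <- numeric(length(dates)); rd <- numeric(length(dates))
  rsmin <- rep(100, length(dates)); shape <- rep(3, length(dates))
  season <- rep(NA_integer_, length(dates))
  for (i in seq_len(nrow(rotation))) {
    r <- rotation[i, ]
    idx <- dates >= r$sowing & dates <= r$harvest
    if (!any(idx)) next
    d <- as.numeric(dates[idx])
    eme <- as.numeric(r$emergence); mat <- as.numeric(r$maturity)
    frac <- pmin(pmax((d - eme) / (mat - eme), 0), 1)
    lai[idx] <- frac * r$max_lai
    rd[idx] <- ifelse(d < eme, 0, 0.05 + frac * (r$max_root_depth - 0.05))
    rsmin[idx] <- r$rsmin
    shape[idx] <- r$root_shape
    season[idx] <- as.integer(format(r$harvest, "%Y"))
  }
  tibble::tibble(date = dates, lai = lai, root_depth = rd, rsmin = rsmin,
                 root_shape = shape, season = season)
}

#' Root fraction per soil layer
#'
#' Exponential root-density profile `exp(-shape * z / root_depth)` truncated
#' at the current root depth and renormalised, integrated over each layer.
#'
#' @param root_depth Current rooting depth (m); 0 gives all-zero fractions.
#' @param shape Exponential shape parameter (> 0).
#' @param layer_bounds Vector of layer interface depths (m), length
#'   `n_layers + 1`, starting at 0.
#' @return Numeric vector of per-layer fractions summing to 1 (or all 0).
#' @export
root_fractions <- function(root_depth, shape, layer_bounds) {
  n <- length(layer_bounds) - 1
  if (root_depth <= 0) return(numeric(n))
  cdf <- function(z) {
    zz <- pmin(pmax(z / root_depth, 0), 1)
    (1 - exp(-shape * zz)) / (1 - exp(-shape))
  }
  diff(cdf(layer_bounds))
}
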