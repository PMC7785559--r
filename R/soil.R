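#' Construct a layered soil profile
#'
#' Default profile for a 1.5 m free-draining lysimeter in a medium-to-highly
#' silty soil: 15 layers of 0.1 m, organic-carbon fraction 0.015 in the upper
#' 0.3 m, decaying to 0.002 below 0.9 m.
#'
#' @param n_layers Number of layers.
#' @param thickness Layer thickness (m), scalar or per layer.
#' @param bulk_density Dry bulk density (g/cm3).
#' @param f_oc Organic-carbon mass fraction (0-1); if `NULL` the default
#'   depth profile above is used.
#' @param theta_sat,theta_fc,theta_wp Volumetric water content at saturation,
#'   field capacity and wilting point (0-1, `sat > fc > wp`).
#' @param k_matrix Maximum matrix percolation rate (mm/d).
#' @param macropore_fraction Fraction of the saturated porosity acting as
#'   preferential bypass domain (0-1); 0 disables macropore flow.
#' @return A tibble with one row per layer and columns `thickness`,
#'   `bulk_density`, `f_oc`, `theta_sat`, `theta_fc`, `theta_wp`,
#'   `k_matrix`, `macropore_fraction`.
#' @examples
#' soil_profile()
#' @export
soil_profile <- function(n_layers = 15, thickness = 0.1, bulk_density = 1.45,
                         f_oc = NULL, theta_sat = 0.45, theta_fc = 0.35,
                         theta_wp = 0.12, k_matrix = 150,
                         macropore_fraction = 0.05) {
  thickness <- rep_len(thickness, n_layers)
  depth_top <- cumsum(c(0, thickness))[seq_len(n_layers)]
  depth_mid <- depth_top + thickness / 2
  if (is.null(f_oc)) {
    # 0.015 in the plough layer, linear decline to 0.002 at 0.9 m depth
    f_oc <- ifelse(depth_mid <= 0.3, 0.015,
                   ifelse(depth_mid >= 0.9, 0.002,
                          0.015 + (depth_mid - 0.3) / 0.6 * (0.002 - 0.015)))
  }
  soil <- tibble::tibble(
    thickness = thickness,
    bulk_density = rep_len(bulk_density, n_layers),
    f_oc = rep_len(f_oc, n_layers),
    theta_sat = rep_len(theta_sat, n_layers),
    theta_fc = rep_len(theta_fc, n_layers),
    theta_wp = rep_len(theta_wp, n_layers),
    k_matrix = rep_len(k_matrix, n_layers),
    macropore_fraction = rep_len(macropore_fraction, n_layers)
  )
  validate_soil(soil)
  soil
}

validate_soil <- function(soil) {
  req <- c("thickness", "bulk_density", "f_oc", "theta_sat", "theta_fc",
           "theta_wp", "k_matrix", "macropore_fraction")
  miss <- setdiff(req, names(soil))
  if (length(miss)) {
    stop("soil profile is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  with(soil, {
    if (any(thickness <= 0)) stop("thickness must be > 0", call. = FALSE)
    if (any(bulk_density <= 0)) stop("bulk_density must be > 0", call. = FALSE)
    if (any(f_oc < 0 | f_oc > 1)) stop("f_oc must be in [0, 1]", call. = FALSE)
    if (any(!(theta_wp > 0 & theta_wp < theta_fc & theta_fc < theta_sat &
                theta_sat < 1))) {
      stop("need 0 < theta_wp < theta_fc < theta_sat < 1 in every layer",
           call. = FALSE)
    }
    if (any(k_matrix < 0)) stop("k_matrix must be >= 0", call. = FALSE)
    if (any(macropore_fraction < 0 | macropore_fraction > 1)) {
      stop("macropore_fraction must be in [0, 1]", call. = FALSE)
    }
  })
  invisible(soil)
}

#' Site parameters
#'
#' @param albedo Surface albedo (0-1).
#' @param latitude Latitude (degrees north).
#' @param column_area Lysimeter surface area (m2); with 1 m2, 1 mm of water
#'   equals 1 litre.
#' @param elevation_m Site elevation (m a.s.l.), used for atmospheric
#'   pressure and clear-sky radiation.
#' @return A list of class `pfas_site`.
#' @export
site_params <- function(albedo = 0.15, latitude = 51.3, column_area = 1,
                        elevation_m = 200) {
  if (albedo < 0 || albedo > 1) stop("albedo must be in [0, 1]", call. = FALSE)
  if (column_area <= 0) stop("column_area must be > 0", call. = FALSE)
  structure(list(albedo = albedo, latitude = latitude,
                 column_area = column_area, elevation_m = elevation_m),
            class = "pfas_site")
}
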