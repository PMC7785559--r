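#' Define a substance and its fate parameters
#'
#' @param name Substance name (e.g. `"PFOA"`).
#' @param k_foc Organic-carbon normalised Freundlich coefficient (ml/g).
#' @param n Freundlich exponent (dimensionless, > 0).
#' @param f_star Transpiration-stream concentration factor (dimensionless).
#' @param scenario Sorption concept: `"I"` = spontaneous + reversible kinetic
#'   two-site sorption; `"II"` = spontaneous reversible sorption +
#'   irreversible first-order NER formation from the adsorbed phase.
#' @param alpha_k Kinetic sorption rate (1/d, scenario I only).
#' @param f_ne Fraction of kinetic sorption sites (0-1, scenario I only).
#' @param r_ner NER formation rate (1/d, scenario II only).
#' @param dispersivity_cm Longitudinal dispersivity (cm).
#' @param diffusion_m2_d Aqueous diffusion coefficient (m2/d); effective
#'   diffusion uses a Millington-Quirk tortuosity `theta^(7/3)/theta_sat^2`.
#' @param applied_mass_g Applied mass (g) on `application_date`; the full
#'   nominal mass enters the dissolved pool of the top layer (worst-case
#'   surface spill).
#' @param application_date Application date.
#' @param purity Product purity (fraction); recorded as metadata, the
#'   nominal mass is applied.
#' @return A list of class `pfas_substance`.
#' @export
substance <- function(name, k_foc, n, f_star, scenario = c("II", "I"),
                      alpha_k = 0.01, f_ne = 0.5, r_ner = 0.005,
                      dispersivity_cm = 8, diffusion_m2_d = 4.9e-5,
                      applied_mass_g = 0,
                      application_date = as.Date("2007-03-31"),
                      purity = 1) {
  scenario <- match.arg(scenario)
  if (k_foc < 0 || n <= 0 || f_star < 0) {
    stop("k_foc >= 0, n > 0 and f_star >= 0 required", call. = FALSE)
  }
  if (alpha_k < 0 || r_ner < 0) stop("rates must be >= 0", call. = FALSE)
  if (f_ne < 0 || f_ne > 1) stop("f_ne must be in [0, 1]", call. = FALSE)
  structure(list(
    name = name, k_foc = k_foc, n = n, f_star = f_star, scenario = scenario,
    alpha_k = alpha_k, f_ne = f_ne, r_ner = r_ner,
    dispersivity_cm = dispersivity_cm, diffusion_m2_d = diffusion_m2_d,
    applied_mass_g = applied_mass_g,
    application_date = as.Date(application_date), purity = purity
  ), class = "pfas_substance")
}

# One explicit upwind advection + dispersive-exchange day with sub-stepping.
# dis: dissolved mass per layer (g); v_l: pore-water volume per layer (l);
# q_l: water flux leaving each layer downward (l/d); evol_l: interface
# dispersive exchange volumes (l/d, length nl-1). Returns updated dis and
# the mass leaving the column bottom. Mass conserved to rounding.
transport_day <- function(dis, v_l, q_l, evol_l, dt = 1, max_substeps = 24,
                          courant_max = 0.5) {
  nl <- length(dis)
  adv_frac <- max(q_l / v_l, 0)
  disp_frac <- if (nl > 1) {
    max(c(evol_l / v_l[-nl], evol_l / v_l[-1]), 0)
  } else 0
  n_sub <- ceiling(max(adv_frac * dt / courant_max,
                       disp_frac * dt / 0.4, 1))
  if (n_sub > max_substeps) {
    stop("advective Courant number too large: ", signif(adv_frac, 3),
         " would need ", n_sub, " sub-steps (cap ", max_substeps, ")",
         call. = FALSE)
  }
  dts <- dt / n_sub
  leach <- 0
  for (s in seq_len(n_sub)) {
    out <- dis * pmin(q_l * dts / v_l, 1)
    dis <- dis - out
    if (nl > 1) dis[-1] <- dis[-1] + out[-nl]
    leach <- leach + out[nl]
    if (nl > 1 && any(evol_l > 0)) {
      conc <- dis / v_l
      j <- evol_l * dts * (conc[-nl] - conc[-1])
      j <- pmin(pmax(j, -dis[-1]), dis[-nl])
      dis[-nl] <- dis[-nl] - j
      dis[-1] <- dis[-1] + j
    }
  }
  list(dissolved = dis, leached = leach)
}

#' One advection-dispersion transport step over the soil column
#'
#' Dissolved mass is advected with the matrix percolation fluxes (first-order
#' upwind), adjacent layers exchange mass by dispersion/diffusion with
#' `D = D_v |v| + D_w tau` (Millington-Quirk tortuosity `tau`), and
#' macropore-routed water carries the dissolved concentration of its source
#' (top) layer directly towards the bottom outflow. Sub-daily sub-steps keep
#' the advective Courant number below 0.5.
#'
#' @param pools List with `dissolved` (g per layer), `dissolved_macro` (g,
#'   scalar bypass store) and `leached` (g, cumulative).
#' @param fluxes List with `perc_mm` (flux leaving each layer, mm/d),
#'   `macro_in_mm` (surface water routed to the bypass domain, mm/d),
#'   `w_mm` (end-of-step layer water, mm), `theta` (volumetric content).
#' @param soil Soil profile tibble.
#' @param subst A [substance()].
#' @param dt Time step (d).
#' @param column_area Column area (m2).
#' @param max_substeps Sub-step cap (default 24).
#' @return Updated `pools`.
#' @export
transport_step <- function(pools, fluxes, soil, subst, dt = 1,
                           column_area = 1, max_substeps = 24) {
  nl <- nrow(soil)
  v_l <- fluxes$w_mm * column_area
  q_l <- fluxes$perc_mm * column_area
  # bypass pickup from the top layer at its current concentration
  if (fluxes$macro_in_mm > 0) {
    pick <- min(fluxes$macro_in_mm * column_area * pools$dissolved[1] / v_l[1],
                pools$dissolved[1])
    pools$dissolved[1] <- pools$dissolved[1] - pick
    pools$dissolved_macro <- pools$dissolved_macro + pick
  }
  evol_l <- interface_exchange(fluxes, soil, subst, column_area)
  tr <- transport_day(pools$dissolved, v_l, q_l, evol_l, dt = dt,
                      max_substeps = max_substeps)
  pools$dissolved <- tr$dissolved
  pools$leached <- pools$leached + tr$leached
  pools
}

# dispersive/diffusive exchange volumes (l/d) at the nl-1 interior interfaces
interface_exchange <- function(fluxes, soil, subst, column_area) {
  nl <- nrow(soil)
  if (nl < 2) return(numeric(0))
  theta_int <- (fluxes$theta[-nl] + fluxes$theta[-1]) / 2
  ts_int <- (soil$theta_sat[-nl] + soil$theta_sat[-1]) / 2
  dz_int <- (soil$thickness[-nl] + soil$thickness[-1]) / 2
  v_m_d <- (fluxes$perc_mm[-nl] / 1000) / pmax(theta_int, 1e-6)
  tau <- theta_int^(7 / 3) / ts_int^2
  d_m2 <- subst$dispersivity_cm / 100 * abs(v_m_d) +
    subst$diffusion_m2_d * tau
  d_m2 * theta_int * column_area / dz_int * 1000
}

#' One plant-uptake step via the transpiration stream
#'
#' Passive uptake: per layer the extracted mass is
#' `f_star * c_soil * transpired volume`, capped at the available dissolved
#' mass, removed from the matrix dissolved pool and accumulated in the
#' plant-uptake sink.
#'
#' @param pools List with `dissolved` (g per layer) and `plant_uptake` (g).
#' @param transpiration_by_layer Transpired water per layer (mm/d).
#' @param w_mm End-of-step layer water (mm).
#' @param f_star Transpiration-stream concentration factor.
#' @param dt Time step (d).
#' @param column_area Column area (m2).
#' @return Updated `pools` plus element `uptake_step` (g this step).
#' @export
plant_uptake_step <- function(pools, transpiration_by_layer, w_mm, f_star,
                              dt = 1, column_area = 1) {
  stopifnot(f_star >= 0)
  v_l <- w_mm * column_area
  upt <- pmin(f_star * (pools$dissolved / v_l) *
                transpiration_by_layer * column_area * dt,
              pools$dissolved)
  pools$dissolved <- pools$dissolved - upt
  pools$plant_uptake <- pools$plant_uptake + sum(upt)
  pools$uptake_step <- sum(upt)
  pools
}
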