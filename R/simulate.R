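#' Simulate water flow, solute fate and plant uptake in a soil column
#'
#' Runs the daily operator-split pipeline for every substance in the
#' configuration: water balance, then per substance equilibrium Freundlich
#' partition, scenario kinetics (two-site kinetic sorption in scenario I,
#' irreversible NER formation in scenario II), advection-dispersion transport
#' with macropore bypass, and transpiration-stream plant uptake. The applied
#' mass enters the dissolved pool of the top layer on the application date.
#'
#' Monthly leachate concentrations are flux-averaged (leached mass over
#' percolated volume) for months with outflow; for months without outflow
#' the pore-water concentration of the lowest layer is available in the
#' daily output instead.
#'
#' @param config A configuration list (see [load_config()] or
#'   [default_config()]) with elements `weather`, `soil`, `rotation`,
#'   `site`, `substances`, `options`.
#' @param water Optionally a precomputed [run_water_balance()] result for the
#'   same weather/soil/site, reused unchanged (the water balance is
#'   independent of substance parameters).
#' @return An object of class `pfas_sim`; see [mass_balance()], [tidy()],
#'   [glance()], [autoplot()].
#' @export
simulate_column <- function(config, water = NULL) {
  config <- as_config(config)
  if (is.null(water)) {
    water <- run_water_balance(config$weather, config$soil, config$rotation,
                               config$site, config$options)
  }
  opts <- modifyList(list(max_substeps = 24, courant_max = 0.5),
                     config$options)
  monthly_q <- aggregate_monthly(water$date, water$bottom_outflow,
                                 config$site$column_area)
  month_of_day <- as.Date(format(water$date, "%Y-%m-01"))
  res <- lapply(config$substances, function(su) {
    simulate_substance(su, water, config$soil, config$site, opts,
                       monthly_q = monthly_q, month_of_day = month_of_day)
  })
  names(res) <- vapply(config$substances, `[[`, "", "name")
  structure(list(
    water = water, substances = res, monthly_q = monthly_q,
    site = config$site, soil = config$soil, rotation = config$rotation
  ), class = "pfas_sim")
}

simulate_substance <- function(su, water, soil, site, opts,
                               monthly_q = NULL, month_of_day = NULL) {
  if (is.null(monthly_q)) {
    monthly_q <- aggregate_monthly(water$date, water$bottom_outflow,
                                   site$column_area)
  }
  if (is.null(month_of_day)) {
    month_of_day <- as.Date(format(water$date, "%Y-%m-01"))
  }
  nl <- nrow(soil)
  n_day <- length(water$date)
  area <- site$column_area
  ms_kg <- soil$bulk_density * 1000 * soil$thickness * area
  kf <- su$k_foc * soil$f_oc
  sc1 <- su$scenario == "I"
  kf_eq <- if (sc1) (1 - su$f_ne) * kf else kf
  r_ner <- if (su$scenario == "II") su$r_ner else 0
  ner_frac <- 1 - exp(-r_ner)

  w_mm_mat <- water$w_mm; perc_mat <- water$perc
  theta_mat <- water$theta; tr_mat <- water$transp_layer
  macro_in_vec <- water$macro_in

  dis <- numeric(nl); seq_ <- numeric(nl); skin <- numeric(nl)
  ner <- numeric(nl)
  macro_sol <- 0; leached <- 0; uptake <- 0
  app_idx <- which(water$date == su$application_date)
  applied_so_far <- 0

  leach_day <- numeric(n_day); upt_day <- numeric(n_day)
  c_bot <- numeric(n_day)
  p_dis <- numeric(n_day); p_seq <- numeric(n_day)
  p_skin <- numeric(n_day); p_ner <- numeric(n_day); p_mac <- numeric(n_day)
  max_rel_err <- 0

  # per-interface constants for the dispersive exchange
  if (nl > 1) {
    ts_int <- (soil$theta_sat[-nl] + soil$theta_sat[-1]) / 2
    dz_int <- (soil$thickness[-nl] + soil$thickness[-1]) / 2
    dv_m <- su$dispersivity_cm / 100
  }

  for (d in seq_len(n_day)) {
    # bypass store from the previous day reaches the outflow
    lm <- macro_sol; macro_sol <- 0; leached <- leached + lm
    if (length(app_idx) && d == app_idx) {
      dis[1] <- dis[1] + su$applied_mass_g
      applied_so_far <- applied_so_far + su$applied_mass_g
    }
    if (applied_so_far == 0) { c_bot[d] <- 0; next }

    v_l <- w_mm_mat[d, ] * area

    # instantaneous equilibrium partition of the reversible pool
    m_rev <- dis + seq_
    c_mg <- freundlich_solve(m_rev * 1000, v_l, ms_kg, kf_eq, su$n)
    dis <- c_mg * v_l / 1000
    seq_ <- m_rev - dis

    if (sc1 && su$alpha_k > 0 && su$f_ne > 0) {
      target <- ms_kg * su$f_ne * kf * c_mg^su$n / 1000
      rate <- su$alpha_k / su$f_ne
      tfr <- (skin + rate * target) / (1 + rate) - skin
      tfr <- pmax(pmin(tfr, dis), -skin)
      skin <- skin + tfr
      dis <- dis - tfr
    } else if (!sc1 && r_ner > 0) {
      tf <- seq_ * ner_frac
      seq_ <- seq_ - tf
      ner <- ner + tf
    }

    # macropore pickup at the source (top) layer
    mi <- macro_in_vec[d]
    if (mi > 0) {
      pick <- min(mi * area * dis[1] / v_l[1], dis[1])
      dis[1] <- dis[1] - pick
      macro_sol <- macro_sol + pick
    }

    # matrix advection-dispersion
    q_l <- perc_mat[d, ] * area
    if (nl > 1) {
      th_int <- (theta_mat[d, -nl] + theta_mat[d, -1]) / 2
      v_m_d <- (perc_mat[d, -nl] / 1000) / pmax(th_int, 1e-6)
      tau <- th_int^(7 / 3) / ts_int^2
      evol <- (dv_m * v_m_d + su$diffusion_m2_d * tau) *
        th_int * area / dz_int * 1000
    } else evol <- numeric(0)
    tr <- transport_day(dis, v_l, q_l, evol, dt = 1,
                        max_substeps = opts$max_substeps,
                        courant_max = opts$courant_max)
    dis <- tr$dissolved
    leached <- leached + tr$leached

    # transpiration-stream uptake
    tl <- tr_mat[d, ]
    if (su$f_star > 0 && any(tl > 0)) {
      upt <- pmin(su$f_star * (dis / v_l) * tl * area, dis)
      dis <- dis - upt
      upt_day[d] <- sum(upt)
      uptake <- uptake + upt_day[d]
    }

    leach_day[d] <- lm + tr$leached
    c_bot[d] <- dis[nl] / v_l[nl] * 1e6
    p_dis[d] <- sum(dis); p_seq[d] <- sum(seq_)
    p_skin[d] <- sum(skin); p_ner[d] <- sum(ner); p_mac[d] <- macro_sol

    tot <- p_dis[d] + p_seq[d] + p_skin[d] + p_ner[d] + macro_sol +
      leached + uptake
    max_rel_err <- max(max_rel_err,
                       abs(tot - applied_so_far) / applied_so_far)
  }

  daily <- tibble::tibble(
    date = water$date, leached_g = leach_day, uptake_g = upt_day,
    bottom_c_ugl = c_bot, dissolved_g = p_dis, sorbed_eq_g = p_seq,
    sorbed_kin_g = p_skin, ner_g = p_ner, macro_g = p_mac
  )
  leach_m <- rowsum(leach_day, month_of_day)
  monthly <- monthly_q
  monthly$leached_g <- as.numeric(leach_m)[match(monthly$month,
                                                 as.Date(rownames(leach_m)))]
  monthly$c_ugl <- ifelse(monthly$q_l > 0,
                          monthly$leached_g / monthly$q_l * 1e6, NA_real_)
  season_day <- water$crop$season
  in_season <- !is.na(season_day)
  upt_s <- rowsum(upt_day[in_season], season_day[in_season])
  seasonal <- tibble::tibble(season = as.integer(rownames(upt_s)),
                             uptake_g = as.numeric(upt_s))

  list(
    substance = su, daily = daily, monthly = monthly, seasonal = seasonal,
    final = list(dissolved = sum(dis) + macro_sol, sorbed_eq = sum(seq_),
                 sorbed_kin = sum(skin), ner = sum(ner),
                 leached = leached, plant_uptake = uptake,
                 applied = applied_so_far),
    max_rel_mass_error = max_rel_err
  )
}

#' Substance balance of a finished simulation
#'
#' Pool accounting at the end of the simulation: leached mass, cumulative
#' plant uptake, NER pool, reversible sorption pool (equilibrium + kinetic
#' sites) and dissolved mass, each in grams and as percent of the applied
#' mass. Percentages sum to 100.
#'
#' @param sim A `pfas_sim` from [simulate_column()].
#' @return Tibble with `substance`, `pool`, `mass_g`, `pct_applied`.
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "pfas_sim"))
  purrr::imap_dfr(sim$substances, function(r, nm) {
    f <- r$final
    mass_balance_table(
      c(leached = f$leached, plant_uptake = f$plant_uptake, ner = f$ner,
        reversible_sorbed = f$sorbed_eq + f$sorbed_kin,
        dissolved = f$dissolved),
      applied_g = f$applied
    ) |>
      dplyr::mutate(substance = nm, .before = 1)
  })
}

#' Pool masses as percent of an applied mass
#'
#' @param pools_g Named numeric vector of pool masses (g).
#' @param applied_g Applied mass (g), > 0.
#' @return Tibble with `pool`, `mass_g`, `pct_applied`.
#' @examples
#' mass_balance_table(c(leached = 13.9), 360) # sampled PFOA leaching
#' @export
mass_balance_table <- function(pools_g, applied_g) {
  stopifnot(applied_g > 0, all(pools_g >= 0))
  tibble::tibble(
    pool = names(pools_g),
    mass_g = unname(pools_g),
    pct_applied = unname(pools_g) / applied_g * 100
  )
}

#' @export
tidy.pfas_sim <- function(x, ...) {
  purrr::imap_dfr(x$substances, function(r, nm) {
    r$daily |>
      tidyr::pivot_longer(-"date", names_to = "variable") |>
      dplyr::mutate(substance = nm, .before = 1)
  })
}

#' @export
glance.pfas_sim <- function(x, ...) {
  purrr::imap_dfr(x$substances, function(r, nm) {
    f <- r$final
    tibble::tibble(
      substance = nm, applied_g = f$applied,
      leached_pct = f$leached / f$applied * 100,
      uptake_pct = f$plant_uptake / f$applied * 100,
      ner_pct = f$ner / f$applied * 100,
      max_rel_mass_error = r$max_rel_mass_error,
      max_abs_water_closure_mm = max(abs(x$water$closure))
    )
  })
}

#' @export
print.pfas_sim <- function(x, ...) {
  cat("<pfas_sim>", length(x$water$date), "days,",
      nrow(x$soil), "layers,", length(x$substances), "substance(s)\n")
  print(glance(x))
  invisible(x)
}

#' Diagnostic plot of a column simulation
#'
#' @param object A `pfas_sim`.
#' @param type `"concentration"` (monthly leachate concentration and
#'   bottom-layer pore water), `"percolation"` (monthly outflow) or
#'   `"pools"` (daily pool masses).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfas_sim <- function(object, type = c("concentration",
                                               "percolation", "pools"), ...) {
  type <- match.arg(type)
  if (type == "percolation") {
    return(ggplot2::ggplot(object$monthly_q,
                           ggplot2::aes(.data$month, .data$q_l)) +
             ggplot2::geom_col() +
             ggplot2::labs(x = NULL, y = "percolation (l/month)"))
  }
  if (type == "pools") {
    dat <- tidy(object) |>
      dplyr::filter(.data$variable %in% c("dissolved_g", "sorbed_eq_g",
                                          "sorbed_kin_g", "ner_g"))
    return(ggplot2::ggplot(dat, ggplot2::aes(.data$date, .data$value,
                                             colour = .data$variable)) +
             ggplot2::geom_line() +
             ggplot2::facet_wrap(~substance) +
             ggplot2::labs(x = NULL, y = "mass (g)", colour = "pool"))
  }
  dat <- purrr::imap_dfr(object$substances, function(r, nm) {
    dplyr::mutate(r$monthly, substance = nm)
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$month, .data$c_ugl)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::facet_wrap(~substance, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "leachate concentration (\u00b5g/l)")
}
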