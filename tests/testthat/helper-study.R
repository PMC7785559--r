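# Shared fixtures, built in code.

# Small column for fast unit tests of flow and transport.
tiny_soil <- function(n_layers = 4, k_matrix = 150,
                      macropore_fraction = 0.05, f_oc = 0.004) {
  soil_profile(n_layers = n_layers, thickness = 0.1, f_oc = f_oc,
               k_matrix = k_matrix, macropore_fraction = macropore_fraction)
}

# Deterministic bare-soil weather: constant rain and temperature, full
# radiation/humidity/wind columns so the Penman-Monteith branch is used.
flat_weather <- function(n_days, precip = 0, tmean = 12, rad = 12,
                         rh = 75, wind = 2, start = "2007-01-01") {
  dates <- seq(as.Date(start), by = "day", length.out = n_days)
  tibble::tibble(date = dates, precip_mm = precip, tmean_c = tmean,
                 tmin_c = tmean - 4, tmax_c = tmean + 4,
                 rad_mj_m2 = rad, rh_pct = rh, wind_ms = wind)
}

# Desk-scale synthetic study used by the calibration experiments: a wetter
# climate and a short 0.4 m column chosen so both substances break through
# within a five-year window.
scaled_config <- function(weather_seed = 7, years = 5, scenario = "II",
                          k_foc_pfoa = 40, k_foc_pfos = 300) {
  cfg <- list(
    site = site_params(albedo = 0.11, latitude = 51.3, column_area = 1),
    soil = soil_profile(n_layers = 4, thickness = 0.1, f_oc = 0.003),
    rotation = default_rotation(2007, rsmin_crops = 57, rsmin_canola = 44),
    substances = list(
      substance("PFOA", k_foc = k_foc_pfoa, n = 0.88, f_star = 1.1e-5,
                scenario = scenario, r_ner = 0.0047, alpha_k = 0.01,
                f_ne = 0.5, dispersivity_cm = 8, applied_mass_g = 360,
                application_date = "2007-03-31"),
      substance("PFOS", k_foc = k_foc_pfos, n = 0.75, f_star = 9.6e-5,
                scenario = scenario, r_ner = 0.0013, alpha_k = 0.01,
                f_ne = 0.5, dispersivity_cm = 8, applied_mass_g = 367.5,
                application_date = "2007-03-31")
    ),
    weather = generate_weather(climate_spec(annual_precip_mm = 900),
                               start = "2006-01-01", years = years,
                               seed = weather_seed),
    options = list()
  )
  class(cfg) <- "pfas_config"
  cfg
}

# Prior ranges of the recovered PFOA triplet (other parameters fixed at
# their truth values in the scaled experiments).
recovery_space <- function() {
  param_space(
    name = c("PFOA.k_foc", "PFOA.r_ner", "PFOA.f_star"),
    lower = c(22, 0.001, 1e-6), upper = c(332, 0.014, 1e-3),
    transform = c("linear", "linear", "log10")
  )
}

# Scenario I counterpart: reversible two-site kinetics instead of NER.
kinetic_space <- function() {
  param_space(
    name = c("PFOA.k_foc", "PFOA.alpha_k", "PFOA.f_ne", "PFOA.f_star"),
    lower = c(22, 1e-4, 0, 1e-6), upper = c(332, 0.1, 1, 1e-3),
    transform = c("linear", "linear", "linear", "log10")
  )
}

# One parameter-recovery replicate: noisy synthetic study, two-stage
# behavioural calibration of the PFOA triplet, truth-containment check on
# the behavioural min-max range.
recovery_replicate <- function(k) {
  cfg <- scaled_config(weather_seed = 100 + k, years = 4)
  st <- generate_study(cfg, noise_spec(), seed = 200 + k)
  obj <- make_kge_objective(cfg, st$observations, recovery_space())
  ens <- two_stage_calibrate(
    recovery_space(), list(score = obj$score, predict = NULL),
    stage1 = list(n_chains = 4, n_particles = 8, max_sims_per_chain = 40),
    stage2 = list(n_chains = 3, n_particles = 6, max_sims_per_chain = 36),
    thresholds = c(0.15, 0.45), seed = 300 + k
  )
  truth <- c(40, 0.0047, 1.1e-5)
  pt <- ens$posterior
  all(pt$min <= truth & truth <= pt$max)
}

# One scenario-discrimination replicate: data generated under the NER
# concept (scenario II), both sorption concepts fitted with equal budgets;
# returns TRUE when scenario II attains the better best score.
discrimination_replicate <- function(k) {
  cfg <- scaled_config(weather_seed = 400 + k, years = 6, k_foc_pfoa = 150)
  cfg$substances <- cfg$substances[1]
  st <- generate_study(cfg, noise_spec(), seed = 500 + k)
  cfg_i <- cfg
  cfg_i$substances[[1]]$scenario <- "I"
  obj_ii <- make_kge_objective(cfg, st$observations, recovery_space())
  obj_i <- make_kge_objective(cfg_i, st$observations, kinetic_space())
  best_ii <- max(pso_stage(recovery_space(), obj_ii$score, n_chains = 2,
                           n_particles = 8, max_sims_per_chain = 48,
                           seed = 600 + k)$score)
  best_i <- max(pso_stage(kinetic_space(), obj_i$score, n_chains = 2,
                          n_particles = 8, max_sims_per_chain = 48,
                          seed = 700 + k)$score)
  best_ii > best_i
}

# Memoised full-scale posterior-median run shared by several tests.
full_scale_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- default_config(years = 10, weather_seed = 42)
      memo <<- simulate_column(cfg)
    }
    memo
  }
})
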