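#' Default study configuration
#'
#' The packaged reference setup: a 1.5 m free-draining lysimeter column
#' (15 x 0.1 m layers, silty defaults), the nine-season winter-cereal/canola
#' rotation harvested 2007-2015, synthetic central-German weather starting
#' 2006-01-01 (one full pre-application year serves as model warm-up), and
#' PFOA/PFOS applied as a one-time surface spill of 360 g and 367.5 g on
#' 1 m2 on 2007-03-31. Substance parameters default to the behavioural
#' posterior medians of the NER scenario (PFOA: r_NER 0.0047 1/d, n 0.88,
#' K_fOC 72 ml/g, f_star 1.1e-5; PFOS: 0.0013, 0.75, 510, 9.6e-5;
#' dispersivity 12 cm, albedo 0.11, stomatal resistances 57/44 s/m).
#'
#' @param years Weather years to generate (default 10: 2006-2015).
#' @param weather_seed Seed for the synthetic weather.
#' @param scenario Sorption scenario for both substances.
#' @param climate A [climate_spec()].
#' @return Configuration list of class `pfas_config`.
#' @export
default_config <- function(years = 10, weather_seed = 42,
                           scenario = "II", climate = climate_spec()) {
  cfg <- list(
    site = site_params(albedo = 0.11, latitude = 51.3, column_area = 1),
    soil = soil_profile(),
    rotation = default_rotation(2007, rsmin_crops = 57, rsmin_canola = 44),
    substances = list(
      substance("PFOA", k_foc = 72, n = 0.88, f_star = 1.1e-5,
                scenario = scenario, r_ner = 0.0047, alpha_k = 0.01,
                f_ne = 0.5, dispersivity_cm = 12, applied_mass_g = 360,
                application_date = "2007-03-31", purity = 0.96),
      substance("PFOS", k_foc = 510, n = 0.75, f_star = 9.6e-5,
                scenario = scenario, r_ner = 0.0013, alpha_k = 0.01,
                f_ne = 0.5, dispersivity_cm = 12, applied_mass_g = 367.5,
                application_date = "2007-03-31", purity = 0.98)
    ),
    weather = generate_weather(climate, start = "2006-01-01", years = years,
                               seed = weather_seed),
    options = list()
  )
  class(cfg) <- "pfas_config"
  cfg
}

as_config <- function(x) {
  if (inherits(x, "pfas_config")) return(x)
  req <- c("weather", "soil", "site", "substances")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("configuration is missing element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$rotation)) x$rotation <- NULL
  if (is.null(x$options)) x$options <- list()
  if (inherits(x$substances, "pfas_substance")) {
    x$substances <- list(x$substances)
  }
  class(x) <- "pfas_config"
  x
}

#' Load a run configuration from a YAML file
#'
#' Every section is optional except `substances`; defaults fill the rest
#' (and are reported via message when `verbose`). Validation errors name
#' the offending field. Weather comes either from `weather: file:` (a CSV
#' with columns `date`, `precip_mm`, `tmean_c`, optional `tmin_c`,
#' `tmax_c`, `rad_mj_m2`, `rh_pct`, `wind_ms`) or from
#' `weather: synthetic:` (fields `start`, `years`, `seed`, plus any
#' [climate_spec()] argument).
#'
#' @param path Path to the YAML configuration.
#' @param verbose Report filled defaults.
#' @return A `pfas_config`.
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  note <- function(...) if (verbose) message(...)

  site <- do.call(site_params, y$site %||% list())
  if (is.null(y$site)) note("site: using defaults")

  soil <- if (is.null(y$soil)) {
    note("soil: using default silty 15 x 0.1 m profile")
    soil_profile()
  } else if (!is.null(y$soil$layers)) {
    s <- dplyr::bind_rows(lapply(y$soil$layers, tibble::as_tibble))
    validate_soil(s)
    s
  } else {
    do.call(soil_profile, y$soil)
  }

  rotation <- if (is.null(y$rotation)) {
    note("rotation: using default nine-season rotation from 2007")
    default_rotation()
  } else if (!is.null(y$rotation$seasons)) {
    dplyr::bind_rows(lapply(y$rotation$seasons,
                            function(s) do.call(crop_season, s)))
  } else {
    do.call(default_rotation, y$rotation)
  }

  if (is.null(y$substances)) {
    stop("config must define at least one substance", call. = FALSE)
  }
  substances <- lapply(y$substances, function(s) {
    # YAML 1.1 parses a bare `n:` key as logical; accept `freundlich_n`
    names(s)[names(s) == "FALSE"] <- "n"
    if (!is.null(s$freundlich_n)) {
      s$n <- s$freundlich_n
      s$freundlich_n <- NULL
    }
    do.call(substance, s)
  })

  weather <- if (!is.null(y$weather$file)) {
    wpath <- y$weather$file
    if (!file.exists(wpath)) {
      wpath2 <- file.path(dirname(path), wpath)
      if (!file.exists(wpath2)) {
        stop("weather file not found: ", wpath, call. = FALSE)
      }
      wpath <- wpath2
    }
    read_weather_csv(wpath)
  } else {
    sy <- y$weather$synthetic %||% list()
    note("weather: generating synthetic series")
    spec_args <- sy[setdiff(names(sy), c("start", "years", "seed"))]
    generate_weather(do.call(climate_spec, spec_args),
                     start = sy$start %||% "2006-01-01",
                     years = sy$years %||% 10, seed = sy$seed %||% 42)
  }
  validate_weather(weather)

  cfg <- list(site = site, soil = soil, rotation = rotation,
              substances = substances, weather = weather,
              options = y$options %||% list(),
              seed = y$seed %||% 1L,
              observations = y$observations,
              calibration = y$calibration,
              output_dir = y$output_dir %||% "pfleach-output",
              source_yaml = y)
  class(cfg) <- "pfas_config"
  cfg
}

#' Read a weather CSV
#'
#' @param path CSV with header `date, precip_mm, tmean_c` and optional
#'   `tmin_c`, `tmax_c`, `rad_mj_m2`, `rh_pct`, `wind_ms`; ISO-8601 dates,
#'   decimal points.
#' @return Weather tibble.
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  w$date <- as.Date(w$date)
  validate_weather(w)
  w
}

#' Save a configuration back to YAML
#'
#' Writes the YAML representation the file-based round trip preserves
#' (configurations loaded with [load_config()] keep their source YAML).
#'
#' @param config A `pfas_config` from [load_config()].
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  if (is.null(config$source_yaml)) {
    stop("only configurations loaded from YAML can be saved", call. = FALSE)
  }
  yaml::write_yaml(config$source_yaml, path)
  invisible(path)
}

#' Run the simulation/calibration pipeline and write its artifacts
#'
#' @param config A `pfas_config` (or path to a YAML config).
#' @param command `"simulate"` (daily/monthly output CSVs and the
#'   mass-balance table), `"calibrate"` (requires `observations: file:` in
#'   the config; writes ensemble, envelope and posterior CSVs) or
#'   `"synth"` (writes synthetic weather and noisy observations).
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `output_dir`.
#' @return Invisibly, the paths written.
#' @export
run_pipeline <- function(config, command = c("simulate", "calibrate",
                                             "synth"), out_dir = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- load_config(config)
  config <- as_config(config)
  out_dir <- out_dir %||% config$output_dir %||% "pfleach-output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    paths <<- c(paths, p)
  }

  if (command == "simulate") {
    sim <- simulate_column(config)
    wr(tidy(sim), "daily_solute.csv")
    wr(tidy(sim$water), "daily_water.csv")
    wr(purrr::imap_dfr(sim$substances,
                       ~dplyr::mutate(.x$monthly, substance = .y)),
       "monthly.csv")
    wr(mass_balance(sim), "mass_balance.csv")
  } else if (command == "synth") {
    st <- generate_study(config, noise_spec(), seed = config$seed %||% 1L)
    wr(config$weather, "weather.csv")
    wr(st$observations, "observations.csv")
    yaml::write_yaml(list(seed = st$truth$seed,
                          substances = lapply(config$substances,
                                              function(s) s[
                                                c("name", "k_foc", "n",
                                                  "f_star", "scenario",
                                                  "r_ner", "alpha_k",
                                                  "f_ne")])),
                     file.path(out_dir, "truth.yaml"))
    paths <- c(paths, file.path(out_dir, "truth.yaml"))
  } else {
    if (is.null(config$observations$file)) {
      stop("calibrate requires `observations: file:` in the config",
           call. = FALSE)
    }
    obs <- readr::read_csv(config$observations$file, show_col_types = FALSE)
    cal <- config$calibration %||% list()
    scen <- config$substances[[1]]$scenario
    space <- default_param_space(
      vapply(config$substances, `[[`, "", "name"), scenario = scen,
      include_site = !isFALSE(cal$include_site)
    )
    objective <- make_kge_objective(config, obs, space)
    ens <- two_stage_calibrate(
      space, objective,
      stage1 = cal$stage1 %||% list(),
      stage2 = cal$stage2 %||% list(),
      thresholds = unlist(cal$thresholds %||% c(0.6, 0.75)),
      seed = config$seed %||% 1L
    )
    wr(ens$behavioural, "ensemble.csv")
    wr(ens$posterior, "posterior.csv")
    if (!is.null(ens$envelopes)) wr(ens$envelopes, "envelopes.csv")
  }
  log_lines <- c(
    paste("command:", command),
    paste("seed:", config$seed %||% NA),
    paste("pfleach version:",
          as.character(utils::packageVersion("pfleach"))),
    paste("R version:", R.version.string),
    paste("runtime_s:",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(c(paths, file.path(out_dir, "run.log")))
}
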