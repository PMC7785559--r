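test_that("weather generation is deterministic for a fixed seed", {
  w1 <- generate_weather(years = 2, seed = 99)
  w2 <- generate_weather(years = 2, seed = 99)
  expect_identical(w1, w2)
  w3 <- generate_weather(years = 2, seed = 100)
  expect_false(isTRUE(all.equal(w1$precip_mm, w3$precip_mm)))
})

test_that("long-run precipitation statistics match the specification", {
  spec <- climate_spec()
  w <- generate_weather(spec, start = "2000-01-01", years = 1000, seed = 123)
  yr <- format(w$date, "%Y")
  annual <- tapply(w$precip_mm, yr, sum)
  expect_equal(mean(annual), spec$annual_precip_mm, tolerance = 0.02)
  # wet-day frequency matches the Markov stationary probability per season
  pi_wet <- pfleach:::markov_stationary_wet(spec)
  seas <- pfleach:::season_of_month(as.integer(format(w$date, "%m")))
  wet_frac <- tapply(w$precip_mm > 0, seas, mean)
  expect_equal(as.numeric(wet_frac), unname(pi_wet), tolerance = 0.01)
  # temperature climatology near 9 degC
  expect_equal(mean(w$tmean_c), spec$t_mean_c, tolerance = 0.05)
})

test_that("default rotation matches the nine-season sequence", {
  rot <- default_rotation(2007)
  expect_equal(nrow(rot), 9)
  expect_equal(rot$name[c(3, 6)], c("canola", "canola"))
  expect_equal(rot$name[1], "winter wheat")
  expect_equal(rot$name[9], "winter rye")
  expect_equal(as.integer(format(rot$harvest, "%Y")), 2007:2015)
  # every harvest precedes the next sowing
  expect_true(all(rot$harvest[-9] < rot$sowing[-1]))
  expect_true(all(rot$sowing < rot$emergence & rot$emergence < rot$maturity &
                    rot$maturity <= rot$harvest))
  # canola carries its own stomatal resistance
  rot2 <- default_rotation(2007, rsmin_crops = 80, rsmin_canola = 30)
  expect_equal(unique(rot2$rsmin[rot2$name == "canola"]), 30)
  expect_equal(unique(rot2$rsmin[rot2$name != "canola"]), 80)
})

test_that("crop state interpolates phenology and root fractions normalise", {
  rot <- default_rotation(2007)
  cs <- crop_daily_state(rot, seq(as.Date("2007-01-01"),
                                  as.Date("2007-12-31"), by = "day"))
  expect_equal(max(cs$lai), 5)  # winter wheat max LAI at maturity
  expect_equal(cs$lai[cs$date == as.Date("2007-08-15")], 0)  # after harvest
  expect_true(all(cs$lai >= 0 & cs$root_depth >= 0))
  rf <- root_fractions(0.5, 3, seq(0, 1.5, by = 0.1))
  expect_equal(sum(rf), 1)
  expect_true(all(diff(rf[1:5]) < 0))  # density declines with depth
  expect_equal(sum(rf[6:15]), 0)      # no roots below root depth
  expect_equal(root_fractions(0, 3, seq(0, 1.5, by = 0.1)), rep(0, 15))
})

test_that("noise-free study reproduces the truth simulation exactly", {
  cfg <- scaled_config(weather_seed = 5, years = 3)
  st <- generate_study(cfg, noise_spec(cv_q = 0, cv_c = 0, cv_u = 0,
                                       detection_limit_ugl = 0), seed = 4)
  sc <- score_simulation(st$sim, st$observations)
  expect_equal(sc$kge_all, 1, tolerance = 1e-12)
  expect_true(all(abs(sc$targets$kge - 1) < 1e-9))
})

test_that("multiplicative observation noise has the stated spread", {
  cfg <- scaled_config(weather_seed = 5, years = 5)
  st0 <- generate_study(cfg, noise_spec(cv_q = 0, cv_c = 0, cv_u = 0,
                                        detection_limit_ugl = 0), seed = 1)
  st <- generate_study(cfg, noise_spec(cv_q = 0, cv_c = 0.2, cv_u = 0,
                                       detection_limit_ugl = 0), seed = 1)
  ratio <- dplyr::inner_join(
    dplyr::filter(st$observations, grepl("^C_", .data$variable)),
    dplyr::filter(st0$observations, grepl("^C_", .data$variable)),
    by = c("date", "variable")
  )
  pos <- ratio$value.y > 0
  r <- ratio$value.x[pos] / ratio$value.y[pos]
  expect_gte(length(r), 40)
  expect_gt(sd(r) / mean(r), 0.13)
  expect_lt(sd(r) / mean(r), 0.27)
  # Q and U are untouched at zero CV
  q1 <- dplyr::filter(st$observations, .data$variable == "Q")
  q0 <- dplyr::filter(st0$observations, .data$variable == "Q")
  expect_equal(q1$value, q0$value)
})

test_that("detection limit censors concentrations to missing", {
  cfg <- scaled_config(weather_seed = 5, years = 3)
  st <- generate_study(cfg, noise_spec(cv_q = 0, cv_c = 0, cv_u = 0,
                                       detection_limit_ugl = 1e12), seed = 1)
  expect_false(any(grepl("^C_", st$observations$variable)))
  expect_true(any(st$observations$variable == "Q"))
  expect_true(any(grepl("^U_", st$observations$variable)))
})
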