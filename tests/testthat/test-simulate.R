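test_that("solute mass closes to 1e-6 relative and NER never decreases", {
  cfg <- scaled_config(weather_seed = 5, years = 4)
  sim <- simulate_column(cfg)
  g <- glance(sim)
  expect_true(all(g$max_rel_mass_error < 1e-6))
  expect_lt(g$max_abs_water_closure_mm[1], 1e-9)
  for (r in sim$substances) {
    expect_true(all(diff(r$daily$ner_g) >= -1e-12))
    expect_true(all(r$daily$dissolved_g >= 0))
    # balance percentages account for everything applied
    }
  mb <- mass_balance(sim)
  sums <- tapply(mb$pct_applied, mb$substance, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-4)
})

test_that("zero applied mass produces zero concentrations and uptake", {
  cfg <- scaled_config(weather_seed = 5, years = 2)
  cfg$substances <- list(substance("PFOA", k_foc = 40, n = 0.88,
                                   f_star = 1e-5, applied_mass_g = 0))
  sim <- simulate_column(cfg)
  d <- sim$substances$PFOA$daily
  expect_true(all(d$bottom_c_ugl == 0))
  expect_true(all(d$uptake_g == 0))
  expect_equal(sim$substances$PFOA$final$leached, 0)
})

test_that("stronger sorption delays and reduces first-year leaching,
           faster NER formation reduces cumulative leaching", {
  run_pfoa <- function(k_foc, r_ner) {
    cfg <- scaled_config(weather_seed = 9, years = 4)
    cfg$substances <- list(substance("PFOA", k_foc = k_foc, n = 0.88,
                                     f_star = 1.1e-5, scenario = "II",
                                     r_ner = r_ner, dispersivity_cm = 8,
                                     applied_mass_g = 360,
                                     application_date = "2007-03-31"))
    simulate_column(cfg)$substances$PFOA
  }
  weak <- run_pfoa(30, 0.0047)
  strong <- run_pfoa(120, 0.0047)
  first_year <- function(r) {
    sum(r$daily$leached_g[r$daily$date <= as.Date("2008-03-31")])
  }
  expect_lt(first_year(strong), first_year(weak))
  peak_month <- function(r) r$monthly$month[which.max(r$monthly$leached_g)]
  expect_gte(as.numeric(peak_month(strong) - peak_month(weak)), 0)

  slow_ner <- run_pfoa(40, 0.001)
  fast_ner <- run_pfoa(40, 0.014)
  expect_lt(fast_ner$final$leached, slow_ner$final$leached)
  expect_gt(fast_ner$final$ner, slow_ner$final$ner)
})

test_that("scenario I with fast kinetics converges to pure equilibrium", {
  base <- scaled_config(weather_seed = 6, years = 3)
  mk <- function(alpha_k, f_ne) {
    cfg <- base
    cfg$substances <- list(substance("PFOA", k_foc = 300, n = 0.88,
                                     f_star = 0, scenario = "I",
                                     alpha_k = alpha_k, f_ne = f_ne,
                                     applied_mass_g = 360,
                                     application_date = "2007-03-31"))
    simulate_column(cfg)$substances$PFOA$final$leached
  }
  fast <- mk(10, 0.5)
  equilibrium <- mk(1, 0)    # f_ne = 0 degenerates to pure equilibrium
  expect_equal(fast, equilibrium, tolerance = 0.01)
  # slow kinetics must differ visibly from equilibrium
  slow <- mk(1e-4, 0.5)
  expect_gt(abs(slow - equilibrium) / equilibrium, 0.01)
})

test_that("mass-balance table reports percent of applied", {
  # sampled leaching masses: 13.9 g of 360 g and 2.7 g of 367.5 g
  expect_equal(round(mass_balance_table(c(leached = 13.9), 360)$pct_applied,
                     1), 3.9)
  expect_equal(round(mass_balance_table(c(leached = 2.7), 367.5)$pct_applied,
                     1), 0.7)
  tab <- mass_balance_table(c(leached = 0, soil = 360), 360)
  expect_equal(tab$pct_applied, c(0, 100))
})

test_that("tidy/autoplot interfaces work on a simulation", {
  cfg <- scaled_config(weather_seed = 5, years = 2)
  sim <- simulate_column(cfg)
  td <- tidy(sim)
  expect_true(all(c("substance", "date", "variable", "value") %in% names(td)))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(sim, "percolation"), "ggplot")
  expect_s3_class(autoplot(sim, "pools"), "ggplot")
  expect_output(print(sim), "pfas_sim")
})
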