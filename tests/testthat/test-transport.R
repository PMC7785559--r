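test_that("zero flux leaves the dissolved profile unchanged", {
  soil <- tiny_soil(4)
  pools <- list(dissolved = c(1, 2, 3, 4), dissolved_macro = 0, leached = 0)
  fx <- list(perc_mm = rep(0, 4), macro_in_mm = 0, w_mm = rep(35, 4),
             theta = rep(0.35, 4))
  su <- substance("X", k_foc = 0, n = 1, f_star = 0, diffusion_m2_d = 0)
  out <- transport_step(pools, fx, soil, su)
  expect_equal(out$dissolved, pools$dissolved)
  expect_equal(out$leached, 0)
})

test_that("transport conserves mass to 1e-10 per step", {
  set.seed(2)
  soil <- tiny_soil(6)
  su <- substance("X", k_foc = 0, n = 1, f_star = 0, dispersivity_cm = 8)
  for (i in 1:20) {
    dis <- runif(6, 0, 10)
    fx <- list(perc_mm = runif(6, 0, 12), macro_in_mm = runif(1, 0, 3),
               w_mm = runif(6, 20, 40), theta = runif(6, 0.2, 0.4))
    pools <- list(dissolved = dis, dissolved_macro = 0, leached = 0)
    out <- transport_step(pools, fx, soil, su)
    total_before <- sum(dis)
    total_after <- sum(out$dissolved) + out$dissolved_macro + out$leached
    expect_equal(total_after, total_before, tolerance = 1e-10)
    expect_true(all(out$dissolved >= 0))
  }
})

test_that("a conservative tracer eventually leaches completely", {
  cfg <- scaled_config(weather_seed = 3, years = 4)
  cfg$substances <- list(substance("tracer", k_foc = 0, n = 1, f_star = 0,
                                   scenario = "II", r_ner = 0,
                                   applied_mass_g = 100,
                                   application_date = "2006-06-01"))
  sim <- simulate_column(cfg)
  f <- sim$substances$tracer$final
  expect_equal(f$applied, 100)
  expect_gt(f$leached / f$applied, 0.95)  # sustained percolation flushes it
  expect_equal(f$leached + f$dissolved + f$sorbed_eq + f$sorbed_kin + f$ner,
               100, tolerance = 1e-8)
})

test_that("tracer pulse moves at the pore-water velocity and spreads with
           dispersivity", {
  # steady 6 mm/d percolation through a 10-layer column
  nl <- 10
  soil <- soil_profile(n_layers = nl, thickness = 0.1, f_oc = 0)
  w_mm <- rep(0.35 * 100, nl)
  q <- 6
  run_pulse <- function(dv_cm, days) {
    su <- substance("X", k_foc = 0, n = 1, f_star = 0,
                    dispersivity_cm = dv_cm, diffusion_m2_d = 0)
    pools <- list(dissolved = c(1, rep(0, nl - 1)), dissolved_macro = 0,
                  leached = 0)
    fx <- list(perc_mm = rep(q, nl), macro_in_mm = 0, w_mm = w_mm,
               theta = rep(0.35, nl))
    for (d in seq_len(days)) pools <- transport_step(pools, fx, soil, su)
    pools$dissolved
  }
  # v = q/theta = 6/0.35 mm/d ~ 17.1 mm/d; after 23 d the front has moved
  # ~0.39 m: peak expected in layer 4 (0.3-0.4 m), within one layer
  prof <- run_pulse(0.01, 23)
  expect_lte(abs(which.max(prof) - 4), 1)
  # larger dispersivity spreads the pulse (smaller peak, larger variance)
  prof_disp <- run_pulse(10, 23)
  expect_lt(max(prof_disp), max(prof))
  centroid <- function(p) sum(seq_along(p) * p) / sum(p)
  spread <- function(p) sum((seq_along(p) - centroid(p))^2 * p) / sum(p)
  expect_gt(spread(prof_disp), spread(prof))
})

test_that("plant uptake is linear in f_star and capped by availability", {
  # c_soil = 1 ug/l uniform (35.3 ug in 35.3 l), 2 mm/d from one layer
  pools <- list(dissolved = rep(35.3e-6, 3), plant_uptake = 0)
  w_mm <- rep(35.3, 3)
  out <- plant_uptake_step(pools, c(0, 2, 0), w_mm, f_star = 1e-4)
  # = 2e-4 ug/d for c = 1 ug/l on 1 m2
  expect_equal(out$uptake_step * 1e6, 2e-4, tolerance = 1e-9)
  out0 <- plant_uptake_step(pools, c(0, 2, 0), w_mm, f_star = 0)
  expect_equal(out0$uptake_step, 0)
  out2 <- plant_uptake_step(pools, c(0, 2, 0), w_mm, f_star = 2e-4)
  expect_equal(out2$uptake_step, 2 * out$uptake_step)
  # cap: uptake never exceeds the dissolved pool
  big <- plant_uptake_step(list(dissolved = c(1e-9, 1e-9, 1e-9),
                                plant_uptake = 0),
                           c(50, 50, 50), w_mm, f_star = 1)
  expect_lte(big$uptake_step, 3e-9 + 1e-20)
  expect_true(all(big$dissolved >= 0))
})
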