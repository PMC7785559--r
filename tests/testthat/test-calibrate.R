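quad_objective <- function(par) {
  -sum((unlist(par) - c(0.3, 0.7))^2)
}
quad_space <- param_space(c("a", "b"), c(0, 0), c(1, 1))

test_that("parameter space validates bounds and transforms", {
  expect_error(param_space("a", 1, 1), "lower < upper")
  expect_error(param_space("a", -1, 1, transform = "log10"), "positive")
  sp <- default_param_space()
  expect_true("PFOA.r_ner" %in% sp$name)
  expect_true(all(c("dv", "albedo", "rsmin_crops", "rsmin_canola") %in%
                    sp$name))
  expect_equal(sp$transform[sp$name == "PFOS.f_star"], "log10")
  sp1 <- default_param_space(scenario = "I")
  expect_true(all(c("PFOA.alpha_k", "PFOA.f_ne") %in% sp1$name))
  expect_false("PFOA.r_ner" %in% sp1$name)
})

test_that("applying parameters updates the configuration consistently", {
  cfg <- scaled_config()
  out <- apply_params(cfg, c(PFOA.k_foc = 99, dv = 4, albedo = 0.2,
                             rsmin_canola = 33))
  expect_equal(out$substances[[1]]$k_foc, 99)
  expect_equal(out$substances[[2]]$k_foc, cfg$substances[[2]]$k_foc)
  expect_equal(out$substances[[1]]$dispersivity_cm, 4)
  expect_equal(out$substances[[2]]$dispersivity_cm, 4)
  expect_equal(out$site$albedo, 0.2)
  expect_equal(unique(out$rotation$rsmin[out$rotation$name == "canola"]), 33)
  expect_error(apply_params(cfg, c(XX.k_foc = 1)), "unknown substance")
  expect_error(apply_params(cfg, c(nonsense = 1)), "unknown parameter")
})

test_that("PSO improves monotonically and respects its budget", {
  ev <- pso_stage(quad_space, quad_objective, n_chains = 1, n_particles = 1,
                  max_sims_per_chain = 60, seed = 2)
  expect_lte(nrow(ev), 60)
  best_by_iter <- tapply(ev$score, ev$iteration, max)
  running <- cummax(best_by_iter)
  expect_true(all(diff(running) >= 0))   # personal best never worsens
  ev2 <- pso_stage(quad_space, quad_objective, n_chains = 2, n_particles = 8,
                   max_sims_per_chain = 120, seed = 2)
  expect_gt(max(ev2$score), -0.01)       # near the optimum at (0.3, 0.7)
  expect_true(all(ev2$a >= 0 & ev2$a <= 1 & ev2$b >= 0 & ev2$b <= 1))
  expect_error(pso_stage(quad_space, quad_objective, n_particles = 32,
                         max_sims_per_chain = 10), "budget")
})

test_that("a fixed seed reproduces PSO trajectories exactly", {
  e1 <- pso_stage(quad_space, quad_objective, n_chains = 2, n_particles = 6,
                  max_sims_per_chain = 30, seed = 7)
  e2 <- pso_stage(quad_space, quad_objective, n_chains = 2, n_particles = 6,
                  max_sims_per_chain = 30, seed = 7)
  expect_identical(e1, e2)
  e3 <- pso_stage(quad_space, quad_objective, n_chains = 2, n_particles = 6,
                  max_sims_per_chain = 30, seed = 8)
  expect_false(identical(e1$a, e3$a))
})

test_that("two-stage calibration nests its search spaces", {
  obj <- list(score = quad_objective, predict = NULL)
  ens <- two_stage_calibrate(quad_space, obj,
                             stage1 = list(n_chains = 2, n_particles = 8,
                                           max_sims_per_chain = 64),
                             stage2 = list(n_chains = 2, n_particles = 8,
                                           max_sims_per_chain = 64),
                             thresholds = c(-0.25, -0.04), seed = 3)
  expect_true(all(ens$space_stage2$lower >= ens$space$lower))
  expect_true(all(ens$space_stage2$upper <= ens$space$upper))
  expect_true(all(ens$behavioural$score > -0.04))
  expect_true(all(abs(ens$behavioural$a - 0.3) < 0.25))
  pt <- ens$posterior
  expect_true(all(pt$min <= pt$q05 & pt$q05 <= pt$q50 &
                    pt$q50 <= pt$q95 & pt$q95 <= pt$max))
  expect_s3_class(tidy(ens), "tbl_df")
  expect_equal(glance(ens)$n_behavioural, nrow(ens$behavioural))
})

test_that("degenerate objective keeps every evaluation behavioural", {
  obj <- list(score = function(par) 1, predict = NULL)
  ens <- two_stage_calibrate(quad_space, obj,
                             stage1 = list(n_chains = 1, n_particles = 4,
                                           max_sims_per_chain = 8),
                             stage2 = list(n_chains = 1, n_particles = 4,
                                           max_sims_per_chain = 8),
                             thresholds = c(0.5, 0.5), seed = 3)
  expect_equal(nrow(ens$behavioural), nrow(ens$stage2))
  # stage-2 bounds equal the stage-1 sampled extremes
  expect_equal(ens$space_stage2$lower[1], min(ens$stage1$a))
  expect_equal(ens$space_stage2$upper[1], max(ens$stage1$a))
})

test_that("hopeless stage 1 aborts with a diagnostic", {
  obj <- list(score = function(par) -abs(sum(unlist(par))), predict = NULL)
  expect_error(
    two_stage_calibrate(quad_space, obj,
                        stage1 = list(n_chains = 1, n_particles = 4,
                                      max_sims_per_chain = 8),
                        thresholds = c(0.6, 0.75), seed = 1),
    "no behavioural models"
  )
})

test_that("superset ensembles have containing envelopes", {
  # envelope of a superset contains the envelope of any subset
  set.seed(5)
  sims <- matrix(rnorm(10 * 6), 10, 6)
  env <- function(m) list(lo = apply(m, 2, min), hi = apply(m, 2, max))
  all10 <- env(sims); sub4 <- env(sims[1:4, ])
  expect_true(all(all10$lo <= sub4$lo))
  expect_true(all(all10$hi >= sub4$hi))
})

test_that("objective caches repeated evaluations", {
  calls <- 0
  obj <- function(par) { calls <<- calls + 1; 1 }
  cache <- new.env(parent = emptyenv())
  sp <- param_space("a", 0, 1)
  pso_stage(sp, obj, n_chains = 1, n_particles = 2, max_sims_per_chain = 4,
            seed = 1, cache = cache)
  n1 <- calls
  pso_stage(sp, obj, n_chains = 1, n_particles = 2, max_sims_per_chain = 4,
            seed = 1, cache = cache)
  expect_equal(calls, n1)  # identical trajectories are fully memoised
})
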