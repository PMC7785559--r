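test_that("K_f scales linearly with organic carbon", {
  expect_equal(kf_from_koc(0, 0.02), 0)
  expect_equal(kf_from_koc(200, 1), 200)
  expect_equal(kf_from_koc(510, 0.015), 7.65)
  expect_error(kf_from_koc(-1, 0.02), "non-negative")
})

test_that("linear-isotherm partition matches the closed form", {
  # K_f = 1 ml/g = 1 l/kg, V = 1 l, 1 kg soil, 2 mg total -> 1 mg/l, 1 mg/kg
  p <- freundlich_partition(2e-3, 1, 1, k_f = 1, n = 1)
  expect_equal(p$c_ug_l, 1000)
  expect_equal(p$s_ug_g, 1)
  expect_equal(p$dissolved_g + p$sorbed_g, 2e-3)
  expect_equal(freundlich_partition(0, 1, 1, 1, 1)$c_ug_l, 0)
  # general linear closed form c = M / (V + Kd * Msoil)
  p2 <- freundlich_partition(0.36, 30, 200, k_f = 5, n = 1)
  expect_equal(p2$c_ug_l, 360 / (30 + 5 * 200) * 1000, tolerance = 1e-10)
})

# independent brute-force bisection oracle on f(c) = V c + Ms Kf c^n - M
bisect_freundlich <- function(m_mg, v, ms, kf, n) {
  f <- function(c) v * c + ms * kf * c^n - m_mg
  lo <- 0; hi <- m_mg / v
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

test_that("nonlinear partition agrees with a bisection oracle", {
  # the worked case: n = 0.75, K_f = 5, V = 30 l, 200 kg soil, 360 g
  p <- freundlich_partition(360, 30, 200, k_f = 5, n = 0.75)
  c_oracle <- bisect_freundlich(360e3, 30, 200, 5, 0.75)
  expect_equal(p$c_ug_l / 1000, c_oracle, tolerance = 1e-10)

  # property sweep: n in [0.6, 1.3], K_f in [0.1, 20], M over 6 decades
  set.seed(1)
  for (i in 1:40) {
    n <- runif(1, 0.6, 1.3)
    kf <- runif(1, 0.1, 20)
    m_mg <- 10^runif(1, -3, 3)
    v <- runif(1, 5, 60)
    ms <- runif(1, 50, 400)
    c_got <- freundlich_partition(m_mg / 1000, v, ms, kf, n)$c_ug_l / 1000
    c_exp <- bisect_freundlich(m_mg, v, ms, kf, n)
    expect_equal(c_got, c_exp, tolerance = 1e-9)
    # mass closes at the returned partition
    expect_equal(v * c_got + ms * kf * c_got^n, m_mg, tolerance = 1e-9)
  }
})

test_that("NER formation is first-order in the sorbed pool", {
  pools <- list(sorbed_eq = 10, ner = 1)
  expect_equal(ner_step(pools, r_ner = 0), pools)
  p1 <- ner_step(pools, r_ner = 0.01, dt = 1)
  expect_equal(p1$ner - 1, 10 * (1 - exp(-0.01)))
  expect_equal(p1$sorbed_eq + p1$ner, 11)
  expect_error(ner_step(pools, r_ner = -1), ">= 0")
})

test_that("half-life conversion matches the prior-range endpoints", {
  expect_equal(rate_from_dt50(50), log(2) / 50)
  expect_equal(round(rate_from_dt50(50), 3), 0.014)
  expect_equal(round(rate_from_dt50(1000), 3), 0.001)
})

test_that("closed batch with constant sorbed fraction loses extractable mass
           as exp(-r * phi_s * t)", {
  # linear isotherm, no flow: sorbed fraction phi_s is constant
  v <- 20; ms <- 150; kf <- 2; n <- 1
  phi_s <- ms * kf / (v + ms * kf)
  r <- 0.01; dt <- 0.1
  m0 <- 5
  dis <- m0 * (1 - phi_s); seq_ <- m0 * phi_s; ner <- 0
  for (i in seq_len(3000)) {
    # equilibrium then NER transfer, the operator order of the simulator
    m_rev <- dis + seq_
    c <- m_rev / (v + kf * ms)
    dis <- c * v; seq_ <- m_rev - dis
    tf <- seq_ * (1 - exp(-r * dt))
    seq_ <- seq_ - tf; ner <- ner + tf
  }
  t_end <- 3000 * dt
  expect_equal((dis + seq_) / m0, exp(-r * phi_s * t_end), tolerance = 1e-4)
})

test_that("kinetic two-site step conserves mass and relaxes to equilibrium", {
  pools <- list(dissolved = 4, sorbed_kin = 0)
  expect_equal(kinetic_sorption_step(pools, target_kin_g = 2, alpha_k = 0,
                                     f_ne = 0.5), pools)
  p <- kinetic_sorption_step(pools, target_kin_g = 2, alpha_k = 0.05,
                             f_ne = 0.5, dt = 1)
  expect_equal(p$dissolved + p$sorbed_kin, 4)
  expect_gt(p$sorbed_kin, 0)
  expect_error(kinetic_sorption_step(pools, 2, 0.05, f_ne = 1.5), "0, 1")

  # trajectory vs a fine-step ODE oracle at fixed concentration:
  # ds/dt = (alpha_k/f_ne) (target - s) with constant target
  alpha <- 0.04; fne <- 0.4; target <- 3
  s_impl <- 0
  for (d in 1:50) {
    st <- kinetic_sorption_step(list(dissolved = 1e6, sorbed_kin = s_impl),
                                target, alpha, fne, dt = 1)
    s_impl <- st$sorbed_kin
  }
  s_ode <- 0; dt <- 1e-3; rate <- alpha / fne
  for (i in seq_len(50 / dt)) s_ode <- s_ode + dt * rate * (target - s_ode)
  # implicit daily discretisation tracks the exact relaxation closely
  s_exact <- target * (1 - exp(-rate * 50))
  expect_equal(s_ode, s_exact, tolerance = 1e-4)
  expect_equal(s_impl, s_exact, tolerance = 0.01)
  expect_lt(abs(s_impl - s_exact), abs(0 - s_exact)) # moving to target
})

test_that("Briggs curve reproduces the screening uptake factors", {
  expect_equal(signif(briggs_fstar(4.81), 2), 0.018)
  expect_equal(signif(briggs_fstar(4.49), 2), 0.039)
  expect_equal(briggs_fstar(1.78), 0.784)  # curve maximum
  expect_lt(briggs_fstar(6), briggs_fstar(4))
})
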