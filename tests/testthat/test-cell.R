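# Cell-level operations: ATFS-1/UPRmt coupling, mitophagy hazard, biogenesis,
# life-state machine, antioxidant monotonicity.

test_that("full import silences the UPRmt; failed import maximises it", {
  cfg <- default_config()
  healthy <- cell_state(mitos = tibble::tibble(
    F = rep(1, 5), Pdam = 0, n_wt = 10L, n_mut = 0L,
    state = "S0_healthy", age = 0))
  out <- step_cell(healthy, dt = 1, seed = 2, n_steps = 5, config = cfg)
  expect_equal(out$atfs1_nuc, 0)
  expect_lt(out$upr, 1e-6)

  cfg$cell$k_biog <- 0    # no fresh organelles diluting the broken pool
  cfg$cell$k_mitophagy <- 0
  broken <- cell_state(mitos = tibble::tibble(
    F = rep(0, 5), Pdam = 0, n_wt = 1L, n_mut = 9L,
    state = "S3_severely_damaged", age = 0))
  out <- step_cell(broken, dt = 1, seed = 2, n_steps = 5, config = cfg)
  # repair nudges F marginally off zero within the 5 steps, so import stays
  # essentially (not exactly) zero
  expect_gt(out$atfs1_nuc, 0.99)
  expect_gt(out$upr, 0.9)
})

test_that("identical cells step to identical successors under one seed", {
  cl <- cell_state(n_mito = 8, seed = 3)
  a <- step_cell(cl, dt = 1, seed = 77, n_steps = 30)
  b <- step_cell(cl, dt = 1, seed = 77, n_steps = 30)
  expect_identical(a, b)
  dead <- cell_state(n_mito = 2, life = "dead")
  expect_error(step_cell(dead), "dead")
})

test_that("mitophagy hazard composes baseline, selectivity, drugs and DAF-16", {
  rates <- default_config()$cell
  h0 <- mitophagy_hazard("S0_healthy", daf16 = 0.4, rates = rates)
  expect_equal(h0, rates$k_mitophagy * (1 + rates$d_daf * 0.4))
  # rapamycin multiplier 2 doubles the hazard exactly
  expect_equal(mitophagy_hazard("S1_slightly_stressed", 0.2, drug_mult = 2,
                                rates = rates) /
                 mitophagy_hazard("S1_slightly_stressed", 0.2, rates = rates),
               2)
  # selectivity: S3 at least as hazardous as S0
  expect_gte(mitophagy_hazard("S3_severely_damaged", rates = rates),
             mitophagy_hazard("S0_healthy", rates = rates))
})

test_that("biogenesis stops at the soft cap and fresh organelles are intact", {
  cfg <- default_config()
  cfg$cell$mito_cap <- 5
  cfg$cell$k_mitophagy <- 0
  cfg$mitochondrion$k_dmg_dna <- 0
  full <- cell_state(n_mito = 5, seed = 1)
  out <- step_cell(full, dt = 1, seed = 5, n_steps = 200, config = cfg)
  expect_equal(nrow(out$mitos), 5)  # capacity term zero at count == cap
  # growth happens below the cap, and from an all-intact pool new organelles
  # carry no damaged copies
  seed_cell <- cell_state(n_mito = 2, seed = 1)
  out <- step_cell(seed_cell, dt = 1, seed = 6, n_steps = 300, config = cfg)
  expect_gt(nrow(out$mitos), 2)
  expect_true(all(out$mitos$n_mut == 0))
})

test_that("biogenesis event frequency matches the Bernoulli rate", {
  # lambda * dt = 0.1 -> P(event) = 1 - exp(-0.1) per draw
  lam_dt <- 0.1
  p <- 1 - exp(-lam_dt)
  draws <- cpp_rbinom(1e5, 1L, p, 301)
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("life transitions respect the triangular threshold bounds", {
  rates <- default_config()$cell
  # below the distribution minimum: never compromised
  for (s in 1:20) {
    out <- check_life_transition("healthy", frac_defective = 0.59,
                                 threshold_c = sample_compromise_threshold(s),
                                 seed = s, rates = rates)
    expect_equal(out$life, "healthy")
  }
  # above the distribution maximum: compromised with certainty
  for (s in 1:20) {
    out <- check_life_transition("healthy", frac_defective = 0.76,
                                 threshold_c = sample_compromise_threshold(s),
                                 seed = s, rates = rates)
    expect_equal(out$life, "compromised")
  }
})

test_that("hysteresis separates the compromise and recovery guards", {
  rates <- default_config()$cell
  rates$k_death <- 0
  # a compromised cell above the recovery bound stays compromised (guards
  # are mutually exclusive: no healthy<->compromised flip within one dt)
  out <- check_life_transition("compromised", frac_defective = 0.65,
                               threshold_c = 0.7, t_compromised = 100,
                               rates = rates)
  expect_equal(out$life, "compromised")
  # below the bound it recovers
  out <- check_life_transition("compromised", frac_defective = 0.55,
                               threshold_c = 0.7, rates = rates)
  expect_equal(out$life, "healthy")
  # dead is absorbing
  out <- check_life_transition("dead", 0, 0.7, rates = rates)
  expect_equal(out$life, "dead")
})

test_that("zero death hazard conserves every cell", {
  cfg <- sim_config(t_end = 2000, n_cells = 6, n_mito_init = 8,
                    n_record = 21, seed = 4,
                    cell = list(k_death = 0))
  res <- run_simulation(cfg)
  expect_true(all(res$tissue$n_dead == 0))
  expect_true(all(res$tissue$survival == 1))
})

test_that("raising antioxidant capacity never raises steady-state ROS", {
  # closed form for the two-species linear chain: sox* = Q / k_sod,
  # h2o2* = Q / k_cat, so total ROS is decreasing in both activities
  Q <- 0.5
  total <- function(k_sod, k_cat) Q / k_sod + Q / k_cat
  grid <- seq(0.5, 3, by = 0.25)
  tot <- vapply(grid, function(a) total(0.1 * a, 0.05 * a), numeric(1))
  expect_true(all(diff(tot) < 0))
  # and the simulated pools reproduce the closed-form steady state: freeze
  # everything except the ROS chain
  cfg <- sim_config(t_end = 4000, n_cells = 1, n_mito_init = 10,
                    n_record = 21, seed = 2,
                    mitochondrion = list(k_dmg_F = 0, k_dmg_dna = 0,
                                         k_deg_dna = 0, leak_gain = 0,
                                         state_fast = 0, state_slow = 0),
                    cell = list(k_biog = 0, k_mitophagy = 0, k_sox_decay = 0,
                                a_upr = 0, a_daf = 0, a_skn = 0, a_cat = 0,
                                eps_nad = 1, k_death = 0))
  res <- run_simulation(cfg)
  last <- res$cells[res$cells$time == max(res$cells$time), ]
  m <- cfg$mitochondrion
  flux <- m$w_flux * last$mean_F + (1 - m$w_flux)
  Qsim <- m$k_sox * flux * last$mito_count
  expect_equal(last$sox, Qsim / cfg$cell$k_sod, tolerance = 0.02)
  expect_equal(last$h2o2, Qsim / cfg$cell$k_cat, tolerance = 0.02)
})

test_that("pool and activity ranges hold over randomized cell stepping", {
  set.seed(7)
  for (i in 1:15) {
    cl <- cell_state(n_mito = sample(3:10, 1), seed = i)
    env <- list(mitophagy_mult = runif(1, 0.2, 3), pq_boost = runif(1, 0, 1),
                pt_daf = runif(1, 0, 0.5), pt_skn = runif(1, 0, 0.5),
                pt_sirt = runif(1, 1, 1.5))
    out <- step_cell(cl, dt = 1, env = env, seed = i, n_steps = 400)
    expect_true(out$sox >= 0 && out$h2o2 >= 0)
    expect_true(out$nad >= 0 && out$atp >= 0)
    for (f in c("upr", "daf16", "skn1", "atfs1_nuc"))
      expect_true(out[[f]] >= 0 && out[[f]] <= 1)
  }
})
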