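# Mitochondrion-level operations: defect fraction, superoxide production,
# stepping, mtDNA replication.

test_that("OXPHOS defect fraction follows 1 - F(1 - w_h * h)", {
  expect_equal(oxphos_defect_fraction(F = 1, n_wt = 10, n_mut = 0), 0)
  expect_equal(oxphos_defect_fraction(F = 0, n_wt = 5, n_mut = 5), 1)
  # hand arithmetic: F = 0.5, h = 0.5, w_h = 0.5 -> 1 - 0.5 * 0.75 = 0.625
  expect_equal(oxphos_defect_fraction(F = 0.5, n_wt = 5, n_mut = 5), 0.625)
  expect_error(oxphos_defect_fraction(F = 1, n_wt = 0, n_mut = 0), "mtDNA")
  # vectorised over organelles
  m <- tibble::tibble(F = c(1, 0.5), n_wt = c(10, 5), n_mut = c(0, 5))
  expect_equal(oxphos_defect_fraction(m), c(0, 0.625))
})

test_that("superoxide production is additive in paraquat and scales with defect", {
  m0 <- mito_state(F = 1, n_wt = 10, n_mut = 0)
  expect_equal(superoxide_production(m0, respiration_flux = 0), 0)
  expect_equal(superoxide_production(m0, respiration_flux = 0, pq_boost = 2.5), 2.5)
  # defect 0 vs 0.5 at leak_gain 1: exactly 1.5x
  rates <- default_config()$mitochondrion
  rates$leak_gain <- 1
  r0 <- superoxide_production(mito_state(F = 1, n_wt = 10), 1, rates = rates)
  r5 <- superoxide_production(mito_state(F = 0.5, n_wt = 10), 1, rates = rates)
  expect_equal(r5 / r0, 1.5)
  expect_error(superoxide_production(m0, respiration_flux = -1), ">= 0")
})

test_that("zero-ROS, zero-repair environment freezes the deterministic flows", {
  rates <- default_config()$mitochondrion
  rates$k_rep_F <- 0
  rates$k_rep_P <- 0
  rates$k_dmg_dna <- 0
  rates$k_deg_dna <- 0
  rates$k_repl <- 0
  rates$state_fast <- 0
  rates$state_slow <- 0
  m <- mito_state(F = 0.8, Pdam = 0.3, n_wt = 7, n_mut = 3)
  out <- step_mito(m, env = list(ros = 0, chaperones = 0, upr = 0, g_nad = 1),
                   dt = 1, seed = 9, n_steps = 50, rates = rates)
  expect_equal(out$F, m$F)
  expect_equal(out$Pdam, m$Pdam)
  expect_equal(out$n_wt, m$n_wt)
  expect_equal(out$n_mut, m$n_mut)
  expect_equal(out$age, 50)
})

test_that("stepping is deterministic under a fixed seed", {
  m <- mito_state(F = 0.9, n_wt = 10)
  env <- list(ros = 50, chaperones = 1, upr = 0.2, g_nad = 0.8)
  a <- step_mito(m, env, dt = 1, seed = 123, n_steps = 20)
  b <- step_mito(m, env, dt = 1, seed = 123, n_steps = 20)
  expect_identical(a, b)
  expect_error(step_mito(m, env, dt = 0), "dt")
})

test_that("mtDNA damage hits follow the Poisson law", {
  # lambda = k_dmg_dna * ROS * N_wt * dt = 2 with these inputs
  rates <- default_config()$mitochondrion
  rates$k_dmg_dna <- 2e-3
  rates$k_deg_dna <- 0
  rates$k_repl <- 0
  lam <- rates$k_dmg_dna * 10 * 100
  expect_equal(lam, 2)
  m <- mito_state(F = 1, n_wt = 100L, n_mut = 0L)
  hits <- vapply(1:4000, function(s) {
    out <- step_mito(m, env = list(ros = 10, chaperones = 0, upr = 0,
                                   g_nad = 1),
                     dt = 1, seed = s, rates = rates)
    out$n_mut
  }, numeric(1))
  expect_lt(abs(mean(hits) - lam), 3 * sqrt(lam / length(hits)))
  expect_lt(abs(var(hits) - lam), 4 * lam / sqrt(length(hits)))
})

test_that("biased replication follows the clonal-expansion probability", {
  # N_wt = N_mut, adv 1 -> p_mut = 1/2 (binomial oracle)
  out <- replicate_mtdna(50000, 50000, 1, adv_mut = 1, seed = 1)
  draws <- cpp_rbinom(1e5, 1L, 0.5, 11)  # engine sampler, p = 1/2
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 1e5))
  # totals increase by exactly n_new
  out <- replicate_mtdna(10, 10, 7, adv_mut = 1.1, seed = 5)
  expect_equal(out$n_wt + out$n_mut, 27)
  # N_wt = N_mut = 10, adv 1.1 -> p_mut = 11/21 (hand arithmetic)
  p <- 1.1 * 10 / (1.1 * 10 + 10)
  expect_equal(p, 11 / 21)
  muts <- vapply(1:4000, function(s)
    replicate_mtdna(10, 10, 10, adv_mut = 1.1, seed = s)$n_mut - 10,
    numeric(1))
  expect_lt(abs(mean(muts) / 10 - p), 3 * sqrt(p * (1 - p) / (10 * 4000)))
  # no damaged templates -> all new copies intact
  out <- replicate_mtdna(10, 0, 5, adv_mut = 1.5, seed = 2)
  expect_equal(out$n_mut, 0)
  expect_error(replicate_mtdna(0, 0, 1), "empty")
})

test_that("clamps hold over randomized stepping", {
  set.seed(99)
  for (i in 1:40) {
    m <- mito_state(F = runif(1), Pdam = runif(1),
                    n_wt = sample(0:20, 1), n_mut = sample(1:20, 1))
    env <- list(ros = runif(1, 0, 500), chaperones = runif(1, 0, 3),
                upr = runif(1), g_nad = runif(1))
    out <- step_mito(m, env, dt = runif(1, 0.1, 5), seed = i, n_steps = 25)
    expect_true(out$F >= 0 && out$F <= 1)
    expect_true(out$Pdam >= 0 && out$Pdam <= 1)
    expect_true(out$n_wt >= 0 && out$n_mut >= 0)
    expect_true(out$n_wt + out$n_mut >= 1)
    expect_true(out$state %in% stress_state_labels())
  }
})

test_that("engine Poisson and binomial samplers match analytic moments", {
  for (lam in c(0.3, 2, 8)) {
    x <- cpp_rpois(1e5, lam, 17)
    expect_lt(abs(mean(x) - lam), 3 * sqrt(lam / 1e5))
    expect_lt(abs(var(x) - lam), 5 * lam / sqrt(1e5))
  }
  for (p in c(0.1, 0.5, 0.9)) {
    x <- cpp_rbinom(1e5, 20L, p, 29)
    expect_lt(abs(mean(x) - 20 * p), 3 * sqrt(20 * p * (1 - p) / 1e5))
  }
})
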