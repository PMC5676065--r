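# Population engine: grid construction, determinism, stream independence,
# conservation, frozen dynamics.

test_that("config invariants are enforced with the offending key named", {
  expect_error(sim_config(t_end = -5), "t_end")
  expect_error(sim_config(t_end = 60, n_record = 2, dt = 40), "dt")
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(mitochondrion = list(adv_mut = 0.9)), "adv_mut")
  expect_error(sim_config(cell = list(state_mult = c(3, 2, 1, 1))),
               "state_mult")
})

test_that("the recording grid spans [0, t_end] evenly", {
  res <- run_simulation(sim_config(t_end = 60, dt = 1, n_cells = 1,
                                   n_mito_init = 2, n_record = 2))
  expect_equal(res$time, c(0, 60))
  res <- run_simulation(tiny_cfg())
  expect_equal(res$time, seq(0, 200, by = 20))
  expect_true(all(diff(res$time) > 0))
})

test_that("a frozen system keeps every observable constant", {
  res <- run_simulation(make_fixture("frozen", seed = 11))
  for (v in c("ros", "nad", "atp", "mito_count", "heteroplasmy_pct"))
    expect_equal(diff(range(res$tissue[[v]])), 0)
  expect_true(all(res$tissue$survival == 1))
})

test_that("identical seeds give bit-identical results; different seeds differ", {
  a <- run_simulation(tiny_cfg(seed = 5))
  b <- run_simulation(tiny_cfg(seed = 5))
  expect_identical(a$cells, b$cells)
  expect_identical(a$tissue, b$tissue)
  c <- run_simulation(tiny_cfg(seed = 6))
  expect_false(identical(a$cells$ros, c$cells$ros))
})

test_that("per-cell streams are order-independent: adding cells leaves earlier cells unchanged", {
  small <- run_simulation(sim_config(t_end = 300, n_cells = 3,
                                     n_mito_init = 5, n_record = 7,
                                     seed = 9))
  big <- run_simulation(sim_config(t_end = 300, n_cells = 6,
                                   n_mito_init = 5, n_record = 7, seed = 9))
  first3 <- big$cells[big$cells$cell <= 3, ]
  expect_equal(as.data.frame(first3), as.data.frame(small$cells))
})

test_that("rng_streams is reproducible and sized n_cells + 1", {
  s1 <- rng_streams(31, 4)
  s2 <- rng_streams(31, 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5)
  expect_equal(s1$stream[1], "engine")
  expect_false(any(duplicated(s1$seed)))
  expect_equal(nrow(rng_streams(1, 1)), 2)
})

test_that("life-state counts always sum to the population size", {
  res <- run_simulation(sim_config(t_end = 3000, n_cells = 8,
                                   n_mito_init = 10, n_record = 31, seed = 2,
                                   cell = list(k_death = 0.01)))
  sums <- res$tissue$n_healthy + res$tissue$n_compromised + res$tissue$n_dead
  expect_true(all(sums == 8))
  expect_true(all(diff(res$tissue$survival) <= 0))
})

test_that("mitochondrion count is conserved without mitophagy and biogenesis", {
  cfg <- sim_config(t_end = 2000, n_cells = 4, n_mito_init = 7,
                    n_record = 21, seed = 3,
                    cell = list(k_mitophagy = 0, k_biog = 0, k_death = 0))
  res <- run_simulation(cfg)
  expect_true(all(res$cells$mito_count == 7))
})

test_that("state fractions sum to one for every living cell", {
  res <- run_simulation(sim_config(t_end = 2000, n_cells = 5,
                                   n_mito_init = 10, n_record = 21, seed = 8))
  cells <- res$cells[res$cells$mito_count > 0, ]
  tot <- cells$s0_frac + cells$s1_frac + cells$s2_frac + cells$s3_frac
  expect_equal(tot, rep(1, length(tot)))
})

test_that("tissue aggregates equal the mean over alive cells", {
  res <- run_simulation(sim_config(t_end = 2000, n_cells = 6,
                                   n_mito_init = 8, n_record = 11, seed = 13,
                                   cell = list(k_death = 0.001)))
  for (tp in res$time[c(3, 7, 11)]) {
    alive <- res$cells[res$cells$time == tp & res$cells$life != "dead", ]
    row <- res$tissue[res$tissue$time == tp, ]
    if (nrow(alive) == 0) {
      expect_true(is.na(row$ros))
    } else {
      expect_equal(row$ros, mean(alive$ros))
      expect_equal(row$atp, mean(alive$atp))
    }
  }
})
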