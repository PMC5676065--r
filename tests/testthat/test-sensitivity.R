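# Normalized sensitivity coefficients: exact formula, surrogate oracles,
# significance flagging, table machinery.

test_that("SC is exact for proportional and power-law outputs", {
  # O proportional to P: 5% reduction gives SC = 1.0000 exactly
  expect_equal(sensitivity_coefficient(1, 0.95), 1, tolerance = 1e-12)
  P <- 3.7
  expect_equal(sensitivity_coefficient(2 * P, 2 * 0.95 * P), 1)
  # O independent of P
  expect_equal(sensitivity_coefficient(4.2, 4.2), 0)
  # O = c * P^k: SC = (1 - 0.95^k) / 0.05, checked to 1e-12 for k = 1, 2, 3
  for (k in 1:3) {
    sc <- sensitivity_coefficient(P^k, (0.95 * P)^k)
    expect_equal(sc, (1 - 0.95^k) / 0.05, tolerance = 1e-12)
  }
  expect_equal(sensitivity_coefficient(1, 0.9025), 1.95)
  # SC -> k as the reduction shrinks
  sc_small <- sensitivity_coefficient(P^2, (0.999 * P)^2, delta_frac = 0.001)
  expect_equal(sc_small, 2, tolerance = 2e-3)
})

test_that("zero baseline output is reported, not silently propagated", {
  expect_warning(sc <- sensitivity_coefficient(0, 1), "undefined")
  expect_true(is.na(sc))
  expect_error(sensitivity_coefficient(1, 1, delta_frac = 0), "delta_frac")
})

test_that("significance flagging is boundary-inclusive and idempotent", {
  tab <- tibble::tibble(parameter = letters[1:5],
                        SC = c(1.0000, -1.2, 0.999, 0, NA))
  kept <- flag_significant(tab)
  expect_equal(kept$parameter, c("a", "b"))
  expect_identical(flag_significant(kept), kept)
  # order-independence
  shuffled <- tab[c(4, 2, 5, 1, 3), ]
  expect_setequal(flag_significant(shuffled)$parameter, kept$parameter)
})

test_that("the surrogate power-law fixture reproduces the closed form", {
  sur <- make_fixture("surrogate_powerlaw")
  P0 <- 1.8
  sc <- sensitivity_coefficient(sur$f(P0), sur$f(0.95 * P0))
  expect_equal(sc, (1 - 0.95^sur$k) / 0.05, tolerance = 1e-12)
})

test_that("global sensitivity builds the full table with paired replicates", {
  cfg <- sim_config(t_end = 400, n_cells = 2, n_mito_init = 4,
                    n_record = 11, seed = 3)
  tab <- global_sensitivity(
    cfg, parameters = c("mitochondrion.k_sox", "cell.k_mitophagy",
                        "drugs.k_pq"),
    responses = c("ros", "mito_count"), age_points = c(200, 400),
    n_reps = 2, seed = 5)
  expect_s3_class(tab, "mitosim_sensitivity")
  expect_equal(nrow(tab), 3 * 2 * 2)  # |params| x |responses| x |ages|
  expect_named(tab, c("parameter", "response", "age_min", "o_base",
                      "o_pert", "SC", "significant"))
  expect_equal(tab$significant, !is.na(tab$SC) & abs(tab$SC) >= 1)
  # a parameter with no dynamical role in this run: k_pq with no paraquat
  kpq <- tab[tab$parameter == "drugs.k_pq", ]
  expect_true(all(kpq$SC == 0))
  # unknown names rejected
  expect_error(global_sensitivity(cfg, parameters = "cell.notakey",
                                  n_reps = 1), "unknown parameter")
  expect_error(global_sensitivity(cfg, parameters = "cell.k_sod",
                                  responses = "banana", n_reps = 1),
               "unknown response")
  expect_error(global_sensitivity(cfg, parameters = "cell.k_sod",
                                  age_points = 999, n_reps = 1),
               "recording grid")
})

test_that("superoxide output responds with SC near 1 to its rate constant", {
  # tissue ROS is proportional to k_sox in a frozen-damage system, so the
  # one-at-a-time procedure should recover SC close to 1
  cfg <- sim_config(t_end = 2000, n_cells = 2, n_mito_init = 10,
                    n_record = 11, seed = 7,
                    mitochondrion = list(k_dmg_F = 0, k_dmg_dna = 0,
                                         state_fast = 0),
                    cell = list(k_biog = 0, k_mitophagy = 0,
                                a_upr = 0, a_daf = 0, a_skn = 0, a_cat = 0))
  tab <- global_sensitivity(cfg, parameters = "mitochondrion.k_sox",
                            responses = "ros", age_points = 2000,
                            n_reps = 2, seed = 2)
  expect_equal(tab$SC, 1, tolerance = 0.05)
})

test_that("common random numbers pair the replicate arms", {
  cfg <- sim_config(t_end = 400, n_cells = 2, n_mito_init = 4,
                    n_record = 11, seed = 3)
  a <- global_sensitivity(cfg, parameters = "cell.k_sod",
                          responses = "ros", age_points = 400,
                          n_reps = 2, seed = 9)
  b <- global_sensitivity(cfg, parameters = "cell.k_sod",
                          responses = "ros", age_points = 400,
                          n_reps = 2, seed = 9)
  expect_identical(a$SC, b$SC)  # same seeds -> same paired runs
  expect_identical(a$o_base, b$o_base)
})
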