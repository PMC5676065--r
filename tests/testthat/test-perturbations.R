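# Dosing schedules, drug effect curves, ablation mapping, presets.

test_that("drug level is windowed, refreshed and optionally decaying", {
  sch <- perturbation("rapamycin", 15, t_start = 1000, t_end = 9000)
  expect_equal(drug_level(sch, c(0, 999)), c(0, 0))
  # constant dosing: exactly the dose anywhere inside the window
  expect_equal(drug_level(sch, c(1000, 3456, 8999)), c(15, 15, 15))
  expect_equal(drug_level(sch, 9000), 0)
  # first-order decay between refreshes: half the dose just before refresh
  dec <- perturbation("bafilomycin", 10, decay_halflife = 2500)
  expect_equal(drug_level(dec, 2500 - 1e-9), 5, tolerance = 1e-6)
  expect_equal(drug_level(dec, 2500), 10)  # reset at the boundary
  expect_equal(drug_level(dec, 1250), 10 * 2^(-0.5))
  expect_error(drug_level(sch, -1), ">= 0")
  expect_error(perturbation("rapamycin", -1), "dose")
})

test_that("mitophagy modulation has the Hill form with unit no-drug point", {
  d <- default_config()$drugs
  expect_equal(mitophagy_modulation(0, 0), 1)
  expect_equal(mitophagy_modulation(d$EC50_r, 0), 1 + d$E_r / 2)
  expect_equal(mitophagy_modulation(0, d$IC50_b), 0.5)
  expect_gt(mitophagy_modulation(15, 0), 1)
  expect_lt(mitophagy_modulation(0, 10), 1)
})

test_that("paraquat boost is linear and rejects negative doses", {
  expect_equal(paraquat_boost(0), 0)
  expect_equal(paraquat_boost(100) / paraquat_boost(5), 20)
  expect_error(paraquat_boost(-1), ">= 0")
})

test_that("pterostilbene drives are saturating and monotone", {
  eff <- pterostilbene_effects(c(0, 1, 5, 20, 50, 100, 300))
  expect_equal(eff$daf16_drive[1], 0)
  expect_equal(eff$skn1_drive[1], 0)
  expect_equal(eff$sirtuin_scale[1], 1)
  expect_true(all(diff(eff$daf16_drive) > 0))
  expect_true(all(diff(eff$skn1_drive) > 0))
  expect_true(all(diff(eff$sirtuin_scale) > 0))
  d <- default_config()$drugs
  expect_true(all(eff$daf16_drive < d$pt_daf))  # ceiling never exceeded
})

test_that("ablations scale the right rate channels", {
  cfg <- sim_config()
  expect_equal(apply_ablation(cfg, ablation("sod-2", 0))$ablations$sod2, 0)
  cfg9 <- apply_ablation(cfg, ablation("sod-2", 0.9))
  expect_equal(cfg9$ablations$sod2, 0.9)
  expect_error(ablation("mev-1", 0.5))
  expect_error(ablation("sod-2", 1.5), "fraction")
  # full sod-2 knockout removes enzymatic dismutation: superoxide piles up
  base <- sim_config(t_end = 2000, n_cells = 2, n_mito_init = 10,
                     n_record = 11, seed = 4)
  ko <- sim_config(t_end = 2000, n_cells = 2, n_mito_init = 10,
                   n_record = 11, seed = 4,
                   ablations = list(ablation("sod-2", 1)))
  r0 <- run_simulation(base)$tissue
  r1 <- run_simulation(ko)$tissue
  expect_gt(r1$sox[11], 5 * r0$sox[11])
  expect_lt(r1$h2o2[11], r0$h2o2[11])
})

test_that("presets echo the published experiment constants", {
  cfg <- preset_config("control")
  expect_equal(cfg$simulation$t_end, 30000)
  expect_equal(cfg$simulation$n_cells, 65L)
  expect_equal(cfg$simulation$n_record, 500L)
  expect_equal(cfg$simulation$dt, 1)
  expect_equal(cfg$simulation$temperature_C, 20)
  expect_equal(cfg$conversion$protein_mass_per_worm_ug, 0.681)
  expect_equal(cfg$conversion$worm_volume_L, 3.5e-9)
  expect_equal(cfg$conversion$ros_aged_threshold_nM, 100)
  expect_equal(cfg$conversion$ros_fold_increase, 10)

  rp <- preset_config("rapamycin15nM")$perturbations[[1]]
  expect_equal(rp$agent, "rapamycin")
  expect_equal(rp$dose, 15)
  expect_equal(rp$dose_unit, "nM")
  expect_equal(rp$refresh_every, 2500)
  bf <- preset_config("bafilomycin10nM")$perturbations[[1]]
  expect_equal(bf$dose, 10)
  expect_equal(bf$refresh_every, 2500)
  expect_equal(preset_config("pq5uM")$perturbations[[1]]$dose, 5)
  expect_equal(preset_config("pq100uM")$perturbations[[1]]$dose, 100)
  pt <- preset_config("pt100uM")$perturbations[[1]]
  expect_equal(pt$dose, 100)
  expect_equal(pt$dose_unit, "uM")
  expect_equal(preset_config("sod2_90")$ablations$sod2, 0.9)
  expect_equal(preset_config("daf16_90")$ablations$daf16, 0.9)
  expect_equal(preset_config("skn1_100")$ablations$skn1, 1)
  sweep <- preset_config("sod2_sweep", t_end = 1000, n_record = 5)
  expect_equal(length(sweep), 6)
  expect_equal(sweep$sod2_100$ablations$sod2, 1)
})

test_that("compromise threshold distribution parameters echo 0.60/0.625/0.75", {
  # the sampler's mode and bounds, recovered from a large sample
  x <- triangular_sample(2e5, 0.60, 0.625, 0.75, seed = 2)
  expect_gte(min(x), 0.60)
  expect_lte(max(x), 0.75)
  dens <- hist(x, breaks = seq(0.6, 0.75, length.out = 31), plot = FALSE)
  expect_equal(dens$mids[which.max(dens$counts)], 0.6275, tolerance = 0.01)
})
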