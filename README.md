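# mitosim

A hybrid agent-based / ODE simulator of mitochondrial function and
dysfunction in aging *Caenorhabditis elegans* cells, for systems biologists
and biogerontologists who want to probe the mitochondrial free radical
theory of aging (MFRTA) together with the stress responses that buffer it —
the ATFS-1–mediated mitochondrial unfolded protein response (UPR^mt^),
selective mitophagy and biogenesis, and the DAF-16/SKN-1 axes — in one
mechanistic, perturbable model.

## The model in brief

A tissue of 65 post-mitotic cell agents is advanced over 0–30 000 min at
20 °C. Each cell carries its own population of mitochondrion agents (50 at
start). Per organelle, the OXPHOS defect fraction

> d = 1 − F·(1 − w_h·h),  h = N_mut / (N_wt + N_mut)

combines lost catalytic capacity *F* and heteroplasmy *h* (damaged/deleted
mtDNA, ∆mtDNA). Superoxide output per organelle is
k_sox·φ·(1 + λ·d) — defective machinery leaks more — and pools at the cell
level, where SOD dismutation and NADPH-limited peroxide clearance set the
ROS balance. ROS damages OXPHOS capacity and mtDNA (Poisson hits);
replication refills copy number with a clonal-expansion bias (adv = 1.1)
toward the damaged class. Organelles are phenotyped into four stress states
(healthy → slightly stressed → significantly stressed → severely damaged) by
banding d at 0.30/0.60/0.90, with stochastic one-band moves allowing both
progression and recovery. Selective mitophagy removes damaged states
preferentially; biogenesis replaces them under a soft carrying capacity.
Cells whose severely-damaged fraction exceeds a threshold drawn from
triangular(0.60, 0.625, 0.75) become compromised and accrue an escalating
death hazard; NAD⁺ and ATP decline as the free-radical feedback loop closes.

Virtual pharmacology (rapamycin, bafilomycin, paraquat, pterostilbene) and
fractional ablations (*sod-2*, *daf-16*, *skn-1*) map onto the rate network,
and a one-at-a-time sensitivity analysis computes normalized sensitivity
coefficients SC = (ΔO/O)×20 under 5% parameter reductions, flagging
|SC| ≥ 1 as significant control.

See the methods vignette (`vignettes/mitosim-methods.Rmd`) for the full
equation set, parameter meanings, calibration procedure and limitations.

## A worked example

```r
library(mitosim)

res <- run_simulation(sim_config(seed = 1))   # the control experiment
glance(res)
#> # A tibble: 1 × 13
#>   t_end n_cells survival n_healthy n_compromised n_dead end_ros end_atp
#>   30000      65    0.431        18            10     37    120.  0.0985
#>   end_nad end_mito_count ros_baseline peak_ros_fold config_hash
#>     0.112             28         13.0          10.6 dc859efd...
```

Read: after a full 30 000-min run, 43% of cells survive, end-of-life tissue
ROS is ~120 nM against a first-day baseline of ~13 nM (a ~10-fold rise — the
model's aged phenotype is defined at 100 nM, a 10-fold increase), ATP has
collapsed to ~0.10 mM, NAD+ to ~11% of its initial level, and the
mitochondrial count has fallen to ~28 per cell after its early-midlife peak.

```r
tidy(res, "tissue")                      # tissue means per grid point
autoplot(res)                            # ROS/ATP/NAD+/counts/survival panels
plot_stress_states(res)                  # mito-phenotyping over time

# perturbations
rapa <- run_simulation(preset_config("rapamycin15nM", seed = 1))
plot_survival(list(control = res, rapamycin = rapa))

# sensitivity (one-at-a-time 5% reductions, paired seeds)
sens <- global_sensitivity(
  sim_config(),
  parameters = c("cell.k_mitophagy", "cell.k_biog", "mitochondrion.k_sox"),
  responses = c("ros", "mito_count"), n_reps = 5, seed = 1)
flag_significant(sens)
```

Presets: `control`, `rapamycin15nM`, `bafilomycin10nM` (refreshed every
2500 min), `pq5uM`, `pq100uM`, `pt100uM` (constant dosing), `sod2_90`,
`daf16_90`, `skn1_90`, `skn1_100`, `sod2_sweep`.

A thin command-line front end is installed at `inst/cli/mitosim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mitosim.R", package="mitosim"))')" \
    run --preset control --seed 1 --outdir out/
```

writing `cells.csv`, `tissue.csv`, `summary.json` and `manifest.json`.

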