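---
title: "Model and methods behind mitosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind mitosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosim)
```

## The model

mitosim simulates a tissue of post-mitotic, energetically demanding
*C. elegans* cells aging over 0--30 000 minutes (roughly the 2--3 week
nematode lifespan) in an isothermal 20 °C environment. It is a hybrid,
hierarchical model: each of the 65 cell agents carries its own population of
mitochondrion agents (50 at the start), a deterministic ODE network advances
the continuous pools, and discrete stochastic events handle what ODEs do
badly — mtDNA copy dynamics, stress-state phenotyping, selective mitophagy,
biogenesis, and the compromise/death fate machine.

### Inside one mitochondrion

Each organelle tracks a functional OXPHOS capacity fraction $F \in [0,1]$, a
damaged matrix-protein fraction $P_{dam}$, intact and damaged/deleted mtDNA
copy counts ($N_{wt}$, $N_{mut}$), a four-level stress-state label, and its
age. The central dysfunction measure is the **OXPHOS defect fraction**

$$d = 1 - F\,(1 - w_h h), \qquad h = \frac{N_{mut}}{N_{wt}+N_{mut}},$$

with heteroplasmy weight $w_h = 0.5$: an organelle with full capacity and no
damaged genomes has $d = 0$; losing either capacity or genomic integrity
pushes $d$ toward 1.

Superoxide output is
$k_{sox}\,\phi\,(1 + \lambda d)$ per organelle, where the electron input
$\phi = w_F F + (1 - w_F)$ is mostly substrate-driven ($w_F = 0.3$): damaged
respiratory complexes divert electrons to superoxide rather than shutting
down, which is what makes the free-radical feedback loop positive — more
defect, more leak ($\lambda = 15$), more damage. Capacity erodes at
$k^F_{dmg}\,\mathrm{ROS}\,F$ and is rebuilt at
$k^F_{rep}\,\mathrm{chap}\,\sigma\,(1-F)$, where the synthesis scale
$\sigma = g(\mathrm{NAD^+})/(1 + s_{upr}\,\mathrm{UPR})$ encodes two
assumptions: protein synthesis and import need energy, and an active
UPR^mt^ down-regulates OXPHOS subunit expression ($s_{upr} = 4$). mtDNA
copies take Poisson-distributed oxidative hits (rate
$k^{dna}_{dmg}\,\mathrm{ROS}$ per intact copy), turn over slowly
($k^{dna}_{deg} = 2\times10^{-4}\,\mathrm{min^{-1}}$), and are replaced by
replication that prefers the damaged class with advantage
$\mathrm{adv_{mut}} = 1.1$ — the clonal-expansion ratchet that acts as the
slow clock of the whole simulation.

The stress-state machine bands $d$ at 0.30 / 0.60 / 0.90 into healthy (S0),
slightly stressed (S1), significantly stressed (S2) and severely damaged
(S3). The two upper edges anchor the 60--90% defect window for deleterious
senescence; 0.30 was chosen to give symmetric band widths below that window.
The label moves at most one band per minute, toward the band of the current
defect with hazard 0.02 min⁻¹ and away from it with hazard 0.002 min⁻¹, so
both progression and recovery occur and a pinned defect yields a birth–death
chain whose stationary law concentrates on the target band (about 83% with
the default 10:1 hazard ratio).

### Inside one cell

Cell pools are superoxide and peroxide (nM), NAD⁺ (relative to $t=0$), and
ATP (mM). Superoxide from all organelles pools at the cell level (single-cell
ROS is what the underlying data resolve; per-organelle exposure uses the cell
pool). SOD activity converts superoxide to peroxide and is boosted by UPR^mt^,
DAF-16 and SKN-1; spontaneous (non-enzymatic) superoxide elimination routes to
non-peroxide sinks. Peroxide clearance is only weakly inducible and is
NADPH-limited (scaled by $0.1 + 0.9\,\mathrm{NAD^+}$), which is one of the
two channels through which an aging cell loses redox control.

The model distinguishes the *signalling* ROS mix from the *damaging* one.
What the transcription factors sense — and what defines the 100 nM aged
phenotype — is combined superoxide plus peroxide. What damages OXPHOS
capacity, matrix proteins, mtDNA and the NAD⁺ pool is
$\mathrm{ROS_{dmg}} = \mathrm{H_2O_2} + w_s\,\mathrm{O_2^-}\,K_s/(K_s +
\mathrm{O_2^-})$ with $w_s = 0.05$ and $K_s = 60$ nM: peroxide is the
diffusible damaging species, while membrane-confined superoxide damages a
saturable set of direct targets (Fe–S clusters). This split is load-bearing
for the *sod-2* experiments — ablating SOD raises the superoxide signal
(activating DAF-16/SKN-1) and cuts peroxide production, so only the full
knockout, which eliminates the damaging flux entirely, shows the strong
longevity gain, while a 90% ablation keeps most of the peroxide flux and
gains little. Nuclear ATFS-1
is the complement of mitochondrial import efficiency,
$1 - \min(1, k_{imp}\,\bar F)$, and drives the UPR^mt^ through a steep Hill
function (K = 0.25, n = 4) — the sharpness matters, because UPR^mt^
activation is the switch that suppresses OXPHOS subunit synthesis and
accelerates NAD⁺ consumption once mean capacity falls below ~0.75. DAF-16
and SKN-1 are single scalar activities relaxing (τ = 200 min) toward a
ROS-driven Hill target plus any drug drive.

NAD⁺ obeys
$\dot n = k_{syn}\,s_{pt} - k_{dec}\,(1 + \beta_{ros}\,o^2 +
\beta_{upr}\,u^2)\,n$ with $o = \max(0, \mathrm{ROS_{dmg}}-40)/100$ and $u$ the
UPR^mt^ activity. With salvage and consumption balanced at 1, NAD⁺ stays flat
until either stress term engages; the quadratic forms keep the young state
genuinely flat and make the decline, once started, fast — which is how the
model reproduces a late, sharp NAD⁺ drop rather than a lifelong drift. ATP
is produced at $k_{atp}\,\Sigma F_i\,g(n)$ with $g$ saturating in NAD⁺
(half-saturation 0.5) and consumed first-order, so the sharp ATP decline
follows the NAD⁺ decline mechanically.

Selective mitophagy removes organelle $i$ with hazard
$k_{mit}\,m_{s_i}\,D(t)\,(1 + d_{daf}\,\mathrm{DAF16})$, with state
multipliers $m = (1, 1.5, 3, 6)$ from S0 to S3 and $D(t)$ the
rapamycin/bafilomycin modulation. Biogenesis adds a fresh organelle
($F \sim \mathrm{tri}(0.93, 0.97, 1.0)$, genomes sampled from the cell-wide
pool proportions with the same replicative bias) at rate
$k_{biog}\,(1 - N/N_{cap})_+\,(1 + b\,s)\,B(t)$, where $s$ is the sirtuin
tone (NAD⁺ times any pterostilbene boost) and $B(t)$ the rapamycin (mTOR)
suppression of biogenesis. The soft capacity (80) with hard cap 160 gives
the early rise of mitochondrial content; the decline after midlife emerges
from falling NAD⁺ (weaker biogenesis) and the growing S2/S3 share (stronger
removal).

A cell becomes **compromised** when its fraction of severely damaged (S3)
mitochondria exceeds a threshold drawn once per cell from
triangular(0.60, 0.625, 0.75); it recovers if the fraction falls back below
0.60 (the distribution minimum — recovery is described but no bound is given,
and using the minimum yields clean hysteresis); while compromised it dies
with hazard $k_{death}(1 + t_c/\tau_d)$, the simplest monotone escalation in
time-in-state ($\tau_d = 5000$ min). Death is absorbing, and dead cells are
excluded from tissue averages rather than carried at their last value.

Two modelling questions without a settled biological answer are resolved as
explicit switches: "defective" mitochondria are S3 only by default
(`defective_include_s2 = 1` widens it to S2+S3), and the speculative
UPR^mt^→TIMM-23→PINK-1 suppression of mitophagy exists as `u_mitoph`,
off by default. mtDNA pools are per-organelle, not a shared cell pool —
selective mitophagy can then physically remove bad genomes, which is the
mechanism the quality-control results rely on. The triangular formula's
mode 0.625 is implemented even though the accompanying prose rounds it to
65%.

## Pharmacology and genetics

* **Rapamycin** multiplies the mitophagy hazard by
  $1 + E_r c/(EC_{50}+c)$ and divides biogenesis by $1 + B_r c/(EC_{50}+c)$
  — mTOR inhibition both induces mitophagy and suppresses organelle
  synthesis. The biogenesis arm is what produces the drastic *decrease* in
  mitochondrial count under rapamycin; mitophagy induction alone cannot,
  because the soft carrying capacity refills the pool.
* **Bafilomycin** divides the mitophagy hazard by $1 + c/IC_{50}$
  ($IC_{50} = 20$ nM: the experimental 10 nM dose suppresses a third of
  mitophagy flux — strong enough to accelerate every damage marker while
  letting part of the cell population survive past 25 000 min).
* **Paraquat** adds a linear redox-cycling term $k_{pq} c$ to every
  organelle's superoxide output; linearity is the minimal assumption that
  fits both reported doses with one constant. Its UPR^mt^ activation is
  emergent (through ROS), not hard-coded, and the occasional late-life
  benefit of the 5 µM dose arises, when it does, from the stronger
  DAF-16/SKN-1 tone it maintains — hormesis as a consequence, not a rule.
* **Pterostilbene** applies saturating Hill drives to DAF-16 and SKN-1 and a
  sirtuin multiplier on NAD⁺ salvage; the three gains are calibrated
  together so the 100 µM preset lowers aged-state tissue ROS by 20--25%
  relative to control — a damping of the aged state, not a prevention of it.
* **Ablations** scale channels by $1-\mathrm{fraction}$: *sod-2* the whole
  enzymatic dismutation activity (including its induced share), *daf-16*
  the DAF-16 activation drive (hence its mitophagy and antioxidant
  contributions), *skn-1* the SKN-1 drive. A spontaneous superoxide
  elimination channel ($k^{sox}_{dec}$, routed to non-peroxide sinks) keeps
  the full knockout finite. The dose–response on longevity follows from the
  damaging/signalling split above: a 90% ablation still converts ~83% of the
  superoxide flux into damaging peroxide (and pays a small saturating
  superoxide-damage toll), so its net benefit is modest, whereas the full
  knockout eliminates enzymatic peroxide production entirely while its
  superoxide signal locks the stress responses on — only complete reduction
  maximizes the longevity effect.

## Calibration

The rate constants are not individually measurable, so the defaults were
fixed by calibrating the network against the aging-timeline anchors the
model is built to reproduce, in this order: (1) young steady state — first-day tissue
ROS ≈ 13 nM (so the 100 nM aged threshold is the canonical ~10-fold increase),
mean F ≈ 0.93, NAD⁺ pinned at 1; (2) the heteroplasmy clock ($k^{dna}_{dmg}$)
so that tissue NAD⁺ begins its sustained decline near 7500 min; (3) the
collapse cascade gains ($s_{upr}$, $\beta_{upr}$, NADPH limitation) so first
compromised cells appear near 10 000 min, ATP saturates toward 17 000--20 000
min (the plateau is dated by the decline rate falling below 10% of its peak), and aged tissue ROS plateaus near 10× baseline; (4) drug constants
against their stated response anchors and orderings. Every constant lives in
one config block and is overridable; none is hidden in code.

## Numerics and reproducibility

The integrator is first-order operator splitting on a fixed 1-min grid:
deterministic Euler sub-steps for the pools, then the stochastic events,
whose probabilities are exponential forms $1 - e^{-\lambda\,dt}$ so that
halving `dt` leaves event intensities consistent. The fastest deterministic
rate (dismutation, 0.1--0.2 min⁻¹) keeps explicit Euler comfortably stable at
dt = 1. Step-size fidelity is checked two ways: with the stochastic events
frozen, the integrated flows change by well under 2% when dt is halved; for
the full stochastic system, trajectories cannot be compared pathwise across
dt (the draw sequences differ), and the ensemble-mean difference between
dt = 1 and dt = 0.5 is indistinguishable from the Monte-Carlo difference
between two same-size seed ensembles — the step contributes nothing beyond
sampling noise. One-band-per-call stress moves prevent unphysical jumps at large dt.
Counts are clamped so fractions stay in [0,1], copy numbers stay
non-negative, and an existing organelle keeps at least one mtDNA copy;
degradation draws that would empty a pool are truncated to spare the last
copy (wild-type preferred when both classes are present, a tie-break that
only matters for single-copy organelles).

Randomness comes from counter-seeded xoshiro256** streams, one per cell plus
one engine stream, all derived from the master seed by splitmix64. Identical
seed and config give bit-identical trajectories; because each cell consumes
only its own stream, stepping order is irrelevant and adding cells to a
population leaves the existing cells' trajectories unchanged. Poisson draws
use Knuth's product method (event means here are far below the
normal-approximation switch at 30), binomials use CDF inversion (pool sizes
are tens of copies), and triangular variates use the closed-form inverse
CDF.

Two trajectory detectors are defined once and used everywhere, including
the acceptance script: `decline_onset()` dates the start of a sustained
decline as the first grid time followed by a monotone decrease over a
2000-min window that loses at least 5% of the series' initial level
(without the drop requirement any slow drift would trigger it), and the
"sharp" ATP decline uses the same detector at a 15% drop. The aged state is
dated by the first crossing of the 100 nM combined-ROS threshold.

## What the simulation does and does not emulate

The virtual experiments generate all inputs themselves; there is no external
data. The population reproduces the *shape* statistics the underlying
biology prints — decline onsets, orderings between pharmacological arms,
fold-changes, survival orderings — under stochastic variation across seeds.
It does not model fission/fusion, spatial organisation, membrane potential,
cell division, intercellular signalling, or the insulin/IIS pathway upstream
of DAF-16, and drug pharmacokinetics are reduced to windowed, refreshed,
optionally decaying concentration profiles. Passing tests therefore support
the internal consistency of this mechanism network and its calibration to
the printed anchors; they are not evidence about real worms beyond what the
anchors themselves encode.

Problem sizes used by the test-suite: the full 65-cell, 30 000-min
configuration for the calibration and perturbation checks (10 seeds per
arm), and miniature populations (2--8 cells, a few hundred minutes) for the
mechanical and invariant checks, which probe the same code paths at a
fraction of the cost.

## Sensitivity analysis

`global_sensitivity()` implements the one-at-a-time scheme: each scalar
parameter is reduced by 5%, paired control/perturbed replicates share seeds
(common random numbers — without pairing the sign of small coefficients is
unstable), and the normalized sensitivity coefficient
$SC = \frac{\Delta O / O}{\Delta P / P} = \frac{\Delta O}{O} \times 20$
is computed from replicate means at young (5000 min), midlife (15 000 min)
and old-age (25 000 min) grid points — the three named life stages given
concrete minutes here, since none are printed. $|SC| \ge 1$ flags
significant sensitive control. The finite difference is one-sided, matching
the $\times 20$ identity. A surrogate power-law model ($O = cP^k$) provides
the analytic oracle $SC = (1 - 0.95^k)/0.05$ used in the tests.

## A worked miniature

```{r example}
cfg <- sim_config(t_end = 2000, n_cells = 4, n_mito_init = 10,
                  n_record = 21, seed = 1)
res <- run_simulation(cfg)
glance(res)
```

```{r plots, fig.width = 7, fig.height = 4, eval = FALSE}
autoplot(res)
plot_stress_states(res)
```
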