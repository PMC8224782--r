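---
title: "A whole-body PBPK model of cabozantinib with enterohepatic recirculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body PBPK model of cabozantinib with enterohepatic recirculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabopbpk)
```

## The problem

Cabozantinib is a multi-target tyrosine kinase inhibitor dosed orally once
daily as a tablet (20–60 mg) or capsule (up to 140 mg). Its plasma
concentration–time profile has three unusual features: a fast initial
decline over the first ~20 h, a very long terminal half-life (on the order
of 100 h), and secondary concentration peaks starting roughly 24 h after a
dose. The drug is ~99.7% bound to plasma proteins, eliminated by CYP3A4
metabolism and fecal excretion with no renal excretion of parent drug, and
is a substrate of the canalicular efflux transporter MRP2 — the combination
that makes enterohepatic recirculation (EHC) the leading explanation for
the secondary peaks: drug secreted into bile is stored and concentrated in
the gallbladder, released into the duodenum when a meal triggers
gallbladder contraction, and partially reabsorbed.

`cabopbpk` implements a whole-body physiologically based pharmacokinetic
(PBPK) model of this system as a reusable simulation package: a segmented
gastrointestinal (GI) tract with Weibull dissolution and pH-dependent
solubility, perfusion-limited organ distribution with Rodgers–Rowland
partitioning, saturable CYP3A4 metabolism in liver and gut wall, saturable
MRP2 biliary efflux, and a meal-triggered gallbladder state machine. On top
of the core model sit three scenario layers — a rifampin CYP3A4-induction
drug–drug interaction (DDI), hepatic-impairment physiology scaling, and
local sensitivity analysis — plus noncompartmental analysis, the standard
PBPK model-evaluation statistics, and a synthetic-data generator that makes
every stage testable without external data.

## Model structure

**Circulation.** Venous pool → lung → arterial pool → organs → venous pool.
Gut wall, spleen, pancreas and stomach wall drain into an (implicit) portal
vein that joins the hepatic arterial inflow at the liver. Organ exchange is
perfusion-limited: for organ $i$ with tissue:plasma partition coefficient
$K_{p,i}$, blood flow $Q_i$, blood:plasma ratio $BP$,

$$\frac{dA_i}{dt} = Q_i\left(C_{art} - \frac{A_i/V_i}{K_{p,i}/BP}\right).$$

$K_p$ values come from the Rodgers–Rowland equations. Cabozantinib is a
weak base (pKa 6.32 < 7), so the weak-base branch applies: partitioning
into tissue water (with Henderson–Hasselbalch ionisation at intracellular
pH 7.0 vs plasma pH 7.4), neutral lipids and phospholipids, plus residual
association with tissue proteins whose association constant is
back-calculated from the plasma unbound fraction. Following the published
method, the adipose neutral-lipid term uses the vegetable-oil:water
correlation $\log D_{vo} = 1.115\,\log P - 1.35$ rather than octanol —
octanol overstates triglyceride partitioning of lipophilic drugs by more
than an order of magnitude, and with $\log P = 4.40$ the difference
(adipose $K_p$ 6.9 vs 48) decides whether the terminal half-life lands near
the clinically observed order of magnitude. For bases with pKa ≥ 7 the
moderate-to-strong-base branch (acidic-phospholipid association calibrated
from the red-cell partition coefficient) is implemented and selected
automatically. The default red-cell partition coefficient is 0: a
99.7%-bound drug is treated as confined to plasma within blood, so
$BP = 1 - hct$.

**Gut.** Eight segments (stomach, duodenum, upper/lower jejunum, upper/lower
ileum, caecum, colon) with first-order transit at fasted transit times.
Solid drug dissolves along a Weibull profile
$F(t) = 1 - 2^{-(t/t_{50})^s}$ parameterised by the half-dissolution time —
so $F(t_{50}) = 0.5$ by construction — applied as a hazard to the remaining
solid so that the solid can transit while dissolving. Luminal solubility
follows Henderson–Hasselbalch for a monoprotic base anchored at the
measured reference point (7.72 × 10⁻³ mg/mL at pH 6.5), which makes the
acidic stomach effectively non-limiting while the near-neutral intestine
saturates at ~15–30 µmol/L. Dissolution is clamped at saturation, and
dissolved drug carried into a segment above its solubility re-precipitates
(rate 10 h⁻¹) into a fine-particle pool that redissolves as absorption
pulls the lumen back below saturation — the pH-shift precipitation weak
bases undergo on gastric emptying. Absorption is a transcellular flux
$P \cdot A \cdot C_{lumen}$ into the gut wall with the published
permeability (1.70 × 10⁻⁴ cm/min) and effective (villous-amplified)
segment areas. The capsule formulation carries a 15-min disintegration lag
for hard-gelatin shell rupture, a standard in-vivo figure; without it the
capsule's compressed dissolution burst (Weibull shape 5) would overtake the
tablet's within 3 h, contrary to the observed formulation contrast.
Formulation defaults: tablet $t_{50}$ 36 min / shape 1.29, capsule 45 min /
shape 5, oral solution treated as instantaneously dissolving with a
configurable solubility scale (default 0.8) to mimic a partly
suspension-like product — the reduction is mild because the solution arm's
absorption is observed to remain fast and essentially complete.

**Hepatobiliary loop.** Both CYP3A4 metabolism (liver and gut wall) and MRP2
transport use the same saturable rate law
$v = k_{cat} E \, c_u / (K_M + c_u)$ on the unbound intracellular
concentration, taken as $f_u \cdot C_{tissue} / K_p$ (the unbound
plasma-equivalent at distribution equilibrium — an explicit modelling
assumption, since perfusion-limited organs carry no separate intracellular
state). Enzyme/transporter amounts are tissue concentrations × organ
volume: CYP3A4 4.32 µmol/L liver and 0.07 µmol/L gut wall (literature
defaults, configurable — these are not printed in the source drug profile);
MRP2 uses the published liver reference concentration 0.09 µmol/L with
$K_M$ 10 µmol/L and $k_{cat}$ 2111.11 min⁻¹.

Biliary output is split three ways. A fraction (default 0.73) is secreted
in reabsorbable form; of that, 10% (the continuous fraction) trickles
straight into the duodenum while the gallbladder is filling and the rest is
stored. The remaining 27% is excreted with the faeces. This reabsorbable
fraction is *derived*, not fitted: the published with/without-EHC exposure
contrast is a factor 2.7, and with metabolic and biliary unbound intrinsic
clearances $m$ and $b$ in the published ratio $b/m \approx 6.4$, the
steady-state relation $\mathrm{AUC_{off}/AUC_{on}} = (m+b)/(m+f_{loss}b)$
gives $f_{loss} \approx 0.27$. The same number independently lands the
total apparent clearance near 2 L/h and the simulated 60-mg steady-state
average concentration within 2% of the published value, and it restores a
genuine fecal elimination route — with perfect reabsorption the loop
retained >99.5% of biliary output and parent drug essentially never reached
the faeces, contradicting the drug's known elimination balance.

**Gallbladder state machine.** Meals (default 4, 10 and 15 h after the
morning dose, repeating daily; dosing is fasted so no event precedes the
first meal) trigger emptying: the ejectable amount is
`ejection_fraction` (0.45) × current content, released exponentially with
half-time 41.44 min into the duodenal lumen. For `refill_time` (241 min)
after the event the contracted gallbladder cannot store bile and all
hepatic bile output bypasses it; then filling resumes. A meal arriving
inside the refractory window simply restarts the event with the current
content. Ejected boluses (hundreds of µmol/L into a 40-mL duodenum) exceed
luminal solubility and partially precipitate, which spreads their
reabsorption over the intestine and, together with the non-reabsorbable
fraction, makes each recirculation cycle lossy.

**Events and integration.** Doses, meals, gallbladder reopening and
perpetrator doses are discrete events implemented by restarting
`deSolve::lsoda`, keeping the state machine exact rather than smoothing it
into forcing functions. The right-hand side exists twice: a readable R
reference implementation and a C implementation through deSolve's
compiled-model interface (the standard approach of this field's
simulators); the two are cross-checked to ~10⁻⁸ in the test suite and the
compiled one is the default. Mass balance is structural — every molecule is
in a luminal, tissue, blood, gallbladder, metabolised or fecal state — and
the suite requires conservation to 10⁻⁶ relative error in every scenario.
At an exact event time the reported row carries the pre-event state.

## Scenario layers

**Rifampin DDI.** The perpetrator is a one-compartment oral model (600 mg
once daily; ka 1.15 h⁻¹, CL 7 L/h, V 55 L, fu 0.17) driving an Emax
induction model on unbound plasma concentration
($E_{max}$ 9, $EC_{50}$ 0.34 µmol/L) through CYP3A4 turnover
$dE/dt = k_{deg}(E_0\,\mathrm{fold} - E)$ with degradation half-lives of
36 h (liver) and 23 h (gut). These are documented literature defaults from
the published rifampin PBPK/DDI modelling work, external to the
cabozantinib profile. Rifampin's weaker competitive-inhibition component is
omitted (the headline interaction is induction). The default scenario gives
the victim 168 h of perpetrator pre-treatment (>4 turnover half-lives, so
the induced enzyme level is ~96% of its plateau) and observes 504 h — 21
days, the order of the clinical studies' sampling for a drug with a
~100-h half-life. Shorter windows truncate the control arm's terminal phase
and bias the AUC ratio upward.

**Hepatic impairment.** `apply_impairment()` applies the published grade
factors: haematocrit replacement (0.47 → 0.39/0.37), portal flow × 0.40/0.36,
renal flow × 0.88/0.65, hepatic arterial flow × 1.30/2.30, other organs
× 1.75/2.25 (brain untouched), liver volume × 0.81/0.65, CYP3A4 activity
× 1.00/0.40, and a plasma protein scale factor 0.85/1.25. Cardiac output is
recomputed as the sum of the scaled flows. One interpretive decision
matters: the protein scale factor is applied as a scale on the *unbound
fraction* (mild 0.85 → slightly lower fu, smaller distribution volume,
higher Cmax; moderate 1.25 → higher fu, more clearance and distribution),
which is the only reading consistent with the clinical narrative the
factors were calibrated to. Since `scaled_fu()` parameterises binding by
the binding-protein concentration, the reciprocal of the printed factor is
passed to it (for fu ≪ 1 this is fu × factor to first order). For the
moderate grade, 1.25 is the tabulated value and 1.30 a documented
alternative (`moderate_protein_scale`). Impairment comparisons use
AUC to 336 h after a single 60-mg capsule.

**Local sensitivity.** Normalised coefficients
$S = (\Delta Y / Y)/(\Delta p / p)$ by central finite difference with
re-simulation; in the degenerate one-compartment configuration the suite
checks the analytic anchors $S = 1$ (AUC vs dose) and $S = -1$ (AUC vs
clearance, up to the known $-1/(1-\delta^2)$ finite-difference factor).

## Synthetic data and what passing tests show

`sample_population()` draws anthropometrics uniformly within stated ranges,
scales organ volumes linearly and flows allometrically (exponent 0.75) with
body weight, and applies lognormal multipliers (median 1) with configurable
CVs — defaults 30% on `kcat_cyp3a4` and `kcat_mrp2`, 15% on flows, typical
magnitudes for hepatic enzyme/transporter abundance. `synthesize_study()`
simulates each individual, samples at a schedule, applies multiplicative
lognormal residual noise (default σ = 0.1 — the source studies publish
digitized means without dispersion, so the residual model is an assumption,
not an estimate), censors below the LLOQ, and records every individual's
generating parameters for recovery tests.

The generator reproduces the *structural* features the analysis relies on —
single-dose profiles over 20–140 mg, secondary post-meal peaks, lognormal
between- and within-subject variation — but not features of the real
clinical data it stands in for: true inter-occasion variability in meal
timing and gallbladder response, food and formulation covariances,
below-LLOQ correlation structure, or model misspecification. Passing
recovery tests therefore demonstrate the estimation machinery is correct
and well-conditioned under the model's own assumptions, not that the model
is identifiable from any given clinical dataset.

## Numerical choices

Internal units are hours, µmol and µmol/L; ng/mL appears only at the I/O
boundary (1 µmol/L × MW g/mol = 1 ng/mL × MW). Default solver tolerances
are rtol 10⁻⁸ / atol 10⁻⁹ (halving them moves AUC by <0.1%); parameter
fitting uses rtol 10⁻⁶ for speed. The Weibull hazard is capped at 100 h⁻¹ —
for shapes > 1 it grows without bound long after a dose, where the residual
solid is negligible but the uncapped rate destabilises the integrator; the
same 100 h⁻¹ serves as the "instantaneous" dissolution rate of the
solution. Precipitation/redissolution run at 10 h⁻¹, fast against transit
(0.08–5 h⁻¹) but finite, so brief saturation overshoots occur when a bolus
arrives and relax within minutes. Multiple doses restart the dissolution
clock of the most recent dose — an approximation that matters little
because earlier doses' solid is almost fully dissolved within one dosing
interval. Steady state is declared when at least five complete dosing
intervals are simulated and the last two interval AUCs agree within 1%;
`css_average()` is the last interval AUC divided by τ. Fitting minimises
the sum of squared log₁₀ residuals with golden-section search (one
parameter) or bounded L-BFGS-B (several); both are deterministic from the
start point, L-BFGS-B using finite-difference gradients. Observed zeros
(below-quantification points) are excluded from all evaluation statistics
with the exclusion count reported; the fold-deviation bounds are inclusive;
the mean relative deviation uses the root-mean-square convention
$\mathrm{MRD} = 10^{\sqrt{\frac1n \sum (\log_{10} c_{pred,i} - \log_{10} c_{obs,i})^2}}$,
the standard reading in this literature. AUC is linear-trapezoidal
throughout.

Test problem sizes are chosen for desk-scale runs: 96-h single-dose
scenarios, 336-h impairment and 504-h DDI/steady-state windows, 20-seed
recovery with 16 sampling points, and population checks at n ≤ 100 on
coarse (0.25–0.5 h) output grids.

## Worked defaults and limitations

The packaged configuration (`cab_defaults()`) reproduces, from mechanism,
the study-scale numbers a user should expect: fraction absorbed at 3 h
ordered solution (0.93) > tablet (0.63) > capsule (0.58) with the solution
essentially complete; secondary plasma peaks within ~2 h after each meal
event, absent when MRP2 is disabled; an exposure gain from recirculation;
a single-dose 140-mg DDI AUC ratio of ~0.34 under induction; impairment
exposure increases of ~+42%/+41% (mild/moderate) at 336 h; and a 60-mg
once-daily steady-state average of ~1170 ng/mL.

Known limitations: the physiology is a single adult reference individual
assembled from standard published values, not a database-backed anatomy;
organ exchange is perfusion-limited (an optional user-supplied permeability
mode exists but no predictive cellular-permeability formula is shipped,
deliberately — the upstream method is proprietary-documented); metabolites
are not modelled; bile-acid physiology and micellar solubilisation are
reduced to the reabsorbable-fraction and precipitation constructs; the
perpetrator is one-compartment, not a full PBPK model; and meal clock times
are configuration defaults, since only "morning, noon, evening" is known.
The rat arm of the original model development (no gallbladder, lumped
clearance) is intentionally out of scope.
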