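# cabopbpk

A whole-body physiologically based pharmacokinetic (PBPK) model of the
tyrosine kinase inhibitor **cabozantinib**, built as a reusable R simulation
package for pharmacometricians and DMPK scientists who want to explore the
drug's unusual kinetics mechanistically: a fast initial decline, a terminal
half-life on the order of 100 h, and secondary plasma peaks ~24 h post-dose
produced by **enterohepatic recirculation (EHC)**.

The model couples:

* a segmented gastrointestinal tract (8 segments) with Weibull
  tablet/capsule dissolution `F(t) = 1 − 2^−(t/t50)^s`, pH-dependent
  luminal solubility (Henderson–Hasselbalch for a monoprotic base, pKa
  6.32) and transcellular absorption flux `P·A·C`;
* perfusion-limited whole-body distribution with **Rodgers–Rowland**
  tissue:plasma partition coefficients (weak-base branch; vegetable-oil
  correlation for adipose);
* saturable **CYP3A4** metabolism in liver and gut wall and saturable
  **MRP2** canalicular efflux, both as `v = kcat·E·cu/(KM + cu)`;
* a meal-triggered **gallbladder state machine** (filling → emptying →
  refractory) with exponential release (half-time 41.44 min), ejection
  fraction 0.45, a 10% continuous bile fraction and a 241-min refill time;
* scenario layers for the **rifampin CYP3A4-induction DDI** (one-compartment
  perpetrator + enzyme turnover `dE/dt = kdeg(E0·fold − E)`,
  `fold = 1 + Emax·c/(EC50 + c)`), **hepatic-impairment** physiology
  scaling, and **local sensitivity analysis**;
* noncompartmental analysis and the standard PBPK evaluation statistics
  (PE/MPE/MAPE, MRD = `10^rms(log10 pred − log10 obs)`, 2-fold and
  1.25-fold fractions, DDI AUC/Cmax ratios), and a seeded synthetic-data
  generator with ground truth for parameter-recovery testing.

The packaged default configuration is the published cabozantinib profile
(MW 501.50 g/mol, logP 4.40, fu 0.24%, solubility 7.72·10⁻³ mg/mL at
pH 6.5, CYP3A4 Km 0.97 µmol/L / kcat 0.67 min⁻¹, MRP2 Km 10 µmol/L /
kcat 2111.11 min⁻¹, tablet Weibull 36 min/1.29, capsule 45 min/5.00).

## Worked example

```r
library(cabopbpk)

cfg <- cab_defaults()          # packaged drug / physiology / EHC profile
sys <- assemble_pbpk(cfg$drug, cfg$physiology, cfg$ehc)
sys
#> <pbpk_system> whole-body: 14 organs, 8 GI segments | MRP2 on | EHC on | DDI off
#>   fu_eff 0.0024 | B:P 0.53 | CO 299.0 L/h

res <- simulate_pbpk(sys, dose_regimen(140, cfg$formulations$tablet, "oral"),
                     t_end = 96)
res
#> <pbpk_result> 140 mg tablet | t 0..96 h | Cmax 881.1 ng/mL at 2.3 h | AUC_last 39294 ng*h/mL

# secondary peaks appear shortly after the meal events (4, 10, 15 h ...)
head(secondary_peaks(res$time, res$conc, after = 4), 3)
#>   time     conc
#> 1  4.7 809.5556
#> 2 11.1 659.7732
#> 3 16.0 632.3051

# cumulative fraction of the dose absorbed at 3 h and 30 h
fa <- fraction_absorbed(res)
round(approx(fa$time, fa$total, c(3, 30))$y, 3)
#> [1] 0.628 0.919

# exposure gain from recirculation: same dose with biliary output
# excreted directly to faeces instead of recirculated
sys_off <- assemble_pbpk(cfg$drug, cfg$physiology, cfg$ehc, list(ehc = FALSE))
res_off <- simulate_pbpk(sys_off, dose_regimen(140, cfg$formulations$tablet,
                                               "oral"), 96)
round(auc_last(res$time, res$conc) / auc_last(res_off$time, res_off$conc), 2)
#> [1] 1.89

# rifampin induction DDI: 140 mg capsule after 7 days of rifampin 600 mg qd
ddi <- simulate_ddi(cfg$drug, cfg$physiology, cfg$ehc, induction_model(),
                    dose_regimen(140, cfg$formulations$capsule, "oral"))
round(ddi$ratios, 3)
#>  auc_ratio cmax_ratio
#>      0.344      0.866
```

Reading the numbers: the 140-mg tablet peaks at ~880 ng/mL around 2 h;
63% of the dose is absorbed within 3 h (solubility-limited, not
dissolution-limited); each meal event releases stored bile and produces a
local plasma maximum; recirculation nearly doubles the 96-h exposure; and
a strong CYP3A4 inducer cuts the victim AUC to about a third while barely
touching Cmax (absorption is unchanged — only elimination is induced).

Hepatic impairment and population simulation follow the same pattern:

```r
ph_mild <- apply_impairment(cfg$physiology, impairment_scaling("mild"))
pop <- simulate_population(cfg$drug, cfg$physiology, cfg$ehc,
                           dose_regimen(60, cfg$formulations$tablet, "oral"),
                           t_end = 96, population_spec(n = 100, seed = 1))
```

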