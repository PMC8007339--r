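# suspeq

When a liquid formulation of a drug does not exist, pharmacists compound an
extemporaneous suspension from crushed commercial tablets — for children,
and for patients who cannot swallow solids.  Such preparations never see a
bioequivalence study, so the practical question is whether the suspension
can be *shown* to behave like its source tablet from bench data alone.
`suspeq` implements the full computational chain used to answer that
question for an amlodipine/valsartan 5/80 mg suspension compounded from
commercial combination tablets: dissolution-profile comparison, a
mechanistic gastrointestinal absorption simulator coupled to compartmental
disposition, non-compartmental analysis, percent-prediction-error model
verification, Monte-Carlo virtual bioequivalence, plus the compounding
batch arithmetic and stability/rheology checks around it.

The package is aimed at formulation scientists and pharmacometricians who
want a transparent, scriptable, fully testable counterpart to commercial
gastrointestinal-simulation software for this class of problem.

## The models

**Dissolution similarity.**  Two cumulative release profiles R and T on a
common time grid are compared with the difference and similarity factors

    f1 = 100 * sum(|R_t - T_t|) / sum(R_t)
    f2 = 50 * log10( 100 / sqrt(1 + mean((R_t - T_t)^2)) )

with f2 > 50 and f1 <= 15 indicating similarity, and release classed
*very rapid* (>= 85% in 15 min), *rapid* (>= 85% in 30 min) or *not rapid*.

**Absorption.**  An oral dose transits a nine-compartment fasted chain
(stomach, duodenum, jejunum x2, ileum x3, caecum, ascending colon), each
compartment with its own pH, volume, radius and mean transit time.  Solid
drug dissolves either by the Johnson/Nernst–Brunner particle law

    dM/dt = 3 D / (rho r h) * M * max(S(pH) - C, 0),   h = min(r, 30 um)

with Henderson–Hasselbalch pH-dependent solubility S(pH) (capped at a
configurable solubilization ratio), or by the measured in vitro release
curve of the product (each gut segment uses the dissolution medium nearest
its own pH).  Supersaturated drug re-precipitates first-order with the mean
precipitation time.  Dissolved drug is absorbed at

    ka_n = 2 Peff / r_n * ASF_n

where the absorption scale factor ASF combines the segment's villous
surface enhancement with a drug-level lipophilicity weight
`10^(a + b logD)` (see the methods vignette for the calibration of a, b).

**Disposition and verification.**  The absorbed-rate series drives a one-
or two-compartment disposition model; Cmax and AUC(0–∞) come from standard
non-compartmental analysis, and model quality is scored as

    %PE = (predicted - observed) / observed * 100

with the study's acceptance bar at |%PE| < 10%.  Virtual bioequivalence
simulates a crossover of virtual subjects (lognormal parameter
variability, identical draws for test and reference) and passes when the
90% confidence interval of the geometric mean ratio of Cmax and AUC lies
within 80–125%.

## Worked example

The bundled data reproduce the published study: two-timepoint dissolution
of both products in three media, the simulation input parameters of both
actives, and the observed tablet pharmacokinetics.  One call runs the whole
chain for the suspension:

```r
library(suspeq)
profs <- reference_dissolution("valsartan")
cfg <- pipeline_config(
  drug = valsartan(),
  dosage_form = "ir_suspension",
  reference_profiles = profs[grep("tablet", names(profs))],
  test_profiles = profs[grep("suspension", names(profs))],
  observed = observed_tablet_pk("valsartan"),
  vbe = list(n_subjects = 12, seed = 2024))
report <- run_pipeline(cfg)
print(report)
```

```
== suspeq pipeline report: valsartan (ir_suspension) ==
dissolution similarity (tablet = reference, suspension = test):
  pH 1.2  f1  8.97  f2  82.69  similar | release ref/test: not_rapid/not_rapid
  pH 4.5  f1  4.59  f2  70.94  similar | release ref/test: not_rapid/not_rapid
  pH 6.8  f1  3.51  f2  70.44  similar | release ref/test: very_rapid/very_rapid
fraction absorbed: 0.2304 (mass-balance error 6.5e-13 mg)
PK: Cmax 778.5 ng/mL at 2.65 h | AUC(0-inf) 9219.33 ng*h/mL
prediction error vs observed:
  cmax     predicted 778.528 vs observed 747.3 -> |%PE| 4.18
  auc_inf  predicted 9219.33 vs observed 8949.7 -> |%PE| 3.01
<be_result> 12 subjects, seed 2024, 90% CI vs 80-125%
  metric gmr_pct ci90_lo_pct ci90_hi_pct n_subjects seed verdict
    cmax  100.18      100.17      100.19         12 2024    pass
 auc_inf  100.20      100.18      100.21         12 2024    pass
```

Reading the output: the suspension's release is similar to the tablet's in
every medium (all f2 > 50, all f1 well under 15); the simulated suspension
absorbs 23% of the 80 mg valsartan dose; its predicted exposure is within
5% of the tablet's observed values; and the virtual crossover places the
90% confidence intervals of both geometric mean ratios inside the 80–125%
bioequivalence window.  The tablet-side verification (`dosage_form =
"ir_tablet"`) and the amlodipine analogue run the same way, as do the
supporting checks:

```r
batch_total_mass(reference_batch())$total_g        # 320.4 g per 20-bottle batch
doses_per_bottle(50, 5)                            # 10 doses per bottle
assess_stability(reference_stability("amlodipine")) # pass, minimum 97.3%
```

## Package layout

| Area | Entry points |
|---|---|
| drug parameters & solubility | `drug_substance()`, `amlodipine()`, `valsartan()`, `solubility_at_ph()` |
| dissolution | `dissolution_profile()`, `f1_difference()`, `f2_similarity()`, `classify_release()`, `release_rate_series()` |
| absorption | `default_fasted_physiology()`, `simulation_config()`, `simulate_absorption()` |
| disposition & NCA | `derive_disposition()`, `simulate_disposition()`, `nca()` |
| evaluation | `percent_prediction_error()`, `virtual_bioequivalence()`, `be_verdict()`, `assess_stability()`, `classify_rheology()` |
| compounding | `reference_batch()`, `batch_total_mass()`, `doses_per_bottle()`, `tablets_required()` |
| synthetic data | `gen_dissolution()`, `gen_plasma()`, `gen_stability()` |
| orchestration | `pipeline_config()`, `run_pipeline()` |

The methods vignette (`vignettes/suspension-equivalence.Rmd`) documents the
model assumptions, the physiology defaults and their calibration, numerical
choices, and known limitations.
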