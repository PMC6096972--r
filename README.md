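# mpsorb

Model-based analysis of pH-dependent equilibrium sorption of ionizable
organic pollutants — pharmaceuticals, pesticides, personal-care
compounds — to microplastic particles such as polyethylene (PE) and
polystyrene (PS). Written for environmental chemists running multi-pH
batch-sorption experiments and for modelers assessing whether
microplastics matter as a pollutant vector at environmental loadings.

## The model

For a monoprotic acid or base, the neutral fraction at a given pH follows
the rearranged Henderson–Hasselbalch equation
(acid: *f*<sub>n</sub> = 1/(1+10^(pH−pK<sub>a</sub>)); base:
*f*<sub>n</sub> = 1/(1+10^(pK<sub>a</sub>−pH))). A closed batch with
water volume *V*<sub>W</sub>, plastic mass *m*<sub>P</sub> and initial
concentration *c*<sub>0</sub> yields, per measured aqueous concentration
*c*<sub>W</sub>, an overall distribution coefficient

> *D*<sub>P</sub> = (*c*<sub>0</sub> − *c*<sub>W</sub>)/*c*<sub>W</sub> · *V*<sub>W</sub>/*m*<sub>P</sub>  [L kg⁻¹],

which the two-species model decomposes as

> *D*<sub>P</sub>(pH) = *K*<sub>P,n</sub> *f*<sub>n</sub> + *K*<sub>P,i</sub> *f*<sub>i</sub>.

The species-specific coefficients are estimated by exact non-negative
linear least squares across the pH design. An analytical error model,

> (*K*<sub>P,c</sub> − *K*<sub>P,m</sub>)/*K*<sub>P,c</sub> = ε/(1+ε) · (1 + *V*<sub>W</sub>/(*m*<sub>P</sub>*K*<sub>P,c</sub>)),

shows that at a liquid-to-solid ratio of 10³ L kg⁻¹ and ε = 5% only
coefficients above 50 L kg⁻¹ carry less than 100% error; smaller fitted
values are censored to the token `<5e+01`. Finally, the dissolved
fraction in a water body with organic carbon and plastic as competing
sorbents,

> *f*<sub>diss</sub> = 1/(1 + *K*<sub>OC</sub>·*m*<sub>OC</sub>/*V*<sub>W</sub> + *K*<sub>P</sub>·*m*<sub>P</sub>/*V*<sub>W</sub>),

is mapped under a batch-like plastic loading (Scenario I, LSR 10³ L kg⁻¹)
and an environmental one (Scenario II, LSR 10¹⁰ L kg⁻¹). A seeded
synthetic generator emulates the triplicate pH {4, 7, 10} study design so
the whole chain is testable without laboratory data. See the vignette
(`vignettes/ph-dependent-sorption.Rmd`) for assumptions and numerical
choices.

## Worked example

```r
library(mpsorb)

compounds <- read_compound_table(mpsorb_example("compounds_table1.csv"))
speciate(compounds[["Diclofenac"]], c(4, 7, 10))
#>   ph          f_n       f_i
#> 1  4 4.942438e-01 0.5057562
#> 2  7 9.762832e-04 0.9990237
#> 3 10 9.772363e-07 0.9999990
```

Diclofenac (an acid, pK<sub>a</sub> 3.99) is half neutral at pH 4 and
essentially fully ionized at pH 7 and 10 — so its sorption must fall with
pH. Simulate the full study, then run the pipeline:

```r
meas <- generate_study_fixture(compounds, study_truths("PE"), seed = 42)
write_measurements(meas, "measurements.csv")
cfg <- run_config(mpsorb_example("compounds_table1.csv"),
                  "measurements.csv", "out")
res <- run_pipeline(cfg)
#> read 19 compounds, 684 measurement rows
#> aggregated D_P for 57 compound x polymer x pH cells
#> fitted 19 compound x polymer groups (10 with censored coefficients; censor threshold 50 L/kg)
#> scenario I mapped (5041 grid points)
#> scenario II mapped (5041 grid points)

subset(res$fit_report,
       compound %in% c("Diclofenac", "Phenanthrene", "4-Nonylphenol"),
       select = c(compound, kp_n_label, kp_i_label, cv_ph4, cv_ph7, cv_ph10))
#>         compound  kp_n_label  kp_i_label cv_ph4 cv_ph7 cv_ph10
#> 1  4-Nonylphenol 5.96030e+03 3.31979e+02   4.32   5.51    6.87
#> 9     Diclofenac 1.52901e+02      <5e+01  71.98 226.45  407.29
#> 13  Phenanthrene 9.95053e+03        n.a.   3.29   5.28    5.39
```

Reading the report: the strong sorbers are recovered precisely (CVs of a
few percent); diclofenac's neutral-species coefficient (~1.5 × 10²
L kg⁻¹) is resolved but its ionic coefficient falls below the 50 L kg⁻¹
reliability limit and is censored, with the CV warning (> 100% at pH 7
and 10) telling the same story; phenanthrene is neutral, so an ionic
coefficient does not exist ("n.a."). The reliability limit itself is a
model output, and the two scenarios bracket the environmental question:

```r
min_reliable_kp(error_model(epsilon = 0.05, vw = 0.1, mp = 1e-4), max_error = 1)
#> [1] 50
dissolved_fraction(scenario_preset("I"),  koc = 0, kp = 9.9e3)
#> [1] 0.09174312
dissolved_fraction(scenario_preset("II"), koc = 0, kp = 9.9e3)
#> [1] 0.999999
```

Even the strongest-sorbing compound is > 90% plastic-bound at batch
loadings yet effectively fully dissolved at environmental plastic
concentrations — seven orders of magnitude apart in liquid-to-solid
ratio (`lsr_gap(1e10, 1e3)` = 7).

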