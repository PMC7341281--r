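# marelife

Lifetime foaling rate construction and pedigree-based genetic evaluation
for horse studbooks.

## The problem

Brood-mare fertility is economically central in heavy-draught and meat-type
horse breeding, yet per-season fertility scores are barely heritable and
hard to compare across managements.  `marelife` implements an alternative:
express a mare's lifetime reproductive performance as a **lifetime foaling
rate (LFR)** — foals produced in her first six breeding seasons divided by
six — and treat it as a quantitative trait.  The package is aimed at
animal-breeding researchers and studbook analysts who want to

* construct the trait from raw reproductive-event records (foaling,
  abortion, open) under explicit editing rules;
* **project** the sixth-season foal count for mares with only 3–5 registered
  seasons, using either classical multiplicative projection factors
  ("coefficients") or a least-squares regression ("equations"), validated by
  percentage squared bias (PSB), mean absolute deviation (MAD) and residual
  standard deviation (SDR) from leave-one-out residuals;
* estimate genetic parameters with the single-trait animal model
  `y = Xb + Z_h h + Z_a a + Z_d d + e`, where `Var(a) = A s2_a` (numerator
  relationship matrix), `Var(d) = D s2_d` (dominance relationship matrix),
  `Var(h) = I s2_h` (environmental-unit-by-birth-year herd effect) and
  `Var(e) = I s2_e`, fitted by monotone EM-REML with damped
  average-information acceleration; heritability is
  `h2 = s2_a / (s2_h + s2_a + s2_d + s2_e)` with a delta-method standard
  error;
* post-process BLUP breeding values: standardization to a base birth-year
  cohort, progeny-test accuracies `r = sqrt(n / (n + (4 - h2)/h2))`,
  stallion selection, Spearman rank correlations between trait expressions
  and annual genetic trends.

Because studbook data of this kind are not publicly deposited, the package
ships a seeded **synthetic studbook generator** with known true breeding
values, dominance deviations, herd effects and inbreeding depression, so
every stage is testable end to end.  Pedigree machinery (inbreeding by
recursive kinship / Meuwissen–Luo, tabular `A`, sparse Henderson `A^-1`,
dominance `D`) is verified against gene-dropping oracles.

## Worked example

```r
library(marelife)

cfg <- pipeline_config(
  simulation = sim_config(n_founders = 250, n_generations = 9,
                          n_recorded_mares_target = 1500,
                          sires_per_generation = 30),
  base_year = 2003, seed = 42)
pp <- run_pipeline(cfg)
pp$validation
summary(pp$fits$lfr_c)
pp$rank_correlations
```

This simulates a 3,286-animal pedigree with 1,233 recorded mares, edits it
into 635 complete six-season careers (training) and 1,230 mares with at
least three seasons (full dataset), and prints:

```
       method k  psb   mad   sdr
 coefficients 3 7.07 0.883 1.096
    equations 3 2.87 0.537 0.698
 coefficients 4 3.88 0.685 0.812
    equations 4 2.08 0.502 0.594
 coefficients 5 1.71 0.482 0.538
    equations 5 1.21 0.410 0.453
```

Both methods predict better as the known horizon grows from 3 to 5
seasons, and the regression ("equations") method beats the multiplicative
factors on every statistic — the factor predictor has no intercept and
cannot regress extreme partial counts toward the mean.

```
Variance components:
 component  estimate        se proportion
      herd 1.917e-04 0.0002725      0.007
  additive 2.415e-03 0.0011480      0.090
 dominance 2.718e-10 0.0092090      0.000
  residual 2.435e-02 0.0090880      0.903

Heritability: 0.090 (SE 0.042)
```

On this mixed dataset (52% actual, 48% projected careers) heritability is
attenuated well below the complete-career truth of 0.242, because honest
projections carry prediction error of roughly half a foal to one foal into
the phenotype; the methods vignette quantifies this.  Rank correlations
between the four trait expressions (printed by the example) run 0.91–0.99:
the arcsine transform and the projection method both reshuffle mare
rankings slightly.

On complete careers the model recovers its generating parameters: the
acceptance script below averages REML heritability over 20 simulated
populations at the reference variance components (herd 0.141, additive
4.848, dominance 1.628, residual 13.426, all ×10⁻³) and obtains **0.2413**
against the expected 0.242.

A thin command-line wrapper over the same functions is installed at
`inst/cli/marelife.R` (subcommands `run`, `simulate`, `edit`, `project`,
`estimate`, `report`).

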