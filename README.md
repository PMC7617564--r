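# vsaslkin

Kinetic modelling of velocity-selective arterial spin labelling (VSASL)
perfusion MRI: estimate cerebral blood flow (CBF), **bolus duration** and a
residual macrovascular component per voxel from difference signals sampled
across label-to-crusher times (LCT), aggregate parameter maps over atlas
regions, compute cerebrovascular reactivity (CVR) from two-condition
(normocapnia/hypercapnia) acquisitions, and study what happens when the LCT
range is truncated. A multi-subject synthetic phantom generator makes the
whole pipeline testable without acquired data.

## Who this is for

ASL methods researchers and analysts who need a tested, reproducible
implementation of the two-compartment VSASL kinetic model — in particular
for questions where bolus duration matters: choosing an LCT for a
population, understanding CVR underestimation at long LCTs, or planning
hypercapnia experiments.

## The model

Tissue compartment (instantaneous bolus arrival; readout always follows
the vascular crusher, so only the post-delivery branch is needed):

    dM(t) = 2 * alpha * alpha_BGS * f * tau * M0 * exp(-t / T1b) * qp(t)
    qp(t) = exp(k t) * (1 - exp(-k tau)) / (k tau)
    k     = 1/T1b - 1/T1',   1/T1' = 1/T1 + f / lambda
    tau   = min(bolus duration, LCT)

plus a macrovascular step compartment

    dM_macro(t) = 2 * alpha * alpha_BGS * macroBV * M0 * exp(-t / T1b),  t <= tau_macro
    dM_macro(t) = 0,                                                     t >  tau_macro

with defaults alpha = 0.56, alpha_BGS = 0.86, T1b = 1.6 s, T1 = 1.3 s,
lambda = 0.9 ml/g; `t = LCT + 0.050 + 0.0425 * slice` for an ascending 2D
EPI readout. Fitting is unconstrained multi-start least squares (the macro
step parameter is handled by exact enumeration of its possible inclusion
sets — see the methods vignette, `vignettes/vsasl-kinetic-modelling.Rmd`).

## Worked example

Generate a noise-free grey-matter curve from published group parameters
(bolus duration 2.20 s, CBF 57 ml/100 g/min, macroBV 0.1%, macrovascular
bolus duration 1.22 s) at the 11-LCT resting protocol, then fit it back:

```r
library(vsaslkin)
tm <- acquisition_timing(c(0.55, 0.66, 0.8, 0.96, 1.15, 1.39, 1.67,
                           2, 2.4, 2.9, 3.5))
truth <- tissue_params(f = 57 / 6000, bolus_duration = 2.20,
                       macro_bv = 0.001, macro_bolus_duration = 1.22,
                       m0 = 1000)
dm <- delta_m_total(truth, tm$lct_values, 0L, tm, physio_constants())
round(dm, 3)
#>  [1] 3.952 4.273 4.583 4.821 4.973 4.617 4.560 4.337 3.550 2.404 1.505
fit <- postprocess_fit(fit_voxel(voxel_series(dm, tm$lct_values, 0L, 1000),
                                 tm, physio_constants()))
fit
#> VSASL voxel fit:
#>   CBF 57.00 ml/100g/min (f = 0.0095 ml/g/s), bolus duration 2.200 s
#>   macroBV 0.001 (0.100%), macro bolus duration 1.200 s
#>   sse 1.271e-13, 96 exploration runs, boundary FALSE
```

CBF and bolus duration come back exactly; the curve peaks near LCT 1.15 s
and decays with blood T1 once the trailing edge (2.20 s) has passed. The
macrovascular bolus duration reads 1.200 s, not 1.22 s: a step trailing
edge sampled at readout times 1.20 and 1.44 s is only identified up to
that interval, and the smallest consistent value is reported.

The a-priori power analysis behind the 19-subject hypercapnia design:

```r
required_sample_size(effect_size = 0.7, alpha = 0.05, power = 0.8)
#> [1] 19
```

A full synthetic study (simulate → fit → regional summary) from the
command line:

```sh
Rscript exec/vsasl simulate --preset experiment2 --seed 7 --out study/
Rscript exec/vsasl fit --study study/subject01/normocapnia --out maps01n/
Rscript exec/vsasl regions --study study/subject01/normocapnia \
        --maps maps01n/ --out regions.csv
Rscript exec/vsasl power --dz 0.7 --alpha 0.05 --power 0.8   # prints 19
```

## Layout

* `R/`, `src/` — forward model (R reference + compiled fitting core),
  fitting, masking/regions, phantom generator, CVR, power, NIfTI-1 I/O,
  YAML config, CLI.
* `inst/extdata/` — published region parameter tables and the
  background-suppression timing protocol fixture (CSV).
* `tests/testthat/` — unit, property and acceptance suites, with
  independent oracles (numerical convolution; chi-square-mixture power
  integration; nibabel cross-check for NIfTI).
* `vignettes/vsasl-kinetic-modelling.Rmd` — the model, every tunable
  parameter with units and defaults, what the phantom does and does not
  emulate, numerical choices, and known limitations.
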