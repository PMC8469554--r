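# pertflux

Perturbation-based modeling of autophagic flux from tandem
mCherry-EGFP-LC3 sensor time courses.

## What problem this solves

Chemotherapeutic drugs perturb autophagy, but *where* in the pathway a
given drug acts — and in which direction — differs between cell lines and
cannot be read directly off microscopy time courses. This package infers a
drug's mode of action by fitting a family of candidate kinetic models to a
panel of coded perturbation experiments and ranking the candidates by
goodness of fit.

The core model is a single-compartment mass-action chain

```
        k_form        k_conv        k_deg
  CYT ---------> AP ---------> AL ---------> sink
```

where AP (autophagosomes) are the mCherry+/GFP+ puncta of the tandem
sensor and AL (autophagolysosomes) the mCherry+/GFP- puncta (GFP quenched
at lysosomal pH). Every perturbing agent — starvation, bafilomycin, five
known autophagy modulators, and drugs of unknown action — is coded 1/0 per
condition and multiplies its target reaction's rate by (1+s) (activation)
or 1/(1+s) (inhibition). Known modulators carry literature-fixed targets
with free strengths; for each unknown drug, all 7 single modes (none, or
{formation, conversion, degradation} x {activate, inhibit}) are enumerated,
giving a family of 7^n joint hypotheses. Each member is fitted to the
observed AP/AL time courses by weighted least squares (weights 1/sigma^2
from each series' SD) using particle swarm optimization (swarm 50, up to
2000 iterations, stop at swarm SD 1e-6), and the family is ranked by
objective value; the top-ranked member names each drug's inferred mode.

Supporting stages implement the rest of the workflow: two-channel puncta
detection and AP/AL classification from images, Bliss-independence synergy
scoring of drug-modulator combinations, DAMP (ATP, calreticulin)
fold-change normalisation with an ATP standard-curve calibration, and a
synthetic-data generator (time courses and two-channel images with ground
truth) that makes the whole pipeline testable end to end.

## Worked example

Recover a known mode of action from noisy synthetic data:

```r
library(pertflux)

spec <- generation_spec(
  hypothesis = mode_hypothesis(c(EPI = "deg-")),  # truth: EPI inhibits degradation
  panel      = recovery_panel("EPI"),             # CM, STV, BAF, STV+BAF, EPI, EPI+BAF, EPI+STV
  cv = 0.1, replicates = 3, seed = 7)
gen  <- generate_timecourses(spec)
fits <- fit_hypotheses(gen$dataset, "EPI", control = pso_control(seed = 7))
rank_models(fits)$table
```

```
  rank hypothesis_id objective n_free
1    1      EPI:deg-  42.50237      1
2    2     EPI:form+  79.66226      1
3    3     EPI:conv-  80.04899      1
4    4      EPI:none  80.34599      0
5    5      EPI:deg+  80.36788      1
6    6     EPI:conv+  80.38968      1
7    7     EPI:form-  80.41157      1
```

The generating hypothesis ("EPI inhibits AL degradation") ranks first with
roughly half the weighted SSE of any competitor; `n_free` counts the free
parameters of each member's second fitting stage, and ties are broken in
favour of parsimony.

The simulator itself is exact and cross-checked against deSolve:

```r
steady_state(flux_params(10, 1, 2))
#>    AP    AL ratio
#>  10.0   5.0   0.5
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study's stages on
synthetic data and write tables under `results/`:

1. `01_simulate_panel.R` — three synthetic cell lines (distinct basal flux
   and drug modes), full 27-condition panel, 10% noise, 3 replicates.
2. `02_fit_hypotheses.R` — fits and ranks the full 343-member family per
   cell line (two-stage; a few minutes each); reports the best hypothesis
   and the rank of the generating truth.
3. `03_interaction_profiles.R` — viability tables, Bliss scores, ATP
   calibration and the tidy heatmap table.
4. `04_puncta_quant.R` — synthetic two-channel frames quantified to
   per-cell AP/AL counts and a time-course CSV.

Run them in order from the repository root after installing the package.

## Vignette

`vignettes/flux-modeling.Rmd` documents the model and its assumptions, the
modifier law, weighting and PSO internals, the two-stage fitting strategy,
the synthetic-data conventions, and known limitations.
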