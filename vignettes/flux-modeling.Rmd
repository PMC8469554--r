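---
title: "Perturbation-based modeling of autophagic flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-based modeling of autophagic flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pertflux)
```

## The model

Autophagic flux is represented as a single-compartment linear chain with
three mass-action reactions:

$$\varnothing \xrightarrow{k_{\mathrm{form}}} AP
  \xrightarrow{k_{\mathrm{conv}}} AL
  \xrightarrow{k_{\mathrm{deg}}} \text{sink}$$

$AP$ is the autophagosome pool (mCherry+/GFP+ puncta of the tandem
mCherry-EGFP-LC3 sensor), $AL$ the autophagolysosome pool (mCherry+/GFP-,
GFP quenched by the acidic lumen), and the sink accumulates degraded
material. The dynamics are

$$\frac{dAP}{dt} = r_{\mathrm{form}} - r_{\mathrm{conv}}\,AP,\qquad
  \frac{dAL}{dt} = r_{\mathrm{conv}}\,AP - r_{\mathrm{deg}}\,AL,\qquad
  \frac{dSINK}{dt} = r_{\mathrm{deg}}\,AL.$$

The cytoplasmic LC3 pool is treated as an unlimited source, so formation is
zeroth-order. This is a deliberate simplification: the sensor is expressed
ectopically and no depletion of the diffuse pool is evident in the assay;
making the pool dynamic would add a species that AP/AL data alone cannot
constrain. With it, all parameters are identifiable from the two observed
pools, and the steady state has the transparent closed form
$AP^\ast = r_{\mathrm{form}}/r_{\mathrm{conv}}$,
$AL^\ast = r_{\mathrm{form}}/r_{\mathrm{deg}}$, so the readout ratio
$AL^\ast/AP^\ast = r_{\mathrm{conv}}/r_{\mathrm{deg}}$ is independent of the
formation rate — a useful sanity check throughout.

### Perturbations

Each perturbing agent (starvation, bafilomycin, rapamycin, Torin-2,
wortmannin, Spautin-1, hydroxychloroquine, and the chemotherapeutic drugs)
is coded 1/0 per condition. An active agent with strength $s \ge 0$
multiplies its target reaction's rate by $(1+s)$ when activating and
$1/(1+s)$ when inhibiting; several active agents compose by product. The
functional form is a package choice (the modifier law is not dictated by
mass action): it is strictly positive, reduces to no effect at $s = 0$, and
saturates inhibition smoothly, and in log-rate space it is linear in the
design coding, which keeps the landscape tame. Known modulators carry fixed
(target, direction) assignments from the autophagy literature —
`agent_library()` — with free strengths; starvation carries two (formation
and conversion activation) because nutrient deprivation both induces new AP
synthesis and enhances lysosomal fusion.

### Solution and integration

The chain is linear with constant coefficients once a condition's effective
rates are fixed, so the package evaluates the exact solution (default
`method = "analytic"` in `simulate_flux()`), written in the numerically
stable building blocks $\varphi(c,t) = (1-e^{-ct})/c$ and
$\psi(c,d,t) = (e^{-ct}-e^{-dt})/(d-c)$ with explicit limits at $c=0$ and
$c=d$ (switched when $|d-c| \le 10^{-9}\max(c,d,1)$); the sink is obtained
from mass balance. A numerical route (`method = "lsoda"`, adaptive and
stiff-capable, rtol $10^{-8}$, atol $10^{-10}$) is kept as an independent
cross-check; the two agree to $\sim 10^{-8}$ relative in the tests, and all
steady-state acceptance checks run the numerical route against the closed
form. Negative excursions beyond tolerance are clamped with a warning.

### Initial condition

Conditions are simulated from the basal steady state of the candidate rates
($AP_0 = k_{\mathrm{form}}/k_{\mathrm{conv}}$,
$AL_0 = k_{\mathrm{form}}/k_{\mathrm{deg}}$, sink 0): cells are equilibrated
in complete medium before treatment starts at $t = 0$, and the untreated
control then correctly predicts flat time courses. The original estimation
setup does not state its initial condition; this is the package's choice.

### Observation model

Observed AP and AL quantities are compared to the species directly
(scales fixed to 1, data taken as pre-normalised): the assay does not pin
down whether counts, integrated intensities or normalised quantities feed
the fit, and free per-observable scale factors are confounded with
$k_{\mathrm{form}}$ in a fully free fit. `build_model(fit_scales = TRUE)`
exposes the scales as parameters for workflows that fix part of the
kinetics (e.g. scale calibration against a reference condition).

## Hypothesis family and estimation

A mode-of-action hypothesis assigns each drug one of 7 modes (none, or one
of 3 reactions $\times$ 2 directions); `enumerate_hypotheses()` builds the
$7^n$ joint family ($343$ for three drugs) with stable canonical ids such
as `CIS:deg-|EPI:conv+|PAC:conv-`. A flag allows $3^3$ per-drug
multi-reaction assignments instead; the default stays single-mode because
the reported best-fit models assign one dominant mode per drug per cell
line, and the joint multi-reaction family is combinatorially gratuitous.

The fit criterion is the weighted SSE
$\sum_{c}\sum_{t}\sum_{o\in\{AP,AL\}} (y - \hat y)^2/\sigma_{c,o}^2$ where
$\sigma_{c,o}$ is the observable's SD within the condition's data series —
the "standard deviation" weighting of COPASI-style parameter estimation.
Series that are constant up to round-off (the untreated control at steady
state) would otherwise get unbounded weight; their $\sigma$ is replaced by
the median positive $\sigma$ of the dataset.

Minimisation is by global-best particle swarm — swarm 50, iteration limit
2000, stopping when the swarm's objective SD falls below $10^{-6}$ —
with standard constriction coefficients (inertia 0.729, cognitive = social
= 1.49445), velocities clamped to 20% of each box range, and positions
clamped to bounds. Rates and strengths default to $[10^{-3}, 10^3]$ and are
searched in log coordinates: the landscape spans decades and linear-space
swarms cannot refine small rate constants. Two additions proved necessary
for reliable optima and are package design choices: a bounded local polish
(`nlminb`) after each PSO run (on by default), and multi-start for the
shared stage-1 fit (3 starts by default) because its 6-parameter landscape
is multimodal. Every stochastic call takes an explicit seed and is
bit-reproducible.

Two fitting strategies are provided. The default *two-stage* strategy fits
basal rates plus modulator strengths on the drug-free conditions once, then
freezes them and fits only each hypothesis' drug strengths on the
drug-containing conditions, finally scoring every member by the full-panel
objective so all hypotheses (including all-none) are comparable; this
mirrors how the drug-free panel is acquired first and decouples the family
combinatorics. *Joint* fitting of all parameters per member is available
and agrees with two-stage on clean data; whether the original study fitted
drugs jointly or drug-by-drug is not stated, and both are supported.
Rankings are by ascending objective with ties (within $10^{-6}$, the
stopping-SD scale) broken by parameter count then id — so the all-none
hypothesis wins ties against effect hypotheses whose strengths collapse to
zero, which is the parsimonious behaviour.

## Synthetic data

`generate_timecourses()` emulates the kinetic imaging assay: 5 time points
every 3 h over 12 h, a condition panel of single and double perturbations
(27 conditions by default; a compact 7-condition panel per drug for
recovery studies), multiplicative Gaussian noise $y(1+\varepsilon)$,
$\varepsilon \sim N(0, CV)$ truncated at 0, and replicate means/SDs
reported per point. Defaults — basal rates $(10, 1, 2)$ per hour, modulator
strength 4, drug strength 5 (a 5–6-fold rate change), CV 10%, 3 replicates
— are the study conditions of the recovery experiments; the true
replicate-to-replicate variability of the original assay is unknown, so the
CV is a convention, not an estimate. The generator reproduces the assay's
qualitative signatures (starvation raises the 12 h AL/AP ratio; conversion
blockade accumulates AP while AL drains), but it shares the fitted model's
functional form: recovery results certify the inference machinery, not the
biological adequacy of the three-reaction chain, and real data add
correlated cell-to-cell variability, photobleaching and segmentation error
that the noise model does not emulate.

`generate_images()` renders the imaging side: 512$\times$512 16-bit
frames, cells as cytoplasmic disks (radius 40–60 px), puncta as Gaussian
spots ($\sigma = 2$ px) — APs in both channels, ALs in mCherry only — with
Poisson-Gaussian noise; spot peak amplitude is `snr` times the background
noise SD. Ground truth (every spot with class and position) is returned
alongside, and a packing flag is raised if the requested spot density
cannot respect the minimum separation.

## Puncta quantification

Cells are segmented on the GFP channel (diffuse LC3-I makes cytoplasm
visible): Gaussian smoothing, Otsu threshold, hole filling, connected
components, small-object removal; background-only frames are rejected by
requiring the threshold to clear the noise floor by 3 robust SDs. Puncta
are detected on mCherry by difference-of-Gaussians at the expected spot
scale followed by local-maximum extraction; the search is restricted to an
interior eroded by $4\sigma_{\mathrm{spot}}$ because the cell boundary is
an intensity step whose filter response would otherwise drown real puncta.
The detection threshold is `k_det` (default 5) robust SDs of the in-cell
response; maxima closer than $3\sigma$ merge.

Classification is deliberately a local rule: a punctum is AP iff its mean
GFP over a small disk exceeds the cell's own background median by `k`
(default 3) standard errors, with background estimated from the cell's
pixels excluding all spot neighbourhoods. A global threshold would be
confounded by the diffuse cytoplasmic GFP level, which varies per cell.
Counts, not sizes, are the readout — puncta sizes change under blockade in
ways that do not track flux. Decreasing `k` monotonically converts AL calls
to AP calls, which the tests exploit as a property check.

## Interaction and DAMP profiles

Live fraction is PI-negative over total cells per well. The combination
null is Bliss independence on live fractions — expected combined survival
is the product of the single-agent survivals, exactly the "multiplied
effect" comparison of the cytotoxicity assay — and the score is expected
minus observed (positive = synergism). The classification threshold
$\tau = 0.05$ is a package choice: the assay colours a continuum and names
no cutoff. Heatmap cells aggregate replicates by the median. DAMP readouts
are expressed as fold increase over the untreated control; ATP readings
pass through a linear calibration on the kit standards (1–1000 µM), with
out-of-range readings flagged as extrapolated rather than refused.

## Numerical choices and limitations

Problem sizes in the tests and the reproduction script are the assay's
own: 5 time points, 7-condition recovery panels, 3 replicates, 20 seeds
per recovery condition, 20 synthetic frames for the imaging pipeline.
Degenerate inputs are handled explicitly: zero rates fall back to the
closed-form limits, zero-AP points yield flagged `NA` ratios rather than
infinities, all-inactive conditions reproduce basal rates exactly, and an
integration failure inside the objective scores $+\infty$ so the swarm
routes around it rather than aborting a family fit.

Known limitations: the chain has no lysosome pool, no GFP-quenching
photophysics and no spatial or stochastic vesicle dynamics; activities are
binary, so dose-response structure is out of reach; ranking is by raw
objective only (no information criteria — the family members the two-stage
strategy compares differ by at most a few parameters); and the modifier law
is one of several defensible choices, so fitted strengths should be read as
effect magnitudes on a particular scale rather than biochemical constants.
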