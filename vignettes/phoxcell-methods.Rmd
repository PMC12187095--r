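---
title: "Models and methods behind phoxcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phoxcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoxcell)
```

phoxcell analyses how extracellular pH (pHe) and oxygen partial pressure
(pO~2~) jointly shape the behaviour of cultured cells. It bundles four
analysis stages — pH-survival curve fitting, fluorometric metabolic flux
quantification, lysosome image analysis, and factorial proteomics — together
with seeded synthetic-data generators that emulate each stage's inputs with
known ground truth. This vignette explains the models, the tunable
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The biphasic Hill survival model

Growth across a gradient of starting medium pH is modelled as the product of
two cooperative proton-binding interactions: an activatory limb that removes
growth at acidic pH and an inhibitory limb that removes it at alkaline pH,

$$G(\mathrm{pH}) = g_{max}
  \cdot \frac{1}{1 + 10^{\,n_{up}(pk_{up} - \mathrm{pH})}}
  \cdot \frac{1}{1 + 10^{\,n_{down}(\mathrm{pH} - pk_{down})}}.$$

Each limb is a Hill function of proton concentration with binding constant
$10^{-pk}$ and Hill coefficient $n$; on the pH axis the limbs become
logistic sigmoids. The model therefore carries four shape parameters
(`pk_up`, `n_up`, `pk_down`, `n_down`) plus a maximum (`g_max`). The
product-of-sigmoids form is the minimal model with independently cooperative
activatory and inhibitory interactions; the functional form is otherwise
unconstrained, so this choice is the package's own.

Fitting details that matter in practice:

* **Normalization.** `normalize_growth()` rescales each replicate so the
  maximum of a monotone (Fritsch–Carlson) piecewise-cubic interpolant of
  absorbance versus pH equals 100%. The monotone interpolant cannot
  overshoot measured points, so the peak estimate is conservative.
  Whether to normalize first and fit with `g_max` free (the default) or fit
  raw absorbances with a shared maximum is exposed via `fix_g_max`; both
  modes are legitimate and equally defensible, so both are exposed.
* **Multi-start optimization.** The likelihood surface has flat ridges in
  the Hill coefficients. Midpoint starts are placed at the pH of
  half-maximal growth on each flank and Hill-coefficient starts at 1, 2 and
  4; the converged fit with the lowest residual sum of squares wins, ties
  broken towards the smallest $n_{up}+n_{down}$ (the least cooperative
  explanation).
* **Bounds.** Midpoints are constrained to pH 5.5–8.5 and Hill coefficients
  to (0, 10]: the physiological window, and a guard against runaway
  cooperativity on sparse flanks.
* **Degenerate inputs.** Strictly monotone curves cannot constrain both
  limbs. The fitter then drops the unidentifiable limb, returns `NA` for its
  parameters and flags `reduced_model`, rather than failing or silently
  returning a boundary solution.

Parameter recovery was verified on simulated plates (2% growth noise, three
replicates, grid 6.2–8.3 in 0.15 steps): median estimates across five
simulation seeds land within 5% (Hill coefficients) and 0.05 pH units
(midpoints) of the generating values. The falling limb of curves restricted
to the default 6.2–7.7 assay grid is only partially sampled when
$pk_{down} \approx 7.9$; recovery tests therefore extend the grid to 8.3,
which remains inside the physiological window.

## Fluorometric flux quantification

During metabolic profiling, cells sit in a weakly buffered medium under an
oil barrier, with a ratiometric pH probe (HPTS-type) and a collisionally
quenched O~2~ probe (RuBPY-type). The calibration model is standard:

* pH from the ratio, $\mathrm{pH} = pK_a +
  \log_{10}\frac{R - R_{min}}{R_{max} - R}$;
* pO~2~ from Stern–Volmer quenching, $pO_2 = (I_0/I - 1)/K_{SV}$;
* cumulative acid production $\mathrm{H}^+(t) = \beta V
  (\mathrm{pH}_0 - \mathrm{pH}(t))$ with buffering capacity $\beta$
  (mol L^-1^ pH^-1^) and volume $V$;
* cumulative O~2~ consumption $\alpha V (pO_{2,0} - pO_2(t))$ plus, when an
  oil-ingress rate constant is configured, the trapezoidal integral of
  $k_{in}(pO_{2,atm} - pO_2)\,\alpha V$.

Probe constants are instrument- and batch-specific and are configuration
inputs; the defaults (pK~a~ 7.2, ratio bounds 0.2–2.2, $I_0$ 1000,
$K_{SV}$ 0.025 mmHg^-1^, $\beta$ 2 mmol L^-1^ pH^-1^, $V$ 200 µL,
$\alpha$ 1.3 µmol L^-1^ mmHg^-1^) are the values used by the package's own
forward simulator, not measured constants. Buffering is treated as a single
constant $\beta$ because profiling runs under a CO~2~-free atmosphere, so
there is no open-system bicarbonate term. Negative cumulative values from
probe noise are retained: clipping would bias slope estimates.

The lactate coupling statistic relates end-point lactate to cumulative H^+^
across wells. Because fermentation releases one proton per lactate, purely
fermentative wells should fall on the identity line; `lactate_slope()`
reports the through-origin least-squares slope as the headline number (the
free-intercept fit and Pearson correlation are diagnostics). On simulated
fermentation-only wells spanning a fourfold rate range, sampled at 8 h and
17 h, the slope is 1.00 (tested to ±0.1). With a volatile (CO~2~) acid
share $f$, the slope drops to $1-f$, which the generator reproduces by
construction and the tests confirm.

The forward simulator integrates pH and pO~2~ with a fixed-step explicit
midpoint scheme at the sampling interval (15 min by default); tests verify
that halving the step changes trajectories by less than 0.1%. Respiration
tapers smoothly below 1 mmHg so the scheme cannot overshoot into negative
oxygen. An optional Hill-type attenuation of the fermentative rate at low pH
mimics the acute acid block of glycolysis.

## Lysosome image analysis

The imaging pipeline mirrors live-cell lysosome quantification: nuclei are
stained in one channel, acidophilic organelles in another.

* **Cell demarcation.** The cytoplasmic background (Gaussian-smoothed,
  sigma 3 px) is thresholded at an absolute level; small holes are filled.
* **Nuclear segmentation.** Otsu threshold of the smoothed nuclear channel,
  hole filling, then a watershed on the Euclidean distance transform of the
  mask. Distance-transform maxima act as seeds, so touching nuclei split
  along the saddle; a tolerance of 1 px (the minimum seed depth) was chosen
  because overlapping soft-edged nuclei produce shallower saddles than hard
  disks would, while clean single nuclei never carry spurious 1-px-deep
  maxima after smoothing.
* **Particle detection** is a two-stage circular Hough transform. Edge
  pixels (gradient magnitude above `min_gradient`, default 0.02 intensity
  fractions per pixel) vote along their gradient direction at a set of
  radial offsets; accumulator peaks above `sensitivity` become candidates.
  Because puncta are radially decaying (Gaussian-profile) spots with
  $\sigma = r/2$, the gradient-maximum ring of a particle of nominal radius
  $r$ sits at $r/2$; the `edge_scale` parameter (default 0.5) encodes this
  profile convention and would be 1 for hard-edged disks. Candidate radii
  are then re-estimated from the circularly averaged intensity profile as
  the distance at which it decays to $e^{-2}$ of its peak — the same
  convention, closing the loop. Circularity is scored as the fraction of 24
  perimeter directions carrying a supra-threshold gradient pointing back at
  the center; the target is 1.0 with a configurable tolerance (default
  0.35), since a strict 1.0 filter would reject every noisy particle.
  Duplicates within one radius of a stronger peak are merged.
* **Classification.** A radius–intensity classifier is trained from
  annotated particles: kernel-smoothed class-conditional densities
  (normal-reference plug-in bandwidths) combined with training-frequency
  priors yield a posterior surface; acceptance is posterior ≥ 0.5 by
  default. On synthetic data the annotation comes from the generator truth
  (`annotate_from_truth()`), standing in for the visual inspection that
  produces training labels on real data.
* **Statistics.** Lysosomes per cell divides accepted in-mask particles by
  the nucleus count of the field of view (whole-field normalization, not
  per-cell territories). Lysosome-to-nucleus distances are the Euclidean
  distance-transform values at particle centers (0 inside nuclei); the
  histogram's half-maximal-abundance position is found on the right flank of
  the mode by linear interpolation, and right-shifts of this marker flag
  peripheral redistribution. Cathepsin-activity counting reuses the
  detector on the activity channel and prunes particles whose mean
  fluorescence is strictly below 15% of saturation.

Sensitivity, circularity tolerance and the gradient threshold are
intrinsically instrument-dependent; the defaults here were tuned on the
synthetic generator to
give particle-level F1 ≥ 0.9 with per-cell count bias below 10%, and should
be re-tuned on real imagery. All analysis-path computations are
deterministic: no random numbers are drawn outside the generators.

### What the image generator emulates — and what it does not

`sim_fov()` renders soft-edged nuclear disks, a cytoplasmic background, and
puncta as Gaussian-profile spots placed in the annulus between nucleus and
cell edge, at a radial position drawn from a Beta distribution whose mean
shifts outward with `peripheral_bias` — this provides the ground truth for
the distance-histogram right-shift readout. Puncta are placed with a minimum
center separation (0.7 times the sum of radii) because lysosomes are solid
organelles; decoy particles (dimmer artefacts) overlap freely. Radii follow
a scaled Beta on 2–10 px matching the detector's acceptance window. The
generator does not model a microscope: no point-spread function, no
photon-counting noise, no axial structure, no uneven illumination. Passing
tests on synthetic fields therefore demonstrates the correctness of the
algorithms under their stated assumptions, not performance on real
micrographs.

## Factorial proteomics

The proteomics stage analyses a proteins × samples log~2~ label-free
quantification matrix under a 2 (pH) × 2 (O~2~) × 3 (batch) design.

* **Imputation** (`impute_minprob()`): missing entries are drawn from a
  narrow normal centered at the 1% quantile of the sample's observed values
  (spread: 1% of the sample SD, configurable) — the minProb model of
  detection-limit missingness. The spread is a free parameter of the method
  with no canonical value. Observed entries are preserved bit-exactly and
  the imputation mask is retained.
* **Differential abundance** (`fit_factorial_anova()`): per protein, a
  linear model with batch as a fixed blocking factor and sum-coded pH and
  O~2~ terms, so the acidosis main effect, hypoxia main effect and
  interaction are each a single degree of freedom; F-tests per effect are
  BH-adjusted across proteins per effect (not pooled across effects). The
  four pairwise condition contrasts are reported as log~2~ fold-changes
  with t-tests and their own BH family. Ordinary least squares is the
  default because it is exactly reproducible by hand (tests check the F
  statistics against brute-force sums of squares); `method = "moderated"`
  switches to limma's empirical-Bayes moderated statistics, which is what
  dedicated proteomics pipelines use and which materially increases power
  at n = 3 — analyses that select proteins at q < 0.05 (clustering, the
  correlation screen follow-ups) should use it. At three batches the
  difference is not cosmetic: a pH-dependent hypoxic response of ±2 log~2~
  units reaches ≥ 90% interaction power at q < 0.05 under moderation, while
  unmoderated per-protein tests fall well short; both routes are surfaced
  rather than hidden.
* **Correlation screen** (`correlate_with_reference()`): every protein
  against a designated reference row (the HIF-1α analogue), Pearson by
  default with a Spearman option, since both are common for this screen and
  neither is canonical; the reference is excluded from its own
  family and zero-variance rows are flagged out.
* **Clustering** (`cluster_hypoxic_responses()`): proteins significant for
  the hypoxia contrast at alkaline pH (or, in interaction mode, for the
  interaction) are standardized and clustered hierarchically on
  batch-averaged condition profiles. Ward linkage is the default: average
  linkage, tried first, chains adjacent response archetypes (partially
  versus strongly acid-suppressed) and degraded recovery; both remain
  available. Cluster letters are assigned by response pattern —
  hypoxia-upregulated groups from most acid-suppressed (A) to most
  acid-potentiated, downregulated groups last (D with the default four
  groups); interaction mode labels the selectively acid-hypoxia-induced
  group E. With four groups these semantics match the A–D
  response taxonomy such heatmaps are read by; exact group memberships are
  sensitive to estimator choices and are not asserted anywhere in the
  package.
* **Enrichment** (`fisher_enrichment()`): a one-sided Fisher exact test
  (hypergeometric tail) on the 2 × 2 set-by-category table over a common
  identifier universe, e.g. testing whether short-half-life proteins are
  over-represented among proteins downregulated under acidotic hypoxia.

The proteomics generator plants five response archetypes (A–D plus null)
with batch offsets and residual noise, and censors entries with probability
rising logistically as abundance falls below a low quantile — a standard
left-censoring stand-in; the real missingness mechanism of DIA proteomics is
not observed and not modelled further. Default archetype effects
(±2–3.5 log~2~) match the swing of canonical HIF targets.

## Ancillary assays

`ddct_fold_change()` implements relative qPCR quantification:
$\Delta C_t$ against a housekeeping gene (replicates averaged first, by
convention; a per-replicate mode is exposed), $\Delta\Delta C_t$ against the
control condition, fold-change $2^{-\Delta\Delta C_t}$, spread by the range
method over replicates. No amplification-efficiency correction is applied.
`proteasome_activity()` computes peak luminescence minus background over an
SRB growth normalizer; both common background conventions
(proteasome-inhibited wells; cell-free wells) are implemented and labelled,
with neither asserted as canonical. Background exceeding signal yields a
flagged non-positive activity, never a silent clip.

## Problem sizes, determinism and limitations

Test and acceptance runs use 256 × 256 pixel fields with 8 nuclei,
12-to-2000-protein matrices, and 12-well flux batches — sizes chosen so the
full verification cycle completes in minutes on a single core while leaving
every statistical check adequately powered. Every generator draws from its
own seeded stream and restores the session RNG state, so a seed fully
determines each output and generators never interfere.

Known limitations: the image pipeline is strictly 2-D and single-time-point;
the flux model has no CO~2~/bicarbonate speciation and treats respiration as
a single rate; survival fitting assumes independent errors across pH points;
the proteomics stage starts from a quantified matrix (no spectra, no peptide
inference); and all quantitative guarantees quoted above are statements
about the synthetic generators' assumptions.
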