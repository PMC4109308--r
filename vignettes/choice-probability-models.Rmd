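---
title: "Dissociating correlated noise from selective decoding in multisensory choice probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating correlated noise from selective decoding in multisensory choice probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Choice probability (CP) measures, with an ROC statistic, how well a sensory
neuron's trial-to-trial rate fluctuations at an ambiguous stimulus predict a
binary perceptual report. A CP of 0.5 means no relation; values above 0.5
mean the neuron fires more before choices toward its preferred stimulus.
Two very different circuit arrangements can produce CPs far from 0.5:

* **Pure correlation** — the neuron is never read out, but its noise is
  correlated with neurons that are. Its CP is inherited entirely through
  interneuronal noise correlations.
* **Selective decoding** — the neuron contributes to the decision with some
  weight, and shared noise within the decoded pool makes that contribution
  visible in single-trial activity.

Multisensory heading-selective neurons (as in dorsal medial superior
temporal cortex, MSTd) give these two accounts divergent signatures,
because *opposite cells* prefer one heading direction for vestibular
(inertial) motion and the other for visual (optic flow) motion. If all
cells are decoded according to their vestibular preference, opposite cells
should show CPs above 0.5 when the judgment relies on vestibular cues and
below 0.5 when it relies on visual cues — and how those CPs behave when
both cues are present separates the two models. `cpdecode` implements the
full simulation pipeline needed to play these models against each other:
synthetic populations, structured-noise trial generation, a weighted
maximum-likelihood decoder, CP and threshold measurement, and the
statistical toolbox for the model comparisons.

# The model components

## Tuning

Hypothetical populations use cosine tuning,
$f(\theta) = A\,(\cos((\theta - P)\,\pi/180) + 1)$, with amplitude
$A = 100$ spikes/s (peak 200, minimum 0) and preferred headings
$P = \pm 90^\circ$, so that tuning is monotone over the fine grid of
headings used in the discrimination task
($\pm 8, \pm 4, \pm 2, \pm 1, \pm 0.5, \pm 0.25, \pm 0.1, 0$ degrees; an
alternative preset replaces $\pm 0.25$ with $\pm 0.2$, matching the grid
onto which recorded tuning is interpolated). Populations are split into two
pools with equal numbers of leftward- and rightward-preferring cells; in
the multisensory variant pool 1 is congruent (same preference for both
cues) and pool 2 opposite (preferences 180° apart).

A neuron's *congruency index* is the product of the Pearson correlations
between rate and heading computed separately for the vestibular and visual
tuning curves: near $+1$ for congruent cells, near $-1$ for opposite
cells. Pairs of neurons are classified *matched* when the product of their
congruency indices exceeds $+0.2$, *mismatched* below $-0.2$, otherwise
*undefined*.

## Correlated noise

Noise correlations are assigned from tuning similarity,

$$ r_{noise,ij} = a_{vest}\, r_{signal,vest,ij} + a_{vis}\, r_{signal,vis,ij}, $$

with the empirically fitted coefficients $a_{vest} = 0.12$,
$a_{vis} = 0.09$ for MSTd-like populations and $0.1$ for both in the
hypothetical simulations. Masks restrict the rule to one modality
(`vestibular_only` / `visual_only`, the pure-correlation structures) or to
within-pool pairs. Because congruent–opposite pairs have
$r_{signal,vis} \approx -r_{signal,vest}$, near-equal coefficients cancel
across pools, which is what makes the two-pool selective-decoding model
internally consistent. The assigned matrix is repaired to positive
semidefiniteness by eigenvalue clipping with diagonal renormalization when
needed (the assignment rule does not guarantee feasibility), and factored
by its symmetric eigendecomposition square root $Q$, which unlike a
Cholesky factor exists for singular PSD matrices.

Single-trial rates follow proportional Gaussian noise,

$$ r = f(\theta) + \sqrt{1.5\, f(\theta)}\; Q\, z, \qquad z \sim \mathcal N(0, I), $$

so that response variance is 1.5 times the mean rate. Negative draws are
*retained* by default: rectifying at zero would distort the assigned
correlation structure, which is the object under study. A `rectify` switch
exists for sensitivity analyses. 200 trials per heading is the
conventional count.

## Decoding

Each trial is decoded with a factorized (correlation-blind) Poisson
log-likelihood over the heading grid,

$$ \log L(\theta) = \sum_i w_i\, r_i \log \max(f_i(\theta), f_0) - \sum_i f_i(\theta), $$

where $f_i$ is the *reference* tuning curve — the vestibular curve for
every condition by default, embodying the hypothesis that all cells are
decoded according to their vestibular preference — and $f_0 = 0.1$
spikes/s guards the logarithm at tuning nulls. Rates are treated as counts
in a one-second window. The second, bias-correcting term is left
unweighted, exactly as in the source formulation. The decoder reports
"right" when likelihood mass over $\theta > 0$ exceeds that over
$\theta < 0$ (0° excluded; exact ties broken by a seeded fair coin and
flagged). Anti-preferred readout of a pool is implemented by mirroring its
reference tuning about 0°, which keeps the Poisson likelihood well formed
rather than introducing negative weights.

## Readout weights

Three congruency-dependent weight rules are implemented, all driven by a
Readout Index RI in $[0,1]$:

* `ri_verbatim` — the exponential profile exactly as printed in the source
  formulation, $w = (1 - e^{-(c/2)RI})/(1 - e^{-1})$. It is negative for
  opposite cells and does not reach 1 for all cells at RI = 1; it is kept
  for reference and tested, but never used by the packaged experiments.
* `ri_additive` — $w = RI + (1 - RI)\,g(c)$ with the congruency sigmoid
  $g(c) = \mathrm{clip}[(1 - e^{-(c/2 + 1/2)})/(1 - e^{-1}), 0, 1]$. This
  satisfies the qualitative contract (all weights 1 at RI = 1;
  opposite-cell weight $\to 0$ as RI $\to 0$; monotone; in $[0,1]$) but
  gives every cell at least RI weight.
* `ri_power` (default) — $w = g(c)^{4(1 - RI)}$. Same boundary behavior,
  but opposite cells receive little weight at mid-range RI (about 0.02 at
  RI = 0.5, with congruent cells near 0.9).

The power profile is the default because of a quantitative property the
additive profile cannot reproduce: with opposite cells at half weight, the
coherent "anti-votes" they cast in the visual condition (where their
responses move against their vestibular reference tuning) inflate the
visual threshold several-fold at RI = 0.5, whereas the observed behavior
of the system being emulated is *roughly matched* vestibular and visual
thresholds at mid-range RI together with near-optimal cue integration.
Under the power profile both properties emerge.

## Metrics

CPs are computed only at the ambiguous 0° heading, splitting trials by
whether the decoder's choice matched the neuron's preference in the
analyzed condition (for the combined condition, the sign of the combined
tuning slope), with at least 5 trials per group. Neurometric thresholds
use the anti-neuron convention — ROC between $+\theta$ and $-\theta$
response distributions — and psychometric thresholds fit
proportion-rightward versus heading. Both fits are cumulative-Gaussian
maximum likelihood realized as probit GLMs; the threshold is the fitted
$\sigma$ (~84%-correct point). Degenerate data (uninformative or
perfectly separated) yield a bounded $\sigma$ and `converged = FALSE`.
The optimal cue-integration prediction is
$\sigma_{vest}\sigma_{vis}/\sqrt{\sigma_{vest}^2 + \sigma_{vis}^2}$.

## Inferential toolbox

* *Type II regression*: major-axis slope (leading eigenvector of the
  sample covariance), bootstrap-percentile 95% CI. Chosen over reduced
  major axis because the two variables (signal and noise correlation) are
  on a common correlation scale; neither variant is named by the source.
* *Sequential F-test*: reduced ($r_{noise} = a\,r_{sv}$) versus full
  ($r_{noise} = a\,r_{sv} + b\,r_{si}$) least squares without intercepts,
  matching the printed model forms; $F = (RSS_r - RSS_f)/(RSS_f/(n-2))$ on
  $(1, n-2)$ degrees of freedom.
* *Dispersion*: two-sided Ansari–Bradley rank test (exact for small
  samples, normal approximation otherwise).
* *Multimodality*: a critical-bandwidth kernel test. $h_k$ is the smallest
  Gaussian bandwidth making the density estimate at most $k$-modal;
  goodness of fit of the sample to the critically smoothed $k$-modal
  density is measured by Watson's $U^2$ on the fitted CDF and calibrated
  by bootstrap from the variance-rescaled smooth. The exact
  grouping-corrected statistic used historically on such data is not
  reconstructable for linear (non-circular) data, so the $U^2$
  distributional distance fills that role; because the null is fitted to
  the data, the test is mildly conservative, which is acceptable for the
  decision rule used ($p_{uni} > 0.05$ unimodal; $p_{uni} < 0.05$ and
  $p_{bi} > 0.05$ bimodal). The decision is invariant under affine
  rescaling of the data.
* *Cluster separation*: two-cluster K-means on scalar CPs (multiple
  restarts), $d$ = centroid distance.

# The synthetic MSTd-like generator

No recordings are distributed with (or used by) this package; the
MSTd-like population generator is a synthetic stand-in whose free
parameters are calibrated to published summary properties. Its design
choices matter, so they are spelled out:

* **Tuning form.** Per condition: baseline + signed slope + smooth ripple,
  rectified at 0. Baselines are log-normal (geometric mean 30 spikes/s).
  Slope magnitudes are derived analytically from target single-neuron
  neurometric thresholds: with variance $1.5 f$, a locally linear curve
  has $\sigma = \sqrt{3B}/(2|b|)$. Congruent-cell targets are geometric
  means of 7.1° (vestibular) and 5.5° (visual) with log-normal spread —
  the published congruent-cell values; opposite cells get the symmetric
  geometric mean in both modalities (nothing is published for them, and
  symmetry keeps either cue equally likely to dominate their combined
  preference); intermediates are weakly tuned in one random modality, with
  the weak correlation realized by *shrinking the slope* at normal ripple
  size (inflating the ripple instead makes cross-referenced decoding
  degenerate).
* **Bounded tuning diversity.** Ripples are drawn from a small shared
  two-function basis per population. This bounds the dimensionality of
  tuning diversity, so the tuning-similarity noise correlations become
  information-limiting and decoder thresholds plateau with population size
  — emulating the effect of resampling a finite recorded sample into a
  large model population. With fully idiosyncratic ripples the
  maximum-likelihood decoder exploits noise-orthogonal fine structure and
  thresholds fall without bound, which is not the regime under study.
* **Mirror pairing.** Neurons are generated in exact left/right mirror
  pairs, making the population balanced by construction and the decoder
  unbiased at 0°. At desk scale (hundreds of neurons) finite-sample
  imbalance otherwise produces deterministic choice biases that swamp CP
  measurement; at full scale the paired and unpaired constructions agree.
* **Cross-modal shape coherence.** Congruent and opposite cells share one
  tuning-linearity value across modalities, so a congruent cell's visual
  curve is (up to affine scaling and a coherence parameter, default 0.9)
  the same shape as its vestibular curve, and an opposite cell's its
  mirror image (coherence 0.5); intermediates get 0.7 against the
  orientation matching their slope signs. This cross-modal shape
  similarity is what lets a vestibular-referenced decoder read
  visual-condition responses coherently.
* **Combined-condition tuning.** The sum of the centered single-cue curves
  weighted by relative reliability ($w_k \propto b_k^2/B_k$), at
  single-cue rate scale, times a gain of 1.1. Congruent cells thereby gain
  sensitivity from their more reliable cue while opposite cells partially
  cancel; the gain is calibrated once so that the decoder's combined
  threshold sits at the optimal cue-integration prediction from its own
  measured single-cue thresholds — the published signature of
  near-optimal integration. Additive superposition was rejected (it
  doubles the rate scale and breaks vestibular-referenced decoding), as
  was an exact quadrature gain of $\sqrt 2$ (it makes the combined
  condition reliably *better* than the optimal prediction).
* **Class mix.** The congruent/intermediate/opposite fractions of the
  reference sample are not published; the default mix is 0.40/0.30/0.30.
  The synthetic pair generator uses its own, congruent-heavier mix
  (0.70/0.12/0.18), calibrated so the Spearman correlation between
  vestibular and visual signal correlations across pairs lands near the
  published 0.29.

What passing tests on these synthetic data do show: the qualitative and
ordinal machinery — CP sign patterns, their reversal with the correlated
cue or the decoding reference, the bimodal/unimodal dissociation in the
combined condition, threshold monotonicities, parameter recovery of the
correlation rule. What they do not show: agreement of absolute CP or
threshold magnitudes with any particular recorded dataset, robustness to
non-Gaussian spiking statistics, or behavior of tuning shapes outside the
fine ±8° range.

# Packaged experiments and problem sizes

The experiment drivers run at a desk scale chosen to keep every
sign/ordering property measurable in minutes on one CPU:

* `run_single_modality_models()` and `run_multisensory_hypothetical()`:
  200 cosine neurons, 100 trials per heading.
* `run_mstd_constrained_models()`: 200 neurons, the conventional 200
  trials per heading (single-neuron CP noise scales as
  $\approx 1/\sqrt{n_{trials}}$ and the distribution-shape battery needs
  it), pooled over 2 population replicates so the multimodality test sees
  ~120 opposite cells.
* `run_threshold_sweeps()`: RI grid 0–1 in steps of 0.1 at 200 neurons and
  200 trials; population-size sweep over 24–400 neurons with 3 replicates
  per size (threshold estimates are noisy enough at this scale that a
  single draw can mask the plateau).
* A `paper` profile (1000 neurons, 200 trials, `cp_profile("paper")`)
  preserves the full-scale sizes.

All randomness funnels through one master seed per entry point;
sub-seeds for population, trials and resampling are derived from it, so
regeneration is bit-identical and components can be varied independently.

# Known limitations

* The decoder is factorized (correlation-blind) by design; absolute
  sensitivities would differ for a decoder with knowledge of the noise
  covariance. A Fisher-linear-discriminant alternative is deliberately out
  of scope.
* The multimodality test's bootstrap null is fitted to the sample, making
  it conservative; borderline bimodality at small n may be missed.
* The pure-correlation readout for heterogeneous populations (weight 1
  for congruent-class cells, 0 otherwise) is one natural population analog
  of the two-pool scheme; the source does not specify the rule for cells
  of intermediate congruency.
* Trial rates, not spike trains, are simulated throughout; there is no
  point-process machinery.
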