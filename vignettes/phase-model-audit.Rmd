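---
title: "Auditing logistic models of phase state: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing logistic models of phase state: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseaudit)
```

## The model and its assumptions

Everything in this package revolves around the binary logistic regression

$$\operatorname{logit} P(E = \text{gregarious} \mid T)
  = \beta_0 + \beta_1 t_1 + \dots + \beta_k t_k,$$

fitted by maximum likelihood to one row per individual, with the phase (or
rearing environment) as outcome and continuous assay traits as predictors.
Geometrically the fit projects every phenotype onto a single latent axis:
the linear predictor. Two consequences drive the package's design. First,
very different phenotypes can share a position on that axis, so a scalar
"gregariousness" is only meaningful when all included traits genuinely
co-vary — which behavioral and morphometric phase traits do *not*, because
they respond to crowding on timescales of hours versus stadia. Every trait
therefore carries a mandatory `domain` and `timescale` annotation, and the
audit warns (`W_HYBRID_DOMAIN`) whenever fast and slow traits are mixed.
Second, the MLE only exists when no hyperplane separates the two phases;
with small limiting samples and many predictors, separation is not an edge
case but the expected failure mode, so it is treated as a first-class
result rather than an exception.

The fitting engine makes the usual LR assumptions: independent rows,
correct link, predictors measured without error. It deliberately does *not*
assume the design is well powered — quantifying what happens when it is not
is the point.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| IRLS deviance tolerance | 1e-8 | relative | explicit, platform-independent convergence rule; iteration counts are reported |
| IRLS max iterations | 100 | — | divergence under separation is detected long before this |
| separation epsilon | 1e-8 | probability | a fitted probability within 1e-8 of 0/1 counts as "numerically 0 or 1" |
| probability clamp | 1e-12 | probability | keeps log-likelihoods finite under separation; far inside epsilon, so diagnostics are unaffected |
| exact-check limits | n ≤ 500, k ≤ 15 | — | cost control for the LP feasibility check; heuristics alone beyond |
| collinearity threshold | 0.99 | \|r\| | flags only near-deterministic pairs; configurable |
| EPV verdicts | fail < 2, warn < 10 | events/coefficient | 2 is indefensibly low; 10 is the lower end of the conventional 10–20 minimum; both configurable |
| sample-size floor | 15 | events/coefficient | midpoint of the conventional band, used by `min_sample_size()` |
| pooling p-value | 0.15 | — | pooling strains requires a *decisively* non-significant LRT, not mere p > 0.05; configurable because it is a convention, not a law |
| bootstrap B | 1000 (200 in the audit default) | replicates | 200 keeps the full audit interactive; corrected indices from two seeds at B = 1000 agree within ±0.05 |

## Numerical choices

**IRLS.** Weighted least squares steps via QR (`lm.wfit`), weights floored
at 1e-10. Convergence is relative deviance change below tolerance. A
rank-deficient design at entry raises a classed error naming the aliased
terms — later-listed terms are the ones blamed, which makes predictor order
meaningful; a rank drop *during* iterations (weights collapsing under
separation) ends the loop with `converged = FALSE` instead. A warning worth
stating plainly: under complete separation the deviance tends to zero, so
the relative-change rule can report "converged" while coefficients diverge.
The separation report, not the convergence flag, is the arbiter.

**Separation classification.** `complete` when all fitted probabilities are
within epsilon of 0/1 and the max-absolute coefficient grew monotonically
over the final (up to) 10 iterations — mirroring the joint appearance of
the "did not converge" and "fitted probabilities numerically 0 or 1"
symptoms; `quasi` when only some rows are extreme; `nonconvergence`
otherwise when IRLS failed. On problems within the exact-check limits, a
linear program decides strict separability outright and overrides the
heuristics: minimize the total slack in
$s_i\,x_i^\top w + e_i \ge 1,\; e_i \ge 0$ (with $s_i = \pm 1$ by class);
the data are strictly separable iff the optimum is zero, because any strict
separator can be rescaled to margin 1. The LP is solved by a dense tableau
simplex with Bland's anti-cycling rule, written for this package:
deterministic, exact to tolerance, and adequate at these sizes (the slack
basis is feasible from the start, so no phase-1 is needed). A converged fit
the LP certifies non-separable is never flagged.

**Somers' Dxy.** Computed from midranks in O(n log n); the numerator is
assembled as the exact integer pair count C − D before the single division,
so the result agrees bit-for-bit with brute-force pair enumeration.

**Optimism bootstrap.** Unstratified row resampling; the entire modeling
procedure (complete-case filtering, standardization, fit) is repeated per
replicate, and each replicate model is evaluated on the original table.
Corrected Dxy = apparent − mean(training − test); corrected calibration
intercept/slope = mean of the original-table recalibration coefficients
(identical to apparent-minus-optimism since the apparent line is (0, 1) by
construction — stated explicitly because the measure's name does not pin
down the estimator). Replicates are excluded and tallied when the refit is
singular, fails to converge, is flagged for separation, or yields a
degenerate linear predictor; there are no replacement draws, so the
effective B varies and is reported. One integer seed initializes the
resampling stream; replicate b consumes the b-th consecutive draw, so any
run is exactly reproducible.

**Degenerate inputs.** Zero-variance predictors, constant linear
predictors, single-class outcomes, non-positive CV means and empty
phase-by-strain cells all raise early, named errors; they are contracts,
not crashes discovered late.

## What the generators emulate — and what they do not

`simulate_latent_axis()` implements the two-trait construction exactly:
$t_1, t_2 \sim U(-0.5, 0.5)$ independently,
$y' = \beta_0 + \beta_1 t_1 + \beta_2 t_2 + \epsilon$ with standard
logistic noise (drawn by inverse-CDF of uniforms for cross-platform seed
stability), environment B iff $y' > 0$. Defaults N = 800 and
$\beta = (0, 2.5, 5)$, making the LR model literally true with latent-axis
slope 2 over $t_1$.

`simulate_phase_population()` emulates the *structure* of a final-instar
crowding-assay dataset: 15 solitarious vs 51 gregarious individuals by
default; thirteen candidate predictors named after typical assay variables,
of which fast behavioral traits respond to crowding and slow morphometric
traits do not; a near-perfectly collinear speed/acceleration pair (target
r = 0.9998, achieved by adding Gaussian jitter whose variance is solved
analytically from the target); a side-of-arena indicator that encodes the
sign of the final coordinate (redundancy by construction); and a
configurable gregarious/solitarious femur-length ratio — 0.9 for the usual
shorter gregarious femur, 1.6 for the anomalous longer-legged gregarious
cohort under which dividing speed by femur length cancels the phase signal.
Trait values are Gaussian around phase-specific means chosen once to give
standardized phase differences between roughly 0.4 and 2; they are
*shape-alikes*, not calibrated measurements, and no claim is made about
real measurement scales beyond the documented pathologies.

The crowding response is an exponential saturation
$f(h) = 1 - 2^{-h/h_{1/2}}$ with half-time 4 h, inside the 4–24 h window
over which behavior converges on the gregarious pattern; only the endpoints
matter for the decoupling argument, so tests target endpoints, and the
functional form is a modeling convenience, not a claim. Labels record the
*natal* phase: a 24 h-crowded solitarious individual behaves gregariously
but keeps its solitarious morphology and label, which is precisely the
individual on which a hybrid model's prediction is shown to be
uninformative.

What passing tests on these data do **not** show: that real assay variables
are Gaussian (several, like ratios, are bounded), that real phase effect
sizes match the defaults, or that real behavioral traits are conditionally
independent given phase (here they are, except the planted collinear
pair). Conclusions about the *machinery* — separation detection, optimism
correction, EPV arithmetic, scale (in)variance — transfer; point estimates
of discrimination on real data do not.

## Design decisions that were genuinely open

* **Event level.** The modeled "event" must be named; if omitted, the
  alphabetically last outcome level is used with a warning, since the
  choice only flips coefficient signs.
* **Failed-replicate policy.** Excluding failed bootstrap refits biases
  corrected indices optimistically if failures correlate with extreme
  resamples; the alternative (replacement draws) hides the failure rate,
  which is itself diagnostic of an overstretched model. The failure
  fraction is therefore reported, never repaired.
* **Hybrid ratios.** A behavioral trait divided by a morphometric size
  trait is tagged domain `"hybrid"`, and the audit refuses a
  "non-morphometric" label for any model containing one
  (`W_NOT_NONMORPHOMETRIC`). This encodes, as behavior rather than prose,
  the fact that size-normalization re-imports morphological phase signal.
* **Feltz–Miller variant.** The asymptotic chi-square test (with
  $m_i = n_i - 1$ weights and the pooled-CV denominator
  $c^2(0.5 + c^2)$); exact or modified variants are out of scope.
* **Recommendation semantics.** `strain_generalization_compare()` returns
  an enum plus the numbers, never an automatic model choice, and returns
  `underpowered` whenever the crossed model's EPV audit fails — a
  non-significant interaction test from an underpowered design is not
  evidence that strains can be pooled.
* **Cross-stadium transfer.** Deliberately unsupported: a model fitted to
  one developmental stage, strain or species carries no warrant for
  another, and validating it there needs about as much data as refitting.

## Problem sizes in the shipped tests

The suite exercises: single fits at n = 66–800 with up to 14 coefficients;
200 replicate fits of the N = 800 latent-axis simulation (recovery is
asserted at 1.5% bias allowance plus three Monte-Carlo standard errors,
because the logistic MLE's O(1/N) away-from-zero bias — about +0.7% per
coefficient at N = 800 — is real and measurable at this replication depth);
50 bootstrap-validated low-EPV datasets at B = 200; 500 null simulations of
the strain LRT against $\chi^2_{k+1}$; 1000 randomized Dxy instances
against brute-force enumeration; and 100 random separability instances with
construction-based ground truth. These sizes were chosen to make the
stochastic assertions stable at conventional 3-sigma margins while keeping
the default run interactive.

## Known limitations

* No penalized fitting (ridge, LASSO, Firth): the package diagnoses the
  few-events/many-predictors problem; it does not attempt to fix it, since
  no shrinkage method creates information a sample of 15 does not contain.
* Quasi-separation is classified heuristically; the exact LP certifies only
  strict (complete) separation.
* The Feltz–Miller test is asymptotic; at very small n its chi-square
  calibration loosens.
* Corrected calibration summaries are linear (intercept/slope); no smooth
  calibration curves.
* The generators draw Gaussian traits; bounded or heavy-tailed real assay
  variables can behave differently in the tails.
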