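---
title: "MC DropWeak: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MC DropWeak: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the methods it implements:
the DropWeak stochastic regularizer, the Monte-Carlo (MC) uncertainty
decomposition built on top of it, the attention mapping, the synthetic
phantom generator used as the test bed, and the design decisions taken
where more than one reasonable reading existed.

## The DropWeak masking scheme

DropWeak combines three masking mechanisms in every stochastic pass
through a layer with weight tensor $W$:

1. **Node dropout.** Each output unit (for convolutions, each output
   channel) is dropped with probability $p$, via a Bernoulli keep mask.
2. **Per-weight dropping (DropConnect style).** Each weight entry is
   independently dropped with probability $\rho$ (a scalar or a
   per-weight array $\rho_{ij}$).
3. **Weak-weight zeroing.** Weights of low magnitude are set to zero for
   the duration of the pass, on the view that small weights mostly carry
   noise. This mask is a *deterministic* function of the weights and the
   rule — no randomness.

All three are applied as per-pass views over intact master weights, so a
dropped weight automatically "reactivates" on the next pass; nothing is
pruned permanently. The effective pre-activation of one pass is

$$z = m_{\text{node}} \odot \big[(M_\rho \odot M_{\text{weak}} \odot W)\,x + b\big],$$

with $M_\rho$ the Bernoulli weight mask and $M_{\text{weak}}$ the
weak-weight mask.

**Scaling.** Whether the surviving weights are rescaled is not specified
in standard descriptions of this combination, so the package makes it a
parameter. The default, `scale_mode = "inverted"`, rescales Bernoulli
survivors by $1/(1-\rho)$ and kept nodes by $1/(1-p)$, which makes the
masked pass unbiased for the dense pass,
$\mathbb{E}[z] = Wx + b$ — the property the MC averaging relies on and
the one the test suite verifies by simulation (4 standard errors at
20{,}000 draws). The weak mask is *never* compensated: it is a
deterministic shrinkage, not a sampling mechanism, and compensating it
would amplify the very weights the rule distrusts. `scale_mode = "none"`
exists so the reduction tests can compare bit-for-bit against plain
dropout and DropConnect.

**Weak rule.** Two rules are provided. `weak_absolute(tau)` zeroes
$|w| < \tau$ (strict, so $\tau = 0$ is a no-op). The default
`weak_quantile(q = 0.10)` zeroes the $\lfloor qn \rfloor$ smallest-
magnitude entries of each wrapped tensor: a scale-free choice that is
robust to weight-norm drift during training. Ties are broken by
ascending flat index so the mask is a total, deterministic function of
the weights. The 10% default is a deliberately mild setting — strong
enough to exercise the mechanism, weak enough not to fight the small
network's capacity.

**Per-weight drop schedules.** $\rho$ may be an array of the weight
tensor's shape, so drop probabilities can vary per weight. The shipped
default is a constant $\rho$, which keeps the estimator analysis clean;
`rho_magnitude_schedule()` is provided as an optional dynamic rule
($\rho_{ij} = \rho_{\max}\cdot$ rank percentile of $-|W_{ij}|$,
recomputable per epoch) since no canonical formula for a dynamic
per-weight schedule is established.

**Gradients.** Masks are treated as constants of the pass: gradients
flow to master weights through surviving entries only. A weight masked
in this pass receives no update from it but is fully available at the
next draw.

## The classifier

The classifier is a compact two-stage residual network for grayscale
patches (default $64\times64$): stem convolution and max-pool; residual
block 1 (two $3\times3$ convolutions, identity shortcut) whose
convolutions and the final fully connected layer are wrapped in
DropWeak; a transition convolution; residual block 2 regularized only by
plain node dropout on its pooled features; global average pooling and a
SoftMax head. The asymmetry — DropWeak on block 1 and the classifier
weights, plain dropout on block 2 — mirrors the architecture this
package operationalizes, in which one block carries the MC masking and
the other only conventional dropout.

At the default configuration the network has about 7{,}000 parameters
and trains from scratch in about a minute on one CPU core. Training
from scratch at desk scale, rather than fine-tuning a pre-trained
backbone at $256\times256$ for hundreds of epochs, is a deliberate
re-scoping: the contribution under test is the masking and estimator
machinery, not any particular set of weights, and every mechanism is
exercised identically. The full-scale reference settings (Adam at
$10^{-5}$, batch 16, 750 epochs, $256\times256$ inputs, 80/10/10
split) remain expressible through `train_config()` and the run
configuration; the desk defaults are Adam at $10^{-3}$, batch 16–32,
10–30 epochs. The learning-rate "factor of 0.2" is read as a
reduce-on-plateau multiplier with a patience of 10 validation epochs;
the best-validation checkpoint is returned. Standardization statistics
come from the training split only, to avoid leakage. Optional
augmentation (horizontal flip, ±10° rotation) is off by default.

One defensible reading of a "naive Bayes + ResNet" fusion is provided
behind a flag that is off by default: a Gaussian naive-Bayes model on
the global-average-pooled penultimate features, fused with the SoftMax
posterior by renormalized elementwise product. No canonical recipe for
such a fusion exists, so the package treats it as optional equipment and
keeps it out of every headline path.

## Monte-Carlo uncertainty decomposition

`mc_predict()` keeps all masks active at prediction time and runs $T$
stochastic passes; each pass draws one mask configuration that is shared
across the batch, which matches the view of a pass as a single draw of
weights from the approximate posterior. With per-pass distributions
$p_t$ and predictive mean $\bar p = \tfrac1T\sum_t p_t$:

* **predictive entropy** $H(\bar p)$ — total uncertainty;
* **aleatoric** $\tfrac1T \sum_t H(p_t)$ — expected per-configuration
  entropy, the irreducible part;
* **epistemic** $= H(\bar p) - \tfrac1T\sum_t H(p_t)$ — the mutual
  information between prediction and mask/weight configuration (the
  BALD decomposition), zero iff all passes agree.

Entropies are in nats (bounds are then simply $[0, \ln C]$); a bits
toggle exists for reporting. The identity
$H = \text{aleatoric} + \text{epistemic}$ holds exactly by
construction and is asserted against an independently coded brute-force
implementation at $10^{-12}$. The MI is nonnegative by Jensen's
inequality; floating-point residue below zero is clipped with the raw
value retained (`epistemic_raw`).

**Jackknife bias correction.** The plug-in entropy of an empirical
average is biased at finite $T$. The "leave-one-out" correction is
implemented as the classical jackknife over MC passes: for a statistic
$\hat\theta$ computed on all $T$ passes and $\hat\theta_{(-j)}$ on the
$T-1$ passes excluding pass $j$,
$$\hat\theta_{\text{bc}} = T\hat\theta - (T-1)\,
  \overline{\hat\theta_{(-j)}}.$$
It is applied to both terms of the MI. The aleatoric term is linear in
the passes, so the jackknife leaves it unchanged — a useful internal
consistency check that the tests exercise. The bias reduction itself is
demonstrated by simulation: one-hot passes from a known two-class
categorical at $T = 25$, 2{,}000 replicates, comparing the mean
absolute bias of the corrected and plug-in estimators against the
analytic entropy.

$T$ defaults to 25, the middle of the sample counts (10, 25, 50) under
which this family of models is typically profiled; the acceptance suite
checks that the spread of the predictive mean shrinks monotonically
across exactly those three counts.

**PH values.** The per-sample maximum of the predictive mean is exposed
as the "probability of hit" confidence score used to sort predictions
for selective classification. Because "accuracy threshold at 0.3 and
0.5" is ambiguous between the PH scale and the entropy scale, both
retention modes are implemented (`mode = "ph"` retains $PH \ge u$,
`mode = "entropy"` retains $H \le u$); entropy is the default and the
mode is recorded in every report.

## Grad-CAM

Standard Grad-CAM from a chosen convolutional stage: channel weights are
spatial means of $\partial s_c / \partial A_k$ where $s_c$ is the
**pre-SoftMax** logit of the target class (the usual choice; post-
SoftMax gradients saturate); the map is
$\mathrm{ReLU}(\sum_k \alpha_k A_k)$, bilinearly upsampled and
max-normalized to $[0,1]$. A raw map that is identically nonpositive
yields an all-zero heat map rather than a division by zero. The default
source layer is the last convolutional stage (block 2) — the standard
choice of the deepest spatial layer, which no convention here overrides.
The MC variant averages the per-pass maps *before* normalization, so
passes with stronger evidence weigh more; normalizing per pass first
would erase exactly that information. Gradient correctness is verified
against central finite differences at differentiable points — the test
deliberately probes strict pool-window maxima, since max-pool ties make
the score one-sidedly kinked and finite differences there test the
kink, not the gradient.

## The synthetic phantom test bed

The generator emulates just enough structure of a CT nodule-patch task
to exercise every mechanism with known ground truth, and no more:

* **geometry** — one bright nodule per patch; benign nodules are small
  discs (diameter 4–12 px) with a nearly smooth boundary, malignant
  nodules are larger (12–28 px) with low-order radial-harmonic boundary
  deformation as a spiculation analog. At the 1 mm ≙ 1 px desk mapping
  this covers the clinically conventional 3–30 mm range, with benign
  sizes concentrated low and malignant high. Nodule masks are returned
  as ground truth for localization tests.
* **background** — correlated Gaussian texture (FFT-smoothed white
  noise, normalized per image), a radial vignette, and i.i.d. pixel
  noise.
* **aleatoric sources** — label flips with probability
  `label_noise_rate` (clean labels retained) and the pixel noise. The
  default flip rate is 5%, a realistic annotation-error level that
  leaves the 90%-accuracy separability guarantee reachable (the
  noise-free ceiling is ~95%).
* **epistemic probe** — `generate_ood()` regenerates the same nodule
  and label process under shifted background statistics (default:
  doubled texture SD, inverted vignette), i.e. pure covariate shift
  with identical labels.

What passing tests on this bed does **not** show: anything about
Hounsfield calibration, 3-D context, scanner physics, annotation
protocols, or class imbalance at clinical prevalence. The bed
demonstrates that the estimators order uncertainty correctly when the
sources are injected by construction — a necessary condition, not a
clinical validation.

Problem sizes used by the test suite and the acceptance script were
chosen as the package's study conditions: $n = 2000$ images at
$64\times64$, 10–12 training epochs, $T = 25$ MC passes, 3-fold
cross-validation for the end-to-end accuracy check, and a reduced
16×16 phantom (n = 300) for unit-level fixtures.

## Numerical choices and degenerate inputs

* Entropy uses $0\ln 0 = 0$; simplex membership is checked at
  $10^{-6}$ on input rows.
* Quantile weak-rule ties: ordered by $(|w|, \text{flat index})$.
* Zero-denominator confusion ratios are reported as `NA`, never 0.
* ROC thresholds sweep the unique scores descending, ties entering
  simultaneously; AUC is trapezoidal and therefore equals the
  pair-counting probability with ties at ½.
* Fold aggregation rounds half-up to 2 decimals for report rows; raw
  means are retained alongside.
* A non-finite training loss aborts with a classed error that carries
  the last good checkpoint.
* All randomness descends from one root seed through named substreams
  (`data`, `masks`, `batches`, `folds`, …), so any stage can be
  reproduced in isolation and mask draws never perturb data draws.

## Known limitations

* The approximate posterior is mask-based only; no variational or
  MCMC weight inference is attempted.
* Weight masks are shared across a batch within a pass; per-sample
  weight masks would require per-sample effective weights and are not
  implemented.
* The jackknife corrects first-order bias of the entropy terms; the
  corrected MI can be slightly negative in small-$T$ regimes and is
  reported as computed.
* The residual topology is fixed (two stages); `channels` and input
  size are the architectural degrees of freedom.
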