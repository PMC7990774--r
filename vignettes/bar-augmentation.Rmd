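---
title: "Brain-area recombination for motor-imagery EEG: model, design, and limits"
author: "barEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-area recombination for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barEEG)
```

## The augmentation model

Two-class motor-imagery BCIs decode which limb a subject imagines moving
from the event-related desynchronization (ERD) of sensorimotor rhythms:
imagining the left hand attenuates 8--30 Hz oscillations over the right
motor cortex, and vice versa. Classifiers for this signal are
data-hungry, while calibration sessions are short; augmentation closes
the gap.

Brain-area recombination (BAR) rests on a single distributional
assumption: conditioned on the imagined class, the left- and
right-hemisphere channel blocks of a trial can be treated as
exchangeable across trials. If $x_i, x_j \in \mathbb{R}^{C \times T}$
are two trials of the same class, the chimera assembled from the right
block of $x_i$ and the left block of $x_j$,

$$\hat{x} = \big[\, x_i^{(R)} \;;\; x_j^{(L)} \,\big],$$

is taken to be another draw from the same class-conditional
distribution. The single-subject augmenter forms, per class, the full
cartesian product of right halves and left halves of the training set:
$n_c$ trials become $n_c^2$, of which $n_c$ are identity pairs
reproducing the originals. The multi-subject variant unions the
products over all ordered pairs of source subjects $(i, j)$ with
$i \neq s$, $j \neq s$ for a target subject $s$, producing a
pre-training pool that provably contains no data from the target.

Two conventions here were genuinely open and are package decisions:

* **Identity pairs are included.** The product reading of the definition
  retains $(i, i)$ pairs, so the augmented set is a superset of the
  originals and no separate concatenation step exists. Callers who want
  generated-only trials can drop rows with `is_original` in the
  provenance table.
* **Recombined trials are returned in montage order**, not as a stacked
  [right; left] block. The blocks are scattered back to their original
  channel indices so that any spatially aware consumer sees a consistent
  layout; the stacked notation is set-membership shorthand, not a memory
  layout.

## The hemisphere partition

Channels are assigned by the 10-20 naming convention: odd terminal
digits are left-hemisphere, even are right, terminal `z` is midline.
Midline electrodes, taken in montage order, are alternated between the
two sets starting with the left (1st, 3rd, ... midline to the left; 2nd,
4th, ... to the right), which splits $m$ midline channels
$\lceil m/2 \rceil$ / $\lfloor m/2 \rfloor$. Published splits sometimes
differ in where the alternation starts and are occasionally internally
inconsistent; the alternation-from-left rule is therefore a documented
default, and `hemisphereSplit(..., midlineOverride = )` reproduces any
explicit assignment. Extended 10-5 names with an `h` suffix are out of
scope; labels with embedded digits ("AF7") classify by the terminal
digit.

## Comparison augmenters

*Time flipping* reverses each trial along the time axis, exactly
doubling the set. It preserves every trial's FFT magnitude spectrum
while destroying temporal order — useful precisely because it isolates
whether a classifier exploits temporal structure.

*SNR-controlled Gaussian noise* adds white noise rescaled **per trial**
so that $\mathrm{var}(x) / \mathrm{var}(\eta) = \mathrm{SNR}$ holds
exactly (default 5, linear). Per-trial enforcement makes the printed
ratio a testable post-condition rather than an expectation; a decibel
interpretation is available via `snrInDb`. Version 1 adds one noisy
copy per original (expansion ratio 2, matching flipping); version 2
resamples source trials uniformly with replacement until the output
size matches a caller-supplied target, conventionally the size of the
matching BAR product, so that comparisons between augmenters are not
confounded by dataset size.

## The CSP baseline

Common spatial patterns seeks filters $w$ extremizing the variance
ratio $J(w) = (w' C_1 w)/(w' C_2 w)$ between the two classes'
covariances. Since $J$ is scale-invariant, the constraint $w'C_2w = 1$
pins the maximizer, and the stationarity condition yields the
generalized eigenproblem $C_1 w = \lambda C_2 w$. The implementation
whitens $C_2$ (symmetric eigendecomposition) and solves a symmetric
problem in the whitened space, which keeps eigenvectors
$C_2$-orthonormal by construction; the $k$ largest eigenvalues give the
class-1 filters, and the class-2 filters come from the swapped problem
$(C_2, C_1)$, which equals the reversed tail of the original spectrum.
Defaults and numerical choices:

* `k = 3` filters per class, the conventional choice for two-class
  motor imagery.
* **Covariance mode** defaults to per-trial trace-normalized averaging,
  which is robust to inter-trial amplitude drift; the pooled
  $\sum_i X_i X_i'$ form is retained as `mode = "pooled"` for literal
  fidelity to the textbook derivation. Both are tested.
* **Ridge regularization**: `reg = 1e-6` times the denominator's mean
  eigenvalue is added to its diagonal before whitening, guarding
  against rank deficiency when trials are few.
* **Sign convention**: each filter's largest-magnitude entry is made
  positive; eigenvalues sort descending with a stable tie-break on the
  original index.

The feature map after spatial filtering is not part of the CSP
derivation and had to be chosen: the package uses the field-standard
log normalized variance,
$f_j = \log\!\big(\mathrm{var}(w_j'X) / \sum_g \mathrm{var}(w_g'X)\big)$,
which is invariant to overall trial amplitude. The downstream
classifier is an SVM (RBF kernel, unit cost by default); kernel and
cost are explicitly configuration, not claims about any reference
implementation.

## Evaluation schemas

`runIS` (intra-subject) sweeps training-set sizes (default 10--100 in
steps of 10, 10 repeats each): per cell it draws a class-balanced
subset from the subject's training pool, augments it, fits the
classifier from scratch, and scores on the untouched held-out set.
`runAS` (adaptive) prepends a pre-training stage on the cross-subject
augmented pool (BAR-multi for BAR; flipping and noise act on the mixed
source pool, noise v2 resampling up to the matching BAR size) and then
fine-tunes on the target's own augmented subset via the classifier's
warm start.

Determinism is handled by a counter scheme: every cell derives its seed
from the master seed and `(subject, size, repeat)` through a
multiplicative hash (`deriveSeed`), so runs are bit-reproducible and
any cell can be replayed in isolation. Each repeat redraws the subset
*and* re-augments it — a fresh subset implies a fresh product.
Augmentation provenance makes leakage auditable: `auditLeakage`
verifies structurally that no record's training sources intersect the
test set.

The classifier contract (`fitClassifier` / `predictClassifier` /
`supportsWarmStart`) keeps the schemas classifier-agnostic. The
shipped reference is CSP+SVM — fast and deterministic, the right tool
for testing the pipeline itself. For the CSP+SVM pair, warm starting
is defined as freezing the pre-trained spatial filter bank and
refitting only the SVM on the target's features: the spatial filters
are the transferable, data-hungry component, while the decision
boundary is cheap to re-estimate. A compact-CNN plug-in (temporal,
depthwise-spatial, separable convolutions; 60 epochs, batch 16, Adam
with lr 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$) satisfies the same
contract but is deliberately not bundled: desk-scale acceptance should
not depend on GPU-class training.

## The synthetic generator

`simulateSubject` emulates exactly the statistical structure the
recombination assumption needs, and nothing more. Each trial is white
Gaussian sensor noise (SD 1) plus one band-limited oscillatory source
per hemisphere (8--12 Hz Butterworth-filtered Gaussian noise, unit SD,
scaled by `sourceScale = 2`), projected onto fixed unilateral
topographies peaking at C3 / C4. The class attenuates the amplitude of
the *contralateral* source by `1 - erdDepth` (default depth 0.6).
Oscillations are stochastic narrowband noise rather than sinusoids so
that trial-to-trial amplitude varies — variance-based CSP features need
amplitude statistics, not phase locking. The defaults (2.5 s at
100 Hz, 100 trials per class, mu-band amplitude about twice the
background) are chosen once as a realistic strong-ERD calibration
session; the no-signal control is `erdDepth = 0`.

Two deliberate idealizations define the gap between the generator and
real EEG, and hence what passing tests do and do not show:

* **Hemispheric sources are conditionally independent given the
  class**, and per-subject forward-model perturbations
  (`subjectMixingSd`, identity plus Gaussian noise) are restricted to
  within-hemisphere blocks. Under this model the recombination
  assumption holds *exactly* — recombined trials are true draws from
  the class-conditional law — so distribution-matching tests (e.g. the
  energy-distance check on band-power features) validate the
  implementation, not the assumption's truth on real brains, where
  volume conduction and interhemispheric coupling violate it to an
  unknown degree.
* No 1/f spectral shaping, no artifacts, no volume-conduction head
  model. Midline channels carry no source, keeping the partition
  exactly signal-separating.

## Problem sizes and tolerances

The test suite and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is meaningfully exercised:
cartesian-product checks at up to 20 trials/class; CSP-vs-brute-force
equivalence on 20 random SPD pairs at 6 channels (sampled lower bound
over $10^5$ random directions plus Nelder-Mead refinement from the best
sample — pure direction sampling alone cannot certify 3-decimal
agreement in 6 dimensions); topography recovery over 20 generator
seeds at 100 trials/class; schema integrity on a 4-subject cohort at
sizes {10, 20} with 2 repeats. Exact contracts (SNR enforcement,
cardinalities, bit-fidelity of recombined blocks, the closed-form
paired $t = 2\sqrt{3}$ for differences (1, 2, 3)) are asserted at
$10^{-6}$ or tighter; stochastic properties use fixed seeds and
pre-registered bounds (correlation > 0.8, accuracy > 0.9, 99% binomial
interval around chance).

## File formats

Epochs persist in a single-file, self-describing JSON container
(schema-versioned; dimensions, sampling rate, channel and class names,
labels, and the data flattened trial-major with 17 significant digits,
making the round trip bit-exact for doubles). Continuous input can
arrive as EDF plus a CSV marker table; the EDF reader is a minimal
16-bit parser requiring one common sampling rate. Provenance and
results tables are plain CSV; run logs are JSON.

## Known limitations

* Binary classification only; no one-vs-rest CSP, filter-bank CSP, or
  Riemannian variants.
* The hemispheric split is the only recombination geometry; other
  channel partitions (e.g. anterior/posterior) are unexplored here.
* Causal single-pass filtering is the default so the realized order
  equals the design order; zero-phase filtering is a flag
  (`zeroPhase = TRUE`), and whether to filter continuous data before or
  after epoching is the caller's choice (filter-then-epoch is the
  default pipeline order in the CLI).
* The generator's independence idealization means augmentation
  *cannot fail* distributionally on synthetic data; conclusions about
  real-EEG gains require real recordings.
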