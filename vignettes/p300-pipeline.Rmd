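---
title: "The p300bci pipeline: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The p300bci pipeline: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic sessions, the feature geometry,
the five classifier families, and every numerical decision a maintainer
might want to revisit. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The generative model

A session follows the oddball speller design: `n_targets` TARGET symbols
(default 8), each presented over `n_repetitions_per_target` repetitions
(default 8) of `flashes_per_repetition` flashes (default 12), of which
`target_flashes_per_repetition` (default 2) contain the TARGET. The
defaults therefore produce 128 TARGET and 640 NON-TARGET trials on 16
channels at 128 Hz — the full-scale condition the acceptance suite checks
exactly.

**P300 template.** The evoked response is a Gaussian bump
`a · exp(-(t - t₀)² / 2σ²)` with peak latency `t₀ = 0.35 s` (inside the
physiological 240–600 ms window), full width at half maximum
`width = 0.2 s` (so `σ = width / 2.355`), and amplitude `a = 5 µV` — a
typical single-trial P300 magnitude. Only the latency range is
physiologically constrained; the Gaussian shape is a modelling choice,
chosen for smoothness and an analytically known edge decay (the template
is below 1 % of its peak at both window edges). The bump is scaled per
channel by `spatial_profile`, a parieto-central topography peaking at Pz
and Cz on the standard 16-channel montage, because the P300 is maximal
over centro-parietal sites.

**Noise.** Each channel carries independent pink (1/f) Gaussian noise of
RMS `noise_scale` (default 4 µV) plus a 0.3-weighted common-mode pink
term shared by all channels; EEG background activity is empirically
1/f-like and spatially correlated. The same noise process drives both
classes — all class information enters through the template. Setting
`amplitude = 0` therefore yields exact null data, which is how the
calibration tests construct their chance-band world.

**Timing.** Flashes are `isi = 0.4 s` apart. The design leaves the
inter-stimulus interval unspecified in the source experiment; 0.4 s is a
conventional oddball rate. Since the 0.6 s analysis window exceeds the
ISI, consecutive epochs overlap and TARGET templates are added
additively, as in real rapid-presentation streams.

**What the generator does not emulate.** Eye-blink and muscle artifacts,
inter-subject and inter-session variability, latency jitter of the P300,
volume-conduction mixing beyond the fixed spatial profile, and
non-stationarity. A green calibration test therefore establishes that the
pipeline is unbiased and leak-free under a well-behaved null — not that
it survives real recording conditions.

## 2. Preprocessing

The band-pass is a Hamming-window FIR design with edges at 1 and 24 Hz.
The tap count derives from the transition width (a quarter of the edge
frequency, clamped between 2 Hz and the distance to DC/Nyquist) by the
standard Hamming approximation `n ≈ 3.3 · fs / Δf`. The design is
applied forward and backward after reflect padding, so the net group
delay is zero and the effective attenuation is the squared single-pass
response. "Zero-phase with a Hamming window" admits both a one-pass
(delay-compensated linear-phase) and a two-pass reading; the two-pass
version was fixed here and is what the response tests assert.

**Sample convention.** The epoch of an onset at sample `s` covers the
half-open index range `[s + floor(tmin·fs), s + floor(tmax·fs))` — 77
samples for 100–700 ms at 128 Hz. Inclusive-end conventions (78 samples)
are equally defensible; what matters is that one convention is fixed,
stated, and used everywhere, since downstream shapes (4 × 4 matrices,
10-element vectors) do not depend on it.

## 3. Feature geometry

Per-class xDAWN filters solve
`max_w (wᵀ Σ_evoked w)/(wᵀ Σ_signal w)`, with `Σ_evoked` the covariance
over time of the class-average evoked response and `Σ_signal` estimated
from the concatenated epochs (not the continuous record — epochs are what
the classifier will ever see) with `1e-8` diagonal loading. Eigenvector
signs are fixed so the largest-magnitude coefficient is positive,
making fits scale- and order-reproducible. With one filter for each of
the two classes, a filtered epoch has 2 virtual channels; stacking the
filtered TARGET prototype on top gives a 4 × T super-trial. Its sample
correlation matrix (rows mean-centered — the standard definition,
configurable) is shrunk as `(1-ε)C + εI`, `ε = 1e-6`: correlation
matrices of finite samples are almost surely positive definite already,
and the minimal loading guarantees it without visibly moving any entry.
A constant row would make correlation undefined; such rows receive
`1e-12` jitter and a warning rather than an error, because zero-variance
virtual channels can arise from degenerate inputs the caller may still
want processed.

The tangent projection at base `G` is
`v = w ∘ vech( logm(G^{-1/2} C G^{-1/2}) )` with weight `√2` on
off-diagonal entries, so `‖v‖₂` equals the affine-invariant Riemannian
distance `d(C, G)` — the property the round-trip and distance tests rely
on. `G` is the Karcher mean (gradient iteration from the arithmetic mean,
tolerance `1e-8`, 50 iterations, shared with the MDM classifier), always
fitted on training folds only.

The reduced "correlation vector" drops the unit diagonal and the
prototype–prototype block — entries that are constant across trials of a
session because they depend only on the shared prototype — keeping the
prototype × epoch cross-block and the epoch-block off-diagonals (5
entries at n = 4). The source text places the redundant block
inconsistently (upper-right in prose, upper-left in the displayed
matrix); this implementation removes the prototype–prototype block
wherever it sits, since its trial-independence is the stated reason for
removal.

## 4. Classifiers

**MDM.** One Karcher mean per class; prediction is the nearest mean in
affine-invariant distance. Ties go to the first class in training order
(a documented, arbitrary choice).

**SVM.** RBF kernel with the `1/(d·var)` width heuristic, C = 1. No SVM
solver exists in the dependency budget, so the dual is solved by a
compact sequential-minimal-optimization routine; the same solver backs
the quantum-kernel classifier, keeping the two comparable.

**HCBR.** Feature vectors are rounded to `digits = 4` decimals and
tokenized as (index, value) pairs; rounding makes nearly equal values
collide so cases can intersect. Tokens with identical case-membership
signatures form the partition cells; `W[j,i]` is the fraction of case
*j*'s tokens in cell *i* (rows sum to 1), and the signed cell strength
`μ` starts from the overlap-weighted class balance `Wᵀy`, normalized to
`‖μ‖₁ = 1`. Then `l0 = 1` correction passes shift `μ` mass (step
`η = 0.1`) along the rows of misclassified cases. The update rule and
initialization are reconstructions — the source method defers them to
its own reference — and both are exposed as configuration. The
lexicographically second class is the positive (support > 0) class, a
convention that makes fits order-invariant; a query intersecting no cell
abstains and receives the majority training class (abstentions count as
errors in balanced accuracy — the conservative choice). A `1e-12` band
around zero support keeps the correction pass independent of
floating-point summation order.

**Quantum classifiers.** States are exact complex statevectors; qubit
*i* carries bit weight `2^(i-1)`. The feature map applies, per
repetition (default 2), Hadamards on all qubits, phase `2xᵢ` per qubit
and pair phase `2(π-xᵢ)(π-xⱼ)` on linearly entangled pairs — compiled,
as in the standard circuit, onto odd-parity basis states. All phase
gates of a repetition commute and are fused into one diagonal; the
entangling CZ layer of the ansatz is likewise a precomputed ±1 diagonal,
and batched trials share every gate application. Correctness is pinned
by an independent dense-matrix oracle (explicit Kronecker-product gates,
including CX–P–CX pair terms) at ≤ 4 qubits to 1e-10. One caveat worth
recording: after the *second* repetition's Hadamard layer the pair
phases interfere, so amplitude magnitudes are uniform only for a
single-repetition map — a property the tests assert in that form.

The fidelity kernel is `|⟨Φ(x)|Φ(y)⟩|²`; shot mode replaces each entry
by a seeded binomial draw at `R` shots, which is exactly the sampling
distribution of the compute–uncompute estimator. The VQC applies a
two-local ansatz (ry/rz rotations, full CZ entanglement, reps = 3, hence
`(3+1)·n·2` parameters) and reads out bitstring parity. Training
minimizes cross-entropy by SPSA with gain sequences
`a_k = a/(k+1+A)^0.602` and `c_k = c0/(k+1)^0.101`, `A = 0.1·maxiter`,
two evaluations per iteration, seeded Rademacher directions. The
canonical setting `c0 = 4, maxiter = 40` is honored as given; note that
in the optimizer library the source study used, the constant named `c0`
is the *step-size* numerator while the perturbation defaults to 0.1 —
the mapping chosen here (c0 = perturbation) follows this package's
documented contract, and both gains are exposed. Because ±4-radian
perturbations can walk away from a good region, the fit keeps whichever
of the start and the final iterate decides the training set better
(a guarded update), then selects the parity-to-label orientation and the
bias `b` on a `[-1, 1]` grid (step 0.05) by training balanced accuracy.
The orientation freedom is the readout's label map; without it the model
family could not represent label-inverted problems.

## 5. Evaluation

Balanced accuracy is the mean of per-class recalls — 0.5 for any
constant predictor regardless of the 640:128 imbalance. Folds are
stratified (per-class round-robin after a seeded shuffle, so per-fold
class counts deviate by at most one trial) and shuffled; stratification
is stated in the source protocol only for the permutation test, and
extending it to the main CV is the safer default for imbalanced data.
The permutation threshold permutes labels, refits the *entire* pipeline
(xDAWN onward) per permutation, and takes the empirical nearest-rank
0.975 quantile of the cross-validated scores. The quantile estimator is
unspecified in the protocol; nearest-rank is the simplest consistent
choice. The pairing of "0.975 quantile" with "α = 0.05" reads as a
two-sided convention applied to a one-sided question; the quantile is
implemented exactly as stated. A dual-route test compares this
permutation threshold with the 0.975 quantile of scores on fresh null
sessions and documents a real subtlety: because epochs overlap in time
(0.4 s between flashes, 0.6 s analysis window) and the noise is
autocorrelated, a label permutation that happens to clump "TARGET"
labels in time produces a class that shares slow noise and is genuinely
more predictable than the evenly spread true labels. The permutation
threshold therefore sits somewhat above the marginal null quantile —
i.e. it is conservative, which preserves the validity (if not the full
power) of the significance call. In the real speller design the
evenly-spaced randomization of targets is exactly what underwrites
exchangeability; the synthetic world reproduces that tension.

**Scale reductions in the test suite.** The full-scale protocol
(10 000 permutations, 768 trials, SPSA maxiter 40) is reachable through
configuration, but the suite runs 200 permutations, 120-trial null
sessions and VQC maxiter 10 to stay inside a CI budget; these reductions
are marked where they occur and change granularity, not logic.

## 6. Known limitations

* The HCBR update rule is a faithful-in-spirit reconstruction, not the
  authors' exact algorithm; conclusions about HCBR's ceiling should not
  rest on it.
* Shot-mode sampling draws from exact probabilities; it models sampling
  noise but no hardware noise or decoherence.
* The SMO solver targets small kernel problems (hundreds of trials); it
  is not tuned for large-scale SVM work.
* On rounded tangent features HCBR memorizes training sessions (training
  balanced accuracy 1.0) while generalizing near chance — visible in the
  high-SNR tests. This mirrors the behavior the method shows on real
  single-session data and is a property of token-exact matching on
  continuous features, not a defect of the fit.
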