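---
title: "Cross-session and cross-subject workload alignment for fNIRS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-session and cross-subject workload alignment for fNIRS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A continuous-wave fNIRS headset records two-wavelength light attenuation over
the prefrontal cortex while a participant performs n-back working-memory tasks
(n = 0, 1, 2, 3). After conversion to oxy- and deoxy-hemoglobin concentration
changes, each session yields a multichannel time series with one task label
per sample. A classifier trained on one session or one subject transfers
poorly to another: baselines drift, optode placement changes, channels are
dropped for poor signal quality (so the data dimension itself changes), and
physiology differs across people. `gwalign` treats this as a domain-adaptation
problem solved with optimal transport on the *within-domain geometry* of the
data, which never requires the two domains to share a feature space.

# The model

**Segments and features.** Task data are cut into non-overlapping windows of
`w = 60` samples (about 8 s at 7.81 Hz). A segment is the `d x w` matrix of
stacked delta-HbO2 and delta-Hb rows, so `d` is twice the retained channel
count. Each segment `i` is summarized by its sample covariance `P_i` (with
shrinkage, below) and mean vector `h_i` — the second-order features that carry
workload information in EEG/fNIRS practice.

**Inner metrics.** Within one session, segment pairs are compared with

* session metric: `( rho_H(P_i, P_j) + ||h_i - h_j||_2 ) / d`,
* subject metric: `rho_H(P_i, P_j) / d`,

where `rho_H` is the matrix Hellinger distance
`rho_H(A, B) = { tr(A) + tr(B) - 2 tr[(A^{1/2} B A^{1/2})^{1/2}] }^{1/2}`,
evaluated through the nuclear norm of `A^{1/2} B^{1/2}`. The mean term is
dropped for cross-subject work because baseline mean structure is
subject-specific, while covariances can be compared as points of a common
cone. Division by `d` makes sessions with different retained channel counts
comparable.

**Session-by-session transfer.** Given a labeled source session and an
unlabeled target session of the same subject, both `N x N` inner distance
matrices are coupled by entropic Gromov–Wasserstein: find a transport plan `T`
with uniform marginals minimizing the squared-loss structure objective
`sum L(Cs_ii', Ct_jj') T_ij T_i'j' - lam H(T)`. The plan is binarized by
column argmax (ties to the lowest row index) and source labels are pushed
through it.

**Subject-by-subject transfer.** All labeled sessions of a source subject are
condensed into a fused Gromov–Wasserstein barycenter: a Fréchet mean under the
FG-W distance, which augments the structure cost with a squared label-matching
cost weighted by `1 - alpha`. Block coordinate descent alternates coupling
solves with closed-form updates of the barycenter distance matrix and label
vector (session weights even, histograms uniform). The real-valued barycenter
labels are rounded half-up to the nearest class. Each target session (mean-free
metric) is then aligned to the barycenter exactly as in the session mode.

**Scoring.** Accuracy is the fraction of correctly labeled target segments;
chance is 25% for four balanced classes. Reports aggregate all ordered session
pairs (within subject) or each source subject against every other subject's
sessions, with row-normalized confusion matrices, inverse-variance weighted
mean ± standard error across subjects, and one-sample/paired t-tests. A
merged variant pools 0- with 1-back and 2- with 3-back into low/high workload;
merging both truth and prediction can only convert within-pair confusions into
hits, so it never lowers accuracy.

# Artifact removal

Motion artifacts appear as transient spikes and step discontinuities. Each
channel is decomposed as `y = f + s + S u + r`: a low-pass signal `f`, sparse
spikes `s`, sparse step increments `u` (`S` = cumulative sum), and noise. The
convex objective

`1/2 ||H(y - s - S u)||^2 + lam_s ||s||_1 + lam_u ||u||_1`

uses the high-pass complement `H = I - L` of a symmetric banded smoother
`L = (I + rho D'D)^{-1}` whose -3 dB cutoff is `fc` (default 0.15 Hz), so the
low-pass signal itself is never penalized. It is minimized by monotone FISTA
(objective non-increasing by construction); cleaned data subtract only
`s + S u`. Two design choices matter:

* *Smoother order.* The penalty uses second differences by default
  (`filter_order = 2`). A first-order penalty biases the fit toward flatness
  at the series edges, and the resulting boundary misfit leaks into the step
  component (on an artifact-free slow sinusoid the steps absorbed ~20% of the
  signal's energy); the curvature penalty recovers artifact-free inputs with
  essentially empty artifact components.
* *Debiasing refit.* After the sparse solve, amplitudes on the detected
  spike/step support are re-estimated by unpenalized least squares
  (`refit = TRUE`). Soft thresholding otherwise leaves shrunken residual
  steps that defeat the purpose of cleaning: on the artifact study below the
  cleaned-versus-truth RMSE is 0.5 uM with the refit and 4.3 uM without.

The thresholds are `lam_s = beta * sigma` and `lam_u = step_weight * beta *
sigma`. `sigma` is the standard deviation of the *high-pass residual* of
artifact-free data — not the instrument noise floor — and `beta` should place
the threshold near the extreme-value scale of that residual over a whole
session, because a single false step that persists for minutes distorts more
energy than many small misses. `theta` parameterizes the optional nonconvex
(firm/MCP) penalty; the convex l1 penalty is the default for reproducibility.

# The synthetic study

No recordings are distributed, so the package generates its own study with the
statistical structure the alignment relies on, at the protocol scale of a real
n-back session: a 155 s baseline, four 200 s task blocks (1562 samples at
7.81 Hz) in randomized order with 30 s rests, and a 155 s tail.

Within a task block the `d = 2 x n_channels` stacked rows follow a stationary
AR(1) process (`ar_coefficient = 0.5`) whose marginal covariance and mean are
the class covariance and class mean. Defaults encode a graded workload
response: a common exponentially-correlated base covariance (0.25 uM^2
variances) scaled by `1 + 0.3 n` per level plus a class-specific rank-one
pattern, and means shifted by 0.4 uM per level along a fixed smooth spatial
pattern. Blockwise mean transitions are ramped with an 8 s raised-cosine
window, since hemodynamic responses do not jump sample-to-sample (and an
instantaneous transition would be indistinguishable from a step artifact).
Slow sinusoidal trends (0.5 uM, 0.005–0.02 Hz), white noise (0.1 uM), and
optional Poisson spike/step artifacts are added on top.

Domain shift has two levels, with defaults chosen once to land in the regime
the method is built for — both transfers clearly above chance, and the
cross-subject problem strictly harder than the cross-session one:

* *Session level*: per-channel gain jitter (5%), a mean drift shared by all
  classes of the session (0.2 uM), and channel dropout (10% per channel, both
  hemoglobin rows dropped together), which exercises the unequal-dimension
  capability.
* *Subject level*: a feature-space rotation (Givens angles, sd 0.3 rad), a
  baseline offset (0.5 uM), a subject-specific channel subset (16–20 of 20),
  and — the decisive ingredient — a per-class covariance dispersion
  (`class_dispersion = 0.25`): each subject rescales every class covariance by
  `exp(N(0, 0.25^2))` and adds a random rank-one deformation. A common
  rotation alone would leave the Hellinger inner metric exactly invariant
  (the distance is unchanged under joint congruence by an orthogonal matrix),
  so without this term the subject problem would be spuriously easy.

What the generator does *not* emulate: hemodynamic response functions,
systemic physiology (cardiac, respiratory, blood-pressure waves), optical
photon transport, or realistic spatial channel correlations from shared
optodes. Passing the package's checks therefore demonstrates that the
pipeline recovers structure *of the kind it assumes*, not performance on real
recordings. Within-class temporal autocorrelation is exposed as
`ar_coefficient` rather than asserted, as no reference value is available.

# Numerical choices

* *Covariance shrinkage* (`shrinkage = 0.05`): `P + shrinkage (tr P / d) I`.
  With all 20 channels retained, `d = 40` and `w = 60` give an
  ill-conditioned (and for `d > w` rank-deficient) sample covariance, while
  the Hellinger distance needs strict positive definiteness. Matrix square
  roots use symmetric eigendecompositions with an eigenvalue floor of 1e-10;
  values under the outer square root in the Hellinger formula are clamped to
  zero when they exceed -1e-8 and raise an error otherwise.
* *Entropic weight*: `lam = lam_rel x median |initial gradient|` with
  `lam_rel = 5e-3`. The solver anneals from 50x down to the target weight
  (warm-started, loose inner tolerance) before the final solve; the reported
  objective trace covers the final solve and is non-increasing by
  construction because a candidate iterate that would raise the objective is
  rejected and iteration stops.
* *Stabilized Sinkhorn*: scaling vectors are absorbed into the dual
  potentials (and the kernel rebuilt) whenever they leave a safe range, so
  very small entropic weights run without underflow. Plans that hit the
  iteration cap are projected exactly onto the marginal polytope by the
  standard rounding construction and flagged `converged = FALSE`; every
  returned plan satisfies its marginals to 1e-6 or better.
* *FG-W trade-off*: `alpha = 0.5` (structure and labels weighted equally) —
  no reference value exists; it is exposed in `align_config()` and
  `fgw_distance()`. Squared losses (`q = 2`) throughout.
* *Barycenter initialization*: the dominant-weight input, ordered by label
  and resampled to the barycenter size — deterministic, and exact for
  identical inputs. Stopping: relative objective change below 1e-6 or 30
  outer iterations.
* *Tie-breaks*: column argmax ties resolve to the lowest row index;
  barycenter labels round half-up.

# Problem sizes used in the checks

The package's own validation uses: the full default study (6 subjects x 4
sessions, about 104 segments per session) over 20 seed replicates for the
above-chance and mode-ordering checks; compact artifact sessions (8 channels,
900 samples per task, about 60 segments) over 30 matched seeds for the
cleaning-helps-alignment comparison; exhaustive permutation enumeration at
n <= 6 as the solver oracle; and 1000 random SPD triples (d <= 10) for the
metric axioms. The acceptance script reruns the study end-to-end with 5 seed
replicates and the artifact comparison with 10, reporting mean accuracies on
the percentage scale.

# Known limitations

* Accuracy on a single session pair is bimodal: when the four class blocks
  are geometrically ambiguous the coupling can lock onto a wrong block
  permutation wholesale, which is why aggregate statistics over many pairs
  and seeds are the meaningful quantities.
* The Gromov–Wasserstein objective is non-convex; the annealed projected
  mirror descent finds good couplings in practice (and provably matches
  exhaustive search on the small instances tested) but carries no global
  guarantee.
* TARA-style decomposition assumes artifacts are sparse and spectrally
  separated from the signal band; broadband signals demand conservative
  thresholds, and oscillatory transients are out of scope.
* Automatic selection of the artifact-removal parameters (`beta`, `sigma`) is
  not attempted; they are per-dataset, per-species choices made by inspection of the data.
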