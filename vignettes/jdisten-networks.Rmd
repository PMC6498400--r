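---
title: "Joint-distribution-entropy functional networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-distribution-entropy functional networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jdnet)
```

## The problem

Short task-related EEG recordings — a second or so of post-stimulus signal
per epoch — are too short for most nonlinear coupling estimators, which
need long stationary series. Joint distribution entropy (JDistEn) was
proposed for exactly this regime: it quantifies the coupling of two
channels through the *distributional* structure of their joint state-space
distances, which stabilizes at far shorter lengths than correlation-sum
style statistics. `jdnet` implements a complete analysis built around it:
per-subject preprocessing, all-pairs JDistEn coupling, fixed-density
binary networks, small-world summaries against random references, and a
normality-gated two-group comparison, together with a synthetic cohort
generator that stands in for clinical data that cannot be shared.

## Per-subject preprocessing

Each subject arrives as a channels × samples × epochs block at sampling
rate $f_s$ (nominally 256 Hz; epochs of 1.40 s with a 0.2 s pre-stimulus
section, i.e. 358 and 51 samples after rounding to the nearest sample —
the durations are given, not the counts, so round-to-nearest is our
convention and any consistent epoch length from file metadata is
accepted). The chain is:

1. **Trim** the pre-stimulus samples from every epoch.
2. **Average across epochs.** Event-related (phase-locked) activity
   survives; epoch-incoherent activity attenuates like $1/\sqrt{E}$.
3. **Band filtering** with a cascade of two-pass Butterworth IIR filters:
   high-pass of design order 4 with half-power frequency 9 Hz, then
   low-pass of design order 8 at 34 Hz. Each stage is applied
   forward-backward, so the net phase response is zero and the amplitude
   response is the squared single-pass magnitude; "order" always means the
   single-pass design order. Transients are suppressed by odd-reflection
   padding of length 3× the filter order at both ends (a standard
   mitigation on short records). The 9–34 Hz band is labelled "beta" in
   parts of the EEG literature although it spans alpha as well; the
   cutoffs are exposed in `filter_spec()` and are not hard-coded.
4. **Rescale** each channel affinely to $[0,1]$:
   $\bar u(i) = (u(i) - \min u)/(\max u - \min u)$. This removes
   per-channel gain, so the coupling stage is invariant to positive affine
   maps of the raw signals. A constant channel cannot be rescaled and
   raises a structured `degenerate-channel` error naming the channel.

## The coupling estimator

For a rescaled channel $\bar u$ of length $N$, delay embedding with
dimension $m$ and delay $\tau$ (defaults $m = 2$, $\tau = 1$ sample,
values established for nonlinear EEG analysis at short lengths) gives
state vectors
$X(i) = [\bar u(i), \bar u(i+\tau), \dots, \bar u(i + (m-1)\tau)]$ for
$i = 1 \dots N - n$ with margin $n = m\tau$. (The printed index range
leaves one usable vector unused when $m = 2,\ \tau = 1$; we reproduce it
as stated.)

The intra-channel distance between vectors $i$ and $j$ is, by the
operational definition used throughout,
$$\lVert X(i), X(j)\rVert = \max[\max(X(i)) - \min(X(j)),\
\max(X(j)) - \min(X(i))],$$
the largest spread between the two vectors' extremes. This is *not* the
Chebyshev norm $\max_k |x_k(i) - x_k(j)|$ — the two disagree in general,
and this variant has a nonzero diagonal (each vector's own range). The
diagonal is excluded from all later steps, so the discrepancy is inert,
but both variants are available (`norm = "range"` default,
`norm = "chebyshev"`).

Two channels' distance matrices $D_1, D_2 \in [0,1]$ combine into the
joint distance matrix
$$JD = J - \sqrt{(J - D_1) \circ (J - D_2)},$$
with $J$ the all-ones matrix and $\circ$ the entrywise product; note
$JD(D, D) = D$ exactly. The off-diagonal entries (both triangles,
$n_{\mathrm{obv}} = (N-n)^2 - (N-n)$ of them) are histogrammed with the
bin count from Doane's rule,
$$B = 1 + \log_2 n_{\mathrm{obv}} + \log_2\!\left(1 +
\frac{|g_1|}{\sigma_{g_1}}\right),\qquad
\sigma_{g_1} = \sqrt{\frac{6(n_{\mathrm{obv}}-2)}
{(n_{\mathrm{obv}}+1)(n_{\mathrm{obv}}+3)}},$$
rounded half away from zero and floored at 2. The coupling is the
normalized Shannon entropy
$$\mathrm{JDistEn} = \frac{-1}{\log_2 \mathrm{Bins}}
\sum_t \rho_t \log_2 \rho_t \in [0, 1],$$
with empty bins excluded. All unordered channel pairs are assembled into a
symmetric coupling matrix; the diagonal (self-coupling, undefined) is set
to 0 and excluded from thresholding.

Numerical conventions that the definitions leave open, fixed here once:

* skewness $g_1$ is the population moment ratio $m_3/m_2^{3/2}$, defined
  as 0 for constant input;
* histogram bins are equal-width over $[\min, \max]$ of the off-diagonal
  joint distances, rightmost bin closed; zero spread puts all mass in one
  bin (entropy 0);
* rounding "to the nearest integer" is half-away-from-zero everywhere
  (ties are measure-zero for these continuous quantities).

The all-pairs computation is compiled (Rcpp); a 128-channel subject takes
a couple of seconds. Its correctness is pinned, in the test suite, to an
independent straight-line R implementation of the full chain at
tolerance $10^{-12}$.

## Networks and small-world summaries

Coupling values' ranges vary across subjects, so a fixed threshold would
give different edge counts per subject. Instead the strongest
$E = \mathrm{round}(d \cdot V(V-1)/2)$ couplings are kept as edges
(fixed density $d = 0.10$ by default; $V = 128$ gives exactly 813 edges).
Ties at the threshold break deterministically by (row, column) position,
which matters only for quantized weights.

Summaries per subject:

* **Clustering coefficient** $C$: mean over *all* nodes of the fraction
  of a node's neighbour pairs that are connected; degree-< 2 nodes
  contribute 0.
* **Characteristic path length** $L$: mean shortest-path length over
  ordered pairs. At 10% density graphs need not be connected (16 nodes at
  density 0.10 have only 12 edges, fewer than a spanning tree); $L$ and
  eccentricity are then computed within the largest connected component.
  This convention is ours — infinite-distance handling is genuinely open
  — and the component size is reported alongside every metrics row.
* **Eccentricity**: each node's maximum shortest-path distance within its
  component; the subject-level summary is the mean over the largest
  component's nodes (the maximum, i.e. the diameter, is available via
  `ecc_summary = "max"`).
* **Small-world quotient**
  $Q = (C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})$, with
  $C_{\mathrm{rand}}, L_{\mathrm{rand}}$ averaged over 10 random
  reference graphs: symmetric uniform weight matrices thresholded at the
  same edge count, i.e. uniform-random $E$-edge (Erdős–Rényi-style)
  graphs, not degree-preserving rewires — matching how the references are
  described for this pipeline. Uniform-random graphs self-normalize to
  $Q \approx 1$; ring lattices of the same size exceed the random
  clustering several-fold. If every reference graph is triangle-free
  ($C_{\mathrm{rand}} = 0$, possible at very sparse sizes), $Q$ is
  undefined and the subject is skipped with a record rather than imputed.

## Group comparison

For each metric, both groups pass through a Jarque–Bera normality gate
(moment form $JB = \tfrac{n}{6}(S^2 + (K-3)^2/4)$ against
$\chi^2_2$; the asymptotic reference is anti-conservative at $n \approx
13$, which is logged, and a Monte-Carlo p is available). If both groups
look normal, an unpaired pooled-variance Student t-test is used (Welch
via config); otherwise a two-sided Wilcoxon rank-sum test whose p-value
comes from the *exact* permutation distribution of the rank sum, computed
by a counting dynamic program over midranks — ties are handled exactly
rather than by falling back to a normal approximation. Significance is
assessed at 5% per metric; no multiple-testing correction is applied
across the four metrics (mirroring the analysis design this package
reproduces; the report footer says so).

Both groups are screened for outliers with Chauvenet's criterion
($n \cdot P(|Z| \ge |x_i - \bar x|/s) < 0.5$) and Tukey's 1.5×IQR fences
with interpolated (type-7) quartiles. The original analysis "checked"
outliers without stating a removal rule, so flagged values are reported
but never removed by default.

## The synthetic cohort generator

The clinical dataset this pipeline was designed for (13 patients vs 14
controls, 128 channels, 23–87 epochs per subject) is not publicly
deposited, so validation runs on synthetic cohorts with known coupling
structure. The generator mirrors the study geometry — group sizes 13/14,
256 Hz, 358-sample epochs with 51 pre-stimulus samples, epoch counts
uniform on 23–87 — and a controllable coupling structure:

* Channels are grouped into modules (default at test scale: 16 channels
  in 8 modules of 2). Each module has one sinusoidal source with a
  per-module frequency spread evenly over 12–30 Hz, per-epoch frequency
  jitter (±0.5 Hz) and a *subject-level* base phase with per-epoch phase
  jitter of ±0.5 rad.
* Partial phase locking is deliberate: it models task-evoked,
  event-related activity, which is precisely what survives epoch
  averaging. With fully random per-epoch phases the averaged sources
  vanish into noise and no coupling structure would reach the estimator;
  `phase_lock = pi` provides that regime when wanted.
* A channel mixes its own module's source (weight 1), its *partner*
  module's source (modules are coupled in mutual pairs 1–2, 3–4, …) with
  the between-module weight, and white noise (sd 0.5). The between-module
  weight is the group contrast: group A defaults to 0.0, group B to 0.6.
  Mutual pairing gives cross-pair correlation $2\beta/(1+\beta^2)$
  (≈ 0.88 at $\beta = 0.6$), strong enough to move the fixed-density
  ranking. Modules of size 2 are chosen so the within-module pairs (8)
  cannot fill the 10% edge budget (12 edges at 16 channels): the
  weak-coupling group then stays random-like rather than fragmenting into
  small cliques — fragmentation would *raise* clustering and shrink the
  largest component, inverting the Q contrast under the
  largest-component convention.

Under these defaults the strongly coupled group forms connected,
clustered networks (higher Q); the weakly coupled group's networks are
noise-dominated and random-like (lower Q) — the direction reported for
controls vs patients. At zero contrast (equal between-module weights) the
groups are exchangeable by construction, which is what the null
calibration exploits.

What the generator does **not** emulate: volume conduction and a forward
head model, 1/f background spectra, artefacts (blinks, muscle), epoch
rejection, non-stationarity within epochs. Passing tests therefore
validate the *pipeline's* contracts — estimator correctness, fixed-density
topology, calibration of the gated test — not the clinical effect size,
and no synthetic result should be read as reproducing the clinical
group-difference values.

## Problem sizes used in the tests

The validation suite runs the full pipeline end to end at a reduced
geometry chosen to keep the all-pairs joint-distance computation light:
16 channels, 110-sample epochs with 16 pre-stimulus samples (the same
0.9 : 0.1 split of usable to pre-stimulus data), full 23–87 epoch range,
13 vs 14 subjects. Null calibration uses 200 zero-contrast cohorts
(checking each metric's false-positive rate against exact binomial 95%
bounds around 5%); power uses 50 high-contrast cohorts (between-module
weights 0.0 vs 0.6). Estimator-level checks run at full 128-channel scale
where they are cheap (edge budget, ER self-normalization, lattice
contrast).

## Known limitations

* The largest-component convention for $L$ and eccentricity is a choice;
  at 10% density with few channels it materially shapes Q, and subjects
  with very fragmented graphs are not comparable to connected ones (the
  component size column makes this auditable).
* The exact rank-sum p is discrete; at $n = 13/14$ the attainable levels
  make the gated procedure slightly conservative near 5%.
* Doane's rule feeds on $n_{\mathrm{obv}} = (N-n)^2-(N-n)$, which counts
  both symmetric copies of every joint distance; whether the original
  analysis deduplicated them is unstated, and we follow the printed
  count.
* JDistEn values concentrate in a narrow high band for band-limited
  signals; per-channel marginal structure (e.g. source frequency)
  contributes variance to couplings that is not pairwise interaction.
  Fixed-density thresholding operates on ranks, which absorbs some, not
  all, of this.
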