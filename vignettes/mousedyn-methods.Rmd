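---
title: "Methods: complex-plane embedding, subspace projection, and complex DFA for unconstrained cursor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex-plane embedding, subspace projection, and complex DFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousedyn)
```

## The problem

Most mouse-tracking analysis assumes trial structure: a movement starts at
a known point, ends at a choice, and is analyzed in isolation. Continuous
tasks — games, browsing, open-ended interfaces — produce one long cursor
stream with no natural segmentation. mousedyn analyzes such streams whole,
asking two questions: *does a participant's frequency-domain structure
resemble that of a reference cohort?* (the η diagnostic), and *what is the
long-range temporal correlation structure of their movements?* (the DFA
exponent α).

## Preprocessing model and assumptions

A raw log is a sequence of time-stamped positions polled only when the
cursor moves, at irregular intervals (browsers poll at roughly 8–12 ms).
The package:

- sorts by timestamp and collapses duplicate timestamps keeping the last
  record (last write wins, matching event order);
- linearly interpolates x and y independently onto a uniform grid anchored
  at the first observed timestamp, never extrapolating beyond the last
  observation — positions outside the observed span would be fabricated;
- embeds the coordinates as one complex series \(z_n = x_n + i y_n\);
- trims a cohort to the length of its shortest member, keeping the *first*
  \(N^*\) samples, and forces \(N^*\) even.

Assumptions worth stating: linear interpolation treats the cursor as
moving in straight lines between polls, which is accurate at 8–12 ms
spacing and cheap; the embedding assumes both screen axes are in the same
units (pixels) and applies no resolution normalization. Trimming from the
start rather than the end is a package choice — either is defensible; the
start was chosen so all participants are aligned on task onset. Even
length is enforced (dropping at most one trailing sample) so the two-sided
spectrum index range \(-N/2 \dots N/2-1\) is well defined.

Click events are carried as metadata only and never enter the spectral or
fluctuation computations. Derivative-based measures (velocity,
acceleration, jerk) are deliberately out of scope: differencing a
discontinuously sampled signal amplifies noise and manufactures infinite
derivatives at polling gaps.

## Spectrum normalization

`spectrum_dft()` puts the \(1/N\) factor on the forward transform, so the
synthesis relation
\(z(t_j) = \sum_{n=-N/2}^{N/2-1} Z_n e^{i 2\pi f_n t_j}\) holds verbatim
and a constant series has \(Z_0\) equal to that constant. Relative to the
common unnormalized FFT convention this divides by \(N\) and rotates the
output so negative frequencies come first. Under this convention Parseval
reads \(\frac1N \sum_j |z_j|^2 = \sum_n |Z_n|^2\); the test suite asserts
it to 1e-10. η is scale-invariant, so the choice of normalization cannot
affect any scientific conclusion — it is fixed so persisted spectra are
bit-stable. Frequencies are reported in Hz (converted from ms); the DC bin
is kept in spectra but excluded from log–log slope fits, where
\(\log f = -\infty\) is undefined. No windowing, tapering or segment
averaging is applied: the analysis transforms the full series once.

## The reference subspace and η

Spectra of a reference cohort are stacked as columns of \(A\)
(\(N \times P\), asserted \(P < N\)) and decomposed as
\(A = U \Sigma V^*\) **without centering**. The decomposition follows the
matrix algebra literally; classical PCA would subtract the mean spectrum
first, and that variant is exposed as `center = TRUE` (off by default).
With a shared mean the uncentered first component largely encodes that
mean — users who want "directions of variation about the mean" semantics
should center; the default favors reproducibility of the plain matrix
factorization.

\(k\) is the smallest number of components whose cumulative squared
singular values reach the `threshold` (default 0.5, i.e. 50% of variance).
The cumulative-variance curve is typically flat near the threshold, so
nearby values of \(k\) give nearly identical subspaces; `k` can also be
set explicitly. Ties among singular values are accepted in solver order:
the *subspace*, not any particular basis, is the contract, and tests
compare spans via principal angles. Basis columns are phase-normalized
(largest-magnitude entry real-positive) so persisted files are
reproducible; phases are irrelevant to η.

η is computed as \(\lVert \tilde U^* Z\rVert / \lVert Z \rVert\) (equal to
the projection-norm form because \(\tilde U\) is orthonormal), clamped to
\([0,1]\) against rounding. η is undefined for an all-zero spectrum and
raises an error. Useful identities checked by the tests: η is invariant to
rescaling of \(Z\); nondecreasing in \(k\) for nested subspaces; and for
directions uniform on the complex sphere \(E[\eta^2] = k/N\) — the
baseline against which "this cohort fits the subspace" must be judged.

## Complex-valued DFA

The profile is \(C_n = \sum_{j\le n} (z_j - \bar z)\). For window size
\(s\), the profile is partitioned into \(\lfloor N/s \rfloor\)
non-overlapping windows from the start; in each a degree-\(d\) polynomial
(default \(d = 1\)) in the time index is least-squares fit — one complex
fit, equivalent to fitting real and imaginary parts with a shared design —
and

\[ F_s = \Big( \tfrac{1}{M} \sum |r_j|^2 \Big)^{1/2}, \]

pooling all \(M = \lfloor N/s\rfloor\, s\) covered points. Residual
*moduli* are squared because residuals are complex. Points beyond the last
full window are excluded; normalizing by \(M\) rather than \(N\) avoids
biasing \(F_s\) low at scales that do not divide \(N\). The
`ends = "both"` option adds a second partition anchored at the series end
and pools both passes, so no data are discarded; the forward-only default
is the simplest reproducible reading.

α is the OLS slope of \(\log F_s\) on \(\log s\) (natural logs; the base
cancels in a slope) over a geometric grid of roughly 20 integer scales in
\([4, N/4]\). The minimum of 4 avoids windows too short to detrend
meaningfully; the \(N/4\) cap keeps at least four windows per scale so
\(F_s\) is an average, not an anecdote. Scales with exactly zero
fluctuation (possible only for locally-linear profiles) cannot enter a log
fit; they are dropped with a warning rather than floored, because any
floor value would silently bend the fitted slope. At least 4 usable scales
are required.

Interpretation: α ≤ 1 indicates a stationary, fGn-like series with Hurst
parameter \(H = \alpha\); α > 1 a non-stationary, fBm-like series with
\(H = \alpha - 1\). Within either regime \(H < 0.5\) is anti-correlated,
\(H = 0.5\) (to within 1e-6) uncorrelated, \(H > 0.5\) positively
correlated; equivalently \(1 < \alpha < 1.5\), \(\alpha = 1.5\), and
\(1.5 < \alpha < 2\) for the non-stationary regime. Exponents outside
\([0, 2)\) fall outside both regimes and produce a warning, with \(H\)
still reported.

## Synthetic-data generators

The generators define the conditions the tests are run under.

**Complex fGn** (`gen_fgn_complex`) uses circulant embedding of the exact
fGn autocovariance: the \(2N\)-circulant of
\(\gamma(k) = \tfrac{\sigma^2}{2}(|k{+}1|^{2H} - 2|k|^{2H} +
|k{-}1|^{2H})\) has nonnegative real eigenvalues; coloring complex white
noise by their square roots yields a complex Gaussian vector whose real
and imaginary parts are *two independent* exact fGn samples — no
approximation bias, which matters because the DFA recovery bands are tight
(mean α within 0.08 of H). Approximate synthesis (wavelet, midpoint
displacement) was rejected for that reason.

**Planted cohorts** (`gen_planted_cohort`) draw an orthonormal random
complex basis of dimension `k_true`; in-cohort spectra are random
combinations of it plus i.i.d. complex Gaussian noise whose expected norm
is `noise_level` times the expected signal norm, and out-cohort spectra
are built identically from a basis in the orthogonal complement. At
`noise_level = 0` the separation is exact (η = 1 vs η = 0); at 0.3 the
groups still separate by a large margin — this is the controlled analogue
of high performers sharing spectral structure.

**Game simulator** (`game_spec`, `agent_spec`, `gen_game_trace`). The game
follows the original task parameters: 650 ms mole visibility, 350 ms
post-hit stun display, 120 moles, 8–12 ms cursor polling. The hill
sequence is generated from the game seed alone (uniform over hills,
excluding the previous hill — the distribution of the original
pre-generated sequence is not documented, so schedules are statistically
rather than literally equivalent), and is therefore identical for every
agent playing the same spec. The agent — a noisy proportional controller
with a reaction latency, speed cap, motor noise and click jitter — is an
invention: the task defines the game, not the players. It exists so
gameplay traces have accuracy known by construction (a zero-latency,
infinite-speed, zero-jitter agent scores exactly 1; an agent whose
latency exceeds visibility plus stun never clicks a live mole and scores
exactly 0), not to model human motor control. Simulated cohorts should
not be read as evidence about what *human* η or α values look like.

What the generators do **not** emulate: drift or nonstationarity of human
attention over minutes, hardware-specific polling pathologies, screen
boundaries shaping trajectories (agents are clamped but rarely touch
edges), or any coupling between a player's spectral structure and their
DFA exponent. A passing test suite therefore demonstrates the estimators
are correct and well-calibrated on processes with known structure — not
that any empirical claim about human players transfers to new data.

## The study pipeline

`run_study()` mirrors a two-sample design: both samples are resampled and
trimmed *jointly* (one frequency grid for everyone), the reference
subspace is fitted on sample 1's high-accuracy group only, and all of
sample 2 is scored out-of-sample. Group thresholds default to strictly
above 0.505 (high) and strictly below 0.12 (low), boundary values
excluded; the middle band is scored but belongs to neither group. Welch's
unequal-variance t-test compares η between sample 2's groups; regressions
are computed in **both** directions (η on accuracy and accuracy on η)
because the two readings answer different questions and differ in slope
units. DFA is run on every participant; the α–accuracy regression is
reported for sample 2, parallel to the η analysis. No multiple-testing
adjustment is applied — the report contains a handful of planned
statistics, and adjusting them is the analyst's decision, not the
pipeline's. All p-values are two-sided. Degenerate situations (a rank-1
cohort making every η equal, an empty group) are flagged in the report
rather than raised, so one pathological participant set cannot kill a
batch run.

## Numerical choices and degenerate inputs

- Detrending uses an orthonormal polynomial design per window size
  (constant column plus `stats::poly`), so window fits are
  well-conditioned at any scale and the residual projector is a single
  matrix product.
- A constant series has an identically zero DFA profile; it is flagged
  degenerate and both `fluctuation()` and `dfa()` refuse it.
- `ols_fit()` treats predictor or response variance below 1e-10 of scale
  as zero — with η values clamped to \([0,1]\), a rank-1 cohort yields
  η ≡ 1 only up to floating point, and must still be recognized as
  degenerate.
- The uniform-trace CSV writer prints 17 significant digits, so the
  writer/reader pair round-trips doubles exactly.
- Fitted-subspace provenance is an order-sensitive hash of the cohort ids
  and fitting configuration, so swapping cohorts or changing the threshold
  is always visible downstream.

## Problem sizes in the test suite

The statistical checks run at: fGn recovery and white-noise baseline —
N = 8192, 50 replicates per condition; η moment identity — N = 64, k = 8,
10⁴ draws; planted-cohort separation — N = 512, k_true = 8, 40 + 40
spectra at noise 0.3; pipeline end-to-end — N = 128–256 with 8–12
participants per group; simulator checks — 30-mole games. These sizes give
Monte-Carlo error comfortably inside each asserted band while keeping the
default test run around a quarter of a minute.

## Known limitations

- η is a *relative* diagnostic: it measures fit to whatever cohort defined
  the subspace, and its baseline grows as \(\sqrt{k/N}\); comparisons
  across subspaces of different k or N need that correction.
- DFA assumes an approximately power-law fluctuation function; crossovers
  (different slopes at small and large scales) are not detected or
  modeled, and no multifractal extension is provided.
- The resampler assumes timestamps are trustworthy; systematic clock skew
  between participants is not corrected.
- The agent simulator's accuracy distribution is a modeling convenience;
  only its boundary guarantees (accuracy exactly 0 or 1 for extreme
  agents) and its schedule determinism are contractual.
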