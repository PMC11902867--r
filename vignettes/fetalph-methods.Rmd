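---
title: "Methods: heart-rate symbolization and the acid-base HMM"
author: "fetalph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate symbolization and the acid-base HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalph)
```

## Overview

`fetalph` estimates the umbilical-cord arterial pH class of a fetus from its
intrapartum heart-rate (bpm) series. The chain is: artifact removal, a
partition of beats into parasympathetic ("downward") and sympathetic
("non-downward") components, approximate-entropy complexity analysis, a
symbolic encoding of beat-to-beat dynamics, and a discrete hidden Markov
model whose four hidden states are clinically defined cord-pH intervals.
This vignette records the modelling assumptions, parameter choices and
numerical conventions, including every place where the method description we
implement left a genuine design decision open.

## Preprocessing

Two artifact classes are removed, in a fixed order.

**Post-delivery noise runs first.** After delivery the scalp electrode is
detached but the monitor keeps recording; the result is a tail of
implausibly low values. Every maximal run of at least `noise_run_len = 5`
consecutive samples strictly below `noise_bpm_cut = 100` bpm is deleted in
full (not truncated to five: the entire run is unusable). A dip of four
samples is physiology, not noise. Removal is idempotent.

**Then the three-sigma band.** With the tail gone, the recording mean and
standard deviation are estimated and only samples inside the *closed* band
$[\mu - 3\sigma,\; \mu + 3\sigma]$ are retained, which keeps
$\approx 99.7\%$ of a Gaussian series. Removed samples are omitted, never
imputed. Running the band *after* noise removal is a deliberate ordering:
a 30-sample tail at 70 bpm shifts $\mu$ down and inflates $\sigma$ enough to
misplace the band around the physiological signal. $\mu$ and $\sigma$ are
per-recording, not cohort-wide: baselines differ by tens of bpm between
fetuses, so a cohort band would be far too wide.

Degenerate case: a constant series has $\sigma = 0$ and every sample lies
exactly on the band boundary; the closed inequalities retain all of them.

## Autonomic partition

The transition into beat $i{+}1$ is *downward* when
$\mathrm{FHR}_{i+1} \le \mathrm{FHR}_i - 5$ bpm (inclusive), otherwise
non-downward. The 5 bpm threshold is the clinically established magnitude
for parasympathetic slowing and is configurable
(`downward_threshold`). The *endpoint* sample of each transition carries the
label, so the two branch series partition samples $2..N$ and
$|{\rm down}| + |{\rm non\text{-}down}| = N - 1$ holds exactly.

## Approximate entropy

For a series $u$ of length $N$, embedding dimension $m$ and tolerance $r$:
templates $x(i) = [u_i, \dots, u_{i+m-1}]$, Chebyshev distance
$d[x_i, x_j] = \max_k |u_{i+k-1} - u_{j+k-1}|$,
$C_i^m(r)$ the fraction of templates within $r$ of template $i$
(*including* the self-match $j = i$, the classic convention that keeps every
count positive and every logarithm finite),
$\Phi^m(r)$ the mean natural logarithm of the $C_i^m$, and
$\mathrm{ApEn}(m, r, N) = \Phi^m(r) - \Phi^{m+1}(r)$.

Defaults are $m = 2$ and $r = 0.2 \cdot \mathrm{SD}$ of the analysed series,
the standard operating point for clinical heart-rate data; because $r$
scales with the SD, ApEn is invariant to adding a constant to the series. A
constant series is defined to have ApEn 0 (the limit of the constant case)
rather than raising an error. The $O(N^2)$ pair scan is implemented in
compiled code (`src/apen.cpp`); the test suite verifies it against a literal
R transcription of the defining formulas to $10^{-12}$.

Two estimator caveats worth knowing. With $\Phi^{m+1}$ computed over its own
$N - m$ templates, ApEn can be *slightly negative* for short, highly regular
series (the mean-log normalizers differ); this is a property of the standard
estimator, not a bug, and our regularity fixture (a period-3 series of
length 10) has ApEn $\approx -0.016$. And for very short series
($N \lesssim 30$) the self-match floor dominates both $\Phi$ terms, so ApEn
reads "regular" regardless of the data; branch-level ApEn is therefore only
meaningful when a branch has on the order of a hundred beats.

Windowed ApEn (`apen_series()`) recomputes $r$ from each window's own SD;
default window 256 samples, step 128. The windowing is a reporting
convenience for time-course plots and has no downstream role.

Cohort analysis correlates per-recording whole-branch ApEn against each
blood gas parameter (Pearson, at least 3 complete pairs required), and a
paired t-test compares the two branches. Correlation and t-test are
delegated to `stats::cor()` / `stats::t.test()`; the degenerate all-zero
difference case is defined as $t = 0, p = 1$, while zero-variance
differences with non-zero mean are an error.

## Symbolization

Beat-to-beat differences $d_i = \mathrm{bpm}_{i+1} - \mathrm{bpm}_i$ fall
into Decrease ($d \le -2$), Stable ($-2 < d < 2$) and Increase
($d \ge 2$); the 2 bpm half-width (`diff_stable_halfwidth`) is configurable.
Each category is split into two subgroups at the midpoint of its observed
range *within the recording*: subgroup 1 is the side of the midpoint nearer
zero (milder change), subgroup 2 the other side, with the midpoint itself in
subgroup 1. Implemented as one total rule: if the midpoint is $\ge 0$,
subgroup 1 is $d \le$ midpoint, otherwise $d \ge$ midpoint — this covers D
(midpoint negative), I (positive) and S (either sign) uniformly.

Three open points resolved here, each a documented choice:

* **Midpoints are per recording**, not per window or cohort-wide: "the range
  of differences" most naturally means the recording's own range, and it
  keeps the encoder causal per recording. The cost is sensitivity of the
  midpoint to a single extreme difference, which is exactly why the
  preprocessing stage must catch artifact spikes.
* **Per-window symbol assignment.** The eight observation symbols are the
  $2^3$ combinations of subgroups. Within each window (default 60
  differences, non-overlapping — one symbol per minute at 1 Hz sampling) the
  *dominant* subgroup of each category (larger within-category count; tie or
  absent category resolves to subgroup 1) forms a triple mapped in
  lexicographic order: $(D_1,S_1,I_1) \to O_1$ through $(D_2,S_2,I_2) \to
  O_8$. This makes the encoder total and deterministic.
* **Window length** is not dictated by the method description; 60
  differences keeps the per-recording sequence length around 60 for an
  hour-long trace, which is comfortable for HMM training.

## The hidden Markov model

Hidden states are the cord-pH classes (inclusive lower bounds):
$H_1: \mathrm{pH} < 7.2$, $H_2: 7.2 \le \mathrm{pH} < 7.25$,
$H_3: 7.25 \le \mathrm{pH} < 7.3$, $H_4: \mathrm{pH} \ge 7.3$ — 0.05-unit
steps that are clinically meaningful in prenatal care.

**Initialization.** $\pi$ is uniform $(0.25, 0.25, 0.25, 0.25)$ — no prior
preference among acid–base states at onset. $B$ rows are class-conditional
symbol frequencies over the labelled training windows (empty class rows fall
back to uniform). $A$ comes from a co-occurrence matrix over the pseudo
hidden-state sequence built by giving every window its recording's class
label and concatenating recordings in input order; with single-label
recordings this is strongly diagonal, which is the intended prior: the
acid–base state changes slowly.

**Training.** Baum–Welch with per-step scaling (the textbook recursions
underflow beyond $T \approx 100$): scaled forward variables
$\hat\alpha_t$ normalized to sum 1 with scales $c_t$, backward variables
scaled by the same $c_t$, posteriors $\gamma_t \propto \hat\alpha_t
\hat\beta_t$ and $\xi_t$ accumulated across sequences (numerators and
denominators pooled, so multi-sequence training is exact). Convergence when
the total log-likelihood moves less than `bw_tol = 1e-6` between iterations,
cap `bw_max_iter = 500`. The log-likelihood trace is non-decreasing — the EM
guarantee — and the suite checks this to $10^{-10}$ over seeded random runs.
Emission entries below $10^{-12}$ (symbols never seen in training) are
floored and the row renormalized, so no held-out observation has zero
likelihood; the floor only touches entries that are essentially zero, which
is what keeps the monotonicity check clean.

**Decoding and classification.** Viterbi in log space with backtracking;
argmax ties break toward the lowest state index, everywhere, so decoding is
deterministic. A recording is classified by the *final* state of its decoded
path — the model's belief closest to delivery, which is when the cord gas is
drawn; a majority-vote alternative is available (`rule = "majority"`).
Whether the hidden state should be allowed to drift within one labour is
genuinely open (each recording carries a single postnatal pH); the final-state
rule is our documented resolution.

**Label switching.** Unsupervised EM recovers states only up to
permutation. `match_states()` aligns an estimate to a reference by the best
of the 24 permutations (minimum max-row L1 on $B$), the standard correction
in recovery studies. `fit_hmm()` adds seeded random restarts keeping the
best final likelihood, the usual guard against EM local optima — with a
well-separated generating model, typically two of three random starts find
the global optimum.

## The synthetic cohort generator

The clinical cohort (469 recordings, each over an hour) is private, so the
generator stands in for it. Defaults: the published class distribution
21/50/146/252 (or balanced $21 \times 4$), 3600 samples per trace (nominal
one hour at 1 Hz), baseline drawn from 130–150 bpm.

Each class has a characteristic event signature on a baseline plus AR(1)
beat-scale jitter:

* **H1**: frequent deep decelerations (depth $\approx 25$ bpm, steep 3-step
  descent *and* recovery);
* **H2**: the same decelerations with a slow, creeping recovery;
* **H3**: frequent accelerations (amplitude $\approx 24$ bpm, steep ascent,
  slow return);
* **H4**: no large events, the most irregular jitter.

All classes also receive sporadic mild dips ($\approx 2.4$ bpm), deep
single-beat drops ($\approx 6$ bpm — so healthier classes still show
downward beats), rare upward jumps, artifact spikes ($\pm 40$–70 bpm, placed
on event-free samples so the 3σ band always catches them), and a 30-sample
post-delivery tail below 100 bpm. Jitter persistence falls and scale rises
from H1 to H4, so complexity (ApEn) increases with pH — the positive
ApEn–pH coupling the method relies on. Event amplitudes are drawn once per
recording (stereotyped recurrent decelerations), which keeps the deep
beat-to-beat steps well clear of the per-recording midpoint that separates
mild from strong subgroups. The blood gas panel draws pH uniformly inside
the class interval and couples PCO2, PO2, HCO3 and BE to it with
physiologically signed slopes.

Class-conditioned dynamics are expressed through event rates and shapes —
never by planting symbols — so end-to-end tests exercise the entire encoder
chain. The generator's dynamics are deliberately *strongly* class-separated:
passing the pipeline test shows the chain is lossless enough to recover a
clean class signal, not that real labours are this separable (the published
balanced test accuracy on clinical data is 79%, against $\ge 0.9$ here).
Real FHR features the generator does not emulate: contraction-locked
deceleration timing, gestational-age and medication effects, electrode
dropouts mid-trace, and the heavy overlap of class-conditional dynamics in
real cohorts.

## Problem sizes and reproducibility

The shipped checks run at desk scale, chosen to finish in minutes on one
CPU: oracle agreement on 100 random series of $N \le 200$; Viterbi against
exhaustive enumeration at $T \le 6$; EM monotonicity over 50 seeded runs;
parameter recovery from 200 sequences of length 500 (max-row L1 within 0.05
after permutation alignment); and the balanced pipeline at $21$ recordings
per class with the published 15/6 split. Every stochastic stage takes its
seed from one master seed via a stable per-stage derivation, so cohort
generation, the balanced split and training are jointly reproducible;
`scripts/acceptance.R --seed N` reproduces its JSON byte-for-byte.

## Known limitations

* The per-recording midpoint rule makes the symbol alphabet
  non-comparable across recordings in absolute terms; two recordings with
  identical dynamics at different deceleration depths produce the same
  codes. That is faithful to the method but limits transfer.
* ApEn on branches with few beats is floor-dominated (see above); the
  cohort correlation quietly skips branches shorter than $m + 2$ but cannot
  rescue short-branch estimates.
* The per-class "Accuracy" column of published metric tables admits no
  single standard one-vs-rest definition consistent with every printed cell;
  we compute $(TP + TN)/\mathrm{total}$ and treat only the
  independently verified cells as reproduction targets.
* No SMOTE/augmentation, spectral HRV indices, or continuous-emission HMM
  variants; those are outside this package's scope.
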