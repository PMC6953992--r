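---
title: "Statistical regularity extraction from tone sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical regularity extraction from tone sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drex)
```

## The inference problem

A listener hears a stream of tones from a single source and must extract the
stream's statistical regularity to predict what comes next — while the
regularity itself can change without warning. `drex` formalizes this as
online Bayesian prediction with latent changepoints. Tones live on a
log-frequency scale (semitones re 440 Hz) because pitch perception is
approximately logarithmic in frequency; the Gaussian assumption below is an
assumption about log-frequencies.

Within one *context* (a maximal changepoint-free stretch), overlapping lag
vectors of `D` consecutive tones are modelled as draws from a D-variate
Gaussian with unknown mean and covariance. `D` is the model's central
scientific dial: `D = 1` collects only marginal statistics (a running mean
and variance of tone height), while `D = k` additionally collects temporal
covariances across k consecutive tones, letting the model learn sequential
structure such as tone patterns. Contexts terminate with a constant per-tone
hazard `h`, so run lengths are geometric a priori.

Because changepoints are never observed, the model carries one hypothesis
per candidate run length c (the number of recent tones in the current
context) and predicts with the mixture

$$P(x_{t+1}\mid x_{1:t}) \;=\; \sum_{c} P(x_{t+1}\mid c,\, x_{t-c+1:t})\;
P(c \mid x_{1:t}),$$

where the first factor depends only on tones inside the context window. The
belief over run lengths follows the usual grow/reset recursion: weight
$w(c)$ becomes $w(c)\,p_c(x_t)\,(1-h)$ at run length $c+1$, and the reset
state receives $h \sum_c w(c)\,p_c(x_t)$. The reported quantity is
surprisal, $S_t = -\log_2 P(x_t = X_t \mid x_{1:t-1})$, evaluated *before*
the update with $X_t$ — the model's prediction error in bits, the analogue
of neural deviance responses.

## Conjugate machinery

The unknown Gaussian parameters carry a Normal-Inverse-Wishart prior
$(\mu_0, \kappa_0, \nu_0, \Lambda_0)$, chosen because it gives exact
constant-time updates from raw sums ($n$, $\sum v$, $\sum vv^\top$ over the
embedded vectors inside the window) and a multivariate Student-t posterior
predictive — no sampling anywhere, so inference is deterministic. The
one-step predictive for the next tone conditions the joint D-variate
Student-t (dof $\nu_n - D + 1$, location $\mu_n$, scale
$\Lambda_n(\kappa_n+1)/(\kappa_n(\nu_n-D+1))$) on the last $D-1$ observed
tones of the context; when fewer than $D-1$ are available (sequence start,
short contexts) it conditions on those that exist and marginalizes the
rest — sub-blocks of a multivariate t are again t with the same dof, so this
is exact.

Default prior: $\mu_0 = 0$ in a *stimulus-centred* semitone space,
$\kappa_0 = 1$ (the prior mean is worth one tone), $\nu_0 = D + 2$ (smallest
integer dof with a finite prior covariance mean), $\Lambda_0 = 25\,I$
semitones² (prior predictive sd of about 5 semitones per coordinate — weak
and wide on the scale of musical stimuli). Because the model is exactly
translation-equivariant, "stimulus-centred" is implemented in the
replication harness by re-centring $\mu_0$ on each stream's mean tone
(empirical-Bayes initialization, as is customary for this model family)
rather than by shifting the tones. This matters: fitting an uncentred
AABB stream (mean +3 st) with $\mu_0 = 0$ biases every prediction low and
manufactures a spurious tone-height effect at the probe comparison.

## Perceptual constraints

* **Working memory `M`** (observations; default 25): no hypothesis may span
  more than M tones. The capped hypothesis is not deleted — deletion would
  discard the best-supported hypothesis in stationary stretches — but
  becomes a sliding window: as each tone arrives, the contribution of the
  embedded vector that left the window is subtracted and the new vector
  added, and the hypothesis grown from run length M−1 (whose window now
  coincides) is merged into it, conserving probability mass. Capped
  statistics equal batch statistics over exactly the last M tones to
  1e-10 (tested).
* **Observation noise `N`** (semitones; default 0.5): a floor on the
  conditional predictive standard deviation, `scale <- max(scale, N)`.
  It bounds prediction confidence from below, keeps surprisal finite for
  any input when N > 0, and stands in for peripheral encoding noise.
* **Hazard `h`** (default 0.01): the paradigms modelled here present
  regularities over tens of tones, so a 1%-per-tone prior changepoint rate
  is a weakly informative choice; it is exposed in `drex_config()`.
* **Log base**: surprisal is reported in bits (base 2) by default,
  configurable to nats.

## Numerical choices

All mixture arithmetic is in log space with log-sum-exp; belief weights
below 1e-300 are dropped and the remainder renormalized. Scale matrices are
symmetrized after every update; a conditional variance that comes out
negative beyond −1e-8 (never observed in practice) raises an error rather
than silently flooring. With bounded M the hypothesis count is at most M+1,
so each tone costs O(M) conditional Student-t evaluations, each O(D³) at
worst.

Correctness of the recursion is established against an independent
exponential-cost oracle, `enumerate_predictive()`, which enumerates all
$2^{t-1}$ changepoint placements, weights each by its hazard prior times the
sequential marginal likelihood of its segments, and mixes the per-placement
predictives. Recursion and enumeration agree to better than 1e-9 in
log-probability for all tested sequences (T ≤ 8, D ∈ {1,2,3},
h ∈ {0.01, 0.1}).

## What the generators emulate

Each generator is a pure function of its parameters and a seed, and records
its irregularities (deviant positions, regime transitions) at construction
time. They emulate the *structure* of classic deviance-detection paradigms,
not any specific published stimulus set — absolute frequencies, sequence
lengths and deviant rates of the original experiments are not public in
detail, so defaults were chosen once to be representative and are all
overridable:

* `gen_oddball()`: repeated standard with rare deviants at configurable
  semitone offsets (default offsets 2–24 st, 9 standards between deviants —
  a 10% deviant rate, typical of oddball designs).
* `gen_roving_oddball()`: trains of a repeated tone whose length is drawn
  per train from the condition set and whose frequency jumps at train
  boundaries (default jumps 2–6 st within a ±12 st band — the modest steps
  of roving-standard designs). Every deviant becomes the new standard.
* `gen_pattern_oddball()`: concatenated AABB-type patterns with rare
  whole-pattern reversals (BBAA), A/B 6 st apart by default.
* `gen_predictability_oddball()`: blocks of standards ending in a deviant;
  "high" predictability uses 4 standards per block (optionally jittered),
  "low" draws 2–6 uniformly, matching the deviant rate in expectation.
* `gen_biased_context()`: one oddball stream per statistical context, three
  deviant offsets whose probabilities are biased toward small (0.7/0.2/0.1)
  or large changes (reversed).
* `gen_gaussian_context()`: i.i.d. Gaussian tones of narrow or broad sd
  with periodic deviants two octaves above the mean.
* `gen_reg_rand()`: half random draws from a 20-tone pool, half a cyclic
  pattern of 4–12 distinct pool tones, in either order.

What they do **not** emulate: inter-stimulus timing (the model is
sequence-indexed), intensity/duration/timbre deviance, multiple concurrent
sources, and any peripheral transduction. Passing tests therefore show that
the *model* behaves as reported on sequences with the right statistical
structure; they do not certify behavior on acoustically realistic input.

## Replication harness: design choices

Trial counts are chosen to match the degrees of freedom of the reported
comparisons: 3 conditions × 50 streams (error df 147) for the roving
ANOVAs; 38 probes per group (df 74) for the pattern t-test; 24 pairs
(df 23) for the predictability comparison; 481 deviants (error df 477 in a
main-effects two-way ANOVA) for the statistical-context design. Probes
within the first 5 tones of a stream are excluded, and each experiment
additionally discards its first trains/blocks/deviants, because the prior
dominates early predictions. Unbalanced two-way cells (deviant counts per
offset differ by design across contexts) are handled with Type II sums of
squares via `car::Anova()`, and the context direction is judged on
per-offset (adjusted) means, since raw marginal means are confounded by the
deliberate imbalance.

Choices where the design was genuinely open:

* **Roving streams mix train lengths.** Each stream draws its trains'
  lengths (balanced) from {2, 6, 12}, as in roving designs where train
  length is unpredictable; probes are grouped by the preceding train's
  length, averaged per stream and condition. With single-condition streams
  of 2-tone trains the model rationally fuses trains into one broad
  context, making deviant surprisal track train length — an artifact of a
  stimulus no roving experiment uses.
* **Predictability is compared across stream pairs, not within a single
  pair of streams.** Each of 24 pairs contributes its mean differential
  surprisal (deviant minus immediately preceding standard) over 10 probed
  blocks, so stream-level variability enters the error term; a single
  stream per condition makes the paired test anti-conservative. The high
  condition uses a 1/3 jitter probability, implementing "usually 4"
  standards; a strictly periodic AAAAB stream has zero composition
  variance and a small systematic convexity advantage over the variable
  low condition.
* **The D = 1 pattern-oddball control is read directionally.** Deviance
  detection means *elevated* surprisal at the deviant pattern's first
  tone. With marginal statistics the model shows no such elevation — its
  tiny residual difference is negative (the first tone of BBAA repeats the
  preceding tone and is mildly *less* surprising, a repetition-suppression
  effect), and because model surprisal is noiseless even a 0.1-bit
  systematic difference defeats a two-sided test at any n. The control
  therefore asserts the absence of a significant surprisal *increase*.
* **Regular/random transitions use detection-with-retention.** The lag is
  the first tone from which the trial-averaged surprisal stays beyond the
  threshold (pre-transition mean + 3 sd for structure loss, − 1 sd for
  structure gain) for the rest of the analysis window. During the first
  pattern cycle the regular half is statistically identical to the random
  half, so a first point-wise crossing of a 1-sd threshold false-alarms on
  a fixed fraction of tones at any trial count.
* **The regular/random analysis runs with D = 13 and M = 50.** D must
  exceed the longest pattern (12) for the conditional prediction to span a
  full cycle. With the blanket default M = 25, memory holds barely two
  cycles of the longest pattern: its steady-state surprisal saturates at
  the memory ceiling and the 8-versus-12 pattern-length contrast collapses
  into measurement noise (+0.018 ± 0.021 bits). With memory spanning
  several cycles (M = 50) the pattern-length effect is clean
  (1.06 < 1.40 < 1.48 bits across lengths 4/8/12, gaps well beyond their
  standard errors). All other replications use M = 25, N = 0.5,
  h = 0.01 and the default prior.
* **Adaptation trend is reported, not asserted.** In the broad Gaussian
  context, deviant probes are binned by the number of the preceding k = 5
  tones falling outside ±5 st of the mean; the harness reports the per-bin
  means and the sign of the fitted slope as a diagnostic.

## Problem sizes

The shipped analyses are sized so that the full test suite and the
reporting script each run in minutes on one core: streams of 80–2,500
tones, 10–50 streams per experiment, and the enumeration oracle limited to
12 tones (2¹¹ placements). These sizes are the package's reporting
defaults; every function accepts larger values.

## Limitations

* Only Gaussian observation models are implemented; the framework is
  agnostic to the observation family, but nothing non-Gaussian is
  exercised here.
* Surprisal is not mapped to ERP amplitude or latency; no EEG/MEG formats
  are read or written.
* The model parameters (D, M, N, h, prior) are set by the user, not fitted
  to behavioral or neural data.
* With very short contexts and D > 1 the conditional predictive leans on
  the prior covariance; conclusions about the first few tones of a context
  are prior-driven by construction.

## A worked fit

```{r example}
seq <- gen_oddball(0, c(2, 6, 12, 24), n_standards_between = 9,
                   n_deviants = 2, seed = 42)
fit <- drex(seq, drex_config(D = 1))
summary(fit)
plot(fit)
```
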