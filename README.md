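# drex: dynamic regularity extraction from tone sequences

`drex` is an R implementation of a Bayesian observer for auditory
statistical-learning experiments. The listener's problem it models: given a
stream of tones from a single source, infer the invariant statistical
structure ("regularity") of the stream, predict the next tone, and register
how surprising each incoming tone is — under the complication that the
generating statistics can change at unknown moments. Its surprisal output is
the model-side analogue of neural deviance responses (e.g., the mismatch
negativity), which makes it useful to researchers who want a single
computational account of oddball-style paradigms ranging from simple
frequency deviants to pattern violations and regular/random transitions.

## The model

Tones are represented in semitones (log-frequency, 12 per octave, 440 Hz =
0). Within one statistical context the lagged tone vectors
(x<sub>t−D+1</sub>, …, x<sub>t</sub>) are modelled as D-variate Gaussian with
unknown mean and covariance; `D` sets the span of temporal covariance
collected (D = 1: marginal mean and variance; D = k: joint statistics over k
consecutive tones). A conjugate Normal-Inverse-Wishart prior over those
parameters gives exact incremental updates and a Student-t posterior
predictive.

Contexts end at latent changepoints with constant per-tone hazard h. The
model maintains one hypothesis per candidate context length c (run length),
with posterior

  P(x<sub>t+1</sub> | x<sub>1:t</sub>) = Σ<sub>c</sub>
  P(x<sub>t+1</sub> | c, x<sub>t−c+1:t</sub>) · P(c | x<sub>1:t</sub>),

i.e., the per-context Student-t predictive (conditioned on the last D−1
tones of the context) integrated over the run-length posterior, which is
updated by the standard grow/reset recursion: each hypothesis's weight is
multiplied by its predictive density and (1−h); the hazard mass h restarts a
fresh context. Two perceptual constraints shape behavior: working memory `M`
caps the run length (the longest hypothesis keeps sliding-window statistics
over the last M tones), and observation noise `N` floors the predictive
standard deviation. The surprisal of tone t is

  S<sub>t</sub> = −log₂ P(x<sub>t</sub> = X<sub>t</sub> | x<sub>1:t−1</sub>)  (bits).

## Worked example

```r
library(drex)

# an oddball stream: standard at 0 semitones, deviants 2/6/12/24 semitones
# away, 9 standards before each deviant
seq <- gen_oddball(standard = 0, deviant_offsets = c(2, 6, 12, 24),
                   n_standards_between = 9, n_deviants = 2, seed = 42)
fit <- drex(seq, drex_config(D = 1))
fit
#> Dynamic regularity extraction fit
#>   80 tones; D = 1, M = 25, N = 0.5, hazard = 0.01
#>   mean surprisal: 3.449 bits; max 17.27 at tone 80
summary(fit)
#> ...
#> mean surprisal at annotated deviants: 11.14; elsewhere: 2.594
```

Deviants carry far more surprisal than standards (11.1 vs 2.6 bits), and
surprisal is ordered by frequency distance — the model's counterpart of the
growth of deviance responses with deviant size:

```r
replicate_oddball_distance(n_trials = 5, base_seed = 42)
#> Experiment: oddball_distance
#>   F(3,16) = 13310, p = 2.21e-27  [increasing with offset]
#>   descriptives (surprisal, bits):
#>  offset   mean      sd
#>       2  3.055 0.02116
#>       6  8.612 0.21999
#>      12 13.304 0.07811
#>      24 17.048 0.00478
```

`plot(fit)` draws the tone sequence and the surprisal trace; `predict(fit)`
exposes the next-tone predictive mixture; `simulate(fit, n_ahead = 20)`
continues the sequence from the learned state.

Other paradigm generators: `gen_roving_oddball()`, `gen_pattern_oddball()`,
`gen_predictability_oddball()`, `gen_biased_context()`,
`gen_gaussian_context()`, `gen_reg_rand()`; paradigm-level analyses:
`replicate_roving()`, `replicate_pattern_oddball()`,
`replicate_predictability()`, `replicate_biased_context()`,
`replicate_gaussian_context()`, `replicate_reg_rand()`. A thin command-line
wrapper lives at `inst/cli/drex.R` (`run`, `simulate`, `replicate`
subcommands). The exhaustive changepoint-enumeration oracle
`enumerate_predictive()` validates the recursion on short sequences.

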