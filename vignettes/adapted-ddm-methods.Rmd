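---
title: "Sequential effects and post-error dynamics in an adapted drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential effects and post-error dynamics in an adapted drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqddm)
```

## The problem

In a two-alternative forced-choice (TAFC) task a subject repeatedly maps one
of two stimuli onto one of two responses. Reaction times (RTs) and error
rates (ERs) on any given trial depend systematically on the recent stimulus
history: trials that repeat the previous stimulus (R transitions) and trials
that alternate (A) are answered at different speeds depending on whether the
preceding transitions were repetitions or alternations, subjects slow down
after committing an error, and error responses on *unexpected* three-trial
sequences (AR, RA) are fast where correct responses are slow. `seqddm`
implements a generative account of these phenomena — a pure drift diffusion
model (DDM) whose starting point and decision thresholds are updated from
trial to trial — together with the stimulus-sequence generators, the
sequence-sorted behavioral analysis, and the summary-statistic fitting
machinery needed to study it end to end on synthetic data.

## The pure DDM core

Within a trial, evidence accumulates as a drifted Wiener process
$dx = \mu\,dt + \sigma\,dW$ from a starting point $x_0$, until it is
absorbed at $+z$ (a correct decision) or $-z$ (an error). All first-passage
statistics depend on the parameters only through the scaled quantities
$\tilde z = z/\mu$, $\tilde x_0 = x_0/\mu$ (both in seconds) and
$\tilde\mu = (\mu/\sigma)^2$ (a squared signal-to-noise rate, 1/s), which is
the parameterization `ddm_params()` stores. RT = DT + $T_{nd}$, with
$T_{nd}$ a non-decision time.

The closed forms implemented are, writing $u = \tilde z \tilde\mu$:

* error rate: $\langle ER\rangle = 1 - \frac{1 - e^{-2(\tilde z + \tilde x_0)\tilde\mu}}{1 - e^{-4\tilde z\tilde\mu}}$,
* mean decision time: $\langle DT\rangle = \tilde z\tanh u + \left[\frac{2\tilde z\,(1 - e^{-2\tilde x_0\tilde\mu})}{e^{2u} - e^{-2u}} - \tilde x_0\right]$,
* conditional means:
  $\langle DT_{correct}\rangle = 2\tilde z\coth(2u) - (\tilde z + \tilde x_0)\coth\!\big((\tilde z + \tilde x_0)\tilde\mu\big)$ and
  $\langle DT_{error}\rangle = 2\tilde z\coth(2u) - (\tilde z - \tilde x_0)\coth\!\big((\tilde z - \tilde x_0)\tilde\mu\big)$.

The conditional means are derived from the standard absorbing-boundary
theory (solving the generator ODE for the outcome-weighted expected exit
time) rather than transcribed: they reduce to $\tilde z\tanh u$ at
$\tilde x_0 = 0$ via the identity $2\coth 2u - \coth u = \tanh u$, and the
package requires them to satisfy two independent checks before anything else
is built on them — the law of total expectation
$(1-ER)\,DT_{correct} + ER\,DT_{error} = DT$ to $10^{-8}$ relative error
over a parameter grid, and agreement with a brute-force Euler–Maruyama
simulation of the diffusion itself (`mc_first_passage()`) within
Monte-Carlo error.

### Numerical choices

All exponentials are arranged to have non-positive arguments (via
`expm1`-style rearrangement), so products $\tilde z\tilde\mu$ of order 10 —
which the reference parameter sets reach, and which overflow the naive
$\sinh^2$ forms — stay finite. $s\coth(s\tilde\mu)$ is evaluated by series
below $s\tilde\mu = 10^{-4}$. Starting points are kept strictly inside the
boundaries; when trial-to-trial updates drive $|\tilde x_0|$ to the current
threshold, it is shrunk by a relative margin of $10^{-9}$, because the
conditional means degenerate on the boundary.

The Monte-Carlo oracle applies the Brownian-bridge within-step crossing
probability $\exp(-2(z - x_t)(z - x_{t+\Delta})/\sigma^2\Delta)$ at both
boundaries on every Euler step. Without this, the $O(\sqrt{\Delta})$
threshold-overshoot bias of naive Euler thresholding at the default step
($10^{-4}$ s) is an order of magnitude larger than the Monte-Carlo standard
error at the default $2\times10^5$ paths, and the oracle could not resolve
the closed forms at the 3-standard-error level. The remaining $O(\Delta)$
time-assignment bias (crossings are booked at the end of the step) is a
factor of several below the standard error at these settings, which is why
path counts are not pushed beyond $2\times10^5$.

## Trial-to-trial adaptation

Two mechanisms, eight parameters (`adaptive_params()`).

**Priming of the starting point.** A memory $M_n \in [0,1]$ of recent
repetitions follows an exponential filter,
$M_n = \Delta M_{n-1} + (1-\Delta)\,\mathbf 1[\text{repetition at } n]$,
with decay $\Delta \in (0,1)$; at $\Delta = 0.5$ the influence of a trial
four steps back is $0.5^4 = 0.0625$, i.e. a memory of roughly four trials.
The printed piecewise definition of this update is typographically ambiguous
in its source; the exponential-filter reading is adopted because it keeps
$M$ in $[0,1]$, makes $\Delta$ a memory-length parameter consistent with the
$\Delta^4$ remark, and matches the description of $M$ as a dynamic memory of
repetitions (the alternative — resetting $M$ to zero on every alternation —
is rejected). The next trial's starting point is
$\tilde x_0 = s\,\big(k(M - \tfrac12) + \tilde x_{offset}\big)$, where
$s = +1$ if the upcoming trial is a repetition and $-1$ if an alternation;
the two printed $\pm$ signs are tied to this single transition-determined
sign, not independent. The magnitude never exceeds $k/2 + \tilde x_{offset}$.
$k$ (seconds per unit memory deviation) scales history sensitivity;
$\tilde x_{offset}$ (seconds) is a fixed bias that favors whichever
transition type the upcoming trial is — it deliberately breaks the exact
R/A mirror symmetry that the $k$ term respects.

**Post-error threshold modulation.** After a correct trial the threshold
drops by $\tilde z_{down}$; after an error it rises by $\tilde z_{up}$,
clamped to $[k/2 + \tilde x_{offset},\, \tilde z_{max}]$ (the lower bound
keeps thresholds at or above any attainable starting point). Lower
thresholds mean faster and more error-prone responses, so the
correct/error asymmetry of the updates produces both post-error slowing and
the fast-error/slow-correct pattern on unexpected sequences.

**Initialization and timing.** Each block starts unbiased:
$M(1) = M(2) = 1/2$ (the filter engages at trial 3), $\tilde z(1) =
\tilde z_{max}$, and trial 1 — having no transition — starts at
$\tilde x_0 = 0$, so trial 2 starts at $\pm\tilde x_{offset}$ only. State is
re-initialized at every block boundary: blocks are separated by breaks and
can change transition probability, and only unbiased initialization is
specified, so the per-block reset is the package's choice (it is also the
conservative one for fitting, since it never lets a block inherit a
mis-adapted state). Whether state should instead carry across blocks is
genuinely open; `simulate_session()` keeps the reset internal to the block
loop so the alternative is a local change.

**Per-trial generation** follows the simulate-and-sort procedure: the
trial's ER comes from the closed form at the current
$(\tilde z, \tilde x_0, \tilde\mu)$, correctness is a biased coin flip, and
the RT is $T_{nd}$ plus the *conditional mean* decision time for the drawn
outcome — no sampling from the full RT distribution. Degenerate ER of
exactly 0 or 1 forces the certain outcome. Exactly one uniform deviate is
consumed per trial, which makes the compiled kernel bit-reproducible against
the plain-R reference implementation kept for cross-checking.

## Reference parameters and synthetic data

Two fitted reference sets ship with the package
(`adaptive_params_defaults()`): one for an unbiased letter task
($\tilde\mu = 38.17$, $T_{nd} = 0.2626$ s, $k = 0.0943$,
$\tilde x_{offset} = 0.0051$, $\Delta = 0.686$, $\tilde z_{down} = 0.0058$,
$\tilde z_{up} = 0.0348$, $\tilde z_{max} = 0.2857$) and one for a
transition-biased dot-motion task ($\tilde\mu = 19.33$, $T_{nd} = 0.3359$,
$k = 0.1181$, $\tilde x_{offset} = 0.0034$, $\Delta = 0.6882$,
$\tilde z_{down} = 0.0034$, $\tilde z_{up} = 0.1635$,
$\tilde z_{max} = 0.2062$). The harder dot-motion task has the lower
signal-to-noise rate and the stronger post-error correction.

The synthetic-data module emulates the two study designs exactly: 13 blocks
of 120 trials at alternation probability $P_A = 0.5$, and 9 blocks of 200
trials at $P_A \in \{0.1, 0.5, 0.9\}$, three blocks each. Stimuli come from
a transition-oriented first-order Markov process: the first stimulus of a
block is equiprobable (unspecified in the source; chosen for symmetry), each
later one alternates with probability $P_A$. Block order in the biased
design is a seeded balanced permutation per subject rather than a Latin
square across subjects: order counterbalancing controls human fatigue and
practice, which the model does not have, and no square is published.
Response-to-stimulus intervals are not generated at all — the model consumes
no RSI, so a gamma-distributed interval column would be decoration.

What the generator deliberately does *not* emulate: dot-motion physics,
anticipatory/premature responses, feedback, fatigue, drifts in attention,
or between-subject heterogeneity. Synthetic subjects are exchangeable
realizations of one parameter set. Passing tests therefore demonstrate
internal consistency of model, analysis, and fitting — they do not
demonstrate that real participants behave like the model beyond the
qualitative patterns the model was built to produce.

## Sequence-sorted analysis

`label_sequences()` assigns each trial its transition (R/A against the
previous stimulus) and its three-trial sequence label (RR, AR, RA, AA — the
previous transition followed by the current one; the label's RT and ER
belong to the final trial). Labels are stimulus-based, never response-based,
and never cross block boundaries; the first two trials of a block are
unlabeled. Outlier RTs (outside 100–900 ms by default) are excluded from
every RT/ER summary but still define their successors' labels, since an
outlier precedes trials that remain in the analysis. Empty label-by-
correctness cells — common at extreme $P_A$, where the rare sequences barely
occur — are carried as missing values, never as zeros.

Error triplets collect, for every error trial with both neighbors inside
the same block, the RTs of the preceding, error, and following trials. The
neighbors' own correctness is not an exclusion criterion (no such rule is
stated in the source; the choice is documented here and the anchor set is
easy to restrict). Each triplet position contributes only non-outlier
entries to its mean.

The 19-element condition summary vector stacks, in fixed order: overall
mean RT for (RR, AR, RA, AA); correct mean RT; error mean RT; ER for the
four labels; and the pre-error, on-error, post-error mean RTs — seconds and
decimal fractions throughout, so all elements are of comparable magnitude.
Three conditions concatenate to 57 elements, ordered by increasing $P_A$.
Two derived statistics summarize the geometry: the sequential RT tradeoff
(OLS line of per-label error RT on correct RT; its negative slope is the
fast-error/slow-correct relation) and the R-line/A-line slopes
$RT(AR)-RT(RR)$ and $RT(RA)-RT(AA)$, which diagnose repetition versus
alternation preference.

Summaries are trial-pooled by default (with per-subject summaries available
by grouping beforehand); whether the original figures pooled trials or
averaged subject means is not stated, and for single synthetic subjects the
two coincide.

## Fitting and model comparison

The objective is the unweighted sum of squared differences between the data
summary vector and the model's, with the model simulated on the *same*
stimulus sequences the subject saw, five passes per evaluation. Elements
undefined in either vector are dropped pairwise (with $N$ reduced
accordingly); this is the package's rule for a case the source does not
address. Minimization is bounded nonlinear least squares via
Levenberg–Marquardt with box constraints (`minpack.lm::nls.lm`), the R
counterpart of trust-region-reflective `lsqnonlin`. The joint constraint
$\tilde z_{max} \ge k/2 + \tilde x_{offset}$ is handled by fitting the
margin $\tilde z_{max} - (k/2 + \tilde x_{offset}) \ge 0$ instead of
$\tilde z_{max}$, so box bounds suffice. Default bounds and the default
start are seeded from the magnitudes of the reference parameter sets.

Because correctness is drawn by coin flips, the objective is stochastic;
common random numbers (one fixed seed reused for every evaluation) make it
deterministic, but only piecewise smooth — an outcome flips discretely as
parameters cross a threshold. Three optimizer choices deal with this:
parameters are rescaled to comparable magnitude; the finite-difference
Jacobian uses deliberately large steps (`epsfcn = 1e-2`, about 10% on the
scaled parameters) so that real slope dominates the micro-jumps; and the
best optimum is polished with 10-fold finer steps. A summary cell the data
define but the model leaves empty is penalized in the optimizer's residual
(not in the reported objective): otherwise degenerate parameter regions
that push every RT past the outlier bounds would empty the model summary
and score a spurious zero.

Parameter-recovery studies on synthetic subjects (one subject, one session,
five passes) show $\tilde\mu$, $T_{nd}$, and $\Delta$ recover with median
relative errors of roughly 19%, 1%, and 6% over ten replicates, while
$\tilde x_{offset}$ — a few milliseconds of fixed bias — is weakly
identified and spreads widely; the recovery study reports that spread
rather than asserting a bound. The objective surface along $\tilde\mu$ is a
noise-flattened ridge at this data volume: fits started far from the truth
land on the ridge near their start, which is why the default start matters
and why multiple random restarts mainly help reject degenerate corners
rather than sharpen $\tilde\mu$.

Model scores use the Gaussian-residual least-squares forms
$AIC = N\ln(Err/N) + 2p$, $AIC_c = AIC + 2p(p+1)/(N-p-1)$ (undefined when
$N - p - 1 \le 0$, i.e. when the number of compared means is too close to
the parameter count), $BIC = N\ln(Err/N) + p\ln N$, with $N$ the number of
compared summary elements (19 or 57), not the trial count — the convention
that matches scores being computable for an 8-parameter model and not for
an 18-parameter one at $N = 19$. Since the original participant data are
not deposited, absolute published scores are not reproduction targets; the
criteria are used for ranking model variants on synthetic data.

After fitting, `replicate_and_average()` reruns the fitted model ten times
and reports per-element means and standard errors, the form in which model
predictions are compared with behavioral summaries.

## Problem sizes and reproducibility

The shipped analyses and tests use one synthetic subject per design (1,560
and 1,800 trials), five model passes per objective evaluation, ten recovery
replicates, $2\times10^5$ oracle paths at a $10^{-4}$ s step, and a
630-point grid for the decomposition identity — sizes at which every
reported number is stable to well inside its stated tolerance. All
randomness flows from explicit root seeds through deterministic per-pass,
per-block child streams, so enlarging `n_passes` reproduces earlier passes
exactly and every table in `analysis/` regenerates byte-identically.

## Known limitations

Only mean conditional decision times are modeled — no RT distributions or
quantiles, and no variable-drift or variable-$T_{nd}$ DDM extensions.
Thresholds stay symmetric at $\pm\tilde z$; there is no within-trial
collapse and no conflict (ACC-style) signal. The fixed offset's sign
convention is tied to the upcoming transition type; the notation would
also permit a fixed direction, which is not implemented. Fitting assumes
one parameter set per table (pool subjects first for a group fit), and the
weak identifiability of $\tilde x_{offset}$ from single-subject data means
its fitted value should not be interpreted without a recovery study at the
data volume in question.
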