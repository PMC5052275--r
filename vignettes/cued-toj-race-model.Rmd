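---
title: "A race model of cued temporal-order judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A race model of cued temporal-order judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedtoj)
```

## The problem

In a temporal-order judgment (TOJ) two targets appear with a variable
stimulus onset asynchrony (SOA) and the observer reports which came
first. When a peripheral cue precedes one target (the *probe*) by a cue
onset asynchrony (COA), the psychometric function of "probe first"
judgments shifts — often far more than attention-based accounts of
*prior entry* can explain. This package implements a process model of
such judgments in the tradition of the Theory of Visual Attention (TVA):
every stimulus, *including the cue*, races for encoding with an
exponential rate, and the cue can win a "cue is the probe"
categorization at rate $v_{cp}$, producing a cue–target confusion that
masquerades as a probe-first percept.

## The model

With the reference target at virtual time zero, the probe at the SOA,
and the cue at SOA − COA, each racer's encoding time is exponential with
its rate ($v_r$, $v_p$, $v_{cp}$), starting $t_0$ after its own onset. A
"probe first" judgment occurs when the probe *or* the cue-as-probe
categorization finishes before the reference. Two refinements shape the
fitted model:

* **Censoring.** The probe masks the cue at its physical onset, so the
  cue's race is terminated (without effect) at probe onset. Its
  uncensored window has length $\max(\mathrm{COA} - t_0, 0)$, and the
  capture probability is $1 - e^{-v_{cp}(\mathrm{COA} - t_0)}$.
* **Reference regime.** When the reference appears before the cue
  (SOA > COA), the cue cannot yet have influenced it, so it races at the
  neutral no-cue rate $v_{neutral}$. The default (`reference_regime =
  "switch"`) implements this as a piecewise-constant hazard — neutral
  until cue onset, $v_r$ afterwards — which the memoryless property makes
  tractable and which reduces exactly to "the reference gets neutral
  resources" whenever it finishes before the cue appears. The
  alternative reading (`"neutral"`: the neutral rate for the whole
  trial on such presentations) is retained behind the config switch; the
  two differ only on SOA > COA trials, and which the original statement
  intends is not decidable from it. Both are exposed so the choice is
  auditable.

The closed form follows from integrating the censored three-racer
competition over the piecewise-exponential reference survival; it was
re-derived from these race rules and is accepted on *oracle
equivalence*: the trial-level Monte-Carlo simulator (`simulate_trials`,
`simulate_curve`) implements the race literally, and the test suite
requires agreement within four binomial standard errors at $n = 10^5$
across 100 random parameter points. The decomposition
(`decompose_contributions`) splits the probability exactly into a
cue-confusion route and a probe route; because a non-censored cue event
always precedes the probe's own completion, the probe route equals
$(1-\kappa)$ times the two-racer probability, with $\kappa$ the capture
probability — a relation the tests check independently.

Ties between racers have probability zero in the model; in floating
point they are resolved as "not probe first" (strict inequality).
Interfaces use milliseconds and Hz; internal arithmetic is in seconds,
converted in one place. $t_0$ defaults to 0 in fitted models — the base
model omits it, and a nonzero threshold (e.g. the conventional 15 ms)
enters only illustrative capture calculations. The obvious
window-shortening formula does not reproduce the published
$t_0$-adjusted capture percentages (60%/66%), whose exact adjustment is
not recoverable; those numbers are therefore not targeted anywhere.

## Synthetic experiments

`make_design("exp1")` reproduces a 30-subject COA-variation design
(no-cue + 40/80/140 ms; nine SOAs per condition with repetitions biased
toward the shifted half-point; 160 trials per condition) and
`make_design("exp2")` a 26-subject cue-displacement design (COA fixed at
80 ms; cue displaced by 0/15/60 px). `population_preset` centres the
generating group rates on the published group-level pattern (neutral
≈ 29 Hz; probe ≈ 69 Hz at COA 80; probe 58, reference 113, confusion 10
Hz at COA 140). Rates the group analysis does not pin down were chosen
once so that each condition's overall rate $C$ (the sum of concurrent
rates) stays near its reported value and the confusion rate grows with
COA: COA 40 = (34, 34, 6) and COA 80 = (69, 19, 8); the displaced-cue
presets interpolate the published endpoints (probe 83 → 27 Hz, confusion
8 → 0 as displacement grows). Between-subject variation is log-normal
with SD 0.3 on the log scale — a typical between-observer spread for TVA
rate parameters — and a subject's neutral rate is shared across
conditions.

Two phenotypes are mixed (80/20 by default): a *beneficial* majority
following the preset table, and a *disadvantageous* minority
(probe 20 < reference 35 Hz, confusion ≈ 0 in every cued condition)
whose curves shift leftward under cueing. The minority's exact rates are
illustrative — no published estimates exist for it — and the generator
draws binomial counts from the closed form, so the synthetic data are
exactly *model-faithful*: no lapses, response errors, learning, or
letter-identity structure. Passing recovery tests therefore demonstrates
that the pipeline is self-consistent at realistic scales, not that real
observers satisfy the model.

## Inference

`fit_toj` estimates subject- and group-level rates by MCMC. Subject log
rates are partially pooled, $\log v \sim N(\mu, \sigma)$ per
condition-specific group; priors are weakly informative with positive
support and heavy right tails on the Hz scale: $\mu \sim N(\log 30,
1.5^2)$ for target rates, $N(\log 5, 1.5^2)$ for the confusion rate, and
$\sigma \sim$ half-Normal(1). The likelihood is binomial with the closed
form supplying each record's success probability. Three variants are
fitted: `full`, `rates_only` ($v_{cp} \equiv 0$) and `confusion_only`
(both targets at the subject's neutral rate).

The sampler is an adaptive Metropolis-within-Gibbs scheme written for
this likelihood's geometry. The posterior has a pronounced ridge — the
data constrain combinations of $(v_p, v_r, v_{cp})$ much more tightly
than the individual rates, visible as a negative posterior correlation
between $(v_p - v_r)$ and $v_{cp}$ — so three update types are combined:
joint random-walk proposals per subject × condition parameter block with
covariance adapted from the chain history; conjugate Gibbs updates of
group means; and repeated joint *translation* moves that shift a
condition's group means together with all member subject rates (the
pooled prior terms are invariant under these, and they carry the longest
autocorrelations). Acceptance targets are 0.44 (scalar) and 0.234
(blocks); adaptation freezes after warmup. Defaults are 3 chains ×
(1500 warmup + 1500 kept). Convergence is summarized by split-chain
$\widehat R$ with a 1.01 flag threshold and effective sample sizes
(Geyer initial-positive-sequence); a fit exceeding the threshold is
returned *flagged*, with a warning — ridge-aligned parameters mix
slowest, and their wide HDIs are a genuine feature of the posterior, not
an artifact. Group-level rates are reported as $e^{\mu}$, the population
median rate.

## Model comparison

`compare_toj_models` scores each variant by approximate leave-one-out
cross-validated predictive density, computed by Pareto-smoothed
importance sampling over the posterior draws (generalized-Pareto tail
fit by the Zhang–Stephens profile method), with standard errors from the
pointwise values. Scoring is per condition by default — each condition's
records are summed separately, which matches reporting a winner per
cueing condition — with a joint mode available; whether the original
comparison was per condition or joint is not recoverable, hence both.
Ranking is *standard-error-aware*: variants are ordered by score, and a
variant with more free mechanisms must lead a simpler nested one by more
than the standard error of their score difference to outrank it (a
one-SE parsimony rule, as in common cross-validation practice).
Score differences between nested variants on data the simpler variant
generated are small by construction, so without this rule the ranking
there would be decided by estimator noise.

## Reporting

`pss_dl_from_rates` root-finds the model curve for the point of
subjective simultaneity (PSS, the SOA of the 0.5 crossing) and a
difference limen (DL), defined — since the classical quantile convention
varies — as half the SOA distance between the 25% and 75% points
(configurable). `fit_classic_curve` is the traditional analysis: a
maximum-likelihood logistic fit to the counts (binomial GLM), with
degenerate data (all floor or all ceiling) returning a flagged failure
rather than a number. `render_reports` writes posterior density panels
with 95% HDI brackets, subject-level posterior predictive curves
normalized to [0, 1] over the raw data, and curves shaded by the
cue-confusion contribution.

The package's central demonstration combines these: on synthetic data
with a reference-rate advantage ($v_r > v_p$, as inhibition of return
produces at long COAs) plus a 10 Hz confusion rate, the classic PSS is
still far *rightward* — the confusions conceal and overcompensate the
inhibitory rate pattern, which only the model-based contrast exposes.

## Problem sizes and numerical choices

The analysis drivers and tests use synthetic experiments at the original
designs' scales (30 and 26 subjects, 160 trials per condition);
recovery checks run 20 seeded replications of the full 30-subject
design, and ranking checks 10 replications per pattern with the
confusion-pattern checks at 10 subjects and the displaced-cue check at
26. Probabilities entering binomial likelihoods are clamped to
$[10^{-12}, 1-10^{-12}]$; the closed form's segment integrals are
evaluated on the log scale so extreme rates cannot overflow; proposals
are rejected outside $|\log v| \le 15$; and the group-spread walker is
confined to $\log \sigma \in [-7, 3]$, all far outside the scientifically
relevant region.

## Limitations

The generator and the likelihood share the same closed form, so
recovery tests validate the pipeline, not the model's adequacy for real
observers. No lapse/guessing parameter is included by default; the
resource-redistribution interpretation of *why* rates change with COA
and displacement is out of scope, as are reaction-time likelihoods and
trial-order effects. Subject exclusion by cueing phenotype (the
disadvantageous minority) is available only as an explicit, transparent
filter on fitted contrasts and is off by default, since no published
rule exists.
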