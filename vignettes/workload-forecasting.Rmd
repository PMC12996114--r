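---
title: "Forecasting athlete workload with recurrent networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting athlete workload with recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(workloadcast)
```

## Scope and data model

`workloadcast` forecasts six per-session activity indicators for every player
of a team-sport squad: total distance (m), maximal speed (km/h), maximal
metabolic power (W), accumulated acceleration load (a.u.), jumps and changes
of direction (counts). The atomic record is one player-session; a panel is a
tibble of such records with a per-player ordinal `session_index`, a session
type (`training`/`match`) and one of three sensed court roles
(`wing`/`back`/`pivot`; goalkeepers do not wear sensors and are out of
scope). Calendar dates are deliberately abstracted away: the series is
indexed by session order, and a player simply lacks a row for sessions they
missed — no imputation happens at the I/O layer. CSV output fixes one decimal
place for KPI values and a deterministic row order so that writes are
byte-stable; full precision is kept in memory.

## The synthetic squad generator

Real squad-level sensor exports are confidential, so the package ships a
generative simulator whose defaults encode the study conditions the package
is developed against: a 15-player squad (4 wings, 7 backs, 4 pivots) observed
over 108 sessions, with position-level KPI means set to published
per-position season averages (e.g. wings run 5294.5 m per session at up to
26.1 km/h, backs peak at 8173.6 W of metabolic power). For player $i$ of
position $p$, session $t$, KPI $k$:

$$y_{itk} = \max\{0,\ (\mu_{pk} + a_{ik} + z_{itk})\, m_k^{\mathbb{1}[\text{match}]}\, e^{\varepsilon_{itk}}\}$$

* $a_{ik} \sim N(0, (s_a\mu_{pk})^2)$ — stable between-player level
  differences, $s_a = 0.08$ by default;
* $z_{it}$ — a latent AR(1) "form" vector shared across KPIs,
  $z_{it} = \phi z_{i,t-1} + \eta_{it}$ with $\phi = 0.5$, stationary sd
  $s_z\mu_{pk}$ ($s_z = 0.10$), innovations correlated across KPIs (0.5 among
  the locomotor trio distance/metabolic power/acceleration load, 0.2
  elsewhere);
* $m_k$ — multiplicative match effects (1.15 for the locomotor trio, 1.05
  for maximal speed, 1.0 for the counts), applied on a shared team calendar
  in which each session is a match with probability 0.25;
* $\varepsilon$ — i.i.d. Gaussian log-noise with mean $-\sigma^2/2$, so the
  multiplicative noise has mean one and a configured coefficient of variation
  (0.15); configured means are therefore exactly the training-session
  expectations.

Only the position means and the squad/season size come from published
figures; every distributional choice (log-normal noise, Gaussian offsets,
shared AR(1) state) and every magnitude not publicly reported (noise CV,
match-effect sizes, correlations, $s_a$, $s_z$) is a package design choice,
picked once for positivity, realistic relative variability (a CV of ~15%
around a 4–5 km session distance) and simple moment-based recovery. The
latent-state scale $s_z$ is a parameter the generative model needs but that
no published summary pins down; it is exposed as `state_sd_frac`. One seed
drives everything: the team calendar is drawn first, then each player gets a
deterministically derived independent stream, so panels are reproducible
record-for-record.

What the simulator does *not* emulate: injuries and absences, seasonal
periodisation (tapering, congested fixture blocks), heteroscedastic
match-to-match intensity, menstrual-cycle or cardiac covariates, and
measurement drift. Tests passing on these panels therefore demonstrate that
the machinery is correct under the stated statistical structure, not that the
model is well calibrated for any particular real squad.

### Parameter recovery

`recover_parameters()` inverts the generator by moments: training-session
means per position estimate $\mu_{pk}$; per-position match/training mean
ratios estimate $m_k$. The AR coefficient is subtler: within-player demeaned
residuals carry multiplicative white noise (which attenuates the lag-1
autocorrelation) and a finite-sample demeaning bias that is nearly constant
across lags. The estimator
$\hat\phi = (\hat\gamma_2 - \hat\gamma_3)/(\hat\gamma_1 - \hat\gamma_2)$
on pooled residual autocovariances cancels both contaminations (white noise
only affects lag 0; differencing removes the common bias term), at the cost
of extra variance — across 24 replicate squads its Monte-Carlo mean is within
sampling error of the true $\phi$, which is exactly what the acceptance suite
checks. The raw lag-1 autocorrelation is also reported for null-case
diagnostics ($\phi = 0$ panels).

## The forecaster

One network serves the whole squad. Inputs per prediction: a window of
`window_length = 10` past sessions (six z-normalised KPI channels plus the
binary session-type channel), the session type of the step being predicted
(the team calendar is known ahead), and a learned 4-dimensional player
embedding that absorbs position and individual ability. A single 32-unit
LSTM layer summarises the window; its final hidden state, the embedding and
the next-step type flag feed one 32-unit ReLU layer and a linear head
emitting all six KPIs simultaneously. Multi-target output lets the model
exploit cross-KPI correlation; the exogenous channel lets it anticipate
match peaks that univariate baselines can only average over.

Training: Adam (learning rate $10^{-3}$, batch 128) on the mean squared
error of the normalised targets, at most 60 epochs with early stopping
(patience 8) on a per-player chronological validation tail (15% of each
player's provided history, at least 3 sessions); the best-validation weights
are restored. Normalisation is a **global** per-KPI z-score fitted on the
training portion only — per-player normalisation would leak exactly the
player effect the embedding is meant to learn. Forward, backpropagation
through time and the optimiser are implemented in vectorised base R; the
backward pass is verified against central finite differences in the unit
suite, and everything (initialisation, shuffling, dropout draws) is
deterministic given the configured seed. Windows are built from each
player's ordered rows, treating the observed sequence as contiguous.

Multi-step forecasts are recursive: the one-step prediction is appended to
the window together with the known next session type, and the rollout
repeats. Recursive (rather than direct multi-horizon) forecasting was chosen
because the exogenous calendar is available per future step and a single
one-step head keeps the parameter count small at squad-scale data volumes.
De-normalised forecasts are clamped at zero, since all KPIs are physical
non-negatives.

## Uncertainty

Dropout is variational: one Bernoulli mask per sample, drawn per forward
pass and reused across time steps — on the recurrent state inside the LSTM,
on the final hidden state, and on each dense activation (rate 0.2). At
inference, `n_mc = 100` stochastic rollouts (each with its own mask set,
held fixed along the recursion) give an epistemic mean and variance per KPI
and step. MC spread alone reflects parameter uncertainty only and badly
under-covers actual observations, so intervals add an aleatoric component:
per-KPI, per-step residual variances estimated after training from
rolling-origin forecasts whose targets lie in each player's validation tail
(two origins per player, lightly smoothed across adjacent steps because each
cell pools only a few dozen squared residuals). The band at level $\alpha$
is $\bar y \pm z_\alpha\sqrt{\sigma^2_{\mathrm{MC}} + \sigma^2_{\mathrm{resid}}}$,
clamped at zero; with zero dropout the epistemic term vanishes exactly and
the band is purely aleatoric. On replicate default squads the pooled
coverage of nominal 95% bands on held-out sessions sits within a few points
of the nominal level (the acceptance suite requires [90, 99] pooled over ten
squads).

## Evaluation protocol

The rolling holdout withholds the final 10 sessions of every player; models
see only the pooled history. Errors are pooled over all (player, step)
residuals into one RMSE and MAPE per model and KPI — pooling (rather than
averaging per-player RMSEs) is the simplest well-defined statistic; RMSE is
printed to 2 decimals and the headline relative improvement
$100(\mathrm{RMSE}_{\text{best baseline}} - \mathrm{RMSE}_{\text{model}})/\mathrm{RMSE}_{\text{best baseline}}$
to 1 decimal. Coverage uses closed intervals (a boundary hit counts).
Baselines produce flat multi-step forecasts for the moving average (window
5) and simple exponential smoothing (the textbook definitions) and recursive
forecasts for ARIMA; MAPE errors out on near-zero actuals rather than
clamping, since all six KPIs are strictly positive in practice.

## Attribution and reports

Importance of input cell $(l, c)$ for target KPI $k$ is
$|\partial\hat y_k/\partial x_{lc}|$ with dropout off — raw gradient rather
than gradient×input by default (the latter is available behind a flag), and
computed at the point forecast; attribution under MC sampling is out of
scope. At horizon step 1 the gradient is exact backpropagation to the
inputs; at later steps the prediction is a recursive composition through
fed-back forecasts, and central finite differences (step $10^{-4}$) on the
rollout are used instead. Aggregation sums scores over lags or channels
(total conserved) with optional sum-to-one renormalisation; default
staff-facing summaries use horizon step 1 and channel-level aggregation.
Report text comes from a pluggable backend; the bundled implementation is a
deterministic template (top-3 drivers in score order with canonical-order
tie-breaks, forecast direction vs the recent-session mean, interval width,
and a fatigue flag when running volume dominates a downward forecast), so
outputs are byte-identical across calls and testable offline. An external
language-model backend can be plugged in with the same contract.

## Numerical choices and degenerate inputs

* Forget-gate bias initialised at +1; other weights uniform in
  $\pm 1/\sqrt{\text{fan}}$; embeddings $N(0, 0.1^2)$.
* KPI standard deviations are floored at $10^{-8}$ before normalising, so a
  constant column cannot divide by zero.
* Early stopping requires an improvement of at least $10^{-7}$ in
  validation MSE.
* `best baseline` ties in the evaluation report break toward the first
  model in declared order; attribution ties break in canonical channel
  order.
* Players with fewer than `window_length + 2` sessions cannot contribute a
  train and a validation window and are dropped with a warning (or an error
  on request); the holdout split likewise excludes players with `<= horizon`
  sessions.
* The summary's team-total row is the session-weighted mean over all
  records, not the mean of position means — with unequal position group
  sizes the two differ, and the weighted version is the one that is
  well-defined for any squad composition.

## Problem sizes

Default test and acceptance runs use the default squad scale (15 players ×
108 sessions, ~1100 training windows, ~6600 parameters), for which one fit
takes a few seconds on a single core; the simulator-fidelity check uses one
long season of 2000 sessions per player, parameter recovery 24 replicate
squads, interval calibration 10 replicate squads, and the model-ordering
comparison 5 replicate squads. These sizes were chosen as the smallest at
which the sampling error of each checked quantity is comfortably below the
effect being verified.

## Known limitations

* The aleatoric variance is estimated from few residuals per (KPI, step)
  cell; its sampling noise moves empirical coverage a few points around the
  nominal level.
* Recursive rollouts compound one-step biases at long horizons; horizons
  beyond the calibrated 10 steps reuse the step-10 residual variance.
* The simulator's stationarity means the forecaster is never tested against
  trends or regime changes; on real data, retraining cadence matters and is
  not addressed here.
* ARIMA order search is a small AIC grid ($p, q \le 2$, $d \le 1$); seasonal
  structure is not modelled.
* Attribution explains the model, not the athlete: a high gradient on a
  channel is evidence about the fitted function, not a causal statement
  about physiology.
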