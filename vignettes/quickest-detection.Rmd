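---
title: "Quickest detection of seizure onset: model, policy and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quickest detection of seizure onset: model, policy and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdetect)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, the numerical choices, and the places where the
design was genuinely open and a choice had to be made.

## 1. From multichannel recording to a one-dimensional statistic

Each second of an $n$-channel recording contributes one connectivity
matrix $A(k)$, computed over the 5-s window $(k-5, k]$ (1-s slide).
Entry $(i, j)$ is the magnitude of the cross-power spectral density of
channels $i$ and $j$ integrated over a frequency band $[lb, ub]$:

$$A_{ij}(k) \;=\; \Bigl|\; \int_{lb}^{ub} P_{ij}(\omega)\, d\omega \;\Bigr| .$$

The causal window alignment matters: the matrix indexed by second $k$ uses
no samples after $k$, so a detector reading the series at stage $k$ is
strictly online.

**Spectral estimator.** No estimator is canonical for this construction,
so the package uses Welch averaging: 1-s Hann-tapered sub-windows with 50%
overlap inside each 5-s window (nine sub-windows), one-sided density
scaling, and trapezoidal integration over the FFT bins whose centres fall
in $[lb, ub]$, endpoints inclusive. At typical clinical sampling rates
(250–500 Hz) this trades variance against a 1-Hz resolution that
comfortably resolves the classical bands. The off-diagonal cross-spectrum
is complex; taking the magnitude of its band integral makes $A$
symmetric, real and nonnegative, which the singular-value analysis
presumes. The real part is selectable (`quantity = "real"`) for users who
prefer to discard quadrature coupling. The auto-power diagonal is
included; whether to include it was an open point, and keeping it makes
$A$ a proper nonnegative-definite-like network matrix whose trace tracks
total band power.

**Band presets.** theta 4–7 Hz, alpha 8–13 Hz, beta 13–30 Hz. Published
descriptions of the beta band vary between a 13-Hz and a 14-Hz lower
edge; the package follows the tabulated 13–30 Hz convention.
`select_band()` picks among candidate bands by fitting the two emission
models per band and maximizing a Wald-type standardized distance
$\lVert(\Theta_1-\Theta_0)/\mathrm{se}\rVert_2$ between the parameter
vectors — the training-only rule that mirrors patient-specific band
selection. Symmetrized-KL between one-step predictive laws was the
considered alternative; the Wald distance was kept because it needs no
reference history distribution and is scale-free.

The detection statistic is $\sigma_1(k)$, the largest singular value of
$A(k)$: as inter-channel coupling strengthens, the network matrix
collapses toward low rank and $\sigma_1$ rises. The first singular vector
$v_1(k)$ (sign-fixed so its largest-magnitude component is positive)
records the dominant coupling direction; its rotation at onset is
diagnostic but is not used by the decision rule.

## 2. The observation model

The quantized statistic $n_k = Q(\sigma_1(k))$ follows a two-state hidden
Markov model. State 0 (nonictal) transitions to the absorbing state 1
(ictal) with per-second hazard $\rho$; monitoring starts nonictal
($P_0 = [1, 0]$; the constructor accepts other priors for validation
studies). Emissions are history-dependent Poisson GLMs,

$$\log \lambda_{x,k} \;=\; \alpha_x + \sum_{j=1}^{L} \beta_{x,j}\, n_{k-j},$$

fitted separately per state by maximum likelihood (IRLS via `stats::glm`,
with a ridge-stabilised fallback, $\lambda = 10^{-6}$, on degenerate
designs). The history term is what lets two states with overlapping
marginal distributions of $\sigma_1$ be distinguished by their dynamics.

Parameter choices and defaults:

* **Quantizer** — uniform bins on the training range, default
  `n_bins = 50`, out-of-range values clipping to the end bins. No
  published rule exists for the quantizer; uniform binning keeps
  $Q$ monotone and makes the code domain explicit. Quantile binning is a
  one-line substitution via `build_quantizer()`'s edges.
* **Lag order** — default $L = 15$ s of history; selected by AIC
  ($2(L+1) - 2\ell$) over candidates when `candidate_L` is given, with
  all candidates refitted on a common response window so likelihoods are
  comparable, ties toward the smaller model.
* **Hazard** — $\hat\rho$ = (observed 0→1 transitions) / (stages in state
  0 with a successor), pooled over training sequences; transitions are
  counted at the annotated onset seconds.
* **Training protocol** — each stage keeps its true preceding history
  from the continuous series, so ictal epochs shorter than $L$ still
  contribute fitting rows; this is the package's resolution of an
  otherwise unspecified boundary case.

## 3. The information-state filter

The posterior $\pi_k = \Pr(x_k = 1 \mid z_k, H_k)$ evolves as

$$\pi_{k+1} \;=\; \frac{L_{k+1}\,(\pi_k + (1-\pi_k)\rho)}
{(1-\pi_k)(1-\rho) + L_{k+1}\,(\pi_k + (1-\pi_k)\rho)},$$

with likelihood ratio $L_k = q_1(z_k|H_k)/q_0(z_k|H_k)$ computed in the
log domain and clipped to $[e^{-50}, e^{50}]$, and the initial condition
$\pi_0 = q_1(z_0)(1-p_0) / (q_0(z_0)p_0 + q_1(z_0)(1-p_0))$. The
empty-history evaluation of $q_x(z_0)$ pads with the integer nearest the
nonictal stationary mean $e^{\alpha_0}$ — the same padding used for all
stages with insufficient history, chosen to avoid a start-of-sequence
transient. $\pi$ is clipped to $[10^{-12}, 1-10^{-12}]$ between updates
so the recursion stays responsive after hours of quiescence. With unit
likelihood ratios the update reduces exactly to the geometric prior CDF,
$\pi_k = 1-(1-\pi_0)(1-\rho)^k$ — one of the package's invariant tests —
and on small alphabets the recursion reproduces the brute-force
path-enumeration posterior to $10^{-12}$.

After a detection the filter terminates and restarts: $\pi$ re-initializes
while the observation history buffer is retained, because the physical
signal is continuous across the alarm (`reset_history = TRUE` restores
the fully independent restart, under which the post-restart trajectory
equals a fresh run on the suffix).

## 4. The stopping policy

The cost-per-stage charges delay while a true onset goes undetected and
prematurity when stopping early:

$$G_k(\pi, u) \;=\;
\begin{cases}
\gamma \; \mathbb{E}[\,k-T \mid T \le k\,] \cdot \pi & u = 0,\\[2pt]
(1-\gamma)\; \rho^{-1} \,(1-\pi) & u = 1,
\end{cases}$$

with $T$ geometric($\rho$). The truncated-geometric delay factor
$\mathbb{E}[k-T \mid T\le k]$ grows without bound in $k$, so the longer an
onset could already have been missed, the cheaper stopping looks — this
is what makes the synthesized threshold fall (non-monotonically) toward
the horizon. Because the factor itself is an expected elapsed delay,
accumulating it over stages penalizes roughly the *squared* delay; a
squared per-stage factor (`delay_exponent = 2`) is available but the
linear form is the default operational cost. The final-stage cost is the
forced stop $G_M(\pi) = (1-\gamma)\rho^{-1}(1-\pi)$, so the horizon
always forces a decision; a delay-style alternative is configurable.

Backward induction runs over a uniform grid of 1001 information-state
points (linear interpolation of $J_{k+1}$ inside the one-step
expectation), giving the per-stage threshold $F_k$ = the smallest grid
point at which stopping is weakly optimal; the online rule is the strict
$\pi_k > F_k$, so ties continue. Degenerate weights collapse correctly:
$\gamma = 1$ gives $F \equiv$ grid minimum (detection at the first
stage), $\gamma = 0$ gives $F \equiv 1$ before $M$ (no detection).

**History in the dynamic program.** Exact DP over history-dependent
emissions is exponential in $L$. The policy is therefore synthesized
against *history-marginalized* emission laws: with training data, the
average one-step predictive pmf over observed training histories per
state; without it, the Poisson pmf at the self-consistent rate
$\lambda = e^{\alpha + \lambda\sum_j\beta_j}$. Poisson tail mass above
the top code is lumped into the top code so the DP alphabet stays finite.
The online filter always uses the full history. The approximation is
validated where it is exact — history-free models — by a grid-free DP
(`qd_value_exact()`) that matches exhaustive enumeration over all state
paths and stopping rules to $10^{-9}$.

**Horizon.** $M$ defaults to the mean inter-onset interval of the
training annotations. Monitoring segments that outlive $M$ keep running
with the threshold held at its final-stage value, a deliberate choice to
keep long recordings armed rather than silently stopping at the horizon.

**Re-arming.** After an alarm the detector restarts and will not fire
again until (i) the 60-s refractory period has elapsed *and* (ii) the
posterior has dropped back below the current threshold. The second,
renewal-style condition exists because a persisting alarm condition —
the posterior saturated through the remainder of a seizure and its
postictal drain — is one event, not a train of events; without it every
event re-fires exactly at refractory expiry, and a spike-triggered alarm
shortly before a true onset can push the true detection outside the
matching window.

## 5. Baselines and scoring

The Bayesian estimator fires at the first $\pi_k > 0.5$; the heuristic
detector at the first $z_k > \bar h = \mu_z + 3\sigma_z$ with mean and
*sample* standard deviation taken over nonictal training data (the SD
convention had to be chosen; $n-1$ is the default any R user would get).
Both share the restart/refractory/hysteresis machinery.

Scoring matches detections to annotated onsets greedily in detection-time
order, one-to-one, within a symmetric ±20-s tolerance; the signed delay
is detection − onset (negative = anticipation), and the combined delay
summary is the mean of absolute values. The false-positive rate is FP per
analyzed hour, the analyzed span excluding annotated ictal time (and
optionally refractory time). `gamma_sweep()` re-synthesizes the policy
per $\gamma$ and traces the delay-versus-FP curve.

## 6. What the synthetic generator emulates — and what it does not

Two generators make every stage testable without clinical data.

`simulate_record()` produces multichannel surrogate signal: independent
AR(1) noise per channel (coefficient 0.9, innovation SD 1) plus a shared
sinusoid at `drive_freq_hz` whose amplitude switches from
`nonictal_coupling` (0.2) to `ictal_coupling` (1) inside annotated
epochs. Because the connectivity matrix responds directly to shared
band-limited power, the generator's effect on $\sigma_1$ is analytically
predictable: a rank-one component of magnitude proportional to the
squared drive amplitude. Epoch onsets are geometric (`state_dwell`,
default 1/300 per s) with fixed 60-s duration.

`make_qd_corpus()` simulates the fitted observation process directly:
ten 2-h runs of counts from the reference model `example_hmm_glm()` —
nonictal $\alpha_0 = \log 3$, $\beta_{0,1} = 0.05$; ictal
$\alpha_1 = \log 8$, $\beta_{1,1} = 0.03$; $L = 1$; 30-code alphabet;
hazard $\rho = 5\times10^{-5}$ per second. The hazard puts the mean onset
latency (~5.6 h) beyond the 2-h monitoring horizon: the rare-event regime
in which seizures genuinely are rare relative to monitoring, and in which
the optimal threshold stays well above the Bayesian-estimator level. Each
run's onset is drawn from the model's *own* geometric prior, conditioned
to fall inside the observation window — consistency that matters, because
a generator whose onsets contradict the filter's prior produces a policy
that is optimal for neither. Two empirically documented features of the
real statistic are reproduced through a multiplicative intensity gain:
the postictal reset (gain 0.3 ramping to 1 over 600 s after each event,
mirroring the drop of $\sigma_1$ below baseline after seizures) and
sporadic abrupt spikes (1.5 per hour, 1–3 s, gain 1.8–3.5 — the noise
transients that trip fixed-threshold detectors).

What is *not* emulated: physiological seizure morphology (spikes,
electrodecrement, evolving rhythms), volume conduction, electrode
artifacts, nonstationary background drift, and patient heterogeneity.
Passing tests on this corpus therefore demonstrate the correctness of the
statistic, filter, policy and protocol under the model's own assumptions
— they do not certify clinical performance, which in the source study
required 168 h of annotated recordings.

## 7. Numerical choices, degenerate inputs, problem sizes

* Likelihood work in the log domain; likelihood ratios clipped at
  $e^{\pm 50}$; $\pi$ clipped at $10^{-12}$ from both ends; the
  information-state denominator cannot underflow silently (a saturating
  branch warns).
* The simulator refuses log-rates above +20 (runaway self-excitation is
  an error, never a silent clip).
* Constant training values make the quantizer degenerate — an error, as
  is a training sequence with no nonictal time for $\hat\rho$.
* AIC ties break toward the smaller lag; the DP's stop region is checked
  for being an upper interval on the grid and warns otherwise.
* One integer seed governs each generator call; the corpus derives
  per-run sub-seeds deterministically from it.
* Problem sizes used by the test-suite studies: 10 × 2-h runs (72 000
  observation stages) for the detector comparisons and the $\gamma$
  sweep; 1000 chains of 300 stages for hazard recovery; 100 replicates of
  20 000 stages for GLM coverage; all length-8 words over a 3-symbol
  alphabet (6561 sequences) for posterior exactness; 20 random models
  with $M \le 6$ for the DP cross-check. These sizes keep the full suite
  in the low minutes while leaving Monte-Carlo margins wide.

## 8. Known limitations

* The DP's history marginalization is an approximation for $L > 0$; its
  error is unquantified beyond the history-free validation. The filter —
  and hence BE — is exact regardless.
* The adaptive threshold depends on the observation only through $\pi$;
  a finer dependence on the current observation and history is possible
  in principle but is not derivable from the printed formulation.
* $\hat\rho$ assumes a homogeneous hazard; circadian or state-dependent
  onset rates are out of scope (as is any $m > 2$-state extension or
  multi-band fusion).
* EDF input is not read directly; recordings enter as delimited text
  matrices (channels as columns) with a sidecar annotation CSV.
* The truncated-geometric delay factor grows linearly in $k$, so for
  horizons far beyond $1/\rho$ the late-stage thresholds become small;
  users monitoring much longer than the mean inter-seizure interval
  should restart monitoring blocks (or re-fit $\rho$) rather than rely on
  a single enormous horizon.
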