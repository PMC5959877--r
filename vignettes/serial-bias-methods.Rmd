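---
title: "Modeling serial dependence in visuospatial working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling serial dependence in visuospatial working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The phenomenon and the model layers

In oculomotor delayed-response tasks a subject views a target angle
$\theta_n$, holds it in memory through a delay, and reports it with a
saccade $r_n$. Responses are systematically attracted toward the target of
the *previous* trial: the bias grows with the current trial's delay,
decays with the intertrial interval (ITI), and is a graded, non-monotonic
function of the angular separation $\theta_n - \theta_{n+1}$. `serialwm`
implements three linked layers that explain this interference and exposes
the protocol generators and analyses needed to measure it.

**Layer 1 — sequential Bayesian prediction** (`predict_exact()` and its
limits). An observer assumes the target-generating distribution changes
between trials with probability $\varepsilon$ and predicts the next target
from the history $\theta_{1:n}$. Conditioning on the run length $l$ (how
many recent trials share the current distribution, with prior
$P(l)=\varepsilon(1-\varepsilon)^l$ for $l<n$ and $(1-\varepsilon)^n$ at
$l=n$) gives a mixture over trailing-segment kernel products. Each
observation enters through a self-conjugate tuning kernel
$f_{\theta'}(\theta) \propto \exp\sum_j a_j \cos(\omega_j(\theta-\theta'))$
with $\omega_j = j\pi/180$ for $\theta$ in degrees. For $\varepsilon \to 0$
all observations weigh equally (`predict_static()`); for
$\varepsilon \approx 1$ the prediction collapses onto the last target,
$\tilde L = \varepsilon/360 + (1-\varepsilon)f_{\theta_n}(\theta)$
(`predict_rapid()`), which is the regime that produces single-trial-back
serial bias.

**Layer 2 — attractor dynamics.** The remembered angle behaves as a
particle on a potential,
$d\theta = -\mathcal U'(\theta)\,dt + \sigma_\theta\,d\xi$. Matching the
stationary Fokker–Planck density
$\bar p(\theta) = \chi \exp[-2\,\mathcal U(\theta)/\sigma_\theta^2]$ to the
predictive distribution gives the exact correspondence
$\mathcal U(\theta) = (\sigma_\theta^2/2)\log(\chi/L_\theta)$
(`potential_from_predictive()` / `stationary_density()` are exact
inverses). In the rapid-change regime
$\mathcal U_{n+1}(\theta) \propto -f_{\theta_n}(\theta)$: the memory drifts
toward the previous target.

**Layer 3 — the ring network with facilitation.** A stochastic neural
field on preferred-angle space $x \in [-180, 180)^\circ$:

$$du = \left[-u + w * \big((1+q)F(u)\big) + I(x,t)\right]\frac{dt}{\tau_u} + dW,
\qquad \tau\,\dot q = -q + \beta F(u)(q_+ - q),$$

with single-cosine coupling $w(x)=\cos x$ (radians internally), sigmoid
rate $F(u) = 1/(1+e^{-\gamma(u-\kappa)})$, and spatially smooth noise with
covariance $\sigma_W^2\cos(x-y)$. A cue nucleates a bump of activity whose
peak stores the angle; short-term facilitation (STF) $q$ strengthens
synapses from recently active neurons on a seconds timescale, leaving a
bump-shaped trace at the previous target that attracts the next trial's
bump — the physiological carrier of the layer-1 prediction.

A timescale separation ($\tau/\tau_u = 100$) reduces the field to the bump
position $\theta(t)$ and the facilitation center $\theta_q(t)$
(`simulate_reduced()`): the drift on $\theta$ is a mixture of the decaying
previous-trial potential $\mathcal A_n(t)\,\bar{\mathcal U}'(\theta-\theta_n)$
and the growing current-trial one, with the Heaviside-limit gradient

$$-\bar{\mathcal U}'(\delta) = \frac{\beta q_+}{2(1+\beta)\tan a}
\left[\mathrm{sign}(\delta)(1-\cos\delta) - \tan a \sin\delta\right],
\qquad |\delta| < 2a,$$

zero outside, where $a$ is the bump half-width solving $\sin 2a = \kappa$
(stable wide branch). The facilitation amplitudes follow exact exponential
kinetics (`facilitation_amplitude()`), and $\theta_q$ relaxes toward
$\theta$ at rate $(1+\beta)/\tau$.

# Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $\tau_u$ | synaptic (activity) time constant | 10 | ms |
| $\tau$ | facilitation time constant | 1000 | ms |
| $\beta$ | facilitation onset rate | 0.01 | – |
| $q_+$ | maximal facilitation | 2 | – |
| $\gamma$ | firing-rate gain | 20 | – |
| $\kappa$ | firing threshold | 0.1 | – |
| $\sigma_W$ | noise amplitude | 0.005 | per $\sqrt{\tau_u}$-time |
| $T_C$ | cue duration | 150 | ms |
| $T_A$ | post-response inactivation | 500 | ms |
| $I_0, I_1, I_R$ | cue peak, cue sharpness, inactivation strength | 1, 1, 2 | – |
| $dx$, $dt$ | grid spacing, step | 0.18°, 0.1 ms | (fast profile: 0.72°, 0.5 ms) |

The comparison tuning kernel defaults to a single harmonic with $a_1 = 2$,
chosen so its central region matches the facilitation-derived kernel shape;
it is a configuration default, not a fitted value.

# Numerical and design choices

**Units.** All interfaces use degrees; the field integrator works in
radians so that the single-cosine coupling has unit spatial frequency and
the Heaviside bump amplitude $2\sin a \approx 2$ sits naturally against
the threshold $\kappa = 0.1$.

**Noise convention and the diffusion coefficient.** Time is
nondimensionalized by $\tau_u$, so the noise increment enters $u$ with
variance $\sigma_W^2\,dt/\tau_u$. This calibration puts the delay-period
response spread in the few-percent-of-the-circle range observed over
1–10 s delays. Projecting the noise on the translation mode gives the
bump diffusion coefficient; for the Heaviside bump this has the closed
form $D = \sigma_W^2/(8\,\tau_u \sin^2 a)$ (rad²/ms), which we also derive
directly: the bump is a first-harmonic profile of amplitude $2\sin a$, and
the rank-two cosine noise shifts its phase by its sine component over the
amplitude. The measured displacement variance of the static-synapse
($\beta=0$) network grows as $2Dt$; the test suite verifies the linear fit
and the slope.

**Convolution.** The coupling is a finite cosine series, so the periodic
convolution is computed exactly by harmonic projection
($w*g = \sum_n \alpha_n[\cos(nx)\langle\cos(ny),g\rangle +
\sin(nx)\langle\sin(ny),g\rangle]$) rather than by FFT; the two are
mathematically identical for this kernel class and the projection is
cheaper and exact. A constant field maps to zero (mean-free coupling).

**Quiescent intertrial periods.** With the default sigmoid
($\gamma = 20$, $\kappa = 0.1$) the homogeneous state is pattern-forming:
left undriven, a bump self-nucleates within tens of milliseconds at a
noise-determined position. Were that allowed during the ITI, the cue could
not reliably recapture the bump and the trial-history signal would be
destroyed. We therefore hold the global inactivating input $-I_R$ from the
response until the next cue ($T_A + T_I$), so activity genuinely ceases
between trials and facilitation alone carries the history. Consistently,
the reduced model's intertrial facilitation decay spans the full
response-to-cue gap, $\mathcal A_n = (1-e^{-(T_C+T_D)/\tau})\,
e^{-(T_A+T_I)/\tau}$. The 2 s noise-driven burn-in before trial 1 ends
with one such inactivation period, and delay ensembles start each path
from a briefly suppressed state followed by the cue.

**Readout.** The response is the argmax of $u$ at delay end (`NA` and an
invalid flag if the bump has collapsed below $\kappa$); ties are resolved
by the circular centroid of the argmax set. Argmax and circular-centroid
readouts agree to a few grid steps on noisy bumps because the smooth
rank-two noise mainly translates the profile.

**Sigmoid bump.** With single-cosine coupling the sigmoid bump is exactly
$A\cos x$; the amplitude solves the scalar self-consistency
$A = \int\cos y\,F(A\cos y)\,dy$, found as the largest root (stable
branch) by bracketed root-finding seeded from the Heaviside amplitude.

**Wrapping and displacement.** Angles are wrapped to $[-180,180)$; bias
uses the shorter signed arc (bias of a response at $-179^\circ$ to a
target at $179^\circ$ is $+2^\circ$). Variance-versus-time analyses use
unwrapped cumulative displacement so long delays do not saturate at the
wrap scale.

# What the generators emulate

`target_sampler()` reproduces the three protocol families: the 20-angle
discrete uniform set (18° spacing) used for bias curves; the continuous
uniform density for independent-trial ensembles; and the serially
correlated conditional
$(1-\epsilon_{\mathrm{mix}})\mathcal N_v e^{25\cos(\theta_n-\theta_{n+1}-\mu)}
+ \epsilon_{\mathrm{mix}}/360$ with $\epsilon_{\mathrm{mix}}=0.5$, drawn by
inverse-CDF on a fine grid ($\mu = 0$ locally peaked, $\mu = 90$ skewed).
The mixture weight is a property of the task and is deliberately a
different configuration key from the observer's $\varepsilon$.
`build_schedule()` implements the printed trial arithmetic
($t_{n+1} = t_n + T_C + T_D^n + T_A + T_I^n$) and the discrete ITI
({1000, 1200, …, 5000} ms) and delay ({0, 200, …, 5000} ms) ladders.

The generator emulates stationary laboratory protocols with a single
target per trial. It does not emulate motor noise in the report itself,
lapses, adaptation or learning across sessions, or multi-item displays —
so passing tests demonstrate the internal consistency of the model under
idealized task statistics, not a fit to any behavioral dataset.

# Problem sizes and default experiments

The ensemble experiments use the fast profile ($dx = 0.72^\circ$,
$dt = 0.5$ ms), validated against the printed-resolution profile on
fixed-seed trials (response difference below half a degree). Defaults:
800 trials for response-spread ensembles with a 2000 ms delay (the delay
for spread ensembles is a package choice; spread grows with delay) and
1500 ms ITI; 500 paths for delay-period variance courses (3 s without STF,
5 s with). Bias-curve and ladder sweeps run the noise-free reduced model,
where a single trial pair per condition suffices.

```{r example}
library(serialwm)
params <- field_params(dx = 0.72)
sched <- build_schedule(800, delay = 2000, iti = 1500,
                        sampler = target_sampler("uniform_density"), seed = 1)
res <- run_trials(sched, params, seed = 2, dt = 0.5)
response_sd(res)          # ensemble spread of wrapped response errors
bias_by_relative_angle(res)  # serial-bias curve
```

# Known limitations

* The weak-interaction reduction underestimates the network's peak
  noise-free bias by roughly a fifth at default parameters: the bump
  half-width is large ($a \approx 87^\circ$, so the footprint spans
  $\approx 174^\circ$), and the new bump's activity partially re-sustains
  the previous trial's facilitation instead of letting it decay as
  $e^{-t/\tau}$. Zero crossings and the non-monotonic shape are preserved.
* The response-spread ensembles are sensitive to the (unconstrained)
  delay used for them; with the 2000 ms default the uniform-protocol
  spread is ≈3.4°.
* The closed-form facilitation profile and potential gradient assume the
  high-gain limit; at $\gamma = 20$ the projection kernel agrees with the
  closed form to well under a percent, but lower gains would require the
  quadrature route.
* Spontaneous bump nucleation means the undriven network is not bistable;
  protocols must include the inactivating input to clear activity, and
  simulations of free evolution should be interpreted with that in mind.
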