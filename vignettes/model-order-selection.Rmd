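---
title: "Establishing the order of brain-state dynamics: models, inversion and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Establishing the order of brain-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orderstates)
```

## The question and the models

In dynamical systems theory, the *state* of a system is whatever suffices
to determine its immediate future. Applied to a neural timeseries this
becomes a model-comparison question. Under a first-order linear equation
of motion,

$$\dot x_i = a_{ii}\,x_i + c_{ii}\,v_i + \omega_i,$$

the present signal $x$, input $v$ and noise $\omega$ determine the next
timepoint: they *are* the state. Under a second-order equation,

$$\ddot x_i = a_{ii}\,x_i + c_{ii}\,v_i + \omega_i,$$

those three quantities only give the acceleration; the velocity $\dot x$
must be added to the state. `orderstates` decides between these two
descriptions for any observed multivariate series by comparing their
(approximate) log model evidence.

Both systems are deliberately restricted:

- **Diagonal Jacobian.** Regions couple only to themselves. This mirrors
  the intended inputs: coordinates obtained by projecting data onto
  mutually orthogonal functional gradients, whose orthogonalization
  removes cross-coupling by construction.
- **No damping term.** The second-order equation has no $\dot x$ term, so
  with $a_{ii} < 0$ each region is an undamped stochastic oscillator of
  angular frequency $\sqrt{-a_{ii}}$. Over finite recordings this is
  well-behaved; it is accepted as the literal second-order counterpart of
  the first-order model rather than augmented with extra parameters.
- **Order capped at two.** Higher-order equations of motion are excluded
  (they are generically unstable in the Ostrogradsky sense), so the
  comparison is binary.

The observation model is $y = x + \varepsilon$ with i.i.d. Gaussian
observation noise on the positions only, for both orders.

## Exact simulation

Second-order models are first rewritten in companion form — a
$2n$-dimensional first-order system over positions and velocities with
block drift $[[0, I], [\mathrm{diag}(a), 0]]$, noise and input entering
the velocity block — so both orders share one integrator. The integrator
discretizes the linear SDE *exactly*: the one-step transition is the
matrix exponential of the drift times $\Delta t$, inputs are held
constant within a step (zero-order hold) through the integrated
exponential, and the process-noise covariance is the Van Loan integral.
Euler–Maruyama is deliberately avoided: an approximate integrator injects
order-dependent discretization bias exactly where the model comparison is
most sensitive. The tests pin this down against closed forms
($e^{-t}$ decay, $\cos t$ oscillation, the Ornstein–Uhlenbeck stationary
variance $\sigma^2/2|a|$).

## Likelihood and variational Laplace

For fixed parameters the discretized model is linear-Gaussian, so the
marginal likelihood of the observations (latent states integrated out) is
computed exactly by a Kalman filter's prediction-error decomposition,
implemented in C++ (Armadillo) with the filter factorized over regions —
valid because the Jacobian is diagonal and noises are independent. The
initial state is a *parameter* (`x0`, plus `xdot0` for order 2) with zero
initial covariance: this is precisely how the second-order model carries
its extra degrees of freedom, and what complexity must pay for.

The free parameters are $\theta = (a, c, x_0[, \dot x_0], \lambda_s,
\lambda_o)$ where $\lambda$ are log-precisions of state and observation
noise ($\sigma^2 = e^{-\lambda}$), kept unconstrained so the whole vector
is Gaussian-friendly. Priors are independent Gaussians, zero-mean and
unit-variance throughout — the inversion "forgets" the generating
parameters. Fitting maximizes the log joint by BFGS from the prior mean
plus `n_restarts` jittered starts (deterministic per seed; defaults:
2 restarts, jitter SD 0.5, 500 iterations, relative tolerance 1e-10),
followed by one polish run; the posterior is the Laplace approximation
whose covariance is the inverse Hessian of the negative log joint at the
mode (repaired to the nearest symmetric positive-definite matrix, and
flagged, in the rare indefinite case). Parameter excursions that make the
likelihood degenerate (explosive dynamics overflowing the filter) return
a large finite penalty rather than NaN, which keeps line searches stable.

The evidence approximation is reported as

$$F \;=\; \underbrace{\langle \log p(y \mid \theta) \rangle_q}_{\text{accuracy}}
\;-\; \underbrace{\mathrm{KL}\!\left[q(\theta)\,\|\,p(\theta)\right]}_{\text{complexity}}.$$

The accuracy term is the *expected* log-likelihood under the Gaussian
posterior, computed as the plug-in log-likelihood at the posterior mean
plus the curvature correction $\tfrac12(\mathrm{tr}(\Sigma_q \Pi_0) - d)$
(exact when the log-likelihood is quadratic in $\theta$). With this
definition $F$ reproduces the closed-form log evidence in the conjugate
linear-Gaussian special case — one of the package's oracle tests — while
the plug-in variant would be biased upward by roughly $d/2$ nats. The
complexity term is the closed-form Gaussian KL divergence over the free
parameters.

This scheme replaces a generalised-coordinates treatment of smooth noise
with an exact discrete-time likelihood. For these linear models the state
inference is exact and the accuracy-minus-complexity contract is
preserved; the driving input is supplied as a known regressor (only its
gain is estimated) rather than being itself estimated. Absolute $F$
values therefore differ from a generalised-filtering implementation, but
the order comparison — the quantity of scientific interest — does not
depend on that choice on data where the input is known.

## Model comparison

Under equal model priors, two-model posterior probabilities are the
softmax of the free energies, $p_1 = 1/(1 + e^{F_2 - F_1})$, and the
winner is the order with higher $F$. Ties within $10^{-9}$ nats go to the
first-order model (parsimony) and are flagged. Cohorts are summarized by
counting winners; no hierarchical (random-effects) model selection is
attempted because the analyses this package reproduces count subjects.

## Gradients, nulls and autocorrelation

`diffusion_embedding()` is a compact diffusion-map implementation for
symmetric connectivity matrices: per-row sparsification (default keeps the
strongest 10% of entries per row), cosine-similarity affinity between
sparsified profiles (negative similarities clipped), $\alpha$-normalization
with $\alpha = 0.5$ (Fokker–Planck convention), then eigendecomposition of
the symmetric normalized operator $D^{-1/2} W D^{-1/2}$. The trivial
stationary component is dropped; variance-explained fractions are the
normalized non-trivial eigenvalues. The defaults match the established
gradient-toolbox conventions; the eigenvectors of the symmetric operator
are returned so that loading columns are orthonormal, which downstream
code relies on. Heavy sparsification of a strongly modular matrix can
disconnect the affinity graph, in which case leading "gradients" become
component indicators; the tests use moderate sparsity on block matrices
for that reason.

`gradient_timeseries()` correlates each timepoint's spatial map with each
gradient (Pearson, centered across regions). Per-timepoint correlation is
scale-free: it recovers the latent gradient coordinates only up to a
per-frame normalization (division by the frame norm). Frames with zero
spatial variance map to 0 with a warning rather than failing a whole run.

`circular_shift_null()` rotates each region's time course by an
independent uniform offset. Because rotation merely permutes samples, each
region's mean, variance, periodogram and circular autocorrelation are
preserved *exactly*, while inter-regional temporal alignment is destroyed
— the appropriate null for analyses that depend on spatial structure
across regions. `acf_curve()` is the standard biased-normalized sample
ACF (delegated to `stats::acf`), and `group_acf()` averages per-gradient
curves within winner groups.

## The synthetic cohort generator

The generator emulates the *structure* of parcellated resting/task fMRI:
~100 regions, 400 timepoints at TR = 0.72 s, low-dimensional latent
dynamics of known order living directly in gradient space, projected onto
spatial maps plus independent Gaussian spatial noise. Its defaults define
the study conditions used by the tests and the acceptance script:

- self-couplings $a_{ii} \sim U(-1.0, -0.2)\,\mathrm{s}^{-1}$ (order 1)
  or $U(-1.0, -0.1)\,\mathrm{s}^{-2}$ (order 2) — negative for
  non-explosive behaviour, giving decay times and oscillation periods
  comfortably resolved at the 0.72 s sampling interval;
- input gains $c_{ii} \sim U(0.2, 1.0)$; state and observation noise SDs
  $\sim U(0.05, 0.3)$; initial conditions $\sim U(-1, 1)$;
- the 3-region order-recovery experiment drives each region with an
  independent random boxcar train (Poisson onsets at 1/40 s⁻¹, 10 s
  bursts, unit amplitude) — a randomized input whose timing is known to
  the inversion;
- resting cohort subjects have *no* external drive (their fluctuations
  are endogenous state noise), while task subjects share a block-design
  boxcar (27.5 s blocks separated by 15 s baselines) on every latent
  dimension;
- latent coordinates are standardized before projection and the synthetic
  gradient maps carry unit-RMS regional entries, so `spatial_noise_sd`
  is expressed relative to unit signal amplitude (default 0.1); the maps
  are mutually orthogonal and orthogonal to the constant map, so
  per-frame correlation recovers the latent coordinates up to frame
  normalization.

Every subject is a pure function of `(spec, seed)`: per-subject seeds are
derived deterministically from the cohort seed and recorded, so cohorts
reproduce bit-for-bit.

What the generator does *not* emulate — hemodynamic convolution, 1/f BOLD
spectra, physiological noise, motion, inter-subject anatomical variation,
gradient misalignment across subjects — bounds what passing tests show:
they validate the inferential machinery (order identification, evidence
accounting, surrogate behaviour, autocorrelation contrasts) under the
stated generative assumptions, not the empirical claims about any
particular neuroimaging dataset.

## Experiment scales and numerical choices

The order-recovery experiment inverts both model orders on 100 randomized
3-region series of 400 samples (a few minutes on one CPU); unit tests use
shorter series (60–200 samples) where the contrast being tested does not
require the full protocol. Oracle comparisons against the dense
joint-Gaussian likelihood use series of at most 20 samples, where
assembling the full observation covariance is cheap and well-conditioned.
Matrix exponentials on the R side use `Matrix::expm` (Padé with scaling
and squaring), accurate to near machine precision; the C++ likelihood
uses Armadillo's `expmat`, so the two routes are independent
implementations that the tests compare. Degenerate inputs follow explicit
rules: constant series make the ACF error out, zero-variance frames map
to zero gradient correlation with a warning, non-finite parameters are
rejected, and per-subject failures in cohort runs are logged and counted
rather than aborting the run.

## Known limitations

- The inversion treats the driving input as known; estimating the input's
  form (as a full generalised-filtering scheme does) is out of scope, so
  applying the package to task data requires the task timing.
- The undamped second-order model cannot represent damped oscillation;
  real data lying between the two model classes will be assigned to
  whichever is closer in evidence, which is the intended behaviour of a
  binary comparison but should be kept in mind when interpreting wins.
- Laplace posteriors can understate uncertainty when the likelihood is
  strongly non-Gaussian in $\theta$ (e.g. very short series, frequencies
  near Nyquist). Multi-start optimization mitigates, but does not
  eliminate, local-optimum risk in the oscillatory-model fit.
- Gradient loadings are not aligned across subjects (no Procrustes step);
  the synthetic cohorts sidestep this by construction, and empirical use
  should supply consistently oriented gradients.
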