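---
title: "Models and methods: rSLDS dynamics, attractor metrics, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rslds)
```

This vignette is the package's account of its science: the generative
model and how it is fit, the attractor metrics and their conventions, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The generative model

A recurrent switching linear dynamical system (rSLDS) couples a discrete
state chain, continuous latents, and linear Gaussian observations:

$$p(z_{t+1} = k \mid x_t, u_t) \propto \exp\{R_k x_t + W_k u_t + r_k\}$$
$$x_{t+1} = A_{z_{t+1}} x_t + V_{z_{t+1}} u_t + b_{z_{t+1}} + \epsilon_t,
  \qquad \epsilon_t \sim N(0, Q)$$
$$y_t = C x_t + d + \eta_t, \qquad \eta_t \sim N(0, S)$$

The discrete state selects which linear law governs the next latent step;
the transitions are *recurrent* — they depend on where the latent
currently is (and on external inputs such as inter-animal distance and
facing angle), which is what lets a piecewise-linear model carve a
nonlinear phase portrait into interpretable pieces.

Conventions worth noting:

- Transition logits are shared across the source state (no per-source
  term); an optional `markov_bias` adds a conventional $K \times K$
  log-bias for generative experiments but is not estimated during
  fitting. The printed form of the transition rule in the literature this
  package follows has no source-state term either; whether published fits
  used one is not decidable from the text, so the simpler model is the
  default.
- Process noise is written into the model even though the dynamics
  equation is often printed noiseless: inference assumes stochastic
  dynamics, and a noiseless latent chain would make the smoother
  degenerate. $Q$ is shared across states.
- Observation noise is diagonal by default; nothing in the text of the
  source methods indicates otherwise.

## Fitting: structured variational EM

`fit_rslds()` alternates:

1. **Latent chain update.** Given soft state weights, the potentials over
   $x_{1:T}$ form a Gaussian Markov chain whose block-tridiagonal
   precision is solved exactly in C++ (forward block elimination, back
   substitution), yielding posterior means, marginal covariances, lag-one
   cross-covariances, and $\log\det J$ for the entropy.
2. **Discrete update.** Because logits are source-independent, the states
   decouple given $x$: each frame's posterior is a softmax over
   (transition logit at the posterior mean + expected dynamics
   log-density, computed with full second moments).
3. **M-steps.** Weighted least squares with exact posterior moments for
   $(A_k, V_k, b_k)$, $Q$, $(C, d)$ and diagonal $S$; a damped Newton
   multinomial logistic regression with soft targets for $(R, W, r)$,
   with backtracking on the penalized likelihood.

**ELBO convention.** The reported ELBO evaluates the recurrent transition
term at the posterior latent mean (Laplace-EM style). When the logits do
not depend on $x$ ($R = 0$) the term is exact and the ELBO is a true
lower bound on the log evidence — that is the regime in which the test
suite checks it against exhaustive enumeration over state paths with
exact Kalman integration (the oracle is only exact there; with recurrent
transitions the softmax factor destroys Gaussian integrability). An
earlier variant added a Jensen-type variance correction to the
normalizer; it was removed because the transition M-step does not
optimize that penalty, and the mismatch broke ELBO monotonicity. With the
mean-evaluated convention the trace is measured monotone on the
synthetic-world fits.

**Initialization** is deterministic given the seed: PCA of the activity
for $(C, d)$ and whitened latent scores, k-means on the scores for the
state labels, then one M-step. `n_restarts` is available but defaults to
1; with this initialization, restarts were not observed to change the
recovered spectra, and the default keeps a 10-seed experiment around two
minutes of CPU.

**Model selection.** `cross_validate_rslds()` uses contiguous-block folds
(random frame folds would leak the strong temporal autocorrelation of
both latents and behavior), refits on the remaining segments, and scores
each held-out block with frozen parameters: held-out ELBO per frame and
the fraction of held-out variance captured by the smoothed
reconstruction. The chosen $(K, D)$ is the smallest pair whose mean
variance explained reaches 90%, the selection rule used for the original
recordings. "Variance explained" is not defined in the source text; the
smoothed-reconstruction convention is this package's documented choice.

**Forward simulation error.** From each frame's posterior latent, the
mean dynamics of the inferred state sequence are rolled forward
$\Delta t$ frames (default 1 s) and compared with the posterior latent
there; the per-frame MSE is min-max normalized across the session and
performance is $1 - \text{mean}$. MSE below $10^{-15}$ of the latent
scale is treated as zero so that an exact model scores exactly 1 instead
of normalizing floating-point dust.

## Attractor metrics

- **Time constants**: $\tau_a = |1/\log|\lambda_a||$ frames, divided by
  the sampling rate for seconds. Complex pairs share a modulus, hence a
  time constant. $|\lambda| = 0 \mapsto \tau = 0$; moduli within
  $10^{-12}$ of (or above) 1 are reported with a $10^{12}$-frame sentinel
  and flagged; moduli above 1 are additionally flagged unstable.
- **Line-attractor score**: $\log_2(\tau_{\max}/\tau_{\text{second}})$ of
  the behavior-enriched state's dynamics matrix. Scale-invariant and
  invariant to latent re-parameterization (it depends only on
  eigenvalues). A rotational system scores ~0 because its dominant
  complex pair shares one modulus.
- **Integration dimension**: the normalized real part of the eigenvector
  of the largest-$\tau$ eigenvalue, with sign fixed so the mean
  projection over user-supplied reference frames (typically the target
  behavior's frames) is positive. Anchoring the sign on behavior frames,
  not on the whole session, is what makes decoder thresholds comparable
  across sessions.
- **PCA re-parameterization**: whiten the centered posterior latents
  ($W$), update $C' = CW^{-1}$, take the SVD $C' = USV^\top$, and map
  $x'' = SV^\top W (x - \bar x)$ so that $y \approx Ux'' + const$ with
  components ordered by explained variance. The printed recipe in the
  source literature applies $P^{-1}$ at the last step, which would order
  components in reverse and contradicts its own variance-ordering claim;
  the variance-maximizing direction is implemented, and observational
  equivalence ($\|Cx - Ux''\| < 10^{-8}$) is asserted on every fit.
- **Flow field**: a grid over (PC1, PC2) (default 50×50, 10% margin);
  each point is lifted through the inverse PC map with non-displayed
  components at their session means, stepped once through the governing
  state's mean dynamics (governing state = argmax transition logits at
  the lifted point with $u = 0$ by default; a fixed-state mode exists),
  and the displacement is projected back. **Slow points** are grid-local
  minima of the displacement norm below the 5th percentile, ordered along
  PC1; the **landscape** uses the same norms as heights, so slow points
  are landscape minima by construction.
- **Dynamic velocity**: the literal metric $\|A_{z_t} x_t\|$ averaged
  within behavior and then across states, normalized to $[0,1]$ by the
  across-behavior maximum. A `displacement` mode computes
  $\|(A_z - I)x + Vu + b\|$ — the actual one-step flow speed. The two
  differ conceptually: $\|Ax\|$ grows with $\|x\|$ wherever the state is
  near-identity (e.g. on the attractor at high integrator values), so the
  trough-versus-walls contrast (entry transients fast, attack slow) is a
  statement about displacement; the package therefore uses displacement
  mode for that contrast and the literal mode as the default definition.
- **Rotation angle**: unwrapped planar angle of the (PC1, PC2) population
  vector, per episode, zeroed at the episode's sniff onset,
  counterclockwise positive; because a fitted PC plane has arbitrary
  handedness, the sign is oriented so the mean progression over social
  frames is positive.
- **Sequentiality index**: episodes are resampled to a common 50-bin
  base and averaged; the index is the mean of (a) the normalized entropy
  of the neurons' peak-time distribution and (b) the mean log
  ridge-to-background activity ratio (±10% window around each peak,
  capped at one decade), giving a value in $[0,1]$. The formula is
  inherited from the literature cited by the source study and is not
  printed there; the result object records this convention. The null
  circularly shifts each neuron independently within each episode before
  averaging, destroying cross-episode alignment while preserving
  single-episode statistics; the data-versus-null comparison is of the
  index against the null mean (the comparison reported in the source
  study), and a 97.5th-percentile flag is also returned. Ridge-to-
  background is computed on raw non-negative activity: per-neuron range
  normalization would make the ratio scale-invariant and blind to the
  amplitude loss that misalignment causes.

## Decoding

Bouts of one behavior separated by less than 5 s merge into trials. The
1D decoder is a maximum-margin threshold on the min-max-normalized
signal: among thresholds minimizing the class-balanced error, the one
centered in the widest gap is chosen (the max-margin solution among
empirical-risk minimizers) — any solver reproducing that threshold is
equivalent, so no SVM machinery is needed for a scalar signal.
Evaluation is leave-one-trial-out with pooled held-out predictions scored
by macro-averaged F1 (symmetric under swapping the pair). The shuffle
null reassigns behavior labels to trials (preserving per-class counts)
and repeats the full procedure; significance is the 97.5th percentile
rule. Cross-animal transfer applies each session's threshold to every
other session's normalized signal. The pose-feature GLM is a
Gaussian-identity model of the signal on distance, facing angle, speed,
acceleration and velocity, scored by cross-validated $R^2$ over
contiguous folds.

## Tuning

`behavior_mean_activity()` averages each neuron over each action × sex
column. The regressor bank enumerates exactly 40 distinct binary
regressors for the default 7-action × 2-sex vocabulary: 14 singletons, 7
sex-paired action unions, male/female-directed class unions, all-social,
investigative and consummatory unions split by sex (6), and 10
escalation/mating-sequence unions. The exact composition used for the
original tuning rasters is not printed in the source; this enumeration is
the package's documented stand-in and is user-overridable. Assignment is
the single regressor with the highest intercept-included $R^2$ on the
behavior-mean profile (ties toward fewer actions); neurons under 50% are
flagged omitted.

## The synthetic world

`ground_truth_scenario()` states the world once; the generator does not
adapt to analyses downstream.

- **Geometry**: 10-minute sessions at 15 Hz (30 Hz supported), 40
  neurons, $D = 8$, $K = 3$, 2 inputs. Emission loadings are Gaussian
  (SD 0.3) with dF/F-like baselines (0.05–0.2) and emission noise SD 0.1;
  isotropic process noise SD 0.01 (≈1% of the latent scale).
- **Line-attractor regime**: state 3 carries one real eigenvalue
  $e^{-1/(\tau f)}$ (default $\tau = 150$ s) plus sub-second modes; the
  other states are uniformly fast, with the integration axis set just
  under the 2 s cap ($\tau = 1.6$ s) so brief excursions do not erase the
  accumulated signal. The gating state drifts the integrator at 0.05
  a.u./s and is made sticky by the recurrent term (weight 1.5 on the slow
  axis); an external drive (zero before intruder introduction at 30 s, a
  2 s novelty overshoot, then a mean-reverting fluctuation) gates
  engagement. Behaviors are drawn from a gamma bout process (shape 2,
  mean bout 5 s, mean inter-bout 8 s — above the 5 s merge gap so trials
  stay plural) and labeled frame-wise by the min-max-normalized slow
  dimension crossing thresholds (0.35, 0.7): sniff, dominance-mount,
  attack; every attack frame sits above the upper threshold by
  construction.
- **Rotational regime**: state 3 carries a conjugate pair at modulus
  0.999 with angle $2\pi/(\text{period} \cdot f)$ (default period 10 s).
  Three generative choices matter and are deliberate: (i) no in-plane
  bias or input drive — a constant displacement would park the orbit far
  off-center and stall the phase; (ii) in-plane process noise 12× the
  isotropic default — for a noise-sustained linear oscillation the phase
  diffusion per cycle depends only on the modulus, so extra excitation
  buys orbit amplitude (and neural modulation well above the emission
  noise floor) without losing coherence; (iii) episodes snap to upward
  phase-zero crossings with the orbit radius above a floor, and labels
  follow the running phase maximum through one full cycle (sniff 0–60°,
  USV⁺ mount 60–120°, intromission 120–180°, post-copulatory
  investigation to 360°), so each episode is one clean phase-complete
  cycle and phase-tuned neurons tile it in a consistent order.
- **Pose features** are label-conditioned means (close distance during
  attack, high speed at entry, etc.) plus AR(1) noise with a 0.5 s
  correlation time; with zero noise they are deterministic functions of
  the labels. They emulate tracking-derived features only — no video or
  keypoint rendering, and no calcium indicator kinetics (emissions are
  Gaussian, not convolved transients).

**What a green test establishes** — that the inference and metric
machinery recovers known ground truth under the stated world. It does not
establish performance on real imaging data: real dF/F has indicator
dynamics, photobleaching drift, motion artifacts, non-Gaussian noise, and
behavior that is not a clean threshold readout of a latent. The
cross-animal transfer number is a case in point: generative signals
sharing thresholds transfer at >0.9 F1, while fitted integration signals
transfer at ≈0.67 because min-max normalization anchors differently
across fitted sessions.

## Numerical choices

- Latent chain prior: $x_1 \sim N(0, 10^2 I)$ per segment.
- Ridges/floors: $10^{-8}$ on regression Grams, eigenvalue floor
  $10^{-9}$ on $Q$, $10^{-6}$ on observation variances; transition ridge
  1 on $(R, W)$ and $10^{-6}$ on offsets, class-1 logits pinned at zero.
- Convergence: stop when the ELBO changes by less than $10^{-4}$
  nats/frame (default cap 50 iterations; the acceptance experiments use
  30).
- Zero-variance neurons are dropped with a warning before PCA; an
  all-constant recording is an error.
- Whitening adds a logged ridge if the latent covariance is
  rank-deficient.
- Ties: state-enrichment ties break toward the lower index (with a
  warning); regressor ties toward the more specific regressor; threshold
  ties toward the widest gap.
- Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; pipeline reports are byte-identical across reruns
  of one configuration.

## Limitations

- Gaussian emissions only (no Poisson/spike variants); shared $Q$; no
  GPU.
- The ELBO is a bound only for non-recurrent transitions; with $R \neq 0$
  it is a Laplace-style approximation (standard for this model class).
- Flow fields depend on a documented lifting convention (pseudo-inverse
  of the PC projection, other components at session means); the source
  text never specifies how its 2D fields were derived from
  higher-dimensional dynamics.
- The sequentiality-index and 40-regressor conventions are documented
  reconstructions of procedures whose exact definitions are not printed
  in the source.
- Session containers are plain text (CSV/JSON) rather than HDF5, keeping
  the package free of compiled I/O dependencies; the layout mirrors the
  dataset structure an HDF5 container would use.
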