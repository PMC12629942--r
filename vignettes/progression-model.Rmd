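---
title: "Latent disease-progression modelling with clinical alignment constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent disease-progression modelling with clinical alignment constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

progflow models neurodegenerative disease progression as a partially observed
continuous-time dynamical system. Each subject $i$ contributes a baseline
multimodal block $x_i = \{x^{img}_i, x^{omics}_i, x^{demo}_i\}$ (precomputed,
standardized feature vectors) and a sequence of irregularly timed visits with
a cognitive score $y_i(t)$, an optional ordinal stage
$s_i(t) \in \{0, \dots, L\}$, and optional biomarker measurements.

The latent state $z_i(t) \in \mathbb{R}^k$ evolves under a learned flow field

$$\frac{dz_i(t)}{dt} = g_\phi(z_i(t), t; \psi_i),$$

where $\psi_i$ is a subject conditioning vector embedded from the baseline
block. $z_i(0)$ is a learned linear map of the concatenated outputs of three
modality-specific two-layer encoders. The flow field is a one-hidden-layer
tanh network; trajectories are integrated with fixed-step fourth-order
Runge–Kutta and linearly interpolated to visit times. Fixed-step rather than
adaptive integration is deliberate: it makes runs exactly reproducible, the
one-step map doubles as the model's discrete-time transition function, and a
41-point grid over the (internally rescaled) cohort horizon is ample for the
slow, smooth dynamics of neurodegeneration. Zeros of the flow field are fixed
disease states; `find_fixed_points()` locates them by multi-start root search.

A parallel graph channel carries per-region pathology embeddings $r_v(t)$ on
a brain-region network. One propagation step is
$r_v' = \sigma\!\left(\sum_{u \in N(v)} \alpha_{uv} W r_u + b\right)$ with
attention $\alpha_{uv}$ obtained by softmax-normalizing cosine similarities
over the in-neighborhood $N(v)$ (computed on the pre-map embeddings). The
channel is anchored to the subject latent through per-region anatomical
projections $A_v$: regional states are initialized at $r_v(0) = A_v z(0)$ and
softly tied to $A_v z(t)$ at later steps — the only coupling between the two
channels, kept soft on purpose so the graph channel can express regional
heterogeneity the global latent does not carry.

Two observation heads read the latent state. The persistent cognitive
readout is the linear cognitive field $C(z) = u^\top z + c$; the visit-level
decoder refines it with a gated memory trace,
$\hat y = u^\top z + c + w_m^\top M$, where $M$ follows the convex update
$M' = (1 - g) \odot M + g \odot (W_p z + b_p)$ with a learned sigmoid gate.
Sharing $u, c$ between the two heads keeps the decoder and the field
consistent (the same choice is made for the stage heads below); without the
shared readout the cognitive field is trained only through the weak template
term and is essentially unidentified.

## The alignment constraints

Training minimizes a weighted sum of a prediction term (squared error of
$\hat y$ at observed visits) and fourteen alignment terms:

* **Stage supervision.** Soft probabilities $p = \mathrm{softmax}(Wz + b)$;
  the loss is $D_{KL}(\text{one-hot}(s^{true}) \,\|\, p) = -\log p_{s^{true}}$.
  The hard stage classifier shares these weights, so its argmax reproduces
  the soft head; ties break toward the lowest stage (clinical conservatism).
* **Anchor geometry.** Stage-labeled latents are pulled toward archetypal
  anchors $\mu_s$; an ordinal regularizer
  $\sum_s \|\mu_s - \mu_{s-1} - \delta\|^2$ keeps consecutive anchors evenly
  spaced along a common shift $\delta$.
* **Cognitive direction.** Since $C$ is linear, $\nabla_z C = u$ everywhere;
  the clinical requirement that trajectories descend the cognitive field is
  the strict inequality $\langle dz/dt, u\rangle < 0$, relaxed to the hinge
  $\max(0, \langle dz/dt, u\rangle)$ averaged over the dense grid so that it
  composes differentiably with the objective.
* **Monotonicity.** Predicted probabilities of stages $l \ge 1$ must not
  decrease between consecutive observed visits (actual gaps, not a uniform
  grid); decreases are penalized linearly. Stage 0 is exempt — early-stage
  probability is expected to fall.
* **Contrastive coherence.** An InfoNCE-style loss pulls a subject's
  embedding toward the same subject's embedding a fixed number of grid steps
  later, against one randomly timed negative per other subject. The positive
  term is included in the denominator so the loss is bounded below by zero
  and the all-similarities-equal case is well defined ($\log 2$ for two
  subjects); a literal negatives-only denominator is available behind
  `contrastive.literal_denominator`. The anchor view passes through the gated
  augmentation $\tilde z = z + \xi \odot \tanh(z) + \varepsilon$, with $\xi$
  learned from zero (augmentation starts as the identity).
* **Disentanglement.** Pairs of subjects with different symbolic labels (by
  default the subject's maximum observed stage) are penalized by a Gaussian
  kernel $\exp(-\|z_i - z_j\|^2)$ on their baseline latents. Only
  different-label pairs enter: intra-class compactness is already enforced
  by the anchors.
* **Spatial coherence.** A synchronization penalty
  $\sum_{v,w} \kappa_{vw} \|r_v - r_w\|^2$ (ordered pairs, so each unordered
  pair counts twice) and the anatomical projection penalty
  $\sum_v \|r_v - A_v z\|^2$. Both use squared norms for differentiability —
  a deliberate, uniform convention.
* **Clinical coherence.** Decoded regional biomarkers must track population
  reference curves; the cognitive readout must match the subject's subtype
  template; the imaging (macro) embedding must be reachable from the omics
  (micro) embedding through a learned linear alignment; counterfactual
  trajectories $z(t) + \Delta_a(t - t_a)$ under a saturating treatment shift
  $\Delta_a(\tau) = \text{scale} \cdot (1 - e^{-\tau/\ell}) \cdot d$ (zero
  before onset) must match observed post-treatment outcomes; and latents may
  be projected onto a canonical disease manifold spanned by expert basis
  vectors. All integrals use the trapezoidal rule, exact for affine
  integrands; latent-state integrals are evaluated on the dense ODE grid and
  regional integrals on the discrete propagation steps (the regional channel
  has no dense trajectory). The counterfactual term is a regression
  regularizer, not a causal estimator.

Reference curves and subtype templates are piecewise-linear knot curves; the
package's data-driven defaults are binned means of the training cohort (six
knots) with a single population subtype. The manifold basis defaults to the
full latent space — i.e. the projection constraint is inactive unless an
expert basis is actually supplied, because no defensible canonical manifold
exists before training.

In the composite objective every term is normalized by its batch count
(visits, subjects, labeled instances, or grid points as appropriate) so that
loss weights mean the same thing at any batch size; the standalone penalty
functions keep the plain sum conventions stated in their documentation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 4 | dimension of $z$; 3–8 covers typical single-disease cohorts |
| `dynamics.grid_points` | 41 | RK4 grid over the rescaled horizon $[0,1]$ (step 0.025, ≈ 0.13 y for a 5-year cohort) |
| `graph.embed_dim`, `graph.steps` | 6, 4 | regional embedding width and propagation steps per forward pass |
| `contrastive.delta`, `contrastive.tau` | 4, 0.5 | temporal offset (grid steps) and temperature |
| `weights` | 1 for prediction and stage supervision, 0.1 for the rest | term weights; prediction and stage labels carry the identifiable signal, the constraints shape geometry |
| `optim` | Adam, step 0.01, 50 epochs, batches of 16 subjects | the step size is the one optimization default revised during development: 1e-3 cannot traverse the distance from random initialization within 50 epochs on cohorts of this size, while 0.01 converges stably |

Time is measured in years from each subject's baseline visit and rescaled to
$[0,1]$ inside the dynamics for conditioning stability; all reported times
are in original units.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces the package's reference study conditions: 200
subjects, a 4-dimensional latent with stable linear drift toward a disease
attractor (so severity grows monotonically and the attractor is a genuine
fixed point of the generating flow), 3 ordinal stages with thresholds at
cohort tertiles of noiseless severity (balanced stages), 3–8 visits per
subject at uniform random times over 5 years, an MMSE-like cognitive score
(intercept 29, declining along a negative direction $u^*$ of norm 2,
measurement noise SD 0.5 points — high test–retest reliability, as for
standardized cognitive batteries), per-region sigmoid biomarker trajectories
(noise SD 0.05), and baseline blocks that are linear maps of $z(0)$ plus
noise (SD 0.1). The mechanistic regional ODE
$dh_v/dt = -\lambda_v h_v + \sum_u \alpha_{uv}\sigma(h_u) + \beta_v x_v(t)$
is exposed separately (`simulate_regional_pathology()`) as the generative
formalization of pathology spread.

Because cognition declines while stages advance, the generating process
satisfies the cognitive-direction constraint exactly: the flow ascends
severity and descends the cognitive field. The stage rule counts how many
severity thresholds a subject's noiseless severity has passed, which makes
stage sequences nondecreasing for every subject — the clinical expectation
the monotonicity constraint encodes.

The simulator matches the *structural assumptions* of the model, not any
real dataset: visits are uniform rather than protocol-scheduled, dropout and
mortality are absent, feature maps are linear with Gaussian noise, stages
derive deterministically from severity, and all subjects share one set of
dynamics. Passing the recovery tests therefore shows that the estimator
recovers the generating structure when the model family contains it — it
says nothing about misspecification on real cohorts.

Exogenous modulators $u(t)$ of the latent transition are represented as an
optional input channel of the flow field (off by default; the simulator can
wire it to the treatment indicator).

## Identifiability and the recovery metrics

The model's latent coordinates are identified only up to an invertible linear
map of the generator's frame, so "recovering the cognitive direction" is
evaluated in the generator's coordinates: `recovered_direction()` regresses
the fitted readout on the true latent states and compares the slope vector
with $u^*$ by cosine similarity — the standard
identifiability-up-to-linear-map evaluation for latent-variable models.
Staging quality is macro-averaged visit-level F1 on held-out subjects
(splits are always subject-level to prevent temporal leakage), and readout
fidelity is the Spearman correlation with the noiseless generating score.

## Numerical choices and degenerate inputs

* Cosine similarities are stabilized with $10^{-12}$ in the denominator, so
  zero vectors yield similarity ≈ 0 rather than NaN.
* Stage KL with an exactly zero probability at the true stage is capped at
  1e3 with a warning (softmax outputs never reach exact zero in training).
* Isolated regions (no in-neighbors) fall back to the bias-only update in
  the standalone propagation operator; the trainer requires every region to
  have an in-neighbor and validates this up front.
* Ties in the hard stage head break toward the lowest stage.
* A single-stage vocabulary makes the ordinal regularizer 0 with a warning.
* Training aborts and returns the last completed epoch's parameters if any
  objective term turns non-finite, naming the term.
* All randomness (initialization, shuffling, contrastive sampling,
  augmentation noise) derives from the single seed argument; repeated runs
  are bit-identical.

The test-time problem sizes are the package's reference conditions: the
recovery experiment uses the full 200-subject cohort for 50 epochs, the
dose–response experiment refits it three times, and determinism checks use a
40-subject cohort for 6 epochs.

## Gradient machinery

No automatic-differentiation backend for R covers a neural ODE with this
constraint suite, so the package carries a small reverse-mode engine
(`R/autodiff.R`) over dense matrices: every operation evaluates plainly on
numeric inputs and records a tape node when any input is a node, so one
implementation of the forward model serves prediction and training alike.
Backward rules are shared top-level functions (not per-node closures), node
traversal is index-based, and gradient storage is integer-addressed — choices
that keep the interpreter and garbage collector out of the hot path. The
engine is validated against central finite differences both per-primitive and
through the entire model (ODE integration, graph attention, memory
recurrence, and all loss terms).

## Known limitations

* The flow field receives time as an input; progression speed heterogeneity
  beyond what $\psi$ carries is not modeled (no subject-specific time warp).
* Stage supervision assumes a single ordinal vocabulary across the cohort.
* The counterfactual term fits observed post-treatment outcomes; it does not
  identify causal effects and should not be read as one.
* The semantic codebook attached to the disentanglement constraint is stored
  for interoperability but does not enter the penalty, whose printed form
  depends only on the labels.
* Memory is per-subject within a forward pass; there is no cross-batch
  memory bank.
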