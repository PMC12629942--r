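# progflow

Latent disease-progression modelling for longitudinal multimodal cohorts,
with clinical alignment constraints.

## What problem this solves, and for whom

Neurodegenerative diseases (Alzheimer's, Parkinson's, and related disorders)
unfold over years, are observed at irregular clinic visits, and manifest
jointly in imaging, molecular, and cognitive measurements. Researchers
modelling such cohorts face two recurring problems: purely data-driven latent
trajectory models drift into clinically implausible configurations (stages
that regress, cognition that improves under advancing pathology), while
purely mechanistic models are too rigid for heterogeneous multimodal data.

progflow is for biostatisticians and computational neuroscientists who want a
middle path: a continuous-time latent model fitted by gradient descent, whose
training objective carries a suite of clinical-alignment constraints that
keep the learned representation medically coherent.

## The model

Each subject's baseline imaging/omics/demographic blocks are encoded into an
initial latent state `z(0) ∈ R^k`; the trajectory follows a learned flow
field integrated with fixed-step 4th-order Runge–Kutta,

    dz_i(t)/dt = g_φ(z_i(t), t; ψ_i),

with a subject conditioning vector `ψ_i`. A graph-attention channel
propagates per-region pathology embeddings `r_v(t)` on a brain-region
network, attention weights being softmax-normalized cosine similarities over
in-neighborhoods. Visit-level outcomes are decoded as
`ŷ = u·z + c + w_m·M` — the linear cognitive field plus a gated memory
correction — and ordinal stages come from a shared softmax stage head.

The composite objective adds, to the squared-error prediction term:
Kullback–Leibler stage supervision, stage-anchor geometry with an ordinal
spacing regularizer, a hinge penalty forcing trajectories to descend the
cognitive field, temporal monotonicity of stage probabilities, an
InfoNCE-style temporal contrastive loss with gated latent augmentation, a
cross-label disentanglement kernel, graph synchronization and anatomical
projection penalties, and coherence terms tying the model to population
biomarker curves, subtype cognitive templates, cross-modality alignment,
counterfactual treatment trajectories, and an optional canonical disease
manifold. Every formula is documented in the methods vignette
(`vignettes/progression-model.Rmd`).

A synthetic-cohort generator with full ground truth (mechanistic regional
pathology ODE, monotone severity, MMSE-like declining cognition, sigmoid
biomarkers) makes every component testable without any external data.

## Worked example

```r
library(progflow)

gen <- generate_cohort(default_sim_config(n_subjects = 80), seed = 42)
gen$cohort
#> pf_cohort: 80 subjects, 443 visits, 3 stages, horizon 5 years
#>   feature dims: img 12 | omics 10 | demo 4 | biomarkers 8
#>   region graph: 8 regions, 22 edges

sp  <- split_cohort(gen$cohort, c(0.8, 0.1, 0.1), seed = 42)
fit <- fit_progression_model(sp$train, default_model_config(), seed = 42)
fit
#> pf_fit: 50 epochs, seed 42 , config 0f39ca66
#>   total loss: 8.205 -> 0.9467

m <- evaluate_stage_metrics(fit, sp$test)
sprintf("accuracy %.3f | macro F1 %.3f | macro AUC %.3f", m$accuracy, m$f1, m$auc)
#> "accuracy 0.974 | macro F1 0.976 | macro AUC 0.994"
m$confusion
#>     predicted
#> true  0  1  2
#>    0 11  0  0
#>    1  0 14  0
#>    2  0  1 13

anchor_correlation(fit, sp$test)
#> spearman 0.947, mse 0.317      # readout vs the observed cognitive score

recovered_direction(fit, sp$test, gen$truth)$cosine
#> 0.989                          # fitted cognitive direction vs the true u*
```

The loss history (`fit$report$history`) falls from 8.2 to 0.95 over 50
epochs; held-out staging is near-perfect on this synthetic cohort (one
advanced-stage visit mislabelled mild in the confusion matrix above); the
readout ranks subjects' cognition almost exactly as the true noiseless score
does (Spearman 0.95 against the noisy observed score, which contains
measurement noise of SD 0.5); and the fitted cognitive direction, expressed
in the generator's latent frame, is within 9 degrees of the true one
(cosine 0.989). Because the generating flow drifts toward a disease
attractor at coordinate 2, `find_fixed_points(gen$truth$flow, ...)` returns
the single fixed point `(2, 2, 2, 2)`.

A command-line wrapper for `simulate` / `train` / `evaluate` lives at
`inst/cli/progflow.R`.

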