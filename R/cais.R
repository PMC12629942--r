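# Clinical-alignment constraints, part 1-2: probabilistic stage supervision,
# anchor geometry, the cognitive-field direction penalty, temporal
# monotonicity of stage probabilities, and label disentanglement.

#' Soft stage probabilities
#'
#' `p = softmax(W z + b)` over the `L + 1` ordinal stages. By default the
#' trained model shares these weights with the hard stage head, so the argmax
#' of these logits reproduces [classify_stage()].
#'
#' @param z Latent state vector, or matrix of states (rows).
#' @param head List with `W` ((L+1) x k) and `b` (length L+1).
#' @return Probability vector (or matrix, rows summing to 1).
#' @export
stage_probabilities <- function(z, head) {
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  stopifnot(ncol(Z) == ncol(head$W), length(head$b) == nrow(head$W))
  P <- ad_value(ad_softmax_rows(
    sweep(Z %*% t(head$W), 2L, head$b, "+")))
  if (is.matrix(z)) P else as.vector(P)
}

#' Stage divergence (KL) loss
#'
#' `D_KL(one_hot(true) || p) = -log p[true]` (with the `0 log 0 = 0`
#' convention), i.e. cross-entropy against a one-hot target. An exactly zero
#' probability at the true stage is capped at `cap` with a warning.
#'
#' @param probabilities Probability vector over stages (stage `l` at index
#'   `l + 1`).
#' @param true_stage Integer stage in `{0..L}`.
#' @param cap Cap applied when `p[true] == 0`.
#' @return Nonnegative scalar.
#' @export
stage_kl_loss <- function(probabilities, true_stage, cap = 1e3) {
  L <- length(probabilities) - 1L
  if (true_stage < 0 || true_stage > L)
    stop("true_stage outside vocabulary {0..", L, "}")
  p <- probabilities[true_stage + 1L]
  if (p == 0) {
    warning("zero probability at the true stage; loss capped at ", cap)
    return(cap)
  }
  min(-log(p), cap)
}

#' Stage anchor loss
#'
#' `sum_i ||z_i - mu_{s_i}||^2` over stage-labeled instances; unlabeled
#' instances (NA stage) contribute 0.
#'
#' @param latents Matrix of latent states (instances x k).
#' @param true_stages Integer stages in `{0..L}` (NA = unlabeled).
#' @param anchors Matrix of stage anchors ((L+1) x k, row `l+1` for stage `l`).
#' @return Nonnegative scalar.
#' @export
anchor_loss <- function(latents, true_stages, anchors) {
  stopifnot(nrow(latents) == length(true_stages),
            ncol(latents) == ncol(anchors))
  lab <- which(!is.na(true_stages))
  if (!length(lab)) return(0)
  resid <- latents[lab, , drop = FALSE] -
    anchors[true_stages[lab] + 1L, , drop = FALSE]
  sum(resid^2)
}

#' Ordinal anchor-spacing regularizer
#'
#' `sum_{s=1..L} ||mu_s - mu_{s-1} - delta||^2`: consecutive anchors should be
#' separated by the common ordinal shift `delta`. Invariant to a global
#' translation of all anchors.
#'
#' @param anchors Matrix of stage anchors ((L+1) x k).
#' @param shift Ordinal shift vector `delta` (length k).
#' @return Nonnegative scalar; 0 with a warning when `L = 0`.
#' @export
ordinal_regularizer <- function(anchors, shift) {
  Lp1 <- nrow(anchors)
  if (Lp1 < 2L) {
    warning("single-stage anchor set: ordinal regularizer is 0")
    return(0)
  }
  d <- diff(anchors) - matrix(shift, Lp1 - 1L, ncol(anchors), byrow = TRUE)
  sum(d^2)
}

#' Cognition-guided direction penalty
#'
#' The linear cognitive field `C(z) = u . z + c` has gradient `u` everywhere;
#' clinically, latent trajectories must descend it (cognition declines).
#' The strict constraint `<dz/dt, u> < 0` is relaxed to the hinge penalty
#' `mean over grid points of max(0, <dz/dt, u>)`, a differentiable surrogate
#' that is 0 exactly when the flow never ascends the field.
#'
#' @param trajectory A `pf_trajectory` from [integrate_trajectory()], or a
#'   matrix of latent states (rows).
#' @param field List with `u` (length k) and `c` (scalar; unused by the
#'   penalty since the gradient of the field is `u`).
#' @param dynamics A `pf_dynamics` flow field used to evaluate `dz/dt` at the
#'   trajectory's states.
#' @return Nonnegative scalar.
#' @export
cognitive_direction_penalty <- function(trajectory, field, dynamics) {
  Z <- if (inherits(trajectory, "pf_trajectory")) trajectory$states
       else trajectory
  tt <- if (inherits(trajectory, "pf_trajectory")) trajectory$times
        else rep(0, nrow(Z))
  psi <- if (inherits(trajectory, "pf_trajectory")) trajectory$psi
  V <- flow_field(Z, tt, psi, dynamics)
  mean(pmax(V %*% field$u, 0))
}

#' Temporal monotonicity penalty on stage probabilities
#'
#' Disease stages should not regress: for every stage `l >= 1` (stage 0 is
#' excluded) and every consecutive pair of observations, a decrease in the
#' predicted probability is penalized:
#' `sum_{l>=1} sum_t max(-(p_l(t+dt) - p_l(t)), 0)`. Consecutive observed
#' visits are used as-is (actual gaps, not a uniform grid).
#'
#' @param probability_series Matrix of stage probabilities over time
#'   (time x (L+1)), rows in time order.
#' @return Nonnegative scalar.
#' @export
monotonicity_penalty <- function(probability_series) {
  P <- as.matrix(probability_series)
  if (nrow(P) < 2L) stop("need at least 2 time points")
  d <- diff(P)[, -1L, drop = FALSE]
  sum(pmax(-d, 0))
}

#' Disentanglement penalty across symbolic labels
#'
#' `sum over ordered pairs i != j with c_i != c_j of exp(-||z_i - z_j||^2)`:
#' a Gaussian-kernel penalty on closeness of different-label pairs
#' (inter-class separation). Intra-class compactness is handled by the anchor
#' loss; same-label pairs contribute nothing.
#'
#' @param latents Matrix of latent states (instances x k).
#' @param labels Symbolic class labels (one per row).
#' @return Nonnegative scalar, approaching 0 as inter-class distances grow.
#' @export
disentangle_penalty <- function(latents, labels) {
  stopifnot(nrow(latents) == length(labels))
  sq <- rowSums(latents^2)
  D2 <- outer(sq, sq, "+") - 2 * latents %*% t(latents)
  D2[D2 < 0] <- 0
  diff_lab <- outer(labels, labels, "!=")
  diag(diff_lab) <- FALSE
  sum(exp(-D2[diff_lab]))
}
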