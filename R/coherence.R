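# Clinical coherence constraints: biomarker-curve alignment, subtype-template
# alignment, cross-modality consistency, counterfactual treatment
# regularization, and projection onto a canonical disease manifold.

#' Trapezoidal quadrature
#'
#' Exact for affine integrands on any grid; second-order convergent on smooth
#' integrands.
#'
#' @param values_on_grid Integrand values at the grid points.
#' @param grid Increasing evaluation times (>= 2 points).
#' @return The integral approximation.
#' @export
quadrature <- function(values_on_grid, grid) {
  if (length(grid) < 2L) stop("quadrature needs a grid of at least 2 points")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  stopifnot(length(values_on_grid) == length(grid))
  sum(diff(grid) * (utils::head(values_on_grid, -1L) +
                      utils::tail(values_on_grid, -1L)) / 2)
}

# Trapezoid weight vector: quadrature(v, grid) == sum(w * v).
trapezoid_weights <- function(grid) {
  n <- length(grid)
  stopifnot(n >= 2L)
  d <- diff(grid)
  c(d[1L] / 2, (d[-1L] + d[-(n - 1L)]) / 2, d[n - 1L] / 2)
}

#' Piecewise-linear reference curve
#'
#' Reference biomarker curves and subtype cognitive templates are stored as
#' (time, value) knots and evaluated by linear interpolation (constant
#' extrapolation beyond the knots).
#'
#' @param times Knot times (increasing).
#' @param values Knot values.
#' @return Function `t -> value`.
#' @export
reference_curve <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1L,
            !is.unsorted(times))
  if (length(times) == 1L) {
    v <- values[1L]
    return(function(t) rep(v, length(t)))
  }
  function(t) stats::approx(times, values, xout = t, rule = 2)$y
}

#' Coherence specifications
#'
#' Bundles the fixed clinical references the coherence constraints compare
#' against: per-variable population biomarker curves, per-subtype cognitive
#' templates, the micro-to-macro modality alignment map, the parameterized
#' treatment shift, and the canonical disease-manifold basis.
#'
#' @param reference_curves Named list of [reference_curve()] functions, one
#'   per biomarker variable.
#' @param biomarker_decoder Function mapping a matrix of regional embeddings
#'   (time x d) to predicted biomarker values (one per row).
#' @param templates Named list of [reference_curve()] cognitive templates, one
#'   per subtype.
#' @param alignment_map Matrix `A` mapping micro-embeddings to macro-embedding
#'   space.
#' @param treatment_shift Function `tau -> latent shift vector`, with
#'   `treatment_shift(tau) = 0` for `tau < 0` (no effect before onset).
#' @param manifold_basis Matrix whose columns are the clinical basis vectors
#'   `e_1..e_K` (k x K, linearly independent).
#' @return List of class `pf_coherence_specs`.
#' @export
coherence_specs <- function(reference_curves = NULL, biomarker_decoder = NULL,
                            templates = NULL, alignment_map = NULL,
                            treatment_shift = NULL, manifold_basis = NULL) {
  structure(list(reference_curves = reference_curves,
                 biomarker_decoder = biomarker_decoder,
                 templates = templates, alignment_map = alignment_map,
                 treatment_shift = treatment_shift,
                 manifold_basis = manifold_basis),
            class = "pf_coherence_specs")
}

#' Saturating treatment latent shift
#'
#' `Delta(tau) = scale * (1 - exp(-tau / length_scale)) * direction` for
#' `tau >= 0`, exactly zero before onset.
#'
#' @param scale Asymptotic shift magnitude.
#' @param direction Latent direction vector.
#' @param length_scale Saturation time scale (> 0).
#' @return Function `tau -> shift vector`.
#' @export
treatment_shift_model <- function(scale, direction, length_scale = 1) {
  stopifnot(length_scale > 0)
  function(tau) {
    if (tau < 0) return(0 * direction)
    scale * (1 - exp(-tau / length_scale)) * direction
  }
}

#' Biomarker-curve alignment loss
#'
#' `sum_v integral_0^T (Gamma(r_v(t)) - bbar_v(t))^2 dt`: the decoded
#' biomarker of every region must track its population reference curve.
#'
#' @param regional_trajectory List of per-region embedding trajectories
#'   (matrices, time x d), named by biomarker variable.
#' @param specs A [coherence_specs()] with `biomarker_decoder` and
#'   `reference_curves`.
#' @param grid Evaluation times matching the trajectory rows.
#' @return Nonnegative scalar.
#' @export
biomarker_alignment_loss <- function(regional_trajectory, specs, grid) {
  tot <- 0
  for (v in names(regional_trajectory)) {
    curve <- specs$reference_curves[[v]]
    if (is.null(curve))
      stop("no reference curve for biomarker variable '", v, "'")
    pred <- specs$biomarker_decoder(regional_trajectory[[v]])
    tot <- tot + quadrature((pred - curve(grid))^2, grid)
  }
  tot
}

#' Subtype-template alignment loss
#'
#' `integral_0^T (O(z(t)) - T_k(t))^2 dt`: the cognitive readout of the
#' subject's latent trajectory must match the clinical progression template of
#' the subject's subtype.
#'
#' @param latent_trajectory A `pf_trajectory`, or a matrix of latent states
#'   evaluated at `grid`.
#' @param subtype_k Subtype name (must exist in `specs$templates`).
#' @param specs A [coherence_specs()] with `templates`.
#' @param observation_head The cognitive readout: list with `u` (length k) and
#'   `c`, applied as `O(z) = u . z + c`, or a function of the state matrix.
#' @param grid Evaluation times.
#' @return Nonnegative scalar.
#' @export
template_alignment_loss <- function(latent_trajectory, subtype_k, specs,
                                    observation_head, grid) {
  tmpl <- specs$templates[[subtype_k]]
  if (is.null(tmpl)) stop("unknown subtype '", subtype_k, "'")
  Z <- .traj_states(latent_trajectory, grid)
  pred <- .apply_readout(observation_head, Z)
  quadrature((pred - tmpl(grid))^2, grid)
}

#' Cross-modality consistency loss
#'
#' `||Z_macro - A Z_micro||^2`: the macro-scale (imaging) embedding must be
#' reachable from the micro-scale (molecular) embedding through the learned
#' linear alignment map.
#'
#' @param macro_embedding,micro_embedding Vectors (or matrices with one row
#'   per subject).
#' @param specs A [coherence_specs()] with `alignment_map` (macro_dim x
#'   micro_dim).
#' @return Nonnegative scalar.
#' @export
modality_consistency_loss <- function(macro_embedding, micro_embedding,
                                      specs) {
  A <- specs$alignment_map
  Zma <- if (is.matrix(macro_embedding)) macro_embedding
         else matrix(macro_embedding, 1L)
  Zmi <- if (is.matrix(micro_embedding)) micro_embedding
         else matrix(micro_embedding, 1L)
  stopifnot(ncol(Zmi) == ncol(A), ncol(Zma) == nrow(A))
  sum((Zma - Zmi %*% t(A))^2)
}

#' Counterfactual treatment-trajectory loss
#'
#' Builds the counterfactual latent path `z_a(t) = z(t) + Delta_a(t - t_a)`
#' (identical to the factual path before onset, since the shift is zero for
#' negative elapsed time) and integrates the squared mismatch between its
#' cognitive readout and the observed post-treatment outcomes over
#' `[t_a, T]`; observed outcomes are linearly interpolated to the grid. A
#' regression regularizer, not a causal estimator.
#'
#' @param latent_trajectory A `pf_trajectory` or matrix of states at `grid`.
#' @param treatment_event List with `onset_time` and `post_outcomes`
#'   (data frame with columns `time`, `value`; times >= onset).
#' @param specs A [coherence_specs()] with `treatment_shift`.
#' @param observation_head Cognitive readout (see
#'   [template_alignment_loss()]).
#' @param grid Evaluation times spanning `[0, T]`.
#' @return Nonnegative scalar.
#' @export
counterfactual_loss <- function(latent_trajectory, treatment_event, specs,
                                observation_head, grid) {
  t_a <- treatment_event$onset_time
  po <- treatment_event$post_outcomes
  if (is.null(po) || nrow(po) == 0L)
    stop("treatment event has no post-onset outcomes")
  if (t_a > max(grid)) stop("treatment onset beyond the evaluation horizon")
  Z <- .traj_states(latent_trajectory, grid)
  post <- which(grid >= t_a)
  if (length(post) < 2L)
    post <- utils::tail(seq_along(grid), 2L)
  shift <- t(vapply(grid[post] - t_a, specs$treatment_shift,
                    numeric(ncol(Z))))
  Zcf <- Z[post, , drop = FALSE] + shift
  pred <- .apply_readout(observation_head, Zcf)
  yobs <- stats::approx(po$time, po$value, xout = grid[post], rule = 2)$y
  quadrature((pred - yobs)^2, grid[post])
}

#' Canonical disease-manifold projection loss
#'
#' Per time point, the latent state is regressed onto the clinical basis
#' (least squares); the loss is the summed squared residual off the span,
#' `sum_t ||z(t) - sum_k alpha_k(t) e_k||^2`. Invariant to any invertible
#' re-parameterization of a basis spanning the same subspace.
#'
#' @param latent_trajectory A `pf_trajectory` or matrix of latent states.
#' @param specs A [coherence_specs()] with `manifold_basis` (k x K, full
#'   column rank).
#' @return Nonnegative scalar.
#' @export
manifold_projection_loss <- function(latent_trajectory, specs) {
  E <- specs$manifold_basis
  Z <- if (inherits(latent_trajectory, "pf_trajectory"))
    latent_trajectory$states else as.matrix(latent_trajectory)
  stopifnot(ncol(Z) == nrow(E))
  qrE <- qr(E)
  if (qrE$rank < ncol(E)) stop("rank-deficient manifold basis")
  # residual off the span: Z - Z P with P the orthogonal projector onto col(E)
  Q <- qr.Q(qrE)
  resid <- Z - (Z %*% Q) %*% t(Q)
  sum(resid^2)
}

.traj_states <- function(latent_trajectory, grid) {
  if (inherits(latent_trajectory, "pf_trajectory")) {
    Z <- matrix(NA_real_, length(grid), ncol(latent_trajectory$states))
    for (j in seq_len(ncol(Z)))
      Z[, j] <- stats::approx(latent_trajectory$dense_times,
                              latent_trajectory$dense_states[, j],
                              xout = grid, rule = 2)$y
    Z
  } else {
    Z <- as.matrix(latent_trajectory)
    stopifnot(nrow(Z) == length(grid))
    Z
  }
}

.apply_readout <- function(observation_head, Z) {
  if (is.function(observation_head)) as.vector(observation_head(Z))
  else as.vector(Z %*% observation_head$u + observation_head$c)
}
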