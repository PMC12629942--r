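# Memory-augmented decoding, hard stage classification, and the temporal
# contrastive objective.

#' Memory parameters
#'
#' The per-subject memory evolves by a gated convex update
#' `M' = (1 - g) * M + g * phi(z)` with `g = sigmoid(W_g [z; M] + b_g)`
#' elementwise in (0, 1) and the linear target map `phi(z) = W_p z + b_p`.
#' With a constant gate the update is a contraction toward `phi(z)`.
#'
#' @param latent_dim Width of the latent state `z`.
#' @param memory_dim Width of the memory vector.
#' @param seed Integer seed for initialization.
#' @param gate_value Optional fixed gate in `[0, 1]` (scalar or length
#'   `memory_dim`) overriding the learned gate; used for diagnostics.
#' @return Object of class `pf_memory_params`.
#' @export
memory_params <- function(latent_dim, memory_dim = 4L, seed = 1L,
                          gate_value = NULL) {
  pars <- .with_seed(seed, c(
    mlp_init(latent_dim + memory_dim, memory_dim, prefix = "mem_gate"),
    mlp_init(latent_dim, memory_dim, prefix = "mem_phi")
  ))
  structure(list(pars = pars, latent_dim = latent_dim,
                 memory_dim = memory_dim, gate_value = gate_value),
            class = "pf_memory_params")
}

# Internal batched memory update (M, Z may be adnodes; n x d / n x k).
memory_step <- function(pars, M, Z, gate_value = NULL) {
  phi <- mlp_forward(pars, Z, prefix = "mem_phi", activation = "identity")
  g <- if (is.null(gate_value)) {
    ad_sigmoid(mlp_forward(pars, ad_cbind(list(Z, M)), prefix = "mem_gate",
                           activation = "identity"))
  } else {
    matrix(gate_value, nrow(ad_value(M)), ncol(ad_value(M)), byrow = TRUE)
  }
  # M + g * (phi - M)  ==  (1 - g) * M + g * phi
  ad_add(M, ad_mul(g, ad_sub(phi, M)))
}

#' Update the per-subject memory state
#'
#' @param memory Current memory vector (length `memory_dim`).
#' @param z Latent state vector.
#' @param params A [memory_params()] object.
#' @return Next memory vector; deterministic.
#' @export
update_memory <- function(memory, z, params) {
  stopifnot(length(memory) == params$memory_dim,
            length(z) == params$latent_dim)
  as.vector(ad_value(memory_step(params$pars, matrix(memory, 1L),
                                 matrix(z, 1L), params$gate_value)))
}

#' Decoder parameters
#'
#' The visit-level decoder refines the persistent cognitive readout (the
#' linear cognitive field `u . z + c`, which the template and counterfactual
#' constraints reuse) with a linear memory correction:
#' `yhat = u . z + c + w_m . M`. Sharing the readout inside the decoder keeps
#' the two observation heads consistent, mirroring the shared soft/hard stage
#' head.
#'
#' @param u Cognitive direction (length `latent_dim`).
#' @param c Readout intercept.
#' @param w_m Memory correction weights (length `memory_dim`).
#' @return Object of class `pf_decoder_params`.
#' @export
decoder_params <- function(u, c = 0, w_m = 0) {
  structure(list(u = as.numeric(u), c = as.numeric(c),
                 w_m = as.numeric(w_m)),
            class = "pf_decoder_params")
}

#' Decode the predicted outcome from latent state and memory
#'
#' `yhat = u . z + c + w_m . M`; deterministic.
#'
#' @param z Latent state vector.
#' @param memory Memory vector.
#' @param params A [decoder_params()] object.
#' @return Predicted outcome (scalar).
#' @export
decode_output <- function(z, memory, params) {
  w_m <- rep_len(params$w_m, length(memory))
  sum(params$u * z) + params$c + sum(w_m * memory)
}

#' Hard stage classification
#'
#' `argmax_l  omega_l . z + nu_l` over stages `0..L`; ties break toward the
#' lowest stage index (clinical conservatism). Adding a constant to every bias
#' leaves the prediction unchanged.
#'
#' @param z Latent state vector, or matrix with one state per row.
#' @param head List with `omega` ((L+1) x k weight matrix, row `l+1` for stage
#'   `l`) and `nu` (length L+1 biases).
#' @return Integer stage(s) in `{0..L}`.
#' @export
classify_stage <- function(z, head) {
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  stopifnot(ncol(Z) == ncol(head$omega),
            length(head$nu) == nrow(head$omega))
  logits <- Z %*% t(head$omega) + matrix(head$nu, nrow(Z), length(head$nu),
                                         byrow = TRUE)
  out <- apply(logits, 1L, which.max) - 1L  # which.max takes the first (lowest)
  if (is.matrix(z)) out else out[[1L]]
}

#' Temporal contrastive loss over latent trajectories
#'
#' InfoNCE-style objective pulling each subject's embedding at time index `t`
#' toward the same subject's embedding `delta_time` indices later, against one
#' randomly timed negative from every other subject:
#' `mean over anchors of -log( exp(s_pos/tau) / (exp(s_pos/tau) +
#' sum_j exp(s_neg_j/tau)) )`.
#' Including the positive term in the denominator bounds the loss below by 0
#' and makes the all-similarities-equal case well defined (`log(n_neg + 1)`);
#' set `literal_denominator = TRUE` for the variant whose denominator contains
#' only the negatives.
#'
#' @param latent_batch List of per-subject latent trajectories (matrices,
#'   time x k), each with at least `delta_time + 1` rows; at least 2 subjects.
#' @param delta_time Positive integer temporal offset between anchor and
#'   positive.
#' @param tau Temperature (> 0).
#' @param seed Integer seed for negative-time sampling.
#' @param literal_denominator Use the negatives-only denominator.
#' @return Scalar loss (nonnegative unless `literal_denominator = TRUE`).
#' @export
contrastive_loss <- function(latent_batch, delta_time = 1L, tau = 0.5,
                             seed = 1L, literal_denominator = FALSE) {
  n <- length(latent_batch)
  if (n < 2L) stop("contrastive loss needs at least 2 subjects (no negatives)")
  stopifnot(delta_time >= 1L, tau > 0)
  for (i in seq_len(n))
    if (nrow(latent_batch[[i]]) < delta_time + 1L)
      stop("trajectory ", i, " has fewer than delta_time + 1 states")
  .with_seed(seed, {
    total <- 0
    n_anchor <- 0L
    for (i in seq_len(n)) {
      Ti <- nrow(latent_batch[[i]])
      for (t in seq_len(Ti - delta_time)) {
        za <- latent_batch[[i]][t, ]
        zp <- latent_batch[[i]][t + delta_time, ]
        s_pos <- cosine_similarity(za, zp)
        s_neg <- vapply(setdiff(seq_len(n), i), function(j) {
          tj <- sample.int(nrow(latent_batch[[j]]), 1L)
          cosine_similarity(za, latent_batch[[j]][tj, ])
        }, numeric(1L))
        denom <- sum(exp(s_neg / tau)) +
          if (literal_denominator) 0 else exp(s_pos / tau)
        total <- total - (s_pos / tau - log(denom))
        n_anchor <- n_anchor + 1L
      }
    }
    total / n_anchor
  })
}
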