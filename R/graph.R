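# Graph-attention propagation of per-region pathology embeddings and the two
# spatial regularizers (synchronization and anatomical projection).

#' Numerically stabilized cosine similarity
#'
#' `a . b / (||a|| ||b|| + 1e-12)`; the stabilizer makes the similarity of a
#' zero vector ~0 instead of NaN.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)) + 1e-12)
}

#' Attention coefficients over in-neighborhoods
#'
#' For each region `v`, softmax-normalized cosine similarities between `v`'s
#' embedding and those of its in-neighbors:
#' `alpha_uv = exp(sim(r_u, r_v)) / sum_{w in N(v)} exp(sim(r_w, r_v))`.
#' Computed on the embeddings as given (before any linear map).
#'
#' @param state Matrix of region embeddings, one row per region, rows ordered
#'   as `graph$region_ids`.
#' @param graph A [region_graph()].
#' @return Named list, one element per region: named numeric vector of
#'   attention weights over `N(v)` summing to 1, or an empty vector for an
#'   isolated region (no in-neighbors).
#' @export
attention_coefficients <- function(state, graph) {
  ids <- graph$region_ids
  stopifnot(nrow(state) == length(ids))
  nb <- graph_in_neighbors(graph)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (v in seq_along(ids)) {
    us <- nb[[v]]
    if (!length(us)) {
      out[[v]] <- stats::setNames(numeric(), character())
      next
    }
    sims <- vapply(us, function(u)
      cosine_similarity(state[u, ], state[v, ]), numeric(1L))
    e <- exp(sims - max(sims))
    out[[v]] <- stats::setNames(e / sum(e), ids[us])
  }
  out
}

#' One step of graph-attention message passing
#'
#' `r_v' = sigma( sum_{u in N(v)} alpha_uv W r_u + b )` with attention from
#' [attention_coefficients()]. An isolated region (empty in-neighborhood)
#' falls back to the bias-only update `r_v' = sigma(b)`.
#'
#' @param state Matrix of region embeddings (regions x d).
#' @param graph A [region_graph()].
#' @param params List with `W` (d x d), `b` (length d), and `activation`
#'   (`"tanh"`, `"sigmoid"`, `"gelu"` or `"identity"`; default `"tanh"`).
#' @return Next regional state, same shape as `state`.
#' @export
propagate_regions <- function(state, graph, params) {
  d <- ncol(state)
  stopifnot(all(dim(params$W) == c(d, d)), length(params$b) == d)
  if (any(!is.finite(state))) stop("non-finite regional state")
  act_name <- if (is.null(params$activation)) "tanh" else params$activation
  act <- .act_fun(act_name)
  alpha <- attention_coefficients(state, graph)
  nb <- graph_in_neighbors(graph)
  out <- matrix(NA_real_, nrow(state), d)
  for (v in seq_len(nrow(state))) {
    us <- nb[[v]]
    msg <- if (length(us)) {
      agg <- colSums(alpha[[v]] * state[us, , drop = FALSE])
      as.vector(params$W %*% agg)
    } else {
      rep(0, d)
    }
    out[v, ] <- ad_value(act(matrix(msg + params$b, 1L)))
  }
  if (any(!is.finite(out))) stop("non-finite regional state after propagation")
  rownames(out) <- rownames(state)
  out
}

#' Synchronization regularizer
#'
#' `sum over ordered pairs (v, w) of kappa_vw ||r_v - r_w||^2`: penalizes
#' desynchronization of regions the compatibility kernel deems coupled. With a
#' symmetric kernel the ordered-pair sum counts each unordered pair twice (a
#' fixed factor-2 convention). Invariant under a global translation of all
#' embeddings.
#'
#' @param state Matrix of region embeddings (regions x d).
#' @param kernel Symmetric nonnegative matrix `kappa` (regions x regions).
#' @return Nonnegative scalar.
#' @export
sync_regularizer <- function(state, kernel) {
  n <- nrow(state)
  stopifnot(all(dim(kernel) == c(n, n)))
  # sum_vw kappa_vw ||r_v - r_w||^2 = 2 tr(R' L R), L the kernel Laplacian
  L <- diag(rowSums(kernel), n) - kernel
  2 * sum((L %*% state) * state)
}

#' Anatomical projection penalty
#'
#' `sum_v ||r_v - A_v z||^2`: ties each regional embedding to a per-region
#' linear projection of the subject latent state (the anatomical expectation).
#' Implemented with the squared norm for differentiability, matching the
#' synchronization penalty's convention.
#'
#' @param state Matrix of region embeddings (regions x d).
#' @param z Latent state vector (length k).
#' @param params List with `A`: list of per-region projection matrices
#'   (d x k each).
#' @return Nonnegative scalar.
#' @export
anatomical_projection_penalty <- function(state, z, params) {
  A <- params$A
  stopifnot(length(A) == nrow(state))
  tot <- 0
  for (v in seq_len(nrow(state))) {
    resid <- state[v, ] - as.vector(A[[v]] %*% z)
    tot <- tot + sum(resid^2)
  }
  tot
}
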