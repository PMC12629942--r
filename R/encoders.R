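# Modality encoders: map baseline imaging / omics / demographic blocks to the
# initial hidden state, embed baseline features into the subject conditioning
# vector, and apply gated latent augmentation.

#' Encoder parameters
#'
#' Each modality gets a dedicated feed-forward map (default two layers with a
#' smooth GELU-style activation); their outputs are concatenated into the
#' initial hidden state. A separate linear embedder maps the full concatenated
#' baseline block to the subject conditioning vector. The augmentation gate
#' `xi` is initialized at zero so augmentation starts as the identity.
#'
#' @param img_dim,omics_dim,demo_dim Input widths of the three blocks.
#' @param img_widths,omics_widths,demo_widths Layer widths (hidden then
#'   output) of the per-modality maps.
#' @param cond_dim Width of the conditioning vector.
#' @param noise_sd Augmentation noise standard deviation (>= 0).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `pf_encoder_params`.
#' @export
encoder_params <- function(img_dim, omics_dim, demo_dim,
                           img_widths = c(16L, 8L),
                           omics_widths = c(16L, 8L),
                           demo_widths = c(8L, 4L),
                           cond_dim = 4L, noise_sd = 0.05, seed = 1L) {
  stopifnot(noise_sd >= 0, cond_dim >= 1L)
  base_dim <- img_dim + omics_dim + demo_dim
  pars <- .with_seed(seed, c(
    mlp_init(img_dim, img_widths, prefix = "enc_img"),
    mlp_init(omics_dim, omics_widths, prefix = "enc_omics"),
    mlp_init(demo_dim, demo_widths, prefix = "enc_demo"),
    mlp_init(base_dim, cond_dim, prefix = "cond")
  ))
  h_dim <- img_widths[length(img_widths)] +
    omics_widths[length(omics_widths)] + demo_widths[length(demo_widths)]
  structure(list(pars = pars,
                 dims = list(img = img_dim, omics = omics_dim,
                             demo = demo_dim, hidden = h_dim,
                             cond = cond_dim),
                 noise_sd = noise_sd),
            class = "pf_encoder_params")
}

# Internal batched encoder; blocks are n x dim matrices (or adnodes),
# pars a flat parameter list. Returns the n x h concatenated hidden state.
encode_forward <- function(pars, img, omics, demo) {
  ad_cbind(list(
    mlp_forward(pars, img, prefix = "enc_img", activation = "gelu"),
    mlp_forward(pars, omics, prefix = "enc_omics", activation = "gelu"),
    mlp_forward(pars, demo, prefix = "enc_demo", activation = "gelu")
  ))
}

#' Encode a baseline modality block into the initial hidden state
#'
#' The three per-modality maps are applied independently and their outputs
#' concatenated, so encoding is permutation-equivariant across subjects.
#'
#' @param block Named list with `imaging`, `omics`, `demographics` vectors
#'   (or matrices with one row per subject).
#' @param params An [encoder_params()] object.
#' @return Hidden-state vector (or matrix) of width
#'   `sum of the per-modality output widths`.
#' @export
encode_baseline <- function(block, params) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, 1L)
  img <- as_m(block$imaging); om <- as_m(block$omics)
  dm <- as_m(block$demographics)
  for (nm in c("img", "omics", "demo")) {
    x <- switch(nm, img = img, omics = om, demo = dm)
    if (ncol(x) != params$dims[[nm]])
      stop("dimension mismatch in modality '", nm, "': got ", ncol(x),
           ", expected ", params$dims[[nm]])
  }
  H <- ad_value(encode_forward(params$pars, img, om, dm))
  if (!is.matrix(block$imaging)) as.vector(H) else H
}

#' Embed baseline features into the subject conditioning vector
#'
#' @param baseline_features Full concatenated baseline block (vector, or
#'   matrix with one row per subject).
#' @param params An [encoder_params()] object.
#' @return Conditioning vector `psi` of width `cond_dim` (matrix for matrix
#'   input); deterministic.
#' @export
condition_vector <- function(baseline_features, params) {
  X <- if (is.matrix(baseline_features)) baseline_features
       else matrix(baseline_features, 1L)
  want <- params$dims$img + params$dims$omics + params$dims$demo
  if (ncol(X) != want)
    stop("dimension mismatch: baseline width ", ncol(X), ", expected ", want)
  P <- ad_value(mlp_forward(params$pars, X, prefix = "cond",
                            activation = "identity"))
  if (!is.matrix(baseline_features)) as.vector(P) else P
}

#' Gated nonlinear latent augmentation
#'
#' `z~ = z + xi * tanh(z) + eps`, with `eps ~ N(0, sd^2)` drawn reproducibly
#' from `seed`. With `xi = 0` and `sd = 0` this is the identity; with
#' `sd = 0` it is a fixed smooth map.
#'
#' @param z Latent vector or matrix (rows = states).
#' @param xi Per-dimension gate (default 0).
#' @param noise_sd Noise SD (default 0).
#' @param seed Integer seed for the noise draw.
#' @return Perturbed latent, same shape as `z`.
#' @export
augment_latent <- function(z, xi = 0, noise_sd = 0, seed = 1L) {
  stopifnot(all(is.finite(z)), noise_sd >= 0)
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  xi <- rep_len(xi, ncol(Z))
  eps <- if (noise_sd > 0)
    .with_seed(seed, matrix(stats::rnorm(length(Z), sd = noise_sd), nrow(Z)))
  else 0
  out <- Z + sweep(tanh(Z), 2L, xi, "*") + eps
  if (is.matrix(z)) out else as.vector(out)
}
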