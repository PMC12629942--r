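# Dense feed-forward layers over the autodiff primitives, plus Adam.
# Parameters are flat named lists of plain matrices (biases stored 1 x d);
# during training each matrix is wrapped in an ad_leaf for the forward pass.

.act_fun <- function(name) {
  switch(name,
    tanh     = ad_tanh,
    gelu     = ad_gelu,
    sigmoid  = ad_sigmoid,
    identity = function(x) x,
    stop("unknown activation: ", name)
  )
}

# Xavier/Glorot-initialized stack of dense layers.
# widths = hidden widths followed by the output width.
mlp_init <- function(in_dim, widths, prefix = "mlp") {
  stopifnot(length(widths) >= 1L, all(widths > 0))
  dims <- c(in_dim, widths)
  pars <- list()
  for (l in seq_along(widths)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    sd <- sqrt(2 / (fan_in + fan_out))
    pars[[paste0(prefix, "_W", l)]] <-
      matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
    pars[[paste0(prefix, "_b", l)]] <- matrix(0, 1L, fan_out)
  }
  pars
}

# Forward pass through layers named <prefix>_W1/_b1, ... in `pars`
# (entries may be plain matrices or ad leaves). X is n x in_dim.
mlp_forward <- function(pars, X, prefix = "mlp", activation = "gelu") {
  act <- .act_fun(activation)
  h <- X
  l <- 1L
  repeat {
    W <- pars[[paste0(prefix, "_W", l)]]
    if (is.null(W)) break
    b <- pars[[paste0(prefix, "_b", l)]]
    h <- ad_addrow(ad_matmul(h, W), b)
    if (!is.null(pars[[paste0(prefix, "_W", l + 1L)]])) h <- act(h)
    l <- l + 1L
  }
  h
}

mlp_n_layers <- function(pars, prefix) {
  l <- 0L
  while (!is.null(pars[[paste0(prefix, "_W", l + 1L)]])) l <- l + 1L
  l
}

adam_init <- function(theta) {
  list(m = lapply(theta, function(p) p * 0),
       v = lapply(theta, function(p) p * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr = 1e-2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, state = state)
}
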