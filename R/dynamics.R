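# Continuous-time latent dynamics: parameterized flow fields, fixed-step RK4
# integration, and fixed-point diagnostics. The flow field gives the direction
# and speed of latent degeneration; its zeros are fixed disease states.

#' Flow-field parameterizations
#'
#' `linear_dynamics(A, b)` defines `dz/dt = A z + b`;
#' `function_dynamics(fun)` wraps an arbitrary `fun(z, t, psi)` (rows of `z`
#' are states); `dynamics_params()` builds a feed-forward flow field
#' `g(z, t, psi, u)` over the latent state, (optionally) time, a subject
#' conditioning vector and an exogenous modulator channel, with
#' tanh-activated hidden layers.
#'
#' @param A Square matrix (k x k).
#' @param b Offset vector (length k, default 0).
#' @return A flow-field parameter object of class `pf_dynamics`.
#' @export
linear_dynamics <- function(A, b = 0) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  b <- rep_len(b, nrow(A))
  structure(list(kind = "linear", A = A, b = b, latent_dim = nrow(A)),
            class = "pf_dynamics")
}

#' @rdname linear_dynamics
#' @param fun Function `(z, t, psi) -> velocity matrix` (rows = states).
#' @param latent_dim Latent dimension k.
#' @export
function_dynamics <- function(fun, latent_dim) {
  structure(list(kind = "function", fun = fun, latent_dim = latent_dim),
            class = "pf_dynamics")
}

#' @rdname linear_dynamics
#' @param hidden_widths Hidden-layer widths of the flow network.
#' @param cond_dim Width of the conditioning vector `psi` (0 = none).
#' @param time_input Include `t` as an input channel.
#' @param exog_input Include an exogenous modulator channel `u(t)`
#'   (zero when absent).
#' @param seed Integer seed for weight initialization.
#' @export
dynamics_params <- function(latent_dim, hidden_widths = 16L, cond_dim = 0L,
                            time_input = TRUE, exog_input = FALSE, seed = 1L) {
  stopifnot(latent_dim >= 1L)
  in_dim <- latent_dim + time_input + cond_dim + exog_input
  pars <- .with_seed(seed,
    mlp_init(in_dim, c(hidden_widths, latent_dim), prefix = "flow"))
  structure(list(kind = "mlp", pars = pars, latent_dim = latent_dim,
                 cond_dim = cond_dim, time_input = time_input,
                 exog_input = exog_input),
            class = "pf_dynamics")
}

# Internal flow evaluation; Z (n x k), tvec scalar or length n, Psi
# (n x cond_dim or NULL), Uvec exogenous channel. Supports adnodes for the
# mlp kind (Z, Psi, and pars entries may be nodes).
flow_eval <- function(params, Z, tvec = 0, Psi = NULL, Uvec = NULL) {
  if (params$kind == "linear") {
    Zv <- ad_value(Z)
    return(sweep(Zv %*% t(params$A), 2L, params$b, "+"))
  }
  if (params$kind == "function") {
    Zv <- ad_value(Z)
    return(params$fun(Zv, tvec, if (!is.null(Psi)) ad_value(Psi)))
  }
  n <- nrow(ad_value(Z))
  inputs <- list(Z)
  if (isTRUE(params$time_input))
    inputs <- c(inputs, list(matrix(rep_len(tvec, n), n, 1L)))
  if (params$cond_dim > 0L) {
    if (is.null(Psi)) Psi <- matrix(0, n, params$cond_dim)
    inputs <- c(inputs, list(Psi))
  }
  if (isTRUE(params$exog_input))
    inputs <- c(inputs,
                list(matrix(if (is.null(Uvec)) 0 else rep_len(Uvec, n), n, 1L)))
  X <- if (length(inputs) > 1L) ad_cbind(inputs) else inputs[[1L]]
  mlp_forward(params$pars, X, prefix = "flow", activation = "tanh")
}

#' Evaluate the latent flow field
#'
#' @param z Latent state: vector of length k or matrix (n x k of states).
#' @param t Time (scalar, or length-n vector for a matrix `z`).
#' @param psi Optional conditioning vector/matrix.
#' @param params A `pf_dynamics` object.
#' @param u Optional exogenous modulator value(s).
#' @return Latent velocity `dz/dt`, same shape as `z`.
#' @export
flow_field <- function(z, t = 0, psi = NULL, params, u = NULL) {
  vec_in <- !is.matrix(z)
  Z <- if (vec_in) matrix(z, 1L) else z
  if (any(!is.finite(Z))) stop("non-finite latent state")
  if (ncol(Z) != params$latent_dim)
    stop("latent state width ", ncol(Z), " does not match latent_dim ",
         params$latent_dim)
  Psi <- if (!is.null(psi)) { if (is.matrix(psi)) psi else matrix(psi, 1L) }
  V <- ad_value(flow_eval(params, Z, t, Psi, u))
  if (vec_in) as.vector(V) else V
}

#' Integrate a latent trajectory with fixed-step RK4
#'
#' Deterministic fixed-step 4th-order Runge-Kutta from `t0` with dense steps
#' of size `step`; states at `query_times` are linearly interpolated from the
#' dense solution. The one-step map of this integrator is the model's
#' discrete-time transition function.
#'
#' @param z0 Initial latent state at `t0` (length k).
#' @param psi Optional conditioning vector.
#' @param query_times Increasing times (first >= `t0`).
#' @param params A `pf_dynamics` object.
#' @param step Step size (> 0).
#' @param t0 Start time of integration (default 0).
#' @param u_fn Optional exogenous modulator `function(t) -> scalar`.
#' @return Object of class `pf_trajectory`: `times`, `states`
#'   (length(query_times) x k), `psi`, and the dense grid (`dense_times`,
#'   `dense_states`).
#' @export
integrate_trajectory <- function(z0, psi = NULL, query_times, params,
                                 step = 0.01, t0 = 0, u_fn = NULL) {
  stopifnot(step > 0, length(query_times) >= 1L)
  if (is.unsorted(query_times) || query_times[1L] < t0 - 1e-12)
    stop("query_times must be increasing with first >= t0")
  k <- params$latent_dim
  stopifnot(length(z0) == k)
  tend <- query_times[length(query_times)]
  n_steps <- if (tend > t0) ceiling((tend - t0) / step - 1e-9) else 0L
  dense_t <- t0 + step * (0:n_steps)
  if (n_steps > 0L) dense_t[n_steps + 1L] <- min(dense_t[n_steps + 1L], tend)
  Psi <- if (!is.null(psi)) matrix(psi, 1L)
  z <- matrix(as.numeric(z0), 1L)
  dense <- matrix(NA_real_, length(dense_t), k)
  dense[1L, ] <- z
  f <- function(tt, zz) {
    u <- if (!is.null(u_fn)) u_fn(tt)
    ad_value(flow_eval(params, zz, tt, Psi, u))
  }
  for (i in seq_len(length(dense_t) - 1L)) {
    tt <- dense_t[i]
    dt <- dense_t[i + 1L] - tt
    k1 <- f(tt, z)
    k2 <- f(tt + dt / 2, z + dt / 2 * k1)
    k3 <- f(tt + dt / 2, z + dt / 2 * k2)
    k4 <- f(tt + dt, z + dt * k3)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(z)))
      stop("latent trajectory blew up (non-finite) at time ",
           format(dense_t[i + 1L]))
    dense[i + 1L, ] <- z
  }
  states <- matrix(NA_real_, length(query_times), k)
  for (j in seq_len(k))
    states[, j] <- stats::approx(dense_t, dense[, j], xout = query_times,
                                 rule = 2)$y
  structure(list(times = query_times, states = states, psi = psi,
                 dense_times = dense_t, dense_states = dense),
            class = "pf_trajectory")
}

#' Locate fixed points of the flow field
#'
#' Multi-start root search for latent points with `||F(z)|| <= tol`; such
#' critical points are fixed disease states (e.g. the healthy state and the
#' fully degenerated attractor). Diagnostic use only (k <= 8).
#'
#' @param params A `pf_dynamics` object.
#' @param psi Optional conditioning vector.
#' @param search_box Matrix (k x 2) of lower/upper bounds, or length-2 vector
#'   recycled to all dimensions.
#' @param n_starts Number of random restarts.
#' @param seed Integer seed for the restart locations.
#' @param tol Acceptance tolerance on `||F(z)||`.
#' @param dedupe Radius within which candidate points are merged.
#' @return Matrix of fixed points (possibly 0 rows), one per row.
#' @export
find_fixed_points <- function(params, psi = NULL, search_box = c(-3, 3),
                              n_starts = 32L, seed = 1L, tol = 1e-6,
                              dedupe = 1e-4) {
  k <- params$latent_dim
  if (k > 8L) stop("fixed-point search is a diagnostic for k <= 8")
  box <- if (is.matrix(search_box)) search_box
         else matrix(rep(search_box, each = k), k)
  obj <- function(z) sum(flow_field(z, 0, psi, params)^2)
  found <- NULL
  .with_seed(seed, {
    for (s in seq_len(n_starts)) {
      z0 <- stats::runif(k, box[, 1L], box[, 2L])
      fit <- try(stats::optim(z0, obj, method = "BFGS",
                              control = list(maxit = 500L, reltol = 1e-16)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      z <- fit$par
      if (sqrt(sum(flow_field(z, 0, psi, params)^2)) > tol) next
      if (!is.null(found) &&
          any(sqrt(rowSums(sweep(found, 2L, z)^2)) < dedupe)) next
      found <- rbind(found, z)
    }
  })
  if (is.null(found)) matrix(numeric(), 0L, k)
  else unname(found[order(found[, 1L]), , drop = FALSE])
}
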