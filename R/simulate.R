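# Synthetic longitudinal cohort generator.
#
# Emulates the structural assumptions of the progression model on an
# ADNI-like multimodal cohort: irregular visit schedules, ordinal stages
# 0..L, a cognitive score that declines as pathology advances (MMSE-like
# convention: lower = worse), sigmoid population biomarker trajectories, and
# regional pathology spreading on a brain-region graph. Every generated
# quantity has recorded ground truth so model components are testable without
# any external data. It matches the model's structural assumptions, not the
# distribution of any real dataset.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Parameters of the mechanistic regional pathology ODE
#'
#' The pathology level `h_v(t)` of region `v` evolves as
#' `dh_v/dt = -lambda_v h_v + sum_{u in N(v)} alpha_uv sigma(h_u) + beta_v x_v(t)`,
#' with `N(v)` the in-neighbors of `v`: intrinsic clearance at rate
#' `lambda_v` (1/year), nonlinear spread from connected regions with coupling
#' weights `alpha_uv`, and an exogenous per-region input `x_v(t)` (e.g. a
#' molecular driver) scaled by `beta_v`.
#'
#' @param decay_rates Positive per-region clearance rates `lambda_v` (1/year).
#' @param coupling Optional directed coupling matrix (`alpha[u, v]` weights the
#'   edge u -> v); defaults to the graph's edge weights.
#' @param input_gains Per-region input gains `beta_v` (default 0).
#' @param input_signal Function `time -> per-region input vector x(t)`
#'   (default: zero input).
#' @param nonlinearity Name of the spread nonlinearity `sigma`
#'   (`"tanh"`, `"sigmoid"` or `"identity"`); default hyperbolic tangent.
#' @return List of class `pf_region_sim_params`.
#' @export
region_sim_params <- function(decay_rates, coupling = NULL, input_gains = 0,
                              input_signal = NULL, nonlinearity = "tanh") {
  if (any(decay_rates < 0)) stop("decay_rates must be >= 0")
  if (!is.null(coupling) && any(!is.finite(coupling)))
    stop("coupling weights must be finite")
  structure(list(decay_rates = decay_rates, coupling = coupling,
                 input_gains = input_gains, input_signal = input_signal,
                 nonlinearity = nonlinearity),
            class = "pf_region_sim_params")
}

#' Simulate regional pathology spread on a brain-region graph
#'
#' Fixed-step 4th-order Runge-Kutta integration of the regional pathology
#' ODE (see [region_sim_params()]); deterministic.
#'
#' @param graph A [region_graph()].
#' @param params A [region_sim_params()].
#' @param initial_state Per-region pathology at `time_grid[1]`.
#' @param time_grid Increasing times (years) at which to report the state.
#' @param step Integration step size (> 0); states at grid times are linearly
#'   interpolated from the dense fixed-step solution.
#' @return Matrix `length(time_grid) x n_regions` of pathology levels.
#' @export
simulate_regional_pathology <- function(graph, params, initial_state,
                                        time_grid, step = 0.01) {
  stopifnot(step > 0, length(time_grid) >= 1L)
  if (is.unsorted(time_grid, strictly = TRUE) && length(time_grid) > 1L)
    stop("time_grid must be strictly increasing")
  n <- length(graph$region_ids)
  stopifnot(length(initial_state) == n)
  lam <- rep_len(params$decay_rates, n)
  beta <- rep_len(params$input_gains, n)
  A <- if (is.null(params$coupling)) graph_adjacency(graph) else params$coupling
  sig <- switch(params$nonlinearity,
                tanh = tanh,
                sigmoid = function(x) 1 / (1 + exp(-x)),
                identity = identity,
                stop("unknown nonlinearity: ", params$nonlinearity))
  xfun <- params$input_signal
  deriv <- function(t, h) {
    -lam * h + as.vector(t(A) %*% sig(h)) +
      beta * (if (is.null(xfun)) 0 else xfun(t))
  }
  t0 <- time_grid[1L]
  tend <- time_grid[length(time_grid)]
  n_steps <- if (tend > t0) ceiling((tend - t0) / step - 1e-12) else 0L
  dense_t <- t0 + step * (0:n_steps)
  dense_t[length(dense_t)] <- min(dense_t[length(dense_t)], tend)
  states <- matrix(NA_real_, length(dense_t), n)
  h <- as.numeric(initial_state)
  states[1L, ] <- h
  for (i in seq_len(length(dense_t) - 1L)) {
    dt <- dense_t[i + 1L] - dense_t[i]
    tt <- dense_t[i]
    k1 <- deriv(tt, h)
    k2 <- deriv(tt + dt / 2, h + dt / 2 * k1)
    k3 <- deriv(tt + dt / 2, h + dt / 2 * k2)
    k4 <- deriv(tt + dt, h + dt * k3)
    h <- h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(h)))
      stop("regional pathology state blew up (non-finite) at time ",
           format(dense_t[i + 1L]))
    states[i + 1L, ] <- h
  }
  out <- matrix(NA_real_, length(time_grid), n,
                dimnames = list(NULL, graph$region_ids))
  for (j in seq_len(n))
    out[, j] <- stats::approx(dense_t, states[, j], xout = time_grid,
                              rule = 2)$y
  out
}

#' Build a default brain-region graph for simulation
#'
#' A directed ring with shortcut edges (both directions on each anatomical
#' link), positive edge weights and a symmetric compatibility kernel derived
#' from the adjacency; every region has at least one in-neighbor.
#'
#' @param n_regions Number of regions.
#' @param seed Integer seed for the shortcut pattern and weights.
#' @return A [region_graph()].
#' @export
make_region_graph <- function(n_regions = 8L, seed = 1L) {
  .with_seed(seed, {
    ids <- sprintf("R%02d", seq_len(n_regions))
    nxt <- c(seq_len(n_regions)[-1L], 1L)
    src <- c(seq_len(n_regions), nxt)
    dst <- c(nxt, seq_len(n_regions))
    n_extra <- max(1L, floor(n_regions / 2))
    for (e in seq_len(n_extra)) {
      u <- sample.int(n_regions, 1L)
      v <- sample.int(n_regions, 1L)
      if (u == v || any(src == u & dst == v)) next
      src <- c(src, u, v); dst <- c(dst, v, u)
    }
    w <- stats::runif(length(src), 0.2, 0.6)
    # symmetric weights on paired directions
    for (i in seq_along(src)) {
      j <- which(src == dst[i] & dst == src[i])
      w[j] <- w[i]
    }
    edges <- data.frame(src = ids[src], dst = ids[dst], weight = w)
    kappa <- matrix(0, n_regions, n_regions)
    kappa[cbind(src, dst)] <- w
    kappa <- (kappa + t(kappa)) / 2
    region_graph(ids, edges, kappa)
  })
}

#' Default synthetic-cohort configuration
#'
#' The defaults define the package's reference study conditions: 200 subjects,
#' a 4-dimensional latent, 3 ordinal stages (cognitively normal / mild /
#' advanced), a 5-year observation horizon with 3-8 irregularly timed visits
#' per subject, an MMSE-like cognitive score (intercept 29, declining with
#' severity, measurement noise SD 0.5 points), sigmoid regional biomarker
#' trajectories (noise SD 0.05) and standardized baseline feature blocks
#' (imaging 12, omics 10, demographics 4; noise SD 0.1).
#'
#' @param ... Named overrides of the defaults.
#' @return Configuration list.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_subjects = 200L,
    latent_dim = 4L,
    stage_count = 3L,
    horizon = 5,
    visit_range = c(3L, 8L),
    n_regions = 8L,
    img_dim = 12L,
    omics_dim = 10L,
    demo_dim = 4L,
    cognitive_intercept = 29,
    cognitive_scale = 2,        # norm of the true cognitive direction
    attractor = 2,              # disease attractor coordinate (per latent dim)
    decay_range = c(0.15, 0.5), # latent drift rates toward the attractor, 1/yr
    z0_range = c(0, 1.2),
    biomarker_width = 0.4,
    noise = list(cognitive = 0.5, biomarker = 0.05, modality = 0.1),
    treated_fraction = 0,
    stage_obs_prob = 1,
    exogenous_input = FALSE     # treatment-indicator channel u(t), off by default
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' Latent trajectories follow a stable linear flow toward a disease attractor
#' `z*`: `dz/dt = Lambda (z* - z)` with per-dimension rates `Lambda`, so the
#' severity score increases monotonically for every subject. The cognitive
#' score is `y(t) = u* . z(t) + c* + eta` with a negative direction `u*`
#' (cognition declines as pathology grows); the ordinal stage counts how many
#' severity thresholds the subject's noiseless severity `-u* . z(t)` has
#' passed, with thresholds placed at cohort tertiles of noiseless severity so
#' stages are balanced; per-region biomarkers are sigmoids of severity plus
#' noise; baseline modality blocks are per-modality linear maps of `z(0)` plus
#' noise. Generation is an exact function of `(config, seed)`.
#'
#' @param config A [default_sim_config()] list.
#' @param seed Integer seed.
#' @return List with elements `cohort` (a `pf_cohort`) and `truth`
#'   (class `pf_ground_truth`: true flow field, `u_star`, `c_star`,
#'   thresholds, biomarker curve parameters, per-visit noiseless severity and
#'   cognitive score, latent states, and noise specification).
#' @export
generate_cohort <- function(config = default_sim_config(), seed = 1L) {
  if (config$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (config$latent_dim < 1L) stop("latent_dim must be >= 1")
  .with_seed(seed, {
    k <- config$latent_dim
    n <- config$n_subjects
    Th <- config$horizon
    graph <- make_region_graph(config$n_regions,
                               seed = sample.int(.Machine$integer.max, 1L))

    # true latent dynamics: dz/dt = Lambda (z_att - z)
    lam <- stats::runif(k, config$decay_range[1L], config$decay_range[2L])
    z_att <- rep(config$attractor, k)
    w <- abs(stats::rnorm(k)); w <- w / sqrt(sum(w^2))
    u_star <- -config$cognitive_scale * w   # cognition declines with pathology
    c_star <- config$cognitive_intercept

    ids <- sprintf("S%04d", seq_len(n))
    z0 <- matrix(stats::runif(n * k, config$z0_range[1L], config$z0_range[2L]),
                 n, k)

    n_vis <- sample(seq(config$visit_range[1L], config$visit_range[2L]),
                    n, replace = TRUE)
    vis <- vector("list", n)
    for (i in seq_len(n)) {
      tt <- c(0, sort(stats::runif(n_vis[i] - 1L, 0, Th)))
      while (anyDuplicated(tt))
        tt <- c(0, sort(stats::runif(n_vis[i] - 1L, 0, Th)))
      # closed-form latent state of the linear attractor flow
      zt <- sapply(seq_len(k), function(j)
        z_att[j] + (z0[i, j] - z_att[j]) * exp(-lam[j] * tt))
      if (length(tt) == 1L) zt <- matrix(zt, nrow = 1L)
      vis[[i]] <- list(time = tt, z = zt)
    }

    sev_all <- unlist(lapply(vis, function(v) -(v$z %*% u_star)))
    thresholds <- unname(stats::quantile(
      sev_all, probs = seq_len(config$stage_count - 1L) / config$stage_count))

    mid <- stats::quantile(sev_all, probs = seq(0.2, 0.8,
                                                length.out = config$n_regions))
    bio_mid <- unname(mid)
    bio_w <- config$biomarker_width

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      v <- vis[[i]]
      sev <- as.vector(-(v$z %*% u_star))
      y0 <- as.vector(v$z %*% u_star) + c_star
      y <- y0 + stats::rnorm(length(sev), sd = config$noise$cognitive)
      stage <- vapply(sev, function(s) sum(s > thresholds), numeric(1L))
      if (config$stage_obs_prob < 1) {
        drop <- stats::runif(length(stage)) > config$stage_obs_prob
        stage[drop] <- NA_real_
      }
      bio <- sapply(seq_len(config$n_regions), function(r)
        1 / (1 + exp(-(sev - bio_mid[r]) / bio_w)) +
          stats::rnorm(length(sev), sd = config$noise$biomarker))
      if (length(sev) == 1L) bio <- matrix(bio, nrow = 1L)
      colnames(bio) <- paste0("bio_", seq_len(config$n_regions) - 1L)
      rows[[i]] <- data.frame(subject_id = ids[i], time = v$time,
                              cognitive_score = y, stage = stage,
                              severity_true = sev, score_true = y0,
                              check.names = FALSE)
      rows[[i]] <- cbind(rows[[i]], as.data.frame(bio))
    }
    visits_full <- do.call(rbind, rows)
    rownames(visits_full) <- NULL

    P_img <- matrix(stats::rnorm(k * config$img_dim), k) / sqrt(k)
    P_omics <- matrix(stats::rnorm(k * config$omics_dim), k) / sqrt(k)
    P_demo <- matrix(stats::rnorm(k * config$demo_dim), k) / sqrt(k)
    mk_block <- function(P, prefix) {
      X <- z0 %*% P + matrix(stats::rnorm(n * ncol(P),
                                          sd = config$noise$modality), n)
      colnames(X) <- paste0(prefix, "_", seq_len(ncol(P)) - 1L)
      X
    }
    baseline <- cbind(
      data.frame(subject_id = ids),
      as.data.frame(mk_block(P_img, "img")),
      as.data.frame(mk_block(P_omics, "omics")),
      as.data.frame(mk_block(P_demo, "demo"))
    )

    visits <- visits_full[, setdiff(names(visits_full),
                                    c("severity_true", "score_true"))]
    cohort <- structure(
      list(baseline = baseline, visits = visits,
           treatments = data.frame(subject_id = character(),
                                   treatment_code = character(),
                                   onset_time = numeric()),
           graph = graph,
           stage_count = as.integer(config$stage_count),
           time_horizon = Th,
           dims = list(img = .block_cols(baseline, "img"),
                       omics = .block_cols(baseline, "omics"),
                       demo = .block_cols(baseline, "demo"),
                       bio = .block_cols(visits, "bio"))),
      class = "pf_cohort"
    )

    truth <- structure(
      list(flow = linear_dynamics(-diag(lam, k), as.vector(diag(lam, k) %*% z_att)),
           decay = lam, attractor = z_att,
           u_star = u_star, c_star = c_star,
           thresholds = thresholds,
           biomarker_curves = list(midpoints = bio_mid, width = bio_w),
           latent0 = structure(z0, dimnames = list(ids, NULL)),
           visit_truth = visits_full[, c("subject_id", "time",
                                         "severity_true", "score_true")],
           latent_visits = do.call(rbind, lapply(seq_len(n), function(i) {
             zz <- vis[[i]]$z
             colnames(zz) <- paste0("z", seq_len(k))
             cbind(data.frame(subject_id = ids[i], time = vis[[i]]$time), zz)
           })),
           noise_spec = config$noise,
           config = config, seed = as.integer(seed)),
      class = "pf_ground_truth"
    )
    if (config$treated_fraction > 0) {
      inj <- inject_treatment_effect(
        cohort, truth, effect_size = 1, onset_quantile = 0.5,
        treated_fraction = config$treated_fraction,
        seed = sample.int(.Machine$integer.max, 1L))
      cohort <- inj
    }
    list(cohort = cohort, truth = truth)
  })
}

#' Inject a treatment effect into a cohort
#'
#' For a seeded subset of subjects a treatment with onset `t_a` (a quantile of
#' the subject's visit times) shifts every post-onset cognitive outcome by
#' `effect_size * (1 - exp(-(t - t_a)))` -- a saturating time-varying shift
#' that is exactly 0 at onset. The treatment table is populated; all other
#' fields are unchanged.
#'
#' @param cohort A `pf_cohort`.
#' @param truth Ground truth from [generate_cohort()] (recorded alongside).
#' @param effect_size Finite asymptotic shift in cognitive-score units
#'   (positive = beneficial for a declining score).
#' @param onset_quantile Quantile of each treated subject's visit times at
#'   which treatment starts.
#' @param treated_fraction Fraction of subjects treated.
#' @param seed Integer seed selecting the treated subjects.
#' @return The modified `pf_cohort` with a populated treatment table.
#' @export
inject_treatment_effect <- function(cohort, truth, effect_size,
                                    onset_quantile = 0.5,
                                    treated_fraction = 0.3, seed = 1L) {
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  .with_seed(seed, {
    ids <- unique(cohort$baseline$subject_id)
    n_tr <- max(1L, round(length(ids) * treated_fraction))
    treated <- sort(sample(ids, n_tr))
    tr_rows <- vector("list", length(treated))
    for (j in seq_along(treated)) {
      sid <- treated[j]
      sel <- cohort$visits$subject_id == sid
      tt <- cohort$visits$time[sel]
      t_a <- unname(stats::quantile(tt, onset_quantile))
      post <- sel & cohort$visits$time >= t_a
      shift <- effect_size * (1 - exp(-(cohort$visits$time[post] - t_a)))
      cohort$visits$cognitive_score[post] <-
        cohort$visits$cognitive_score[post] + shift
      tr_rows[[j]] <- data.frame(subject_id = sid, treatment_code = "tx1",
                                 onset_time = t_a)
    }
    cohort$treatments <- do.call(rbind, tr_rows)
    cohort
  })
}
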