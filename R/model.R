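# Model state: parameter initialization, default configuration, coherence
# defaults, and the batched forward pass computing the composite objective.
# The forward pass is written against the autodiff primitives, so the same
# code evaluates plainly for prediction and builds a tape for training.

#' Default model configuration
#'
#' Architecture and optimization defaults: per-modality two-layer encoders,
#' a 4-dimensional latent with a tanh-MLP flow field integrated on a 41-point
#' fixed RK4 grid over the (internally rescaled) cohort horizon, a
#' 4-dimensional gated memory, a 6-dimensional regional embedding propagated
#' for 4 graph-attention steps, InfoNCE contrastive settings, loss weights
#' (1 for prediction and stage supervision, 0.1 for every regularizer), and a
#' first-order adaptive optimizer (Adam, step 0.01, 50 epochs, batches of 16
#' subjects).
#'
#' @param ... Named overrides (nested lists are replaced wholesale).
#' @return Configuration list.
#' @export
default_model_config <- function(...) {
  cfg <- list(
    latent_dim = 4L,
    cond_dim = 4L,
    encoder = list(img_widths = c(16L, 8L), omics_widths = c(16L, 8L),
                   demo_widths = c(8L, 4L)),
    dynamics = list(hidden_widths = 16L, grid_points = 41L),
    memory_dim = 4L,
    graph = list(embed_dim = 6L, steps = 4L),
    contrastive = list(delta = 4L, tau = 0.5, literal_denominator = FALSE),
    augment = list(noise_sd = 0.05),
    weights = c(prediction = 1, stage_kl = 1, contrastive = 0.1, sync = 0.1,
                anatomical = 0.1, anchor = 0.1, ordinal = 0.1,
                direction = 0.1, monotonicity = 0.1, disentangle = 0.1,
                biomarker = 0.1, template = 0.1, consistency = 0.1,
                counterfactual = 0.1, projection = 0.1),
    optim = list(lr = 1e-2, epochs = 50L, batch_size = 16L)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown model config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (any(cfg$weights < 0)) stop("loss weights must be >= 0")
  cfg
}

# 32-bit FNV-1a hash of a serialized object (for config fingerprints).
.fnv_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Default coherence references built from a training cohort: binned-mean
# population biomarker curves, a single population cognitive template, an
# inactive (full-space) manifold basis, and every subject assigned to the one
# subtype.
pf_default_coherence <- function(cohort, n_knots = 6L) {
  Th <- max(cohort$time_horizon, 1e-9)
  knots <- seq(0, Th, length.out = n_knots)
  binned <- function(times, values) {
    ok <- !is.na(values)
    times <- times[ok]; values <- values[ok]
    if (!length(values)) return(reference_curve(c(0, Th), c(0, 0)))
    idx <- pmin(pmax(findInterval(times, knots, rightmost.closed = TRUE), 1L),
                n_knots - 1L)
    vals <- vapply(seq_len(n_knots - 1L), function(j) {
      v <- values[idx == j]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1L))
    mids <- (knots[-1L] + knots[-n_knots]) / 2
    ok2 <- !is.na(vals)
    reference_curve(mids[ok2], vals[ok2])
  }
  curves <- lapply(cohort$dims$bio, function(cl)
    binned(cohort$visits$time, cohort$visits[[cl]]))
  names(curves) <- cohort$dims$bio
  templates <- list(
    "1" = binned(cohort$visits$time, cohort$visits$cognitive_score))
  subtype <- stats::setNames(rep("1", nrow(cohort$baseline)),
                             cohort$baseline$subject_id)
  list(reference_curves = curves, templates = templates,
       subtype = subtype, manifold_basis = NULL)
}

#' Initialize a progression model for a cohort
#'
#' Builds the full trainable parameter set (modality encoders, conditioning
#' embedder, initial-state map, flow field, shared stage head, stage anchors
#' and ordinal shift, cognitive field, memory and decoder, graph-attention
#' layer and per-region anatomical projections, biomarker decoder, modality
#' alignment map, treatment-shift parameters, augmentation gate) plus the
#' fixed coherence references derived from the cohort.
#'
#' @param cohort A `pf_cohort` (with a region graph).
#' @param config A [default_model_config()] list.
#' @param seed Integer seed controlling initialization.
#' @param coherence Optional coherence references (see
#'   [coherence_specs()]-style list from `pf_default_coherence`); by default
#'   derived from the cohort.
#' @return Object of class `pf_model`.
#' @export
pf_init_model <- function(cohort, config = default_model_config(), seed = 1L,
                          coherence = NULL) {
  if (is.null(cohort$graph)) stop("cohort must carry a region graph")
  k <- config$latent_dim
  L1 <- cohort$stage_count
  p <- length(cohort$dims$img); q <- length(cohort$dims$omics)
  r <- length(cohort$dims$demo)
  d <- config$graph$embed_dim
  dm <- config$memory_dim
  R <- length(cohort$graph$region_ids)
  ew <- config$encoder
  h_dim <- ew$img_widths[length(ew$img_widths)] +
    ew$omics_widths[length(ew$omics_widths)] +
    ew$demo_widths[length(ew$demo_widths)]
  macro_dim <- ew$img_widths[length(ew$img_widths)]
  micro_dim <- ew$omics_widths[length(ew$omics_widths)]

  theta <- .with_seed(seed, {
    th <- c(
      mlp_init(p, ew$img_widths, prefix = "enc_img"),
      mlp_init(q, ew$omics_widths, prefix = "enc_omics"),
      mlp_init(r, ew$demo_widths, prefix = "enc_demo"),
      mlp_init(p + q + r, config$cond_dim, prefix = "cond"),
      mlp_init(h_dim, k, prefix = "z0"),
      mlp_init(k + 1L + config$cond_dim,
               c(config$dynamics$hidden_widths, k), prefix = "flow"),
      mlp_init(k + dm, dm, prefix = "mem_gate"),
      mlp_init(k, dm, prefix = "mem_phi")
    )
    th$dec_Wm <- matrix(0, dm, 1L)
    th$stage_W <- matrix(stats::rnorm(k * L1, sd = 0.2), k, L1)
    th$stage_b <- matrix(0, 1L, L1)
    th$anchor_mu <- matrix(stats::rnorm(L1 * k, sd = 0.05), L1, k)
    th$anchor_shift <- matrix(stats::rnorm(k, sd = 0.05), 1L, k)
    th$cog_u <- matrix(stats::rnorm(k, sd = 0.1), k, 1L)
    th$cog_c <- matrix(mean(cohort$visits$cognitive_score, na.rm = TRUE),
                       1L, 1L)
    if (!is.finite(th$cog_c[1L])) th$cog_c[1L] <- 0
    th$gr_W <- matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)
    th$gr_b <- matrix(0, 1L, d)
    for (v in seq_len(R))
      th[[paste0("anat_A", v)]] <-
        matrix(stats::rnorm(k * d, sd = sqrt(1 / k)), k, d)
    th$bio_W <- matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1L)
    th$bio_b <- matrix(0.5, 1L, 1L)
    th$align_W <- matrix(stats::rnorm(micro_dim * macro_dim,
                                      sd = sqrt(1 / micro_dim)),
                         micro_dim, macro_dim)
    th$treat_scale <- matrix(0, 1L, 1L)
    th$treat_lograte <- matrix(0, 1L, 1L)   # length scale = exp(-lograte)
    th$treat_dir <- matrix(0, 1L, k)
    th$aug_xi <- matrix(0, 1L, k)
    th
  })

  if (is.null(coherence)) coherence <- pf_default_coherence(cohort)

  structure(list(
    theta = theta,
    config = config,
    stage_count = L1,
    graph = cohort$graph,
    coherence = coherence,
    time_horizon = cohort$time_horizon,
    dims = list(img = p, omics = q, demo = r, latent = k, hidden = h_dim,
                memory = dm, graph_embed = d, regions = R,
                macro = macro_dim, micro = micro_dim),
    seed = as.integer(seed)
  ), class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  np <- sum(vapply(x$theta, length, numeric(1L)))
  cat("pf_model: latent dim", x$dims$latent, "|", x$stage_count, "stages |",
      x$dims$regions, "regions |", np, "parameters\n")
  invisible(x)
}

# ---- batched forward pass -------------------------------------------------

# Assemble per-batch constant structures (gather/interpolation matrices,
# masks). ids must be a character vector of subject ids present in cohort.
.batch_constants <- function(model, cohort, ids) {
  B <- length(ids)
  G <- model$config$dynamics$grid_points
  Th <- max(model$time_horizon, 1e-9)
  bl <- cohort$baseline[match(ids, cohort$baseline$subject_id), , drop = FALSE]
  vis <- cohort$visits[cohort$visits$subject_id %in% ids, , drop = FALSE]
  vis <- vis[order(match(vis$subject_id, ids), vis$time), , drop = FALSE]
  V <- nrow(vis)
  subj_idx <- match(vis$subject_id, ids)
  ds <- 1 / (G - 1)

  # visit -> dense-grid linear interpolation matrix (V x G*B)
  s <- pmin(vis$time / Th, 1)
  pos <- s / ds
  g0 <- pmin(floor(pos), G - 2)
  w1 <- pos - g0
  Wint <- matrix(0, V, G * B)
  Wint[cbind(seq_len(V), g0 * B + subj_idx)] <- 1 - w1
  Wint[cbind(seq_len(V), (g0 + 1) * B + subj_idx)] <-
    Wint[cbind(seq_len(V), (g0 + 1) * B + subj_idx)] + w1

  # visit ordinal within subject, and per-step gathers for the memory
  ord <- stats::ave(seq_len(V), subj_idx, FUN = seq_along)
  J <- max(ord)
  Gj <- lapply(seq_len(J), function(j) {
    M <- matrix(0, B, V)
    sel <- which(ord == j)
    M[cbind(subj_idx[sel], sel)] <- 1
    M
  })
  mask_j <- lapply(seq_len(J), function(j) {
    m <- as.numeric(vapply(seq_len(B), function(i)
      any(ord == j & subj_idx == i), logical(1L)))
    matrix(m, B, model$dims$memory)
  })
  Gm <- matrix(0, V, J * B)
  Gm[cbind(seq_len(V), (ord - 1L) * B + subj_idx)] <- 1

  # consecutive-visit difference matrix for monotonicity
  pair_from <- which(ord[-1L] > 1 & subj_idx[-1L] == subj_idx[-V])
  Dv <- NULL
  if (length(pair_from)) {
    Dv <- matrix(0, length(pair_from), V)
    Dv[cbind(seq_along(pair_from), pair_from + 1L)] <- 1
    Dv[cbind(seq_along(pair_from), pair_from)] <- -1
  }

  # stage supervision constants
  lab <- which(!is.na(vis$stage))
  H1 <- matrix(0, V, model$stage_count)
  if (length(lab)) H1[cbind(lab, vis$stage[lab] + 1L)] <- 1
  obs_y <- which(!is.na(vis$cognitive_score))
  w_obs <- matrix(0, V, 1L)
  if (length(obs_y)) w_obs[obs_y, 1L] <- 1 / length(obs_y)

  # per-subject symbolic label: maximum observed stage
  sym <- vapply(seq_len(B), function(i) {
    st <- vis$stage[subj_idx == i]
    if (all(is.na(st))) NA_real_ else max(st, na.rm = TRUE)
  }, numeric(1L))

  list(ids = ids, B = B, G = G, V = V, Th = Th, ds = ds,
       baseline = bl, visits = vis, subj_idx = subj_idx,
       Wint = Wint, Gj = Gj, mask_j = mask_j, Gm = Gm, J = J,
       Dv = Dv, H1 = H1, n_lab = length(lab), w_obs = w_obs,
       n_obs = length(obs_y), sym_label = sym,
       s_grid = seq(0, 1, length.out = G), t_grid = seq(0, Th, length.out = G))
}

# Constant graph structures shared across batches.
.graph_constants <- function(model, B) {
  R <- model$dims$regions
  Madj <- graph_adjacency(model$graph)
  Madj <- (Madj > 0) * 1
  if (any(colSums(Madj) == 0))
    stop("regional channel requires every region to have an in-neighbor")
  kap <- model$graph$kappa
  Lk <- diag(rowSums(kap), R) - kap
  perm <- matrix(0, B * R, B * R)   # region-major -> subject-major
  for (i in seq_len(B)) for (v in seq_len(R))
    perm[(i - 1L) * R + v, (v - 1L) * B + i] <- 1
  list(mask_adj = kronecker(diag(B), Madj),
       L_big = kronecker(diag(B), Lk),
       perm = perm, R = R)
}

.row_gather <- function(rows, n_rows_total) {
  M <- matrix(0, length(rows), n_rows_total)
  M[cbind(seq_along(rows), rows)] <- 1
  M
}

# Squared entries helper on nodes/matrices.
.sq <- function(x) ad_mul(x, x)

# Full batched forward pass. theta entries may be plain matrices or ad
# leaves. Returns total (node/1x1), per-term values (numeric), and fitted
# quantities. Sampling inside (contrastive negatives, augmentation noise) is
# drawn from `seed`.
pf_forward <- function(theta, model, cohort, ids, seed = 1L,
                       losses = TRUE) {
  cst <- .batch_constants(model, cohort, ids)
  cfg <- model$config
  B <- cst$B; G <- cst$G; V <- cst$V
  k <- model$dims$latent

  Ximg <- as.matrix(cst$baseline[, cohort$dims$img, drop = FALSE])
  Xom <- as.matrix(cst$baseline[, cohort$dims$omics, drop = FALSE])
  Xdm <- as.matrix(cst$baseline[, cohort$dims$demo, drop = FALSE])

  Zma <- mlp_forward(theta, Ximg, prefix = "enc_img", activation = "gelu")
  Zmi <- mlp_forward(theta, Xom, prefix = "enc_omics", activation = "gelu")
  Zde <- mlp_forward(theta, Xdm, prefix = "enc_demo", activation = "gelu")
  H0 <- ad_cbind(list(Zma, Zmi, Zde))
  Z0 <- mlp_forward(theta, H0, prefix = "z0", activation = "identity")
  Psi <- mlp_forward(theta, ad_cbind(list(Ximg, Xom, Xdm)), prefix = "cond",
                     activation = "identity")

  # dense RK4 over rescaled time s in [0, 1]
  ds <- cst$ds
  flow_at <- function(Z, s) {
    X <- ad_cbind(list(Z, matrix(s, B, 1L), Psi))
    mlp_forward(theta, X, prefix = "flow", activation = "tanh")
  }
  states <- vector("list", G)
  vels <- vector("list", G - 1L)
  states[1L] <- list(Z0)   # x[i] <- list(v): classed [[<- is pathologically slow
  Z <- Z0
  for (g in seq_len(G - 1L)) {
    s <- cst$s_grid[g]
    k1 <- flow_at(Z, s)
    k2 <- flow_at(ad_add(Z, ad_mul(k1, ds / 2)), s + ds / 2)
    k3 <- flow_at(ad_add(Z, ad_mul(k2, ds / 2)), s + ds / 2)
    k4 <- flow_at(ad_add(Z, ad_mul(k3, ds)), s + ds)
    incr <- ad_add(ad_add(k1, ad_mul(ad_add(k2, k3), 2)), k4)
    Z <- ad_add(Z, ad_mul(incr, ds / 6))
    if (any(!is.finite(ad_value(Z))))
      stop("non-finite term in latent integration at grid step ", g)
    vels[g] <- list(k1)
    states[g + 1L] <- list(Z)
  }
  Zall <- ad_rbind(states)              # (G*B) x k, row (g-1)*B + i
  Zvis <- ad_matmul(cst$Wint, Zall)     # V x k

  # memory recurrence and decoding
  M <- matrix(0, B, model$dims$memory)
  Mlist <- vector("list", cst$J)
  for (j in seq_len(cst$J)) {
    zj <- ad_matmul(cst$Gj[[j]], Zvis)
    Mstep <- memory_step(theta, M, zj)
    M <- ad_add(M, ad_mul(cst$mask_j[[j]], ad_sub(Mstep, M)))
    Mlist[j] <- list(M)
  }
  Mvis <- ad_matmul(cst$Gm, ad_rbind(Mlist))
  readout <- ad_add(ad_matmul(Zvis, theta$cog_u), theta$cog_c)
  # decoder = persistent readout + linear memory correction
  Yhat <- ad_add(readout, ad_matmul(Mvis, theta$dec_Wm))

  logits <- ad_addrow(ad_matmul(Zvis, theta$stage_W), theta$stage_b)
  P <- ad_softmax_rows(logits)

  fits <- list(
    visits = cst$visits,
    z_visits = ad_value(Zvis),
    z0 = ad_value(Z0),
    yhat = as.vector(ad_value(Yhat)),
    readout = as.vector(ad_value(readout)),
    stage_prob = ad_value(P),
    t_grid = cst$t_grid
  )
  if (!losses)
    return(list(total = NULL, terms = NULL, fits = fits))

  terms <- list()

  # prediction: masked mean squared error of the decoded outcome
  y <- cst$visits$cognitive_score
  y0 <- ifelse(is.na(y), 0, y)
  terms$prediction <- ad_sum(ad_mul(cst$w_obs, .sq(ad_sub(Yhat,
    matrix(y0, ncol = 1L)))))

  # stage KL: cross-entropy of soft stage probabilities at labeled visits
  terms$stage_kl <- if (cst$n_lab > 0) {
    ad_div(ad_neg(ad_sum(ad_mul(cst$H1, ad_log(P)))), cst$n_lab)
  } else matrix(0, 1L, 1L)

  # anchors + ordinal spacing
  if (cst$n_lab > 0) {
    lab_mask <- matrix(rowSums(cst$H1), V, k)
    MuSel <- ad_matmul(cst$H1, theta$anchor_mu)
    terms$anchor <- ad_div(ad_sum(.sq(ad_mul(lab_mask,
      ad_sub(Zvis, MuSel)))), cst$n_lab)
  } else terms$anchor <- matrix(0, 1L, 1L)
  L1 <- model$stage_count
  if (L1 >= 2L) {
    Dm <- matrix(0, L1 - 1L, L1)
    Dm[cbind(seq_len(L1 - 1L), seq_len(L1 - 1L))] <- -1
    Dm[cbind(seq_len(L1 - 1L), seq_len(L1 - 1L) + 1L)] <- 1
    shift_rep <- ad_matmul(matrix(1, L1 - 1L, 1L), theta$anchor_shift)
    terms$ordinal <- ad_sum(.sq(ad_sub(ad_matmul(Dm, theta$anchor_mu),
                                       shift_rep)))
  } else terms$ordinal <- matrix(0, 1L, 1L)

  # cognitive-field direction: flow must not ascend the field
  Vel <- ad_rbind(vels)
  terms$direction <- ad_mean(ad_relu(ad_matmul(Vel, theta$cog_u)))

  # monotonicity of stage probabilities over consecutive visits (stages >= 1)
  terms$monotonicity <- if (!is.null(cst$Dv) && L1 >= 2L) {
    dP <- ad_cols(ad_matmul(cst$Dv, P), 2:L1)
    ad_div(ad_sum(ad_relu(ad_neg(dP))), nrow(cst$Dv))
  } else matrix(0, 1L, 1L)

  # disentanglement of subject-level symbolic labels at baseline
  sym <- cst$sym_label
  diff_mask <- outer(sym, sym, function(a, b)
    as.numeric(!is.na(a) & !is.na(b) & a != b))
  diag(diff_mask) <- 0
  terms$disentangle <- if (sum(diff_mask) > 0) {
    sq <- ad_rowsums(.sq(Z0))
    D2 <- ad_sub(ad_add(ad_matmul(sq, matrix(1, 1L, B)),
                        ad_matmul(matrix(1, B, 1L), ad_t(sq))),
                 ad_mul(ad_matmul(Z0, ad_t(Z0)), 2))
    ad_div(ad_sum(ad_mul(diff_mask, ad_exp(ad_neg(D2)))), sum(diff_mask))
  } else matrix(0, 1L, 1L)

  # contrastive: anchors on the dense grid, positives delta steps ahead,
  # one random-time negative per other subject; anchor view is augmented
  terms$contrastive <- if (B >= 2L) {
    delta <- cfg$contrastive$delta
    tau <- cfg$contrastive$tau
    # draws keyed to sorted subject ids so the term is invariant to the
    # order of subjects within the batch
    ids_ord <- order(cst$ids)
    smp <- .with_seed(seed, {
      ga_s <- sample.int(G - delta, B, replace = TRUE)
      gn_s <- sample.int(G, B, replace = TRUE)
      eps_s <- matrix(stats::rnorm(B * k, sd = cfg$augment$noise_sd), B, k)
      back <- order(ids_ord)
      list(ga = ga_s[back], gn = gn_s[back],
           eps = eps_s[back, , drop = FALSE])
    })
    Za <- ad_matmul(.row_gather((smp$ga - 1L) * B + seq_len(B), G * B), Zall)
    Zp <- ad_matmul(.row_gather((smp$ga + delta - 1L) * B + seq_len(B), G * B),
                    Zall)
    Zn <- ad_matmul(.row_gather((smp$gn - 1L) * B + seq_len(B), G * B), Zall)
    XiRep <- ad_matmul(matrix(1, B, 1L), theta$aug_xi)
    Za <- ad_add(ad_add(Za, ad_mul(XiRep, ad_tanh(Za))), smp$eps)
    rnorm_of <- function(X) ad_sqrt(ad_add(ad_rowsums(.sq(X)), 1e-12))
    Zan <- ad_mulcol(Za, ad_div(1, rnorm_of(Za)))
    Zpn <- ad_mulcol(Zp, ad_div(1, rnorm_of(Zp)))
    Znn <- ad_mulcol(Zn, ad_div(1, rnorm_of(Zn)))
    spos <- ad_rowsums(ad_mul(Zan, Zpn))
    Sneg <- ad_matmul(Zan, ad_t(Znn))
    offdiag <- 1 - diag(B)
    negsum <- ad_rowsums(ad_mul(offdiag, ad_exp(ad_div(Sneg, tau))))
    denom <- if (isTRUE(cfg$contrastive$literal_denominator)) negsum
             else ad_add(negsum, ad_exp(ad_div(spos, tau)))
    ad_mean(ad_sub(ad_log(denom), ad_div(spos, tau)))
  } else matrix(0, 1L, 1L)

  # regional graph channel: attention propagation + spatial penalties
  gct <- .graph_constants(model, B)
  R <- gct$R
  Jr <- cfg$graph$steps
  step_g <- round(seq(0, 1, length.out = Jr + 1L) * (G - 1L)) + 1L
  t_steps <- cst$t_grid[step_g]
  anat_of <- function(Zg) {
    blocks <- lapply(seq_len(R), function(v)
      ad_matmul(Zg, theta[[paste0("anat_A", v)]]))
    ad_matmul(gct$perm, ad_rbind(blocks))   # subject-major (B*R) x d
  }
  Zsteps <- lapply(step_g, function(g)
    ad_matmul(.row_gather((g - 1L) * B + seq_len(B), G * B), Zall))
  AZ <- lapply(Zsteps, anat_of)
  Rst <- AZ[[1L]]
  sync_acc <- NULL; anat_acc <- NULL
  bio_sq <- vector("list", Jr + 1L)
  ref_mat <- vapply(model$coherence$reference_curves, function(cf)
    cf(t_steps), numeric(Jr + 1L))   # (Jr+1) x R, variable order = region
  sync_of <- function(Rn) ad_mul(ad_sum(ad_mul(ad_matmul(gct$L_big, Rn), Rn)),
                                 2 / B)
  for (j in seq_len(Jr + 1L)) {
    if (j > 1L) {
      rn <- ad_mulcol(Rst, ad_div(1, ad_sqrt(ad_add(ad_rowsums(.sq(Rst)),
                                                    1e-12))))
      S <- ad_matmul(rn, ad_t(rn))
      E <- ad_mul(gct$mask_adj, ad_exp(S))
      cs <- ad_matmul(ad_t(E), matrix(1, B * R, 1L))
      At <- ad_mulcol(ad_t(E), ad_div(1, cs))
      Rst <- ad_tanh(ad_addrow(ad_matmul(ad_matmul(At, Rst), theta$gr_W),
                               theta$gr_b))
    }
    sj <- sync_of(Rst)
    aj <- ad_div(ad_sum(.sq(ad_sub(Rst, AZ[[j]]))), B)
    sync_acc <- if (is.null(sync_acc)) sj else ad_add(sync_acc, sj)
    anat_acc <- if (is.null(anat_acc)) aj else ad_add(anat_acc, aj)
    pred_b <- ad_addrow(ad_matmul(Rst, theta$bio_W), theta$bio_b)
    refv <- matrix(as.vector(t(ref_mat[j, , drop = FALSE])), B * R, 1L)
    bio_sq[j] <- list(ad_sum(.sq(ad_sub(pred_b, refv))))
  }
  terms$sync <- ad_div(sync_acc, Jr + 1L)
  terms$anatomical <- ad_div(anat_acc, Jr + 1L)
  wq_step <- trapezoid_weights(t_steps)
  bio_tot <- NULL
  for (j in seq_len(Jr + 1L)) {
    contrib <- ad_mul(bio_sq[[j]], wq_step[j] / B)
    bio_tot <- if (is.null(bio_tot)) contrib else ad_add(bio_tot, contrib)
  }
  terms$biomarker <- bio_tot

  # template alignment of the cognitive readout on the dense grid
  tmpl_names <- model$coherence$subtype[cst$ids]
  tmpl_vals <- matrix(NA_real_, G, B)
  for (i in seq_len(B))
    tmpl_vals[, i] <- model$coherence$templates[[tmpl_names[i]]](cst$t_grid)
  wq_grid <- trapezoid_weights(cst$t_grid)
  Wq <- matrix(rep(wq_grid, each = B) / B, ncol = 1L)
  Ygrid <- ad_add(ad_matmul(Zall, theta$cog_u), theta$cog_c)
  terms$template <- ad_sum(ad_mul(Wq,
    .sq(ad_sub(Ygrid, matrix(as.vector(t(tmpl_vals)), ncol = 1L)))))

  # cross-modality consistency (macro imaging vs mapped micro omics)
  terms$consistency <- ad_div(ad_sum(.sq(ad_sub(Zma,
    ad_matmul(Zmi, theta$align_W)))), B)

  # counterfactual treatment alignment
  tr <- cohort$treatments
  tr <- tr[tr$subject_id %in% cst$ids, , drop = FALSE]
  cf_tot <- NULL; n_cf <- 0L
  if (nrow(tr)) {
    ell <- ad_exp(ad_neg(theta$treat_lograte))
    for (q in seq_len(nrow(tr))) {
      sid <- tr$subject_id[q]
      i <- match(sid, cst$ids)
      t_a <- tr$onset_time[q]
      post_g <- which(cst$t_grid >= t_a)
      if (length(post_g) < 2L) next
      sel <- cst$visits$subject_id == sid & cst$visits$time >= t_a &
        !is.na(cst$visits$cognitive_score)
      if (!any(sel)) next
      ot <- cst$visits$time[sel]; ov <- cst$visits$cognitive_score[sel]
      yobs <- if (length(ot) >= 2L)
        stats::approx(ot, ov, xout = cst$t_grid[post_g], rule = 2)$y
      else rep(ov, length(post_g))
      tau_el <- matrix(cst$t_grid[post_g] - t_a, ncol = 1L)
      sat <- ad_sub(1, ad_exp(ad_div(-tau_el, ell)))
      shift <- ad_matmul(ad_mul(sat, theta$treat_scale), theta$treat_dir)
      Zs <- ad_matmul(.row_gather((post_g - 1L) * B + i, G * B), Zall)
      ycf <- ad_add(ad_matmul(ad_add(Zs, shift), theta$cog_u), theta$cog_c)
      wcf <- matrix(trapezoid_weights(cst$t_grid[post_g]), ncol = 1L)
      contrib <- ad_sum(ad_mul(wcf, .sq(ad_sub(ycf, matrix(yobs,
        ncol = 1L)))))
      cf_tot <- if (is.null(cf_tot)) contrib else ad_add(cf_tot, contrib)
      n_cf <- n_cf + 1L
    }
  }
  terms$counterfactual <- if (n_cf > 0) ad_div(cf_tot, n_cf)
                          else matrix(0, 1L, 1L)

  # canonical manifold projection (inactive under the full-space default)
  basis <- model$coherence$manifold_basis
  terms$projection <- if (!is.null(basis) && ncol(basis) < k) {
    Q <- qr.Q(qr(basis))
    resid <- ad_sub(Zall, ad_matmul(ad_matmul(Zall, Q), t(Q)))
    ad_div(ad_sum(.sq(resid)), G * B)
  } else matrix(0, 1L, 1L)

  w <- cfg$weights
  total <- NULL
  for (nm in names(w)) {
    tm <- terms[[nm]]
    if (is.null(tm)) stop("missing objective term: ", nm)
    if (!is.finite(ad_value(tm)[1L])) stop("non-finite objective term: ", nm)
    if (w[[nm]] == 0) next
    contrib <- ad_mul(tm, w[[nm]])
    total <- if (is.null(total)) contrib else ad_add(total, contrib)
  }
  if (is.null(total)) total <- matrix(0, 1L, 1L)
  list(total = total,
       terms = vapply(terms, function(tm) as.numeric(ad_value(tm)),
                      numeric(1L)),
       fits = fits)
}
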