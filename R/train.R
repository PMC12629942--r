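# Training pipeline: composite objective, gradient-based fitting, prediction,
# staging metrics, anchor-variable validation, and constraint diagnostics.

#' Composite training objective
#'
#' Evaluates every objective term on a subject batch and returns the weighted
#' total together with the unweighted per-term breakdown. Terms are
#' batch-count normalized (means over visits / subjects / grid points, as
#' appropriate) so loss weights are batch-size invariant; terms whose inputs
#' are absent from the batch (no stage labels, no treatments, full-space
#' manifold basis) contribute exactly 0.
#'
#' @param cohort A validated `pf_cohort`.
#' @param model A `pf_model` (see [pf_init_model()]).
#' @param subject_ids Subjects forming the batch (default: all).
#' @param weights Optional named replacement for `model$config$weights`.
#' @param seed Integer seed for the batch's contrastive sampling and
#'   augmentation noise.
#' @return List with `total` (scalar) and `terms` (named numeric vector of
#'   unweighted terms).
#' @export
composite_objective <- function(cohort, model, subject_ids = NULL,
                                weights = NULL, seed = 1L) {
  if (is.null(subject_ids)) subject_ids <- cohort$baseline$subject_id
  if (!is.null(weights)) {
    missing_w <- setdiff(names(model$config$weights), names(weights))
    if (length(missing_w)) stop("weights missing term(s): ",
                                paste(missing_w, collapse = ", "))
    model$config$weights <- weights[names(model$config$weights)]
  }
  out <- pf_forward(model$theta, model, cohort, subject_ids, seed = seed)
  list(total = as.numeric(ad_value(out$total)), terms = out$terms)
}

#' Fit the progression model
#'
#' Gradient-based optimization (Adam) of the composite objective. A fixed
#' seed controls initialization, epoch shuffling and all in-batch sampling, so
#' two runs with the same seed and configuration produce bit-identical loss
#' histories. If the objective turns non-finite, fitting aborts with a warning
#' and the last completed epoch's parameters are returned.
#'
#' @param cohort A validated `pf_cohort` (training split).
#' @param config A [default_model_config()] list.
#' @param seed Integer seed.
#' @return List of class `pf_fit` with `model` (the fitted `pf_model`) and
#'   `report` (per-epoch per-term loss history, epochs run, seed, config
#'   hash).
#' @export
fit_progression_model <- function(cohort, config = default_model_config(),
                                  seed = 1L, verbose = FALSE) {
  model <- pf_init_model(cohort, config, seed = seed)
  ids <- cohort$baseline$subject_id
  n_epochs <- config$optim$epochs
  bs <- config$optim$batch_size
  plan <- .with_seed(seed, {
    list(perms = lapply(seq_len(max(n_epochs, 1L)), function(e) sample(ids)),
         batch_seeds = matrix(sample.int(2^30, max(n_epochs, 1L) * 64L),
                              nrow = max(n_epochs, 1L)))
  })
  history <- list()
  theta <- model$theta
  opt <- adam_init(theta)
  checkpoint <- theta
  epochs_run <- 0L
  for (epoch in seq_len(n_epochs)) {
    perm <- plan$perms[[epoch]]
    starts <- seq(1L, length(perm), by = bs)
    batches <- lapply(starts, function(s0)
      perm[s0:min(s0 + bs - 1L, length(perm))])
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) < 2L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches <- batches[-nb]
    }
    epoch_terms <- NULL
    epoch_total <- 0
    ok <- TRUE
    for (b in seq_along(batches)) {
      leaves <- lapply(theta, ad_leaf)
      out <- tryCatch(
        pf_forward(leaves, model, cohort, batches[[b]],
                   seed = plan$batch_seeds[epoch, b]),
        error = function(e) e)
      if (inherits(out, "error")) {
        warning("fitting aborted at epoch ", epoch, ": ",
                conditionMessage(out), "; returning last checkpoint")
        ok <- FALSE
        break
      }
      grads_env <- ad_backward(out$total)
      grads <- lapply(leaves, function(lf) ad_grad(grads_env, lf))
      upd <- adam_step(theta, grads, opt, lr = config$optim$lr)
      theta <- upd$theta
      opt <- upd$state
      epoch_total <- epoch_total + as.numeric(ad_value(out$total))
      epoch_terms <- if (is.null(epoch_terms)) out$terms
                     else epoch_terms + out$terms
    }
    if (!ok) {
      theta <- checkpoint
      break
    }
    history[[epoch]] <- c(total = epoch_total / length(batches),
                          epoch_terms / length(batches))
    checkpoint <- theta
    epochs_run <- epoch
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message("epoch ", epoch, ": total ",
              signif(epoch_total / length(batches), 5))
  }
  model$theta <- theta
  hist_df <- if (length(history)) {
    df <- as.data.frame(do.call(rbind, history))
    df$epoch <- seq_len(nrow(df))
    df[, c("epoch", setdiff(names(df), "epoch"))]
  } else {
    data.frame(epoch = integer())
  }
  structure(list(
    model = model,
    report = list(history = hist_df, epochs_run = epochs_run,
                  seed = as.integer(seed), config_hash = .fnv_hash(config))
  ), class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat("pf_fit:", x$report$epochs_run, "epochs, seed", x$report$seed,
      ", config", x$report$config_hash, "\n")
  if (nrow(x$report$history)) {
    h <- x$report$history
    cat("  total loss:", format(h$total[1L], digits = 4L), "->",
        format(h$total[nrow(h)], digits = 4L), "\n")
  }
  invisible(x)
}

#' Visit-level predictions
#'
#' Runs the fitted model forward on a cohort and returns per-visit latent
#' states, the memory-conditioned decoded outcome, the persistent cognitive
#' readout `u . z + c`, stage probabilities and hard stage predictions.
#'
#' @param model A fitted `pf_model` (or a `pf_fit`).
#' @param cohort A `pf_cohort`.
#' @param subject_ids Optional subset of subjects.
#' @return List with `visits` (data frame including `yhat`, `readout`,
#'   `stage_pred`), `stage_prob` (matrix), `z_visits`, `z0`.
#' @export
predict_visits <- function(model, cohort, subject_ids = NULL) {
  if (inherits(model, "pf_fit")) model <- model$model
  if (is.null(subject_ids)) subject_ids <- cohort$baseline$subject_id
  out <- pf_forward(model$theta, model, cohort, subject_ids, losses = FALSE)
  f <- out$fits
  vis <- f$visits
  vis$yhat <- f$yhat
  vis$readout <- f$readout
  vis$stage_pred <- max.col(f$stage_prob, ties.method = "first") - 1L
  list(visits = vis, stage_prob = f$stage_prob, z_visits = f$z_visits,
       z0 = f$z0)
}

# Rank-statistic AUC (Mann-Whitney), average ranks for ties.
.auc_binary <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pure metric computation from labels, hard predictions and a probability
# matrix (column l+1 = stage l); macro averages over classes present in the
# labels.
stage_metrics <- function(truth, est, prob, stages) {
  confusion <- table(factor(truth, levels = stages),
                     factor(est, levels = stages),
                     dnn = c("true", "predicted"))
  present <- stages[stages %in% truth]
  prf <- vapply(present, function(s) {
    tp <- sum(truth == s & est == s)
    fp <- sum(truth != s & est == s)
    fn <- sum(truth == s & est != s)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3L))
  auc <- mean(vapply(present, function(s)
    .auc_binary(prob[, s + 1L], truth == s), numeric(1L)), na.rm = TRUE)
  list(accuracy = mean(truth == est),
       precision = mean(prf[1L, ]),
       recall = mean(prf[2L, ]),
       f1 = mean(prf[3L, ]),
       auc = auc,
       confusion = confusion,
       n_visits = length(truth))
}

# Spearman rank correlation (average ranks on ties) and mean squared error.
spearman_mse <- function(pred, obs) {
  c(spearman = stats::cor(pred, obs, method = "spearman"),
    mse = mean((pred - obs)^2))
}

#' Staging metrics
#'
#' Visit-level hard stage predictions against observed stage labels:
#' accuracy, macro-averaged recall and F1 (over classes present in the
#' labels), one-vs-rest macro AUC from the soft stage probabilities, and the
#' confusion matrix.
#'
#' @param model A fitted `pf_model` or `pf_fit`.
#' @param cohort A `pf_cohort` with stage labels on at least one visit.
#' @return List with `accuracy`, `recall`, `f1`, `auc`, `confusion`,
#'   `n_visits`.
#' @export
evaluate_stage_metrics <- function(model, cohort) {
  pred <- predict_visits(model, cohort)
  vis <- pred$visits
  lab <- which(!is.na(vis$stage))
  if (!length(lab)) stop("cohort has no stage labels")
  if (inherits(model, "pf_fit")) model <- model$model
  stage_metrics(vis$stage[lab], vis$stage_pred[lab],
                pred$stage_prob[lab, , drop = FALSE],
                stages = 0:(model$stage_count - 1L))
}

#' Correlation of the cognitive readout with an anchor variable
#'
#' Spearman rank correlation (average ranks on ties) and mean squared error
#' between the model's predicted cognitive readout and a clinical anchor
#' variable observed at visits.
#'
#' @param model A fitted `pf_model` or `pf_fit`.
#' @param cohort A `pf_cohort`.
#' @param anchor_variable Name of a visit column (e.g. `"cognitive_score"`),
#'   or a numeric vector aligned with the cohort's visit rows.
#' @return Named vector `c(spearman = ..., mse = ...)`.
#' @export
anchor_correlation <- function(model, cohort,
                               anchor_variable = "cognitive_score") {
  pred <- predict_visits(model, cohort)
  vis <- pred$visits
  anchor <- if (is.character(anchor_variable)) {
    if (!anchor_variable %in% names(vis))
      stop("unknown anchor variable: ", anchor_variable)
    vis[[anchor_variable]]
  } else {
    if (length(anchor_variable) != nrow(cohort$visits))
      stop("anchor vector must align with the cohort's visit rows")
    # align external vector (cohort row order) with prediction row order
    key_c <- paste(cohort$visits$subject_id, cohort$visits$time)
    key_p <- paste(vis$subject_id, vis$time)
    anchor_variable[match(key_p, key_c)]
  }
  ok <- !is.na(anchor)
  if (sum(ok) < 3L) stop("anchor variable observed at fewer than 3 visits")
  spearman_mse(vis$readout[ok], anchor[ok])
}

#' Monotonicity-violation mass of predicted stage probabilities
#'
#' Average per-consecutive-visit-pair monotonicity penalty
#' (see [monotonicity_penalty()]) of the model's predicted stage-probability
#' series across a cohort; the quantity the monotonicity constraint drives
#' toward zero.
#'
#' @param model A fitted `pf_model` or `pf_fit`.
#' @param cohort A `pf_cohort`.
#' @return Nonnegative scalar.
#' @export
monotonicity_violation_mass <- function(model, cohort) {
  pred <- predict_visits(model, cohort)
  vis <- pred$visits
  tot <- 0
  n_pairs <- 0L
  for (sid in unique(vis$subject_id)) {
    rows <- which(vis$subject_id == sid)
    if (length(rows) < 2L) next
    tot <- tot + monotonicity_penalty(pred$stage_prob[rows, , drop = FALSE])
    n_pairs <- n_pairs + length(rows) - 1L
  }
  if (n_pairs == 0L) return(0)
  tot / n_pairs
}

#' Fitted cognitive direction in the generator's latent frame
#'
#' The model's latent coordinates are identified only up to an invertible
#' linear map of the generating latent frame, so the fitted cognitive
#' direction is expressed in the generator's frame by least-squares
#' regression of the model's predicted cognitive readout on the true latent
#' states at the matched visits; the regression slope vector is the effective
#' direction, compared with the true direction by cosine similarity.
#'
#' @param model A fitted `pf_model` or `pf_fit`.
#' @param cohort A `pf_cohort` generated by [generate_cohort()].
#' @param truth The matching `pf_ground_truth`.
#' @return List with `direction` (effective direction in the true frame) and
#'   `cosine` (signed cosine similarity with the true direction `u*`).
#' @export
recovered_direction <- function(model, cohort, truth) {
  pred <- predict_visits(model, cohort)
  vis <- pred$visits
  lt <- truth$latent_visits
  key_p <- paste(vis$subject_id, signif(vis$time, 10))
  key_t <- paste(lt$subject_id, signif(lt$time, 10))
  m <- match(key_p, key_t)
  ok <- !is.na(m)
  zc <- grep("^z[0-9]+$", names(lt), value = TRUE)
  Zt <- as.matrix(lt[m[ok], zc, drop = FALSE])
  fit <- stats::lm.fit(cbind(1, Zt), vis$readout[ok])
  u_eff <- unname(fit$coefficients[-1L])
  cosine <- sum(u_eff * truth$u_star) /
    (sqrt(sum(u_eff^2)) * sqrt(sum(truth$u_star^2)))
  list(direction = u_eff, cosine = cosine)
}
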