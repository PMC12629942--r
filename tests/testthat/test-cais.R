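# Stage supervision, anchor geometry, cognitive-field direction,
# monotonicity and disentanglement penalties.

test_that("stage probabilities form a simplex and match a toy softmax", {
  head0 <- list(W = matrix(0, 3, 2), b = rep(0, 3))
  expect_equal(stage_probabilities(c(1, -1), head0), rep(1 / 3, 3))
  head1 <- list(W = matrix(0, 3, 2), b = c(10, 0, 0))
  expect_gt(stage_probabilities(c(0, 0), head1)[1], 0.9999)
  W <- rbind(c(0.5, -1), c(0.2, 0.3), c(-0.4, 0.1))
  b <- c(0.1, -0.2, 0)
  z <- c(0.7, -0.3)
  logits <- as.vector(W %*% z) + b
  expect_equal(stage_probabilities(z, list(W = W, b = b)),
               exp(logits) / sum(exp(logits)), tolerance = 1e-6)
  set.seed(1)
  Z5 <- matrix(rnorm(10), 5, 2)
  P <- stage_probabilities(Z5, list(W = W, b = b))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-9)
  # the soft head's argmax reproduces the shared hard classifier
  expect_identical(unname(apply(P, 1, which.max) - 1L),
                   classify_stage(Z5, list(omega = W, nu = b)))
})

test_that("stage KL equals cross-entropy with a one-hot target", {
  expect_equal(stage_kl_loss(c(0, 1, 0), 1), 0)
  expect_equal(stage_kl_loss(rep(1 / 3, 3), 2), log(3), tolerance = 1e-9)
  expect_equal(stage_kl_loss(c(0.7, 0.2, 0.1), 1), -log(0.2),
               tolerance = 1e-9)
  expect_warning(v <- stage_kl_loss(c(1, 0), 1), "capped")
  expect_equal(v, 1e3)
  expect_error(stage_kl_loss(c(0.5, 0.5), 3), "vocabulary")
  set.seed(2)
  for (i in 1:25) {
    p <- stats::runif(4); p <- p / sum(p)
    s <- sample(0:3, 1)
    one_hot <- replace(rep(0, 4), s + 1, 1)
    ce <- -sum(one_hot * log(p))
    expect_equal(stage_kl_loss(p, s), ce, tolerance = 1e-9)
  }
})

test_that("anchor loss measures squared distance to stage anchors, masking NAs", {
  mu <- rbind(c(0, 0), c(1, 1), c(2, 2))
  z <- rbind(c(0, 0), c(1, 1))
  expect_equal(anchor_loss(z, c(0, 1), mu), 0)
  z2 <- matrix(c(1, 2), 1)
  expect_equal(anchor_loss(z2, 0, mu), 5)
  expect_equal(anchor_loss(rbind(z2, c(50, 50)), c(0, NA), mu), 5)
})

test_that("ordinal regularizer rewards evenly spaced anchors", {
  delta <- c(0.5, -1)
  mu <- rbind(c(0, 0), c(0, 0) + delta, c(0, 0) + 2 * delta)
  expect_equal(ordinal_regularizer(mu, delta), 0)
  mu1 <- matrix(c(0, 1, 3), 3, 1)
  expect_equal(ordinal_regularizer(mu1, 1), 1)
  shift <- c(3, -4)
  expect_equal(ordinal_regularizer(sweep(mu, 2, shift, "+"), delta),
               ordinal_regularizer(mu, delta), tolerance = 1e-12)
  expect_warning(v <- ordinal_regularizer(matrix(0, 1, 2), c(0, 0)),
                 "single-stage")
  expect_equal(v, 0)
})

test_that("direction penalty hinges on ascent of the cognitive field", {
  u <- c(1, 1)   # ||u||^2 = 2
  field <- list(u = u, c = 0)
  k <- 2L
  down <- function_dynamics(function(z, t, psi)
    matrix(-u, nrow(z), k, byrow = TRUE), k)
  up <- function_dynamics(function(z, t, psi)
    matrix(u, nrow(z), k, byrow = TRUE), k)
  Z <- matrix(rnorm(10), 5, 2)
  expect_equal(cognitive_direction_penalty(Z, field, down), 0)
  expect_equal(cognitive_direction_penalty(Z, field, up), 2)
  expect_equal(cognitive_direction_penalty(Z, list(u = c(0, 0), c = 1), up), 0)
})

test_that("monotonicity penalty targets decreasing higher-stage probabilities", {
  P_ok <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(monotonicity_penalty(P_ok), 0)
  P_bad <- rbind(c(0.2, 0.8), c(0.4, 0.6))
  expect_equal(monotonicity_penalty(P_bad), 0.2, tolerance = 1e-12)
  expect_equal(monotonicity_penalty(P_bad[2:1, ]), 0)
  # stage 0 is excluded: rising stage-0 probability is not penalized
  P0 <- rbind(c(0.1, 0.9), c(0.9, 0.1))
  expect_equal(monotonicity_penalty(P0), 0.8, tolerance = 1e-12)
  expect_error(monotonicity_penalty(P_ok[1, , drop = FALSE]), "2 time points")
})

test_that("disentanglement penalizes only cross-label closeness", {
  z <- matrix(rnorm(8), 4, 2)
  expect_equal(disentangle_penalty(z, rep("a", 4)), 0)
  z2 <- rbind(c(1, 1), c(1, 1))
  expect_equal(disentangle_penalty(z2, c("a", "b")), 2)
  far <- rbind(c(0, 0), c(100, 100))
  expect_lt(disentangle_penalty(far, c("a", "b")), 1e-300)
})

test_that("every penalty is nonnegative and zero at its identity configuration", {
  set.seed(77)
  n_rand <- 1000L
  for (i in seq_len(n_rand)) {
    k <- sample(2:4, 1)
    L1 <- sample(2:4, 1)
    z <- matrix(rnorm(3 * k), 3, k)
    mu <- matrix(rnorm(L1 * k), L1, k)
    st <- sample(0:(L1 - 1), 3, replace = TRUE)
    p <- stats::runif(L1); p <- p / sum(p)
    P <- matrix(stats::runif(3 * L1), 3); P <- P / rowSums(P)
    expect_gte(stage_kl_loss(p, sample(0:(L1 - 1), 1)), 0)
    expect_gte(anchor_loss(z, st, mu), 0)
    expect_gte(ordinal_regularizer(mu, rnorm(k)), 0)
    expect_gte(monotonicity_penalty(P), 0)
    expect_gte(disentangle_penalty(z, sample(letters[1:2], 3,
                                             replace = TRUE)), 0)
  }
})

test_that("a small gradient step decreases the anchor loss", {
  set.seed(10)
  mu <- matrix(rnorm(6), 3, 2)
  z <- matrix(rnorm(10), 5, 2)
  st <- sample(0:2, 5, replace = TRUE)
  l0 <- anchor_loss(z, st, mu)
  grad <- 2 * (z - mu[st + 1, ])     # analytic gradient wrt z
  for (step in c(1e-3, 1e-2, 0.1)) {
    expect_lt(anchor_loss(z - step * grad, st, mu), l0)
  }
})
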