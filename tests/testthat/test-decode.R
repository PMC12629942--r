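# Memory updates, decoding, hard staging, and the contrastive objective.

mem_toy <- function(W_g = 0, b_g = 0, W_p = 0, b_p = 0, k = 1L, d = 1L,
                    gate_value = NULL) {
  prm <- memory_params(k, d, seed = 1, gate_value = gate_value)
  prm$pars$mem_gate_W1 <- matrix(W_g, k + d, d)
  prm$pars$mem_gate_b1 <- matrix(b_g, 1, d)
  prm$pars$mem_phi_W1 <- matrix(W_p, k, d)
  prm$pars$mem_phi_b1 <- matrix(b_p, 1, d)
  prm
}

test_that("gated memory update respects forced gates and the toy value", {
  prm0 <- mem_toy(gate_value = 0)
  expect_equal(update_memory(0.7, 0.3, prm0), 0.7)
  prm1 <- mem_toy(W_p = 2, gate_value = 1)
  expect_equal(update_memory(0.7, 0.3, prm1), 0.6)   # phi = 2 * 0.3
  prm_half <- mem_toy(b_p = 2, gate_value = 0.5)
  expect_equal(update_memory(0, 0.3, prm_half), 1)   # (1-g) 0 + g * 2 = 1
})

test_that("constant-gate memory update contracts geometrically toward phi(z)", {
  prm <- mem_toy(W_p = 1.5, b_p = -0.2, gate_value = 0.3)
  z <- 0.8
  phi <- 1.5 * z - 0.2
  M <- 5
  errs <- numeric(6)
  for (i in 1:6) {
    M <- update_memory(M, z, prm)
    errs[i] <- abs(M - phi)
  }
  expect_equal(errs[-1] / errs[-6], rep(0.7, 5), tolerance = 1e-9)
})

test_that("decoding is the readout plus a linear memory correction", {
  prm <- decoder_params(u = c(0, 0), c = 1.3, w_m = 0)
  expect_equal(decode_output(c(5, -2), c(9, 9), prm), 1.3)
  prm2 <- decoder_params(u = c(0.5, -1), c = 2, w_m = c(0.1, 0.2))
  z <- c(2, 1); M <- c(1, -1)
  expect_equal(decode_output(z, M, prm2),
               0.5 * 2 - 1 * 1 + 2 + 0.1 * 1 - 0.2 * 1)
  expect_identical(decode_output(z, M, prm2), decode_output(z, M, prm2))
})

test_that("hard staging takes the argmax with ties toward the lowest stage", {
  head <- list(omega = matrix(0, 3, 2), nu = c(1, 1, 1))
  expect_equal(classify_stage(c(0.3, -2), head), 0L)
  head2 <- list(omega = rbind(c(1, 0), c(0, 1)), nu = c(0, 0))
  expect_equal(classify_stage(c(0.2, 0.9), head2), 1L)
  head0 <- list(omega = matrix(rnorm(2), 1, 2), nu = 0)
  expect_equal(classify_stage(rnorm(2), head0), 0L)
  # invariant to adding a constant to every bias
  set.seed(2)
  headr <- list(omega = matrix(rnorm(8), 4, 2), nu = rnorm(4))
  Z <- matrix(rnorm(20), 10, 2)
  heads <- headr; heads$nu <- headr$nu + 7.3
  expect_identical(classify_stage(Z, headr), classify_stage(Z, heads))
})

test_that("contrastive loss reproduces the symmetric and limiting cases", {
  # 2 subjects, all embeddings identical -> every similarity equal -> ln 2
  traj <- list(matrix(1, 3, 2), matrix(1, 3, 2))
  expect_equal(contrastive_loss(traj, delta_time = 1, tau = 0.7, seed = 1),
               log(2), tolerance = 1e-9)
  # perfectly aligned positives, antipodal negatives, small tau -> loss -> 0
  tr2 <- list(rbind(c(1, 0), c(1, 0)), rbind(c(-1, 0), c(-1, 0)))
  expect_lt(contrastive_loss(tr2, delta_time = 1, tau = 0.05, seed = 1),
            1e-10)
  expect_error(contrastive_loss(list(matrix(1, 3, 2)), seed = 1),
               "2 subjects")
  expect_error(contrastive_loss(list(matrix(1, 1, 2), matrix(1, 3, 2)),
                                seed = 1),
               "delta_time")
})

test_that("three-subject case matches a hand computation, incl. literal variant", {
  # duplicate rows per subject make negative-time sampling irrelevant
  z1 <- c(1, 0); z2 <- c(0.6, 0.8); z3 <- c(-1, 0.5)
  traj <- list(rbind(z1, z1), rbind(z2, z2), rbind(z3, z3))
  tau <- 1
  expected <- mean(vapply(1:3, function(i) {
    zi <- traj[[i]][1, ]
    sp <- cosine_similarity(zi, zi)
    sn <- vapply(setdiff(1:3, i), function(j)
      cosine_similarity(zi, traj[[j]][1, ]), numeric(1))
    -(sp / tau - log(exp(sp / tau) + sum(exp(sn / tau))))
  }, numeric(1)))
  expect_equal(contrastive_loss(traj, delta_time = 1, tau = tau, seed = 3),
               expected, tolerance = 1e-6)
  expected_lit <- mean(vapply(1:3, function(i) {
    zi <- traj[[i]][1, ]
    sp <- cosine_similarity(zi, zi)
    sn <- vapply(setdiff(1:3, i), function(j)
      cosine_similarity(zi, traj[[j]][1, ]), numeric(1))
    -(sp / tau - log(sum(exp(sn / tau))))
  }, numeric(1)))
  expect_equal(contrastive_loss(traj, delta_time = 1, tau = tau, seed = 3,
                                literal_denominator = TRUE),
               expected_lit, tolerance = 1e-6)
})

test_that("contrastive loss is nonnegative and decreases as alignment grows", {
  set.seed(9)
  base <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2),
               matrix(rnorm(8), 4, 2))
  expect_gte(contrastive_loss(base, seed = 2), 0)
  # sweep the positive alignment with fixed negatives
  neg <- rbind(c(-1, 0), c(-1, 0))
  losses <- vapply(c(0, 0.5, 0.9), function(rot) {
    pos2 <- c(cos(acos(rot)), sin(acos(rot)))   # cosine = rot with anchor (1,0)
    tr <- list(rbind(c(1, 0), pos2), neg)
    contrastive_loss(tr, delta_time = 1, tau = 0.5, seed = 4)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})
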