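# Clinical coherence constraints: quadrature, biomarker/template alignment,
# modality consistency, counterfactual regularization, manifold projection.

test_that("trapezoidal quadrature is exact for affine integrands", {
  expect_equal(quadrature(rep(0.25, 5), seq(0, 2, 0.5)), 0.5)
  g <- sort(c(0, stats::runif(7), 1))
  expect_equal(quadrature(g, g), 0.5, tolerance = 1e-12)        # f(t) = t
  expect_equal(quadrature(3 * g - 1, g), 3 / 2 - 1, tolerance = 1e-12)
  g2 <- seq(0, 1, length.out = 1001)
  expect_equal(quadrature(g2^2, g2), 1 / 3, tolerance = 1e-5)
  expect_error(quadrature(1, 0.5), "at least 2")
})

test_that("quadrature converges at second order on smooth integrands", {
  errs <- vapply(c(101, 201, 401), function(n) {
    g <- seq(0, pi, length.out = n)
    abs(quadrature(sin(g), g) - 2)
  }, numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("biomarker alignment integrates squared deviations per variable", {
  grid <- seq(0, 2, length.out = 51)
  traj <- list(v1 = matrix(0.3, 51, 2))
  specs <- coherence_specs(
    reference_curves = list(v1 = reference_curve(c(0, 2), c(0.6, 0.6))),
    biomarker_decoder = function(r) 2 * r[, 1])
  expect_equal(biomarker_alignment_loss(traj, specs, grid), 0,
               tolerance = 1e-12)
  # constant offset 0.5 over T = 2 -> integral of 0.25 over 2 = 0.5
  specs$reference_curves$v1 <- reference_curve(c(0, 2), c(0.1, 0.1))
  expect_equal(biomarker_alignment_loss(traj, specs, grid), 0.5,
               tolerance = 1e-9)
  # two variables, offsets 0.5 and 1 over T = 1
  grid1 <- seq(0, 1, length.out = 26)
  traj2 <- list(a = matrix(0, 26, 1), b = matrix(0, 26, 1))
  specs2 <- coherence_specs(
    reference_curves = list(a = reference_curve(0, 0.5),
                            b = reference_curve(0, 1)),
    biomarker_decoder = function(r) r[, 1])
  expect_equal(biomarker_alignment_loss(traj2, specs2, grid1), 0.25 + 1,
               tolerance = 1e-9)
  expect_error(biomarker_alignment_loss(list(zz = traj2$a), specs2, grid1),
               "zz")
})

test_that("template alignment matches closed-form integrals", {
  grid <- seq(0, 3, length.out = 61)
  head <- list(u = c(1, 0), c = 0)
  specs <- coherence_specs(templates = list(
    k1 = reference_curve(c(0, 3), c(2, 2))))
  Z <- cbind(rep(2, 61), rnorm(61))
  expect_equal(template_alignment_loss(Z, "k1", specs, head, grid), 0,
               tolerance = 1e-12)
  Z1 <- cbind(rep(3, 61), 0)   # constant deviation 1 over T = 3
  expect_equal(template_alignment_loss(Z1, "k1", specs, head, grid), 3,
               tolerance = 1e-9)
  grid2 <- seq(0, 1, length.out = 201)
  specs2 <- coherence_specs(templates = list(k1 = reference_curve(0, 0)))
  Z2 <- cbind(grid2, 0)        # deviation t over [0, 1] -> integral 1/3
  expect_equal(template_alignment_loss(Z2, "k1", specs2, head, grid2), 1 / 3,
               tolerance = 1e-4)
  expect_error(template_alignment_loss(Z2, "nope", specs2, head, grid2),
               "unknown subtype")
})

test_that("modality consistency is a squared alignment residual", {
  specs <- coherence_specs(alignment_map = diag(3))
  z <- rnorm(3)
  expect_equal(modality_consistency_loss(z, z, specs), 0)
  expect_equal(modality_consistency_loss(c(1, 2, 2) + z, z, specs), 9)
  expect_equal(modality_consistency_loss(0 * z, 0 * z, specs), 0)
  A <- matrix(rnorm(6), 2, 3)
  specs2 <- coherence_specs(alignment_map = A)
  zmi <- rnorm(3)
  expect_equal(modality_consistency_loss(as.vector(A %*% zmi), zmi, specs2),
               0, tolerance = 1e-12)
})

test_that("counterfactual loss integrates post-onset readout mismatch", {
  grid <- seq(0, 3, length.out = 61)
  head <- list(u = c(1, 0), c = 0)
  # factual path matches observations and the shift is zero -> loss 0
  specs0 <- coherence_specs(treatment_shift = treatment_shift_model(
    0, c(1, 0)))
  Z <- cbind(5 - grid, 0)
  ev <- list(onset_time = 1,
             post_outcomes = data.frame(time = c(1, 2, 3),
                                        value = 5 - c(1, 2, 3)))
  expect_equal(counterfactual_loss(Z, ev, specs0, head, grid), 0,
               tolerance = 1e-12)
  # pre-onset identity: the shift function is exactly zero before onset
  sh <- treatment_shift_model(2, c(1, 1), length_scale = 0.5)
  expect_equal(sh(-0.3), c(0, 0))
  expect_equal(sh(0), c(0, 0))
  expect_equal(sh(1), 2 * (1 - exp(-2)) * c(1, 1), tolerance = 1e-12)
  # constant mismatch 1 over [t_a, T] with T - t_a = 2 -> loss 2
  ev1 <- list(onset_time = 1,
              post_outcomes = data.frame(time = c(1, 3),
                                         value = (5 - c(1, 3)) + 1))
  expect_equal(counterfactual_loss(Z, ev1, specs0, head, grid), 2,
               tolerance = 1e-9)
  expect_error(counterfactual_loss(Z, list(onset_time = 1,
                                           post_outcomes = NULL),
                                   specs0, head, grid),
               "post-onset")
})

test_that("manifold projection measures the residual off the clinical span", {
  basis <- cbind(c(1, 0, 0), c(0, 1, 0))
  specs <- coherence_specs(manifold_basis = basis)
  Z_in <- cbind(rnorm(5), rnorm(5), 0)
  expect_lt(manifold_projection_loss(Z_in, specs), 1e-10)
  specs1 <- coherence_specs(manifold_basis = matrix(c(1, 0), 2, 1))
  expect_equal(manifold_projection_loss(matrix(c(1, 1), 1), specs1), 1,
               tolerance = 1e-12)
  # residual is orthogonal to every basis vector
  set.seed(3)
  B <- matrix(rnorm(8), 4, 2)
  Z <- matrix(rnorm(12), 3, 4)
  Q <- qr.Q(qr(B))
  resid <- Z - (Z %*% Q) %*% t(Q)
  expect_lt(max(abs(resid %*% B)), 1e-8)
  # invariance under invertible re-parameterization of the basis
  M <- matrix(c(2, 1, 0.5, -1), 2)
  expect_equal(manifold_projection_loss(Z, coherence_specs(manifold_basis = B)),
               manifold_projection_loss(Z, coherence_specs(
                 manifold_basis = B %*% M)),
               tolerance = 1e-9)
  expect_error(manifold_projection_loss(Z, coherence_specs(
    manifold_basis = cbind(B[, 1], 2 * B[, 1]))), "rank")
})

test_that("coherence losses stay nonnegative over random configurations", {
  set.seed(55)
  grid <- seq(0, 1, length.out = 21)
  for (i in 1:1000) {
    Z <- matrix(rnorm(42), 21, 2)
    head <- list(u = rnorm(2), c = rnorm(1))
    specs <- coherence_specs(
      reference_curves = list(a = reference_curve(c(0, 1), rnorm(2))),
      biomarker_decoder = function(r) r[, 1],
      templates = list(k = reference_curve(c(0, 1), rnorm(2))),
      alignment_map = matrix(rnorm(4), 2),
      treatment_shift = treatment_shift_model(rnorm(1), rnorm(2),
                                              stats::runif(1, 0.3, 2)),
      manifold_basis = matrix(rnorm(2), 2, 1))
    expect_gte(biomarker_alignment_loss(list(a = Z), specs, grid), 0)
    expect_gte(template_alignment_loss(Z, "k", specs, head, grid), 0)
    expect_gte(modality_consistency_loss(rnorm(2), rnorm(2), specs), 0)
    ev <- list(onset_time = stats::runif(1, 0, 0.6),
               post_outcomes = data.frame(time = c(0.7, 1),
                                          value = rnorm(2)))
    expect_gte(counterfactual_loss(Z, ev, specs, head, grid), 0)
    expect_gte(manifold_projection_loss(Z, specs), 0)
    expect_gte(sync_regularizer(Z[1:3, ],
                                {k3 <- abs(matrix(rnorm(9), 3))
                                 (k3 + t(k3)) / 2}), 0)
    expect_gte(anatomical_projection_penalty(
      Z[1:2, ], rnorm(3),
      list(A = list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)))), 0)
    expect_gte(cognitive_direction_penalty(
      Z[1:4, ], head,
      function_dynamics(function(z, t, psi)
        matrix(rnorm(length(z)), nrow(z)), 2L)), 0)
  }
})
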