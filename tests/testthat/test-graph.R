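# Graph-attention propagation and the spatial regularizers.

test_that("cosine similarity handles identity, antipodes and known values", {
  a <- c(3, -1, 2)
  expect_equal(cosine_similarity(a, a), 1, tolerance = 1e-9)
  expect_equal(cosine_similarity(a, -a), -1, tolerance = 1e-9)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.70711,
               tolerance = 1e-5)
  expect_lt(abs(cosine_similarity(c(0, 0), c(1, 1))), 1e-6)
})

test_that("attention weights normalize over in-neighborhoods", {
  # 4 regions all feeding region D, identical embeddings -> uniform weights
  g <- region_graph(c("A", "B", "C", "D"),
                    data.frame(src = c("A", "B", "C"), dst = "D",
                               weight = 1),
                    kappa = matrix(0, 4, 4))
  st <- matrix(1, 4, 3)
  al <- attention_coefficients(st, g)
  expect_equal(unname(al$D), rep(1 / 3, 3))
  expect_length(al$A, 0L)   # isolated: no in-neighbors

  # single neighbor -> weight 1
  g1 <- toy_graph()
  st1 <- matrix(rnorm(6), 2, 3)
  al1 <- attention_coefficients(st1, g1)
  expect_equal(unname(al1$A), 1)

  # sims {1, 0} to the target -> (e/(e+1), 1/(e+1))
  g2 <- region_graph(c("U1", "U2", "V"),
                     data.frame(src = c("U1", "U2"), dst = "V", weight = 1),
                     kappa = matrix(0, 3, 3))
  st2 <- rbind(c(1, 0), c(0, 1), c(1, 0))  # sim(U1,V)=1, sim(U2,V)=0
  al2 <- attention_coefficients(st2, g2)
  expect_equal(unname(al2$V), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-5)
})

test_that("attention columns sum to one for every non-isolated node", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    g <- make_region_graph(n, seed = rep)
    st <- matrix(rnorm(n * 4), n)
    al <- attention_coefficients(st, g)
    sums <- vapply(al, sum, numeric(1))
    expect_true(all(abs(sums[lengths(al) > 0] - 1) < 1e-8))
  }
})

test_that("message passing matches a hand-computed toy and handles isolation", {
  prm <- list(W = matrix(0, 2, 2), b = c(0, 0), activation = "tanh")
  g <- toy_graph()
  st <- matrix(rnorm(4), 2)
  expect_equal(propagate_regions(st, g, prm), matrix(0, 2, 2),
               ignore_attr = TRUE)

  # single in-neighbor, identity weights: r_v' = r_u
  prm_id <- list(W = diag(2), b = c(0, 0), activation = "identity")
  out <- propagate_regions(st, g, prm_id)
  expect_equal(out[1, ], st[2, ])  # A receives from B
  expect_equal(out[2, ], st[1, ])

  # 3-node toy with explicit numbers, checked against direct computation
  g3 <- region_graph(c("A", "B", "C"),
                     data.frame(src = c("A", "B"), dst = c("C", "C"),
                                weight = 1),
                     kappa = matrix(0, 3, 3))
  st3 <- rbind(c(0.2, -0.1), c(0.4, 0.3), c(-0.5, 0.1))
  W <- matrix(c(0.5, 0.1, -0.2, 0.3), 2)
  b <- c(0.05, -0.02)
  prm3 <- list(W = W, b = b, activation = "tanh")
  out3 <- propagate_regions(st3, g3, prm3)
  sA <- cosine_similarity(st3[1, ], st3[3, ])
  sB <- cosine_similarity(st3[2, ], st3[3, ])
  al <- exp(c(sA, sB)) / sum(exp(c(sA, sB)))
  agg <- al[1] * st3[1, ] + al[2] * st3[2, ]
  expect_equal(out3[3, ], tanh(as.vector(W %*% agg) + b), tolerance = 1e-6)
  # isolated nodes fall back to the bias-only update
  expect_equal(out3[1, ], tanh(b), tolerance = 1e-12)
})

test_that("propagation commutes with region relabeling", {
  set.seed(21)
  g <- make_region_graph(5, seed = 3)
  st <- matrix(rnorm(15), 5)
  prm <- list(W = matrix(rnorm(9), 3) * 0.3, b = rnorm(3) * 0.1,
              activation = "tanh")
  out <- propagate_regions(st, g, prm)
  perm <- sample(5)
  ids_p <- g$region_ids[perm]
  g_p <- region_graph(ids_p, g$edges, g$kappa[perm, perm])
  out_p <- propagate_regions(st[perm, ], g_p, prm)
  expect_equal(out_p, out[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sync regularizer: zero case, hand value, linearity, translation", {
  st <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(sync_regularizer(st, matrix(1, 3, 3)), 0)
  st2 <- rbind(c(0, 0), c(1, 1))
  expect_equal(sync_regularizer(st2, matrix(1, 2, 2)), 4)   # 2 ordered pairs
  k2 <- matrix(c(0, 0.7, 0.7, 0), 2)
  expect_equal(sync_regularizer(st2, 2 * k2),
               2 * sync_regularizer(st2, k2), tolerance = 1e-12)
  shift <- matrix(rnorm(2), 2, 2, byrow = TRUE)
  st3 <- matrix(rnorm(8), 4)
  k4 <- abs(matrix(rnorm(16), 4)); k4 <- (k4 + t(k4)) / 2
  expect_equal(sync_regularizer(st3 + matrix(c(3, -2), 4, 2, byrow = TRUE), k4),
               sync_regularizer(st3, k4), tolerance = 1e-9)
})

test_that("anatomical projection penalty: zero case, hand value, permutation", {
  A <- list(diag(2), matrix(c(0, 1, 1, 0), 2))
  z <- c(0.4, -0.6)
  st <- rbind(as.vector(A[[1]] %*% z), as.vector(A[[2]] %*% z))
  expect_equal(anatomical_projection_penalty(st, z, list(A = A)), 0)

  A1 <- list(diag(2))
  st1 <- matrix(c(0.4 + 3, -0.6 + 4), 1)
  expect_equal(anatomical_projection_penalty(st1, z, list(A = A1)), 25)

  set.seed(5)
  A3 <- lapply(1:3, function(i) matrix(rnorm(4), 2))
  st3 <- matrix(rnorm(6), 3)
  v1 <- anatomical_projection_penalty(st3, z, list(A = A3))
  perm <- c(3, 1, 2)
  v2 <- anatomical_projection_penalty(st3[perm, ], z, list(A = A3[perm]))
  expect_equal(v1, v2, tolerance = 1e-12)
})
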