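# Synthetic-cohort generator: the mechanistic regional pathology ODE, cohort
# generation with ground truth, and treatment injection.

test_that("isolated region with unit clearance decays as exp(-t)", {
  g <- region_graph("A", data.frame(src = character(), dst = character(),
                                    weight = numeric()),
                    kappa = matrix(0, 1, 1))
  prm <- region_sim_params(decay_rates = 1)
  h <- simulate_regional_pathology(g, prm, initial_state = 1,
                                   time_grid = c(0, 1), step = 0.01)
  expect_equal(unname(h[2, 1]), exp(-1), tolerance = 1e-6)
})

test_that("zero clearance, no neighbors, no input gives a constant state", {
  g <- region_graph("A", data.frame(src = character(), dst = character(),
                                    weight = numeric()),
                    kappa = matrix(0, 1, 1))
  prm <- region_sim_params(decay_rates = 0)
  h <- simulate_regional_pathology(g, prm, 0.7, seq(0, 2, 0.5), step = 0.05)
  expect_equal(as.vector(h[, 1]), rep(0.7, 5), tolerance = 1e-12)
})

test_that("two-region chain matches an independent stiff-solver oracle", {
  skip_if_not_installed("deSolve")
  g <- region_graph(c("A", "B"),
                    data.frame(src = "A", dst = "B", weight = 0.8),
                    kappa = matrix(0, 2, 2))
  lam <- c(0.5, 1.2)
  beta <- c(0.3, 0)
  xfun <- function(t) c(sin(t), 0)
  prm <- region_sim_params(decay_rates = lam, input_gains = beta,
                           input_signal = xfun, nonlinearity = "tanh")
  grid <- seq(0, 3, 0.5)
  h <- simulate_regional_pathology(g, prm, c(1, 0), grid, step = 0.01)
  A <- progflow:::graph_adjacency(g)
  oracle <- deSolve::lsoda(
    y = c(1, 0), times = grid,
    func = function(t, y, p)
      list(-lam * y + as.vector(t(A) %*% tanh(y)) + beta * xfun(t)),
    rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(h), unname(oracle[, 2:3]), tolerance = 1e-5)
})

test_that("blow-up is reported with the time of failure", {
  g <- region_graph("A", data.frame(src = character(), dst = character(),
                                    weight = numeric()),
                    kappa = matrix(0, 1, 1))
  prm <- region_sim_params(decay_rates = 1e-12, input_gains = 1,
                           input_signal = function(t) exp(200 * t))
  expect_error(
    simulate_regional_pathology(g, prm, 1, c(0, 10), step = 0.5),
    "non-finite")
})

test_that("generation is an exact function of seed and config", {
  cfg <- default_sim_config(n_subjects = 12L)
  g1 <- generate_cohort(cfg, seed = 42)
  g2 <- generate_cohort(cfg, seed = 42)
  d1 <- tempfile(); d2 <- tempfile()
  save_cohort(g1$cohort, d1)
  save_cohort(g2$cohort, d2)
  for (f in c("baseline.csv", "visits.csv", "graph.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  g3 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(g1$cohort$visits, g3$cohort$visits))
})

test_that("noiseless stages are exactly reproducible from the ground truth", {
  cfg <- default_sim_config(n_subjects = 20L,
                            noise = list(cognitive = 0, biomarker = 0,
                                         modality = 0))
  gen <- generate_cohort(cfg, seed = 5)
  vt <- gen$truth$visit_truth
  stage_from_truth <- vapply(vt$severity_true, function(s)
    sum(s > gen$truth$thresholds), numeric(1))
  key_v <- paste(gen$cohort$visits$subject_id, gen$cohort$visits$time)
  key_t <- paste(vt$subject_id, vt$time)
  expect_equal(gen$cohort$visits$stage, stage_from_truth[match(key_v, key_t)])
  # and the noiseless cognitive score equals the recorded truth
  expect_equal(gen$cohort$visits$cognitive_score,
               vt$score_true[match(key_v, key_t)], tolerance = 1e-12)
})

test_that("stage sequences are nondecreasing under the monotone flow field", {
  gen <- small_gen()
  for (sid in unique(gen$cohort$visits$subject_id)) {
    st <- gen$cohort$visits$stage[gen$cohort$visits$subject_id == sid]
    st <- st[!is.na(st)]
    expect_false(is.unsorted(st), label = paste("stages of", sid))
  }
})

test_that("default cohort passes validation and injected noise has the right SD", {
  gen <- generate_cohort(default_sim_config(), seed = 42)
  expect_equal(nrow(validate_cohort(gen$cohort)), 0L)
  # empirical SD of cognitive noise over all visits (n large)
  vt <- gen$truth$visit_truth
  key_v <- paste(gen$cohort$visits$subject_id, gen$cohort$visits$time)
  key_t <- paste(vt$subject_id, vt$time)
  resid <- gen$cohort$visits$cognitive_score -
    vt$score_true[match(key_v, key_t)]
  expect_lt(abs(stats::sd(resid) / gen$truth$noise_spec$cognitive - 1), 0.05)
})

test_that("treatment injection shifts only post-onset outcomes, saturating", {
  gen <- small_gen()
  # zero effect: outcomes unchanged, treatment table populated
  ch0 <- inject_treatment_effect(gen$cohort, gen$truth, effect_size = 0,
                                 seed = 3)
  expect_equal(ch0$visits$cognitive_score, gen$cohort$visits$cognitive_score)
  expect_gt(nrow(ch0$treatments), 0L)
  # unit effect: shift = 1 - exp(-(t - t_a)), 0 at onset
  ch1 <- inject_treatment_effect(gen$cohort, gen$truth, effect_size = 1,
                                 seed = 3)
  shift <- ch1$visits$cognitive_score - gen$cohort$visits$cognitive_score
  for (i in seq_len(nrow(ch1$treatments))) {
    tr <- ch1$treatments[i, ]
    rows <- which(ch1$visits$subject_id == tr$subject_id)
    tt <- ch1$visits$time[rows]
    expected <- ifelse(tt >= tr$onset_time, 1 - exp(-(tt - tr$onset_time)), 0)
    expect_equal(shift[rows], expected, tolerance = 1e-12)
  }
  expect_equal(1 - exp(-1), 0.63212, tolerance = 1e-5)
})
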