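# Shared fixtures and aliases for internal functions under test.

# internal autodiff / model machinery
ad_leaf <- progflow:::ad_leaf
ad_value <- progflow:::ad_value
ad_backward <- progflow:::ad_backward
ad_grad <- progflow:::ad_grad
pf_forward <- progflow:::pf_forward
mlp_init <- progflow:::mlp_init
mlp_forward <- progflow:::mlp_forward
memory_step <- progflow:::memory_step
stage_metrics <- progflow:::stage_metrics
spearman_mse <- progflow:::spearman_mse
trapezoid_weights <- progflow:::trapezoid_weights
with_seed <- progflow:::.with_seed

# two-region toy graph with symmetric unit kernel
toy_graph <- function() {
  region_graph(c("A", "B"),
               data.frame(src = c("A", "B"), dst = c("B", "A"),
                          weight = c(1, 1)),
               kappa = matrix(c(0, 1, 1, 0), 2))
}

# write a small hand-built cohort to CSV files; returns the directory
write_toy_cohort <- function(dir = tempfile("cohort")) {
  dir.create(dir)
  baseline <- data.frame(
    subject_id = c("s1", "s2"),
    img_0 = c(0.1, -0.2), img_1 = c(1.0, 0.3),
    omics_0 = c(0.5, -0.5),
    demo_0 = c(0.0, 1.0)
  )
  visits <- data.frame(
    subject_id = c("s1", "s1", "s2"),
    time = c(0, 1.5, 0),
    cognitive_score = c(29, 27.5, NA),
    stage = c(0L, 1L, NA),
    bio_0 = c(0.1, 0.6, NA)
  )
  treatments <- data.frame(subject_id = "s1", treatment_code = "tx1",
                           onset_time = 1.0)
  utils::write.csv(baseline, file.path(dir, "baseline.csv"), row.names = FALSE)
  utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(treatments, file.path(dir, "treatments.csv"),
                   row.names = FALSE)
  write_region_graph(toy_graph(), file.path(dir, "graph.json"))
  dir
}

# small synthetic cohort shared across model tests (cached per session)
small_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(default_sim_config(n_subjects = 24L), seed = 7)
    cache
  }
})

small_model_config <- function(...) {
  default_model_config(
    dynamics = list(hidden_widths = 8L, grid_points = 11L),
    optim = list(lr = 1e-2, epochs = 3L, batch_size = 8L),
    ...
  )
}
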