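# Longitudinal multimodal cohort container and file I/O.
#
# A cohort holds one baseline row per subject (standardized imaging, omics and
# demographic feature blocks), a visit table (time in years from the subject's
# baseline visit, cognitive score, optional ordinal stage in {0..L}, optional
# biomarker vector), an optional treatment-event table, and a brain-region
# graph. Missing optional fields stay missing (NA); nothing is imputed here.

#' Construct a region graph
#'
#' @param region_ids Character vector of region identifiers.
#' @param edges Data frame with columns `src`, `dst`, `weight`: directed
#'   weighted edges (no self loops). An undirected anatomical graph should be
#'   supplied with both directions. Neighborhoods `N(v)` are in-neighbors.
#' @param kappa Symmetric nonnegative compatibility kernel, one row/column per
#'   region, weighting region pairs in the synchronization penalty.
#' @return An object of class `pf_region_graph`.
#' @export
region_graph <- function(region_ids, edges, kappa = NULL) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  stopifnot(n >= 1L, !anyDuplicated(region_ids))
  edges <- as.data.frame(edges)
  stopifnot(all(c("src", "dst", "weight") %in% names(edges)))
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  if (!all(edges$src %in% region_ids) || !all(edges$dst %in% region_ids))
    stop("edge endpoints must be region ids")
  if (any(edges$src == edges$dst))
    stop("self-loops are not allowed in the region graph")
  if (is.null(kappa)) kappa <- matrix(0, n, n)
  kappa <- as.matrix(kappa)
  if (!all(dim(kappa) == c(n, n)))
    stop("kappa must be ", n, " x ", n)
  structure(
    list(region_ids = region_ids, edges = edges, kappa = kappa),
    class = "pf_region_graph"
  )
}

# In-neighbor index list: for each region v, integer indices of u with edge u->v.
graph_in_neighbors <- function(graph) {
  ids <- graph$region_ids
  si <- match(graph$edges$src, ids)
  di <- match(graph$edges$dst, ids)
  lapply(seq_along(ids), function(v) si[di == v])
}

# Dense adjacency with alpha-prior weights: A[u, v] = weight of edge u -> v.
graph_adjacency <- function(graph) {
  ids <- graph$region_ids
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(graph$edges$src, ids), match(graph$edges$dst, ids))] <-
    graph$edges$weight
  A
}

#' Read a region graph from JSON
#'
#' Expects keys `region_ids`, `edges` (list of `[src, dst, weight]` triples or
#' an object array) and `kappa` (matrix).
#' @param path Path to a graph JSON file.
#' @return A [region_graph()] object.
#' @export
read_region_graph <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  edges <- g$edges
  if (is.matrix(edges)) {
    edges <- data.frame(src = edges[, 1L], dst = edges[, 2L],
                        weight = as.numeric(edges[, 3L]))
  }
  region_graph(g$region_ids, edges, g$kappa)
}

#' Write a region graph to JSON
#' @param graph A [region_graph()] object.
#' @param path Output path.
#' @export
write_region_graph <- function(graph, path) {
  jsonlite::write_json(
    list(region_ids = graph$region_ids,
         edges = graph$edges,
         kappa = graph$kappa),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

.block_cols <- function(df, prefix) {
  cols <- grep(paste0("^", prefix, "_[0-9]+$"), names(df), value = TRUE)
  idx <- as.integer(sub(paste0(prefix, "_"), "", cols))
  cols[order(idx)]
}

#' Load a longitudinal cohort from CSV/JSON files
#'
#' @param baseline_path CSV with columns `subject_id`,
#'   `img_0..img_{p-1}`, `omics_0..omics_{q-1}`, `demo_0..demo_{r-1}`.
#' @param visits_path CSV with columns `subject_id`, `time` (years from the
#'   subject's baseline visit), `cognitive_score`, `stage`,
#'   `bio_0..bio_{m-1}`; empty cells are missing values.
#' @param treatments_path Optional CSV with columns `subject_id`,
#'   `treatment_code`, `onset_time`.
#' @param graph_path Optional region-graph JSON (see [read_region_graph()]).
#' @param stage_count Number of ordinal stages `L + 1`; defaults to
#'   `max(stage) + 1` over observed labels.
#' @return A validated object of class `pf_cohort`.
#' @export
load_cohort <- function(baseline_path, visits_path, treatments_path = NULL,
                        graph_path = NULL, stage_count = NULL) {
  for (p in c(baseline_path, visits_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  baseline <- utils::read.csv(baseline_path, check.names = FALSE)
  visits <- utils::read.csv(visits_path, check.names = FALSE)
  treatments <- if (!is.null(treatments_path)) {
    if (!file.exists(treatments_path))
      stop("file not found: ", treatments_path)
    utils::read.csv(treatments_path, check.names = FALSE)
  } else {
    data.frame(subject_id = character(), treatment_code = character(),
               onset_time = numeric())
  }
  graph <- if (!is.null(graph_path)) read_region_graph(graph_path)

  .need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("parse error in ", file, ": missing column(s) ",
           paste(miss, collapse = ", "))
  }
  .need(baseline, "subject_id", baseline_path)
  .need(visits, c("subject_id", "time"), visits_path)
  if (nrow(treatments))
    .need(treatments, c("subject_id", "treatment_code", "onset_time"),
          treatments_path)
  if (!"cognitive_score" %in% names(visits)) visits$cognitive_score <- NA_real_
  if (!"stage" %in% names(visits)) visits$stage <- NA_integer_

  baseline$subject_id <- as.character(baseline$subject_id)
  visits$subject_id <- as.character(visits$subject_id)
  if (anyDuplicated(baseline$subject_id)) {
    row <- which(duplicated(baseline$subject_id))[1L]
    stop("parse error in ", baseline_path, ": duplicate subject_id at row ",
         row, ", column subject_id")
  }
  bad <- !visits$subject_id %in% baseline$subject_id
  if (any(bad))
    stop("parse error in ", visits_path, ": row ", which(bad)[1L],
         ", column subject_id: unknown subject '",
         visits$subject_id[which(bad)[1L]], "'")
  if (any(!is.finite(visits$time) | visits$time < 0)) {
    row <- which(!is.finite(visits$time) | visits$time < 0)[1L]
    stop("parse error in ", visits_path, ": row ", row,
         ", column time: times must be finite and >= 0")
  }
  dup <- duplicated(visits[, c("subject_id", "time")])
  if (any(dup)) {
    row <- which(dup)[1L]
    stop("parse error in ", visits_path, ": row ", row,
         ": duplicate (subject_id, time) pair")
  }

  if (is.null(stage_count)) {
    stage_count <- if (all(is.na(visits$stage))) 1L
                   else max(visits$stage, na.rm = TRUE) + 1L
  }
  stage_count <- as.integer(stage_count)
  bad_stage <- !is.na(visits$stage) &
    (visits$stage < 0 | visits$stage > stage_count - 1L |
       visits$stage != round(visits$stage))
  if (any(bad_stage)) {
    row <- which(bad_stage)[1L]
    stop("parse error in ", visits_path, ": row ", row,
         ", column stage: label ", visits$stage[row],
         " outside stage vocabulary {0..", stage_count - 1L, "}")
  }

  visits <- visits[order(visits$subject_id, visits$time), , drop = FALSE]
  rownames(visits) <- NULL
  if (nrow(treatments)) {
    treatments$subject_id <- as.character(treatments$subject_id)
    if (any(treatments$onset_time < 0))
      stop("parse error in ", treatments_path, ": onset_time must be >= 0")
  }

  cohort <- structure(
    list(
      baseline = baseline,
      visits = visits,
      treatments = treatments,
      graph = graph,
      stage_count = stage_count,
      time_horizon = max(visits$time),
      dims = list(
        img = .block_cols(baseline, "img"),
        omics = .block_cols(baseline, "omics"),
        demo = .block_cols(baseline, "demo"),
        bio = .block_cols(visits, "bio")
      )
    ),
    class = "pf_cohort"
  )
  rep <- validate_cohort(cohort)
  if (nrow(rep))
    stop("invalid cohort: ", rep$message[1L], " (subject ",
         rep$subject[1L], ", field ", rep$field[1L], ")")
  cohort
}

#' Save a cohort to a directory of CSV/JSON files
#'
#' Writes `baseline.csv`, `visits.csv`, `treatments.csv` and, when a region
#' graph is attached, `graph.json`; [load_cohort()] on the directory
#' round-trips the cohort field-for-field.
#' @param cohort A `pf_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$treatments, file.path(dir, "treatments.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$graph))
    write_region_graph(cohort$graph, file.path(dir, "graph.json"))
  invisible(dir)
}

#' Load a cohort previously written by [save_cohort()]
#' @param dir Directory containing `baseline.csv`, `visits.csv`, and
#'   optionally `treatments.csv` / `graph.json`.
#' @param stage_count Optional stage vocabulary size `L + 1`.
#' @return A `pf_cohort`.
#' @export
load_cohort_dir <- function(dir, stage_count = NULL) {
  tp <- file.path(dir, "treatments.csv")
  gp <- file.path(dir, "graph.json")
  load_cohort(file.path(dir, "baseline.csv"), file.path(dir, "visits.csv"),
              treatments_path = if (file.exists(tp)) tp,
              graph_path = if (file.exists(gp)) gp,
              stage_count = stage_count)
}

#' Validate cohort invariants
#'
#' Checks every structural invariant (finite feature blocks, sorted strictly
#' increasing visit times, stage vocabulary, nonnegative times, symmetric
#' nonnegative compatibility kernel, post-outcome times after onset) and
#' reports violations instead of raising.
#'
#' @param cohort A `pf_cohort`.
#' @return Data frame with columns `subject`, `field`, `message`; zero rows
#'   iff the cohort satisfies all invariants.
#' @export
validate_cohort <- function(cohort) {
  bad <- list()
  note <- function(subject, field, message) {
    bad[[length(bad) + 1L]] <<-
      data.frame(subject = subject, field = field, message = message)
  }
  feat_cols <- unlist(cohort$dims[c("img", "omics", "demo")], use.names = FALSE)
  if (length(feat_cols)) {
    fin <- vapply(seq_len(nrow(cohort$baseline)), function(i)
      all(is.finite(as.numeric(cohort$baseline[i, feat_cols]))), logical(1L))
    for (i in which(!fin))
      note(cohort$baseline$subject_id[i], "baseline",
           "non-finite feature value")
  }
  for (sid in unique(cohort$visits$subject_id)) {
    tt <- cohort$visits$time[cohort$visits$subject_id == sid]
    if (any(tt < 0)) note(sid, "time", "negative visit time")
    if (is.unsorted(tt, strictly = TRUE))
      note(sid, "time", "visit times not strictly increasing")
  }
  st <- cohort$visits$stage
  bad_stage <- !is.na(st) & (st < 0 | st > cohort$stage_count - 1L)
  for (i in which(bad_stage))
    note(cohort$visits$subject_id[i], "stage", "stage outside vocabulary")
  if (!is.null(cohort$graph)) {
    k <- cohort$graph$kappa
    if (!isTRUE(all.equal(k, t(k), tolerance = 1e-12)))
      note("-", "kappa", "compatibility kernel not symmetric")
    if (any(k < 0))
      note("-", "kappa", "compatibility kernel has negative entries")
    if (any(cohort$graph$edges$src == cohort$graph$edges$dst))
      note("-", "edges", "self-loop in region graph")
  }
  if (nrow(cohort$treatments)) {
    for (i in seq_len(nrow(cohort$treatments))) {
      tr <- cohort$treatments[i, ]
      vt <- cohort$visits[cohort$visits$subject_id == tr$subject_id, ]
      if (!is.na(tr$onset_time) && tr$onset_time < 0)
        note(tr$subject_id, "onset_time", "negative onset time")
    }
  }
  if (!length(bad))
    return(data.frame(subject = character(), field = character(),
                      message = character()))
  do.call(rbind, bad)
}

.subset_cohort <- function(cohort, ids) {
  out <- cohort
  out$baseline <- cohort$baseline[cohort$baseline$subject_id %in% ids, ,
                                  drop = FALSE]
  out$visits <- cohort$visits[cohort$visits$subject_id %in% ids, ,
                              drop = FALSE]
  out$treatments <- cohort$treatments[
    cohort$treatments$subject_id %in% ids, , drop = FALSE]
  rownames(out$baseline) <- rownames(out$visits) <- NULL
  out
}

#' Split a cohort into train/validation/test at the subject level
#'
#' Subjects (never individual visits) are assigned to exactly one split, so no
#' subject's visit history straddles the train/test boundary.
#'
#' @param cohort A `pf_cohort`.
#' @param fractions Length-3 positive numeric summing to 1.
#' @param seed Integer seed; the same seed always yields the same membership.
#' @return Named list of `pf_cohort`s: `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 positive numbers summing to 1")
  ids <- sort(unique(cohort$baseline$subject_id))
  n <- length(ids)
  counts <- floor(n * fractions)
  # largest-remainder rounding so the counts sum to n
  rem <- n * fractions - counts
  short <- n - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    sample(ids)
  })
  cut1 <- counts[1L]
  cut2 <- counts[1L] + counts[2L]
  list(
    train = .subset_cohort(cohort, perm[seq_len(cut1)]),
    validation = .subset_cohort(cohort, perm[seq(cut1 + 1L, length.out = counts[2L])]),
    test = .subset_cohort(cohort, perm[seq(cut2 + 1L, length.out = counts[3L])])
  )
}

#' @export
print.pf_cohort <- function(x, ...) {
  cat("pf_cohort:", nrow(x$baseline), "subjects,", nrow(x$visits), "visits,",
      x$stage_count, "stages, horizon", format(x$time_horizon), "years\n")
  cat("  feature dims: img", length(x$dims$img),
      "| omics", length(x$dims$omics),
      "| demo", length(x$dims$demo),
      "| biomarkers", length(x$dims$bio), "\n")
  if (!is.null(x$graph))
    cat("  region graph:", length(x$graph$region_ids), "regions,",
        nrow(x$graph$edges), "edges\n")
  invisible(x)
}

# Matrix of a baseline feature block in subject order; subjects = row ids.
cohort_block <- function(cohort, block) {
  cols <- cohort$dims[[block]]
  m <- as.matrix(cohort$baseline[, cols, drop = FALSE])
  rownames(m) <- cohort$baseline$subject_id
  m
}
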