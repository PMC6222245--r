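# Fixtures and independent oracles shared across the suite.
# Everything here is generated in code; no binary fixtures.

# ---- tiny volumes ---------------------------------------------------------

# Uniform-label cube: `n` voxels a side, voxel size `vx` mm, centred at the
# origin.
uniform_volume <- function(label = 5L, n = 20L, vx = 2) {
  v2w <- diag(c(vx, vx, vx, 1))
  v2w[1:3, 4] <- -(n - 1) * vx / 2
  label_volume(array(label, dim = c(n, n, n)), v2w,
               data.frame(label_id = label, label_name = "zoneA"),
               space = "average")
}

# Two-slab volume: label `a` for z > 0, `b` for z <= 0 (by voxel centre).
slab_volume <- function(a = 1L, b = 2L, n = 20L, vx = 2,
                        names = c("zoneA", "zoneB")) {
  v2w <- diag(c(vx, vx, vx, 1))
  v2w[1:3, 4] <- -(n - 1) * vx / 2
  zs <- (seq_len(n) - 1) * vx - (n - 1) * vx / 2
  arr <- array(0L, dim = c(n, n, n))
  for (k in seq_len(n)) arr[, , k] <- if (zs[k] > 0) a else b
  label_volume(arr, v2w,
               data.frame(label_id = c(a, b), label_name = names),
               space = "average")
}

# A zone config where every label is its own zone, all admissible.
identity_zone_config <- function(vol, ...) {
  zone_config(entry_zones = vol$label_table$label_name,
              target_zones = vol$label_table$label_name,
              merge_map = stats::setNames(vol$label_table$label_name,
                                          as.character(vol$label_table$label_id)),
              ...)
}

# Hand-rolled label sequence (for descriptor unit tests that bypass sampling).
label_seq <- function(labels, step = 1) {
  data.frame(arc_mm = seq_along(labels) - 1, label = as.integer(labels))
}

# ---- pattern fixtures -----------------------------------------------------

# Wrap a 6-column matrix of (entry, target) coordinates into a pattern; plan
# ids default to one plan per member.
make_pattern <- function(x, plan_ids = sprintf("p%03d", seq_len(nrow(x)))) {
  m <- data.frame(patient_id = plan_ids, plan_id = plan_ids,
                  electrode_id = sprintf("e%03d", seq_len(nrow(x))),
                  ep_x = x[, 1], ep_y = x[, 2], ep_z = x[, 3],
                  tp_x = x[, 4], tp_y = x[, 5], tp_z = x[, 6],
                  space = "average",
                  entry_zone = "A", target_zone = "B",
                  outlier = FALSE, stringsAsFactors = FALSE)
  list(entry_zone = "A", target_zone = "B", members = m)
}

# Random fuzzed pattern: a mixture of 1..4 blobs in 6-D.
random_pattern <- function() {
  n <- sample(2:30, 1)
  j <- sample(1:4, 1)
  centres <- matrix(stats::runif(6 * j, -50, 50), j, 6)
  assign <- sample(j, n, replace = TRUE)
  x <- centres[assign, , drop = FALSE] +
    matrix(stats::rnorm(6 * n, 0, stats::runif(1, 0.5, 8)), n, 6)
  x
}

# Independent oracle for the iterative k-means: exhaustive sweep over k,
# same seeding policy, returning the largest significant k (floor 1).
sweep_oracle_k <- function(x, U_init, min_frac, seed) {
  n <- nrow(x)
  kmax <- min(U_init, nrow(unique(x)))
  best <- 1L
  for (k in seq_len(kmax)) {
    km <- seegplan:::kmeans_seeded(x, k, seed)
    if (all(tabulate(km$cluster, nbins = k) >= min_frac * n)) best <- k
  }
  best
}

# ---- assignment oracle ----------------------------------------------------

# Brute-force minimum assignment cost over all permutations (n <= m).
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tot < best) best <- tot
  }
  best
}

# ---- model fixture --------------------------------------------------------

# Minimal hand-built model bundle: 2 mean trajectories, optional strategy.
tiny_model <- function(with_strategy = TRUE) {
  mts <- list(
    list(entry_zone = "A", target_zone = "B", index_u = 1L,
         mean_entry = c(0, 0, 30), mean_target = c(0, 0, -20),
         sigma_entry = 2.5, sigma_target = 3.25, n_members = 4L,
         final_k = 1L,
         member_refs = data.frame(plan_id = c("p1", "p1", "p2", "p3"),
                                  electrode_id = c("e1", "e2", "e1", "e1"),
                                  stringsAsFactors = FALSE)),
    list(entry_zone = "C", target_zone = "D", index_u = 1L,
         mean_entry = c(10, 5, 30), mean_target = c(12, 5, -18),
         sigma_entry = 1.75, sigma_target = 2, n_members = 2L,
         final_k = 1L,
         member_refs = data.frame(plan_id = c("p1", "p2"),
                                  electrode_id = c("e3", "e2"),
                                  stringsAsFactors = FALSE)))
  strategies <- if (with_strategy) {
    list(list(strategy_id = "S1", name = NULL, bits = c(TRUE, TRUE),
              member_plan_ids = c("p1", "p2"), degenerate = FALSE))
  } else list()
  validate_model(structure(list(
    schema_version = 1L,
    mean_trajectories = mts,
    plan_ids = c("p1", "p2", "p3"),
    strategies = strategies,
    zone_config = zone_config(entry_zones = c("A", "C"),
                              target_zones = c("B", "D"),
                              merge_map = c(`1` = "A", `2` = "B",
                                            `3` = "C", `4` = "D"),
                              ignore_labels = 0L),
    provenance = list(n_patients = 3L, n_plans = 3L, n_trajectories = 6L,
                      n_outliers = 0L, n_patterns = 2L, step = 1,
                      min_frac = 0.05, seed = 1L)
  ), class = "seeg_model"))
}

# Random invertible affine for round-trip properties.
random_affine <- function() {
  repeat {
    L <- matrix(stats::rnorm(9), 3, 3)
    if (abs(det(L)) > 0.05) break
  }
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4] <- stats::rnorm(3, 0, 20)
  affine_transform(A)
}

# Write a trajectory CSV from raw fields (for parser tests).
write_plan_csv <- function(path, rows) {
  header <- "patient_id,plan_id,electrode_id,ep_x,ep_y,ep_z,tp_x,tp_y,tp_z"
  writeLines(c(header, rows), path)
  path
}
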