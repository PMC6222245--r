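#' Transform a plan table between subject and average space
#'
#' Maps every entry and target point through the subject-to-average affine
#' and flips the space tag. `to_subject_space()` applies the inverse.
#'
#' @param plans Trajectory data frame in subject space.
#' @param xfm A [affine_transform()] mapping subject to average space.
#' @return The transformed table, tagged `space = "average"`.
#' @export
to_average_space <- function(plans, xfm) {
  if (nrow(plans) && any(plans$space != "subject")) {
    stop_contract("to_average_space expects a subject-space plan table")
  }
  transform_plans(plans, xfm, "average")
}

#' @rdname to_average_space
#' @export
to_subject_space <- function(plans, xfm) {
  if (nrow(plans) && any(plans$space != "average")) {
    stop_contract("to_subject_space expects an average-space plan table")
  }
  transform_plans(plans, invert_affine(xfm), "subject")
}

transform_plans <- function(plans, xfm, new_space) {
  xfm <- affine_transform(xfm)
  if (nrow(plans)) {
    plans[, c("ep_x", "ep_y", "ep_z")] <- apply_affine(xfm, entry_points(plans))
    plans[, c("tp_x", "tp_y", "tp_z")] <- apply_affine(xfm, target_points(plans))
  }
  plans$space <- rep(new_space, nrow(plans))
  plans
}

#' Group classified trajectories into exploratory patterns
#'
#' Partitions non-outlier, average-space trajectories by exact descriptor
#' equality. Each pattern pools, across all patients, the trajectories aimed
#' at the same (entry zone, target zone) pair.
#'
#' @param classified A classified, average-space trajectory table (see
#'   [classify_trajectories()]).
#' @return A list of patterns sorted by (entry_zone, target_zone); each is a
#'   list with `entry_zone`, `target_zone` and `members` (a trajectory data
#'   frame).
#' @export
group_patterns <- function(classified) {
  if (nrow(classified) && any(classified$space != "average")) {
    stop_contract("patterns must be built from average-space trajectories")
  }
  keep <- classified[!classified$outlier, , drop = FALSE]
  if (!nrow(keep)) return(list())
  key <- paste(keep$entry_zone, keep$target_zone, sep = "\r")
  split_idx <- split(seq_len(nrow(keep)), key)
  split_idx <- unname(split_idx[order(names(split_idx))])
  lapply(split_idx, function(idx) {
    m <- keep[idx, , drop = FALSE]
    rownames(m) <- NULL
    list(entry_zone = m$entry_zone[1], target_zone = m$target_zone[1],
         members = m)
  })
}

#' Maximum per-plan multiplicity of a pattern
#'
#' U is the largest number of same-descriptor trajectories any single plan
#' devotes to the pattern; it bounds the number of k-means groups, on the
#' assumption that large regions explored with several electrodes in one
#' plan need one mean trajectory per electrode.
#'
#' @param pattern A pattern from [group_patterns()].
#' @return Integer >= 1.
#' @export
compute_U <- function(pattern) {
  if (!nrow(pattern$members)) stop_contract("empty pattern")
  max(table(pattern$members$plan_id))
}

# Deterministic k-means used by both the iterative procedure and the
# exhaustive-sweep oracle in the tests: the RNG state depends only on
# (seed, k), never on the iteration history, so both paths see identical
# clusterings at every k. The k = 1 and k = #distinct cases have exact
# closed-form solutions (stats::kmeans additionally requires k < n).
kmeans_seeded <- function(x, k, seed, nstart = 10) {
  if (k == 1) {
    return(list(cluster = rep(1L, nrow(x)),
                centers = matrix(colMeans(x), 1)))
  }
  ux <- unique(x)
  if (k >= nrow(ux)) {
    key <- do.call(paste, c(as.data.frame(x), sep = "\r"))
    ukey <- do.call(paste, c(as.data.frame(ux), sep = "\r"))
    return(list(cluster = match(key, ukey), centers = ux))
  }
  with_seed(seed + k, stats::kmeans(x, centers = k, nstart = nstart,
                                    iter.max = 100))
}

#' Compress an exploratory pattern into mean trajectories
#'
#' Runs k-means on the joint 6-D (entry, target) coordinates of the
#' pattern's members, starting from `k = U` groups. A cluster is significant
#' only if it holds at least `min_frac` of the pattern's trajectories
#' (default 5 %, inclusive, no rounding); if any cluster fails, k is
#' decreased by one and k-means rerun, down to the k = 1 floor. Each final
#' cluster becomes one mean trajectory: centroid entry/target coordinates
#' plus scalar dispersions `sigma_entry` / `sigma_target`, the RMS Euclidean
#' distance of member points from the centroid (the radius used by the
#' 2-sigma mapping criterion).
#'
#' Clustering is joint over entry and target so that each cluster keeps its
#' entry–target pairing. `index_u` orders clusters by descending member
#' count, ties broken by entry-point lexicographic order, making the model
#' bundle reproducible.
#'
#' @param pattern A pattern from [group_patterns()].
#' @param U_init Starting number of clusters; defaults to [compute_U()].
#' @param min_frac Significance fraction (default 0.05).
#' @param seed Integer seed for the k-means restarts.
#' @return A list of mean trajectories; each has `entry_zone`, `target_zone`,
#'   `index_u`, `mean_entry`, `mean_target`, `sigma_entry`, `sigma_target`,
#'   `n_members`, `final_k`, and `member_refs` (data frame of
#'   `plan_id`, `electrode_id`).
#' @export
build_mean_trajectories <- function(pattern, U_init = compute_U(pattern),
                                    min_frac = 0.05, seed = 1L) {
  m <- pattern$members
  n <- nrow(m)
  if (n < 1 || U_init < 1) stop_contract("pattern size and U_init must be >= 1")
  x <- cbind(entry_points(m), target_points(m))
  n_distinct <- nrow(unique(x))
  k <- min(U_init, n_distinct)
  if (k < U_init) {
    warning("U_init = ", U_init, " exceeds the number of distinct points (",
            n_distinct, "); clamped", call. = FALSE)
  }
  repeat {
    km <- kmeans_seeded(x, k, seed)
    sizes <- tabulate(km$cluster, nbins = k)
    if (all(sizes >= min_frac * n) || k == 1) break
    k <- k - 1
  }
  order_mt <- mt_order(km, x)
  lapply(seq_along(order_mt), function(u) {
    cl <- order_mt[u]
    idx <- which(km$cluster == cl)
    ctr_e <- unname(km$centers[cl, 1:3])
    ctr_t <- unname(km$centers[cl, 4:6])
    de <- x[idx, 1:3, drop = FALSE] - matrix(ctr_e, length(idx), 3, byrow = TRUE)
    dt <- x[idx, 4:6, drop = FALSE] - matrix(ctr_t, length(idx), 3, byrow = TRUE)
    list(entry_zone = pattern$entry_zone,
         target_zone = pattern$target_zone,
         index_u = u,
         mean_entry = ctr_e,
         mean_target = ctr_t,
         sigma_entry = sqrt(mean(rowSums(de * de))),
         sigma_target = sqrt(mean(rowSums(dt * dt))),
         n_members = length(idx),
         final_k = k,
         member_refs = data.frame(plan_id = m$plan_id[idx],
                                  electrode_id = m$electrode_id[idx],
                                  stringsAsFactors = FALSE))
  })
}

# index_u assignment: descending cluster size, ties by lexicographic order of
# the entry centroid.
mt_order <- function(km, x) {
  k <- nrow(km$centers)
  sizes <- tabulate(km$cluster, nbins = k)
  ord <- order(-sizes, km$centers[, 1], km$centers[, 2], km$centers[, 3])
  ord
}
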