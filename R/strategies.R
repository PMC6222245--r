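#' Encode plans as binary presence vectors over the mean-trajectory list
#'
#' Each plan becomes a fixed-length boolean vector f with one position per
#' mean trajectory of the model, set when the plan contributed at least one
#' member trajectory to that mean trajectory (membership is taken from the
#' clustering assignment stored in the bundle, not re-derived by matching).
#'
#' @param bundle A `seeg_model` whose mean trajectories carry member
#'   references.
#' @return Logical matrix, one row per plan (rownames are plan ids, in
#'   `bundle$plan_ids` order), one column per mean trajectory.
#' @export
plans_to_vectors <- function(bundle) {
  bundle <- validate_model(bundle)
  pids <- bundle$plan_ids
  m <- length(bundle$mean_trajectories)
  bits <- matrix(FALSE, length(pids), m, dimnames = list(pids, NULL))
  for (y in seq_len(m)) {
    contributors <- unique(bundle$mean_trajectories[[y]]$member_refs$plan_id)
    bits[pids %in% contributors, y] <- TRUE
  }
  empty <- rownames(bits)[rowSums(bits) == 0]
  if (length(empty)) {
    warning("plan(s) with no non-outlier trajectory (all-false vector): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  bits
}

#' Jaccard distance between binary vectors
#'
#' 1 - |intersection| / |union| of the TRUE supports. Two all-false vectors
#' are at distance 0 by convention.
#'
#' @param f1,f2 Logical vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
jaccard_distance <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop_contract("jaccard_distance: vectors differ in length")
  }
  u <- sum(f1 | f2)
  if (u == 0) return(0)
  1 - sum(f1 & f2) / u
}

#' @rdname jaccard_distance
#' @param bits Logical matrix of plan vectors (plans in rows).
#' @return `jaccard_matrix()` returns a symmetric distance matrix.
#' @export
jaccard_matrix <- function(bits) {
  n <- nrow(bits)
  storage.mode(bits) <- "double"
  inter <- bits %*% t(bits)
  sizes <- rowSums(bits)
  uni <- outer(sizes, sizes, "+") - inter
  d <- ifelse(uni == 0, 0, 1 - inter / uni)
  diag(d) <- 0
  dimnames(d) <- list(rownames(bits), rownames(bits))
  d
}

#' Cluster plans hierarchically under the Jaccard distance
#'
#' Agglomerative clustering of the plan vectors with the given linkage
#' (average/UPGMA by default, the usual companion of Jaccard dissimilarity),
#' cut at a flat threshold, as a dendrogram cut balances group count against
#' group population. Groups are returned in order of decreasing size.
#'
#' @param bits Logical matrix of plan vectors with plan-id rownames.
#' @param cut_threshold Dendrogram cut height in Jaccard-distance units.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A list with `groups` (list of plan-id character vectors, largest
#'   first), `membership` (named integer vector) and `tree` (the hclust
#'   object, for dendrogram export).
#' @export
cluster_plans <- function(bits, cut_threshold, linkage = "average") {
  if (nrow(bits) < 2) stop_contract("need at least 2 plan vectors to cluster")
  d <- stats::as.dist(jaccard_matrix(bits))
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, h = cut_threshold)
  tab <- sort(table(raw), decreasing = TRUE)
  groups <- lapply(names(tab), function(g) names(raw)[raw == as.integer(g)])
  membership <- stats::setNames(match(as.character(raw), names(tab)),
                                names(raw))
  list(groups = groups, membership = membership, tree = tree)
}

#' Derive a planning strategy from a group of plan vectors
#'
#' A strategy keeps the mean trajectories supported by at least two plans of
#' the group, encoding the reusable core of that family of plans. A
#' singleton group can never reach the threshold and yields a degenerate
#' all-false strategy, which is kept (flagged) so the G-group partition is
#' preserved.
#'
#' @param group_bits Logical matrix of the group members' plan vectors.
#' @param strategy_id Identifier for the new strategy.
#' @param name Optional free-text name (e.g. surgeon-assigned).
#' @return A strategy: list with `strategy_id`, `bits`, `member_plan_ids`,
#'   `name`, `degenerate`.
#' @export
derive_strategy <- function(group_bits, strategy_id = "S1", name = NULL) {
  if (is.null(dim(group_bits))) group_bits <- matrix(group_bits, nrow = 1)
  if (!nrow(group_bits)) stop_contract("empty plan group")
  bits <- colSums(group_bits) >= 2
  degenerate <- !any(bits)
  if (degenerate) {
    message("strategy ", strategy_id,
            " is degenerate (no mean trajectory supported by >= 2 plans)")
  }
  list(strategy_id = strategy_id, name = name, bits = unname(bits),
       member_plan_ids = rownames(group_bits) %||% character(),
       degenerate = degenerate)
}

#' Add planning strategies to a model bundle
#'
#' Convenience pipeline: plan vectors, hierarchical clustering, one strategy
#' per group. Strategy ids are `S1`, `S2`, ... in decreasing group size.
#'
#' @inheritParams plans_to_vectors
#' @inheritParams cluster_plans
#' @return The bundle with its `strategies` section replaced.
#' @export
add_strategies <- function(bundle, cut_threshold = 0.7, linkage = "average") {
  bits <- plans_to_vectors(bundle)
  cl <- cluster_plans(bits, cut_threshold, linkage)
  bundle$strategies <- lapply(seq_along(cl$groups), function(g) {
    derive_strategy(bits[cl$groups[[g]], , drop = FALSE],
                    strategy_id = paste0("S", g))
  })
  bundle$provenance$cut_threshold <- cut_threshold
  bundle$provenance$linkage <- linkage
  validate_model(bundle)
}
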