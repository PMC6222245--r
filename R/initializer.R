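#' Initialise a plan for a new subject from a planning strategy
#'
#' Maps every mean trajectory selected by the strategy from the average
#' space into the subject's space through the inverse of the subject's
#' registration affine. The result is an initialised plan (IP): a starting
#' point for manual adjustment or downstream optimisation, not a finished
#' plan.
#'
#' @param bundle A `seeg_model` with strategies.
#' @param strategy_id Identifier of the strategy to map.
#' @param subject_affine Subject-to-average [affine_transform()] of the new
#'   subject.
#' @param patient_id Identifier for the new subject.
#' @return Subject-space trajectory table with an extra `mt_index` column;
#'   electrode ids are `mT<y>`.
#' @export
init_plan <- function(bundle, strategy_id, subject_affine,
                      patient_id = "new-subject") {
  bundle <- validate_model(bundle)
  ids <- vapply(bundle$strategies, `[[`, "", "strategy_id")
  pos <- match(strategy_id, ids)
  if (is.na(pos)) {
    stop_seeg(paste0("unknown strategy '", strategy_id, "'; available: ",
                     paste(ids, collapse = ", ")), "seeg_lookup_error")
  }
  s <- bundle$strategies[[pos]]
  ys <- which(s$bits)
  if (!length(ys)) {
    warning("strategy ", strategy_id, " selects no mean trajectories; ",
            "empty initialised plan", call. = FALSE)
  }
  inv <- invert_affine(subject_affine)
  rows <- lapply(ys, function(y) {
    mt <- bundle$mean_trajectories[[y]]
    ep <- apply_affine(inv, mt$mean_entry)
    tp <- apply_affine(inv, mt$mean_target)
    data.frame(patient_id = patient_id, plan_id = patient_id,
               electrode_id = paste0("mT", y),
               ep_x = ep[1], ep_y = ep[2], ep_z = ep[3],
               tp_x = tp[1], tp_y = tp[2], tp_z = tp[3],
               space = "subject", mt_index = y, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), plan_id = character(),
               electrode_id = character(),
               ep_x = numeric(), ep_y = numeric(), ep_z = numeric(),
               tp_x = numeric(), tp_y = numeric(), tp_z = numeric(),
               space = character(), mt_index = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Minimum-cost linear assignment
#'
#' Hungarian algorithm (shortest augmenting path with potentials, O(n^3)).
#' Solves rectangular problems by assigning every row when
#' `nrow(cost) <= ncol(cost)`.
#'
#' @param cost Numeric cost matrix with `nrow(cost) <= ncol(cost)`; all
#'   entries finite.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimising the total cost.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer())
  if (n > m) stop_contract("solve_assignment needs nrow <= ncol")
  if (any(!is.finite(cost))) stop_contract("assignment costs must be finite")
  INF <- .Machine$double.xmax / 4
  # Index offset: column j lives at slot j + 1; slot 1 is the virtual column 0.
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j + 1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF; j1 <- 0L
      free <- which(!used[-1])  # candidate columns 1..m
      if (length(free)) {
        cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
        upd <- cur < minv[free + 1]
        minv[free[upd] + 1] <- cur[upd]
        way[free[upd] + 1] <- j0
        best <- which.min(minv[free + 1])
        delta <- minv[free[best] + 1]
        j1 <- free[best]
      }
      su <- which(used)
      u[p[su] + 1] <- u[p[su] + 1] + delta
      v[su] <- v[su] - delta
      minv[-su] <- minv[-su] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Pair initialised and manual trajectories
#'
#' Finds the one-to-one correspondence between the mapped mean trajectories
#' (IP) and the surgeon's manual plan (MP) minimising the total entry-point
#' plus target-point distance, solved as a linear assignment. When manual
#' descriptors are supplied, pairs with differing descriptors are forbidden;
#' a forbidden-only row/column ends up unpaired. Surplus trajectories on
#' either side are listed as unpaired.
#'
#' @param ip Initialised plan from [init_plan()] (subject space).
#' @param manual Manual plan table (subject space).
#' @param bundle The `seeg_model` that produced `ip`.
#' @param manual_descriptors Optional data frame aligned with `manual` rows,
#'   columns `entry_zone`, `target_zone` (NA = not computable, pairing
#'   unconstrained for that trajectory).
#' @return A pairing: data frame with `mt_index`, `electrode_id` (manual),
#'   `d_ep`, `d_tp` (mm), plus attributes `unpaired_initialized` and
#'   `unpaired_manual`.
#' @export
match_trajectories <- function(ip, manual, bundle, manual_descriptors = NULL) {
  if (nrow(ip) && any(ip$space != "subject")) {
    stop_contract("initialised plan must be in subject space")
  }
  if (nrow(manual) && any(manual$space != "subject")) {
    stop_contract("manual plan must be in subject space")
  }
  n_ip <- nrow(ip); n_mp <- nrow(manual)
  if (n_ip == 0 || n_mp == 0) {
    out <- data.frame(mt_index = integer(), electrode_id = character(),
                      d_ep = numeric(), d_tp = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "unpaired_initialized") <- ip$electrode_id
    attr(out, "unpaired_manual") <- manual$electrode_id
    return(out)
  }
  dep <- cross_dist(entry_points(ip), entry_points(manual))
  dtp <- cross_dist(target_points(ip), target_points(manual))
  cost <- dep + dtp
  BIG <- 1e9
  if (!is.null(manual_descriptors)) {
    for (i in seq_len(n_ip)) {
      mt <- bundle$mean_trajectories[[ip$mt_index[i]]]
      known <- !is.na(manual_descriptors$entry_zone)
      clash <- known & (manual_descriptors$entry_zone != mt$entry_zone |
                          manual_descriptors$target_zone != mt$target_zone)
      cost[i, clash] <- BIG
    }
  }
  flip <- n_ip > n_mp
  a <- if (flip) solve_assignment(t(cost)) else solve_assignment(cost)
  pairs <- if (flip) cbind(ip = a, mp = seq_len(n_mp)) else
    cbind(ip = seq_len(n_ip), mp = a)
  ok <- cost[pairs] < BIG / 2
  pairs <- pairs[ok, , drop = FALSE]
  out <- data.frame(mt_index = ip$mt_index[pairs[, "ip"]],
                    electrode_id = manual$electrode_id[pairs[, "mp"]],
                    d_ep = dep[pairs], d_tp = dtp[pairs],
                    stringsAsFactors = FALSE)
  attr(out, "unpaired_initialized") <-
    ip$electrode_id[setdiff(seq_len(n_ip), pairs[, "ip"])]
  attr(out, "unpaired_manual") <-
    manual$electrode_id[setdiff(seq_len(n_mp), pairs[, "mp"])]
  out
}

cross_dist <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    d <- a - matrix(b[j, ], nrow(a), 3, byrow = TRUE)
    out[, j] <- sqrt(rowSums(d * d))
  }
  out
}

#' Validate a mapping with the 2-sigma criterion
#'
#' A paired trajectory is correctly mapped when its entry-point distance is
#' at most twice the mean trajectory's entry dispersion and its target-point
#' distance at most twice the target dispersion (both inclusive). Singleton
#' mean trajectories have sigma = 0, so their pairs only pass at exactly
#' zero distance; such pairs are flagged. `fraction_mapped` is the passing
#' fraction over *paired* trajectories.
#'
#' @param pairing Output of [match_trajectories()].
#' @param bundle The `seeg_model` supplying the dispersions.
#' @return A list of class `"validation_report"`: `pairs` (data frame with
#'   distances, sigmas, `pass`, `singleton_sigma` flags), `fraction_mapped`,
#'   `unpaired_initialized`, `unpaired_manual`.
#' @export
validate_mapping <- function(pairing, bundle) {
  bundle <- validate_model(bundle)
  sig_e <- vapply(pairing$mt_index,
                  function(y) bundle$mean_trajectories[[y]]$sigma_entry, 0)
  sig_t <- vapply(pairing$mt_index,
                  function(y) bundle$mean_trajectories[[y]]$sigma_target, 0)
  pass <- pairing$d_ep <= 2 * sig_e & pairing$d_tp <= 2 * sig_t
  singleton <- sig_e == 0 | sig_t == 0
  pairs <- data.frame(mt_index = pairing$mt_index,
                      electrode_id = pairing$electrode_id,
                      d_ep = pairing$d_ep, d_tp = pairing$d_tp,
                      sigma_ep = sig_e, sigma_tp = sig_t,
                      pass = pass, singleton_sigma = singleton,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 fraction_mapped = if (nrow(pairs)) mean(pass) else NA_real_,
                 unpaired_initialized = attr(pairing, "unpaired_initialized"),
                 unpaired_manual = attr(pairing, "unpaired_manual")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$pairs), " pairs, fraction mapped = ",
      formatC(x$fraction_mapped, digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}
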