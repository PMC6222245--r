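#' Specify a synthetic SEEG cohort
#'
#' Describes a self-contained synthetic cohort with known ground truth:
#' planted mean trajectories laid out in a block-structured label volume,
#' planted strategies (subsets of the mean trajectories), plans drawn from
#' the strategies with positional noise, per-electrode dropout and optional
#' per-plan multiplicity, and random invertible per-subject affines so the
#' pipeline's average-space normalisation is genuinely exercised.
#'
#' Geometry: the volume is divided along x into equal-width columns. Each
#' column carries a cortical entry slab near the top of the volume and a
#' deep target block below, separated by white-matter filler, so that a
#' roughly vertical trajectory picks up exactly one (entry zone, target
#' zone) descriptor. Planted mean trajectories sharing a column share a
#' descriptor, i.e. an exploratory pattern; pair columns hold two planted
#' mean trajectories `cluster_sep_mm` apart in y (exercising per-plan
#' multiplicity U = 2), singleton columns hold one. Each planted mean
#' trajectory belongs to `strategy_overlap` of the `n_strategies` strategies
#' (balanced round-robin membership), so every mean trajectory accrues
#' members from several strategy groups.
#'
#' @param n_strategies Number of planted strategies.
#' @param mts_per_strategy Mean trajectories per strategy.
#' @param strategy_overlap Number of strategies each mean trajectory belongs
#'   to; `n_strategies * mts_per_strategy / strategy_overlap` must be a
#'   whole number (the total planted mean-trajectory count).
#' @param n_plans Number of plans (= patients; strategies assigned
#'   round-robin for balance).
#' @param noise_sigma_mm Isotropic Gaussian noise added per axis to each
#'   entry and target point in average space.
#' @param plan_dropout_prob Probability that a strategy's mean trajectory is
#'   omitted from a given plan.
#' @param multiplicity_map Named integer vector (names = planted mean
#'   trajectory indices as strings) giving the maximum electrode
#'   multiplicity for selected mean trajectories; per plan the multiplicity
#'   is drawn uniformly from 1..max, with the strategy's first plan forced
#'   to the maximum so the per-pattern bound U is deterministic.
#' @param cluster_sep_mm Within-pattern separation of planted mean
#'   trajectories (y axis).
#' @param affine_jitter List with `rot_deg`, `scale_frac`, `trans_mm` ranges
#'   for the random per-subject subject-to-average affines.
#' @param volume_shape,voxel_size_mm Label-volume geometry.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_strategies = 4,
                        mts_per_strategy = 9,
                        strategy_overlap = 3,
                        n_plans = 40,
                        noise_sigma_mm = 2,
                        plan_dropout_prob = 0.02,
                        multiplicity_map = integer(),
                        cluster_sep_mm = 40,
                        affine_jitter = list(rot_deg = 10, scale_frac = 0.1,
                                             trans_mm = 10),
                        volume_shape = c(96L, 48L, 48L),
                        voxel_size_mm = 2,
                        seed) {
  if (missing(seed) || is.null(seed)) stop_contract("cohort_spec: seed is mandatory")
  if (plan_dropout_prob < 0 || plan_dropout_prob > 1) {
    stop_contract("plan_dropout_prob must be in [0, 1]")
  }
  if (noise_sigma_mm < 0) stop_contract("noise_sigma_mm must be >= 0")
  total <- n_strategies * mts_per_strategy / strategy_overlap
  if (abs(total - round(total)) > 1e-9) {
    stop_contract("n_strategies * mts_per_strategy / strategy_overlap must be integer")
  }
  if (strategy_overlap < 1 || strategy_overlap > n_strategies) {
    stop_contract("strategy_overlap must be in 1..n_strategies")
  }
  structure(list(n_strategies = as.integer(n_strategies),
                 mts_per_strategy = as.integer(mts_per_strategy),
                 strategy_overlap = as.integer(strategy_overlap),
                 n_mts = as.integer(round(total)),
                 n_plans = as.integer(n_plans),
                 noise_sigma_mm = noise_sigma_mm,
                 plan_dropout_prob = plan_dropout_prob,
                 multiplicity_map = multiplicity_map,
                 cluster_sep_mm = cluster_sep_mm,
                 affine_jitter = affine_jitter,
                 volume_shape = as.integer(volume_shape),
                 voxel_size_mm = voxel_size_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Balanced membership: planted mT i belongs to strategies
# {(class_i + j) mod S} for j = 0 .. overlap-1, with class_i = (i-1) mod S.
# mTs of one class co-occur in exactly the same strategies, so two mTs of a
# class can safely share a column (same descriptor, U = 2 patterns).
planted_layout <- function(spec) {
  S <- spec$n_strategies
  M <- spec$n_mts
  class <- (seq_len(M) - 1L) %% S
  per_class <- split(seq_len(M), class)
  cols <- list()
  for (cl in per_class) {
    i <- 1
    while (i <= length(cl)) {
      if (i + 1 <= length(cl) && length(cols) < 999) {
        cols <- c(cols, list(cl[i:(i + 1)]))  # pair column
        i <- i + 2
      } else {
        cols <- c(cols, list(cl[i]))          # singleton column
        i <- i + 1
      }
    }
  }
  membership <- matrix(FALSE, S, M)
  for (i in seq_len(M)) {
    membership[(class[i] + seq_len(spec$strategy_overlap) - 1L) %% S + 1L, i] <- TRUE
  }
  list(columns = cols, class = class, membership = membership)
}

#' Generate the synthetic atlas and planted geometry
#'
#' Builds the block-structured label volume (entry slabs, deep target
#' blocks, white-matter filler, background air), the matching zone
#' configuration, and the planted mean-trajectory table. Fails fast if any
#' planted point does not classify into its intended zone.
#'
#' @param spec A [cohort_spec()].
#' @return List with `atlas` (a [label_volume()]), `zone_config`, and
#'   `planted` (data frame of planted mean trajectories with descriptors and
#'   strategy membership class).
#' @export
generate_atlas <- function(spec) {
  layout <- planted_layout(spec)
  n_cols <- length(layout$columns)
  dm <- spec$volume_shape
  vx <- spec$voxel_size_mm
  extent <- dm * vx
  half <- extent / 2
  if (extent[3] < 88) stop_contract("volume too shallow for the planted geometry (need >= 88 mm in z)")
  width <- extent[1] / n_cols
  if (width < 6 * spec$noise_sigma_mm + 4) {
    stop_contract("columns too narrow for the requested noise level")
  }
  x0 <- -half[1]
  slab_top <- half[3] - 8; slab_bot <- slab_top - 16
  block_top <- -8; block_bot <- -40
  entry_z <- (slab_top + slab_bot) / 2
  target_z <- (block_top + block_bot) / 2

  # voxel-centre coordinate vectors (0-based index i -> i*vx - (d-1)*vx/2)
  xs <- (seq_len(dm[1]) - 1) * vx - (dm[1] - 1) * vx / 2
  zs <- (seq_len(dm[3]) - 1) * vx - (dm[3] - 1) * vx / 2
  colx <- pmin(pmax(floor((xs - x0) / width) + 1, 1), n_cols)
  lab_slice <- matrix(1L, dm[1], dm[3])           # x-z slice; filler = 1
  for (k in seq_along(zs)) {
    z <- zs[k]
    if (z > slab_top) lab_slice[, k] <- 0L
    else if (z >= slab_bot) lab_slice[, k] <- 100L + colx
    else if (z <= block_top && z >= block_bot) lab_slice[, k] <- 200L + colx
  }
  labels <- array(0L, dim = dm)
  for (j in seq_len(dm[2])) labels[, j, ] <- lab_slice

  vox2world <- diag(c(vx, vx, vx, 1))
  vox2world[1:3, 4] <- -(dm - 1) * vx / 2
  lut <- data.frame(label_id = c(1L, 100L + seq_len(n_cols), 200L + seq_len(n_cols)),
                    label_name = c("white-matter",
                                   sprintf("entry-%02d", seq_len(n_cols)),
                                   sprintf("deep-%02d", seq_len(n_cols))),
                    stringsAsFactors = FALSE)
  atlas <- label_volume(labels, vox2world, lut, space = "average")
  cfg <- zone_config(entry_zones = sprintf("entry-%02d", seq_len(n_cols)),
                     target_zones = sprintf("deep-%02d", seq_len(n_cols)),
                     merge_map = stats::setNames(lut$label_name,
                                                 as.character(lut$label_id))[-1],
                     exclusion_zones = character(),
                     ignore_labels = c(0L, 1L))

  rows <- list()
  for (c_idx in seq_along(layout$columns)) {
    members <- layout$columns[[c_idx]]
    xc <- x0 + (c_idx - 0.5) * width
    ys <- if (length(members) == 2) {
      c(-spec$cluster_sep_mm / 2, spec$cluster_sep_mm / 2)
    } else 0
    for (k in seq_along(members)) {
      i <- members[k]
      rows[[length(rows) + 1]] <- data.frame(
        mt_index = i, column = c_idx, class = layout$class[i],
        ep_x = xc, ep_y = ys[k], ep_z = entry_z,
        tp_x = xc, tp_y = ys[k], tp_z = target_z,
        entry_zone = sprintf("entry-%02d", c_idx),
        target_zone = sprintf("deep-%02d", c_idx),
        stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, rows)
  planted <- planted[order(planted$mt_index), ]
  rownames(planted) <- NULL

  # fail fast: every planted trajectory must classify into its descriptor
  for (i in seq_len(nrow(planted))) {
    d <- extract_descriptor(
      sample_labels(c(planted$ep_x[i], planted$ep_y[i], planted$ep_z[i]),
                    c(planted$tp_x[i], planted$tp_y[i], planted$tp_z[i]),
                    atlas, step = 1), cfg)
    if (is.null(d) || d$entry_zone != planted$entry_zone[i] ||
        d$target_zone != planted$target_zone[i]) {
      stop_seeg(paste0("planted mean trajectory ", planted$mt_index[i],
                       " does not classify into its zones"),
                "seeg_generation_error")
    }
  }
  list(atlas = atlas, zone_config = cfg, planted = planted)
}

random_subject_affine <- function(jitter) {
  theta <- stats::runif(1, -jitter$rot_deg, jitter$rot_deg) * pi / 180
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  s <- stats::runif(1, 1 - jitter$scale_frac, 1 + jitter$scale_frac)
  t <- stats::runif(3, -jitter$trans_mm, jitter$trans_mm)
  A <- diag(4)
  A[1:3, 1:3] <- s * R
  A[1:3, 4] <- t
  affine_transform(A)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the plans described by the spec: each plan follows a planted
#' strategy (round-robin assignment), includes each of the strategy's mean
#' trajectories with probability `1 - plan_dropout_prob`, replicates
#' multiplicity-mapped mean trajectories with small lateral offsets, adds
#' isotropic Gaussian noise to every entry and target point in average
#' space, and maps the result into subject space through the inverse of a
#' random per-subject affine. All randomness derives from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `"seeg_cohort"`: `plans` (subject-space trajectory
#'   table), `affines` (named list, subject to average), `atlas`,
#'   `zone_config`, and `truth` (planted mean trajectories, strategy bit
#'   matrix, per-plan strategy assignment, and the spec) — the pipeline
#'   under test never reads `truth`.
#' @export
generate_cohort <- function(spec) {
  gen <- generate_atlas(spec)
  layout <- planted_layout(spec)
  S <- spec$n_strategies
  planted <- gen$planted
  with_seed(spec$seed, {
    plan_rows <- list()
    affines <- list()
    plan_strategy <- integer(spec$n_plans)
    first_of_strategy <- !logical(S)
    for (j in seq_len(spec$n_plans)) {
      g <- (j - 1L) %% S + 1L
      plan_strategy[j] <- g
      pid <- sprintf("P%03d", j)
      mts <- which(layout$membership[g, ])
      e <- 0L
      for (y in mts) {
        if (stats::runif(1) < spec$plan_dropout_prob) next
        maxmult <- spec$multiplicity_map[as.character(y)]
        count <- if (!is.na(maxmult) && length(maxmult)) {
          if (first_of_strategy[g]) as.integer(maxmult)
          else sample.int(as.integer(maxmult), 1)
        } else 1L
        offs <- (seq_len(count) - (count + 1) / 2) * 6  # lateral y offsets
        p <- planted[planted$mt_index == y, ]
        for (r in seq_len(count)) {
          e <- e + 1L
          ep <- c(p$ep_x, p$ep_y + offs[r], p$ep_z) +
            stats::rnorm(3, 0, spec$noise_sigma_mm)
          tp <- c(p$tp_x, p$tp_y + offs[r], p$tp_z) +
            stats::rnorm(3, 0, spec$noise_sigma_mm)
          plan_rows[[length(plan_rows) + 1]] <- data.frame(
            patient_id = pid, plan_id = pid,
            electrode_id = sprintf("E%02d", e),
            ep_x = ep[1], ep_y = ep[2], ep_z = ep[3],
            tp_x = tp[1], tp_y = tp[2], tp_z = tp[3],
            space = "average", mt_truth = y, stringsAsFactors = FALSE)
        }
      }
      first_of_strategy[g] <- FALSE
      affines[[pid]] <- random_subject_affine(spec$affine_jitter)
    }
    avg <- do.call(rbind, plan_rows)
    rownames(avg) <- NULL
    subj <- do.call(rbind, lapply(unique(avg$patient_id), function(pid) {
      to_subject_space(avg[avg$patient_id == pid, , drop = FALSE],
                       affines[[pid]])
    }))
    rownames(subj) <- NULL
    mt_truth <- subj$mt_truth
    subj$mt_truth <- NULL
    structure(list(plans = subj,
                   affines = affines,
                   atlas = gen$atlas,
                   zone_config = gen$zone_config,
                   truth = list(planted = planted,
                                strategy_bits = layout$membership,
                                plan_strategy = stats::setNames(
                                  plan_strategy,
                                  sprintf("P%03d", seq_len(spec$n_plans))),
                                trajectory_mt = mt_truth,
                                spec = spec)),
              class = "seeg_cohort")
  })
}

#' Write a cohort to a directory
#'
#' Emits `plans.csv`, per-subject affine files under `xfm/`, the atlas as
#' uncompressed NIfTI plus label lookup table, the zone configuration, and
#' the ground truth under a separate `truth/` subdirectory (which the
#' analysis pipeline must never read).
#'
#' @param cohort A `seeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "xfm"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_plans(cohort$plans, file.path(dir, "plans.csv"))
  for (pid in names(cohort$affines)) {
    write_affine(cohort$affines[[pid]], file.path(dir, "xfm", paste0(pid, ".mat")))
  }
  write_label_volume(cohort$atlas, file.path(dir, "atlas.nii"),
                     file.path(dir, "atlas_labels.txt"))
  write_zone_config(cohort$zone_config, file.path(dir, "zones.json"))
  truth <- cohort$truth
  json <- jsonlite::toJSON(list(planted = truth$planted,
                                strategy_bits = truth$strategy_bits,
                                plan_strategy = as.list(truth$plan_strategy),
                                spec = unclass(truth$spec)),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  write_atomic(json, file.path(dir, "truth", "truth.json"))
  invisible(dir)
}
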