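#' Sample atlas labels along a trajectory
#'
#' Walks the straight line from entry to target at regular arc-length steps
#' (plus the exact endpoint) and reads the atlas label at each point by
#' nearest-voxel lookup. Points outside the grid get label 0.
#'
#' @param entry,target Length-3 numeric vectors, world mm, in the atlas'
#'   space.
#' @param atlas A [label_volume()].
#' @param step Sampling step in mm (default 1).
#' @param space Space tag of the trajectory; must match `atlas$space`.
#' @return Data frame with columns `arc_mm` (strictly increasing, starting at
#'   0 and ending at the trajectory length) and `label` (integer).
#' @export
sample_labels <- function(entry, target, atlas, step = 1, space = atlas$space) {
  if (!identical(space, atlas$space)) {
    stop_contract(paste0("trajectory space '", space,
                         "' does not match atlas space '", atlas$space, "'"))
  }
  if (step <= 0) stop_contract("step must be > 0")
  d <- target - entry
  len <- sqrt(sum(d * d))
  if (len <= 0) stop_contract("zero-length trajectory")
  arc <- seq(0, len, by = step)
  if (arc[length(arc)] < len) arc <- c(arc, len)
  pts <- outer(arc / len, d) + matrix(entry, length(arc), 3, byrow = TRUE)
  data.frame(arc_mm = arc, label = lookup_labels(atlas, pts))
}

#' Reduce a label sequence to a trajectory descriptor
#'
#' Implements the descriptor d = \[entry zone; target zone\]: raw labels are
#' mapped through the zone configuration's merge map (ignored labels are
#' dropped), the entry zone is the first traversed zone belonging to the
#' entry-zone set, and the target zone is the member of the target-zone set
#' traversed at the greatest arc length — a deterministic surrogate for the
#' surgeon's choice of the clinically relevant target among the zones the
#' electrode crosses. A trajectory is an *outlier* (returns `NULL`) when its
#' terminal zone is in the exclusion set (ventricles, brain stem,
#' cerebellum), or when no admissible entry or target zone is traversed.
#'
#' @param seq A label sequence from [sample_labels()].
#' @param cfg A [zone_config()].
#' @return A list `(entry_zone, target_zone)`, or `NULL` for an outlier.
#' @export
extract_descriptor <- function(seq, cfg) {
  if (!nrow(seq)) stop_contract("empty label sequence")
  lab <- seq$label
  keep <- !(lab %in% cfg$ignore_labels)
  lab <- lab[keep]
  if (!length(lab)) return(NULL)  # e.g. entirely white matter
  zone <- unname(cfg$merge_map[as.character(lab)])
  arc <- seq$arc_mm[keep]
  known <- !is.na(zone)
  zone <- zone[known]; arc <- arc[known]
  if (!length(zone)) return(NULL)
  if (zone[length(zone)] %in% cfg$exclusion_zones) return(NULL)
  in_entry <- zone %in% cfg$entry_zones
  if (!any(in_entry)) return(NULL)
  in_target <- zone %in% cfg$target_zones
  if (!any(in_target)) return(NULL)
  list(entry_zone = zone[which(in_entry)[1]],
       target_zone = zone[max(which(in_target))])
}

#' Classify every trajectory of a plan table
#'
#' Convenience wrapper running [sample_labels()] and [extract_descriptor()]
#' over each row of a trajectory table.
#'
#' @param plans Trajectory data frame (see [read_plans()]); must be in the
#'   atlas' space.
#' @param atlas A [label_volume()].
#' @param cfg A [zone_config()].
#' @param step Sampling step in mm.
#' @return `plans` with added columns `entry_zone`, `target_zone` (NA for
#'   outliers) and logical `outlier`.
#' @export
classify_trajectories <- function(plans, atlas, cfg, step = 1) {
  ep <- entry_points(plans); tp <- target_points(plans)
  ez <- tz <- rep(NA_character_, nrow(plans))
  for (i in seq_len(nrow(plans))) {
    d <- extract_descriptor(
      sample_labels(ep[i, ], tp[i, ], atlas, step = step,
                    space = plans$space[i]),
      cfg)
    if (!is.null(d)) {
      ez[i] <- d$entry_zone
      tz[i] <- d$target_zone
    }
  }
  plans$entry_zone <- ez
  plans$target_zone <- tz
  plans$outlier <- is.na(ez)
  plans
}
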