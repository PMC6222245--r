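#' Insertion angle at the entry point
#'
#' Angle in degrees between the electrode direction and the local surface
#' normal at the entry point: 0 deg is a perpendicular (ideal) insertion,
#' 90 deg a tangential one. The absolute dot product makes the result
#' independent of the normal's orientation (inward vs outward).
#'
#' @param entry,target Length-3 numeric vectors (mm, same space as the
#'   surface point).
#' @param surface_normal Unit-norm length-3 vector.
#' @return Angle in degrees, in \[0, 90\].
#' @export
insertion_angle <- function(entry, target, surface_normal) {
  d <- target - entry
  len <- sqrt(sum(d * d))
  if (len <= 0) stop_contract("zero-length trajectory")
  nn <- sqrt(sum(surface_normal^2))
  if (abs(nn - 1) > 1e-6) stop_contract("surface_normal must have unit norm")
  acos(min(1, abs(sum(d / len * surface_normal)))) * 180 / pi
}

#' Vessel mask
#'
#' Binary 3-D mask of vessel voxels with its voxel-to-world affine, in the
#' same space as the trajectories it scores.
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @param vox2world 4x4 affine, 0-based voxel index to world mm.
#' @param space Coordinate-space tag.
#' @export
vessel_mask <- function(mask, vox2world, space = "subject") {
  if (length(dim(mask)) != 3) stop_format("vessel mask must be a 3-D array")
  structure(list(mask = array(as.logical(mask), dim = dim(mask)),
                 vox2world = affine_transform(vox2world), space = space),
            class = "vessel_mask")
}

#' Minimum distance from vessels along a trajectory, split in two tracts
#'
#' Samples the trajectory at regular arc-length steps and measures, at each
#' sample, the distance to the nearest vessel voxel centre. The proximal
#' tract covers samples with arc length up to `split_depth` from the entry
#' point; the distal tract the remainder. Returns the minimum clearance in
#' each tract. An empty vessel mask yields `c(Inf, Inf)` with a warning.
#'
#' @param entry,target Length-3 numeric vectors, world mm.
#' @param vessels A [vessel_mask()] in the same space.
#' @param split_depth Tract boundary in mm from the entry point (default 10,
#'   a configurable surrogate for the proximal/distal split used by
#'   trajectory optimisers).
#' @param step Sampling step in mm.
#' @param space Space tag of the trajectory.
#' @return Named numeric vector `c(tract1 = ..., tract2 = ...)`, mm.
#' @export
vessel_distance <- function(entry, target, vessels, split_depth = 10,
                            step = 1, space = vessels$space) {
  if (!identical(space, vessels$space)) {
    stop_contract("trajectory and vessel mask are in different spaces")
  }
  d <- target - entry
  len <- sqrt(sum(d * d))
  if (len <= 0) stop_contract("zero-length trajectory")
  if (split_depth <= 0 || split_depth >= len) {
    stop_contract("split_depth must lie strictly inside (0, trajectory length)")
  }
  vox <- which(vessels$mask, arr.ind = TRUE) - 1  # 0-based indices
  if (!nrow(vox)) {
    warning("empty vessel mask; distances are +Inf", call. = FALSE)
    return(c(tract1 = Inf, tract2 = Inf))
  }
  centres <- apply_affine(vessels$vox2world, vox)
  if (is.null(dim(centres))) centres <- matrix(centres, nrow = 1)
  arc <- seq(0, len, by = step)
  if (arc[length(arc)] < len) arc <- c(arc, len)
  pts <- outer(arc / len, d) + matrix(entry, length(arc), 3, byrow = TRUE)
  dmin <- apply(cross_dist(pts, centres), 1, min)
  t1 <- arc <= split_depth
  c(tract1 = min(dmin[t1]), tract2 = min(dmin[!t1]))
}

#' Risk metrics for every trajectory of a plan
#'
#' @param plans Trajectory table.
#' @param vessels A [vessel_mask()].
#' @param normals Data frame aligned with `plans` rows, columns
#'   `nx`, `ny`, `nz` (unit surface normals at each entry point).
#' @inheritParams vessel_distance
#' @return `plans` with added columns `insertion_angle_deg`,
#'   `vessel_dist_tract1_mm`, `vessel_dist_tract2_mm`.
#' @export
plan_metrics <- function(plans, vessels, normals, split_depth = 10, step = 1) {
  ep <- entry_points(plans); tp <- target_points(plans)
  ang <- t1 <- t2 <- numeric(nrow(plans))
  for (i in seq_len(nrow(plans))) {
    ang[i] <- insertion_angle(ep[i, ], tp[i, ],
                              c(normals$nx[i], normals$ny[i], normals$nz[i]))
    vd <- vessel_distance(ep[i, ], tp[i, ], vessels,
                          split_depth = split_depth, step = step,
                          space = plans$space[i])
    t1[i] <- vd[["tract1"]]; t2[i] <- vd[["tract2"]]
  }
  plans$insertion_angle_deg <- ang
  plans$vessel_dist_tract1_mm <- t1
  plans$vessel_dist_tract2_mm <- t2
  plans
}
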