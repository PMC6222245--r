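#' Build a practice model from retrospective plans
#'
#' Runs the mining pipeline on a cohort of subject-space plans: each
#' patient's trajectories are mapped to the average space through their
#' registration affine, classified into descriptors against the atlas,
#' pooled into exploratory patterns, and compressed into mean trajectories
#' by [build_mean_trajectories()]. The result is a model bundle — the
#' ordered mean-trajectory list (whose order defines the positions of all
#' plan vectors and strategies), the zone configuration, and provenance.
#' Strategies are added separately by [add_strategies()].
#'
#' @param plans Subject-space trajectory table ([read_plans()]).
#' @param affines Named list of subject-to-average [affine_transform()]s,
#'   one per `patient_id`.
#' @param atlas Average-space [label_volume()].
#' @param cfg A [zone_config()]; defaults to
#'   [default_zone_config()] of the atlas' label table.
#' @param step Label-sampling step in mm.
#' @param min_frac Cluster-significance fraction (default 0.05).
#' @param seed Integer seed controlling the k-means restarts.
#' @return An object of class `"seeg_model"`.
#' @export
build_model <- function(plans, affines, atlas,
                        cfg = default_zone_config(atlas$label_table),
                        step = 1, min_frac = 0.05, seed = 1L) {
  plans <- validate_plans(plans)
  pids <- unique(plans$patient_id)
  missing <- setdiff(pids, names(affines))
  if (length(missing)) {
    stop_contract(paste0("no registration affine for patient(s): ",
                         paste(missing, collapse = ", ")))
  }
  avg <- do.call(rbind, lapply(pids, function(p) {
    to_average_space(plans[plans$patient_id == p, , drop = FALSE],
                     affines[[p]])
  }))
  rownames(avg) <- NULL
  classified <- classify_trajectories(avg, atlas, cfg, step = step)
  patterns <- group_patterns(classified)
  mts <- list()
  for (pt in patterns) {
    mts <- c(mts, build_mean_trajectories(pt, min_frac = min_frac,
                                          seed = seed))
  }
  bundle <- structure(list(
    schema_version = 1L,
    mean_trajectories = mts,
    plan_ids = unique(plans$plan_id),
    strategies = list(),
    zone_config = cfg,
    provenance = list(n_patients = length(pids),
                      n_plans = length(unique(plans$plan_id)),
                      n_trajectories = nrow(plans),
                      n_outliers = sum(classified$outlier),
                      n_patterns = length(patterns),
                      step = step, min_frac = min_frac,
                      seed = as.integer(seed))
  ), class = "seeg_model")
  validate_model(bundle)
}

#' @rdname build_model
#' @param bundle A `seeg_model`.
#' @export
validate_model <- function(bundle) {
  if (!inherits(bundle, "seeg_model")) stop_format("not a seeg_model")
  m <- length(bundle$mean_trajectories)
  for (mt in bundle$mean_trajectories) {
    if (length(mt$mean_entry) != 3 || length(mt$mean_target) != 3) {
      stop_format("mean trajectory coordinates must be length 3")
    }
    if (mt$n_members < 1) stop_format("mean trajectory with n_members < 1")
    # a singleton has zero dispersion by construction; the converse does not
    # hold (coincident members, e.g. in noiseless simulations, give sigma 0)
    if (mt$n_members == 1 && (mt$sigma_entry != 0 || mt$sigma_target != 0)) {
      stop_format("sigma must be 0 exactly for singleton mean trajectories")
    }
    if (mt$sigma_entry < 0 || mt$sigma_target < 0) {
      stop_format("negative sigma")
    }
  }
  for (s in bundle$strategies) {
    if (length(s$bits) != m) {
      stop_format(paste0("strategy ", s$strategy_id, " has bit-vector length ",
                         length(s$bits), "; expected ", m))
    }
  }
  bundle
}

#' Mean trajectories of a model as a data frame
#'
#' @param bundle A `seeg_model`.
#' @return One row per mean trajectory, in bundle order (the order that
#'   defines plan-vector and strategy positions).
#' @export
mt_table <- function(bundle) {
  mts <- bundle$mean_trajectories
  do.call(rbind, lapply(seq_along(mts), function(y) {
    mt <- mts[[y]]
    data.frame(mt_index = y, entry_zone = mt$entry_zone,
               target_zone = mt$target_zone, index_u = mt$index_u,
               ep_x = mt$mean_entry[1], ep_y = mt$mean_entry[2],
               ep_z = mt$mean_entry[3],
               tp_x = mt$mean_target[1], tp_y = mt$mean_target[2],
               tp_z = mt$mean_target[3],
               sigma_entry = mt$sigma_entry, sigma_target = mt$sigma_target,
               n_members = mt$n_members, stringsAsFactors = FALSE)
  }))
}

#' @export
print.seeg_model <- function(x, ...) {
  cat("<seeg_model> ", length(x$mean_trajectories), " mean trajectories, ",
      x$provenance$n_patterns %||% NA, " patterns, ",
      length(x$strategies), " strategies, ",
      length(x$plan_ids), " plans\n", sep = "")
  invisible(x)
}

# ---- persistence ----------------------------------------------------------

model_to_list <- function(bundle) {
  list(
    schema_version = bundle$schema_version,
    mean_trajectories = lapply(bundle$mean_trajectories, function(mt) {
      list(entry_zone = mt$entry_zone, target_zone = mt$target_zone,
           index_u = mt$index_u, mean_entry = mt$mean_entry,
           mean_target = mt$mean_target, sigma_entry = mt$sigma_entry,
           sigma_target = mt$sigma_target, n_members = mt$n_members,
           final_k = mt$final_k,
           member_refs = list(plan_id = mt$member_refs$plan_id,
                              electrode_id = mt$member_refs$electrode_id))
    }),
    plan_ids = bundle$plan_ids,
    strategies = lapply(bundle$strategies, function(s) {
      list(strategy_id = s$strategy_id, name = s$name,
           bits = s$bits, member_plan_ids = s$member_plan_ids,
           degenerate = s$degenerate)
    }),
    zone_config = list(entry_zones = bundle$zone_config$entry_zones,
                       target_zones = bundle$zone_config$target_zones,
                       merge_map = as.list(bundle$zone_config$merge_map),
                       exclusion_zones = bundle$zone_config$exclusion_zones,
                       ignore_labels = bundle$zone_config$ignore_labels),
    provenance = bundle$provenance
  )
}

chr <- function(x) as.character(unlist(x) %||% character())
num <- function(x) as.numeric(unlist(x) %||% numeric())
int <- function(x) as.integer(unlist(x) %||% integer())
lgl <- function(x) as.logical(unlist(x) %||% logical())

model_from_list <- function(x) {
  if (is.null(x$schema_version)) stop_format("model bundle: missing schema_version")
  mts <- lapply(x$mean_trajectories, function(mt) {
    list(entry_zone = chr(mt$entry_zone), target_zone = chr(mt$target_zone),
         index_u = int(mt$index_u),
         mean_entry = num(mt$mean_entry), mean_target = num(mt$mean_target),
         sigma_entry = num(mt$sigma_entry), sigma_target = num(mt$sigma_target),
         n_members = int(mt$n_members), final_k = int(mt$final_k),
         member_refs = data.frame(plan_id = chr(mt$member_refs$plan_id),
                                  electrode_id = chr(mt$member_refs$electrode_id),
                                  stringsAsFactors = FALSE))
  })
  strategies <- lapply(x$strategies, function(s) {
    list(strategy_id = chr(s$strategy_id),
         name = if (is.null(s$name)) NULL else chr(s$name),
         bits = lgl(s$bits),
         member_plan_ids = chr(s$member_plan_ids),
         degenerate = lgl(s$degenerate))
  })
  zc <- zone_config(entry_zones = chr(x$zone_config$entry_zones),
                    target_zones = chr(x$zone_config$target_zones),
                    merge_map = unlist(x$zone_config$merge_map),
                    exclusion_zones = chr(x$zone_config$exclusion_zones),
                    ignore_labels = int(x$zone_config$ignore_labels))
  prov <- x$provenance
  prov$n_patients <- int(prov$n_patients)
  prov$n_plans <- int(prov$n_plans)
  prov$n_trajectories <- int(prov$n_trajectories)
  prov$n_outliers <- int(prov$n_outliers)
  prov$n_patterns <- int(prov$n_patterns)
  prov$step <- num(prov$step)
  prov$min_frac <- num(prov$min_frac)
  prov$seed <- int(prov$seed)
  validate_model(structure(list(schema_version = int(x$schema_version),
                                mean_trajectories = mts,
                                plan_ids = chr(x$plan_ids),
                                strategies = strategies,
                                zone_config = zc,
                                provenance = prov),
                           class = "seeg_model"))
}

#' Persist or load a model bundle
#'
#' The bundle is stored as a single JSON document with an explicit
#' `schema_version`, human-inspectable and diff-able. Doubles are written
#' with 17 significant digits so that write–read round-trips are exact.
#'
#' @param bundle A `seeg_model`.
#' @param path JSON file path.
#' @export
write_model <- function(bundle, path) {
  bundle <- validate_model(bundle)
  json <- jsonlite::toJSON(model_to_list(bundle), auto_unbox = TRUE,
                           digits = I(17), null = "null", pretty = TRUE)
  write_atomic(json, path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_format(paste0("model file not found: ", path))
  model_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
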