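#' Trajectory tables
#'
#' Electrode plans are stored as one flat data frame of trajectories, one row
#' per electrode, with columns `patient_id`, `plan_id`, `electrode_id`,
#' entry-point coordinates `ep_x`, `ep_y`, `ep_z`, target-point coordinates
#' `tp_x`, `tp_y`, `tp_z` (all RAS mm) and a `space` tag, either `"subject"`
#' or `"average"`. A *plan* is the set of rows sharing one `plan_id`; the
#' number of electrodes E varies freely between plans.
#'
#' `read_plans()` parses the on-disk CSV dialect (same columns, without
#' `space`; coordinates in mm, assumed subject space) and validates the
#' invariants: finite coordinates, strictly positive trajectory length, and
#' unique `(plan_id, electrode_id)` keys.
#'
#' @param path CSV file with header
#'   `patient_id,plan_id,electrode_id,ep_x,ep_y,ep_z,tp_x,tp_y,tp_z`.
#' @return A validated trajectory data frame with `space = "subject"`.
#' @export
read_plans <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("plan file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       plan_id = "character",
                                       electrode_id = "character"))
  needed <- c("patient_id", "plan_id", "electrode_id",
              "ep_x", "ep_y", "ep_z", "tp_x", "tp_y", "tp_z")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_parse(paste0("plan table is missing column(s): ",
                      paste(missing, collapse = ", ")))
  }
  df <- df[needed]
  for (col in c("ep_x", "ep_y", "ep_z", "tp_x", "tp_y", "tp_z")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$space <- rep("subject", nrow(df))
  validate_plans(df)
}

#' @rdname read_plans
#' @param plans A trajectory data frame.
#' @export
write_plans <- function(plans, path) {
  plans <- validate_plans(plans)
  cols <- c("patient_id", "plan_id", "electrode_id",
            "ep_x", "ep_y", "ep_z", "tp_x", "tp_y", "tp_z")
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(plans[cols], tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}

#' @rdname read_plans
#' @export
validate_plans <- function(plans) {
  coord_cols <- c("ep_x", "ep_y", "ep_z", "tp_x", "tp_y", "tp_z")
  for (col in coord_cols) {
    v <- plans[[col]]
    if (is.null(v)) stop_parse(paste0("missing coordinate column ", col))
    if (!is.numeric(v)) {
      stop_parse(paste0("non-numeric values in column ", col))
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_parse(paste0("non-finite coordinate in column ", col,
                        ", row ", bad[1]))
    }
  }
  if (nrow(plans)) {
    if (!all(plans$space %in% c("subject", "average"))) {
      stop_contract("space tag must be 'subject' or 'average'")
    }
    len <- trajectory_lengths(plans)
    zero <- which(len <= 0)
    if (length(zero)) {
      stop_parse(paste0("zero-length trajectory (entry == target) at row ",
                        zero[1], " (plan ", plans$plan_id[zero[1]],
                        ", electrode ", plans$electrode_id[zero[1]], ")"))
    }
    key <- paste(plans$plan_id, plans$electrode_id, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop_parse(paste0("duplicate (plan_id, electrode_id) at row ", dup[1],
                        ": (", plans$plan_id[dup[1]], ", ",
                        plans$electrode_id[dup[1]], ")"))
    }
  }
  plans
}

#' @rdname read_plans
#' @export
trajectory_lengths <- function(plans) {
  d <- as.matrix(plans[, c("tp_x", "tp_y", "tp_z")]) -
    as.matrix(plans[, c("ep_x", "ep_y", "ep_z")])
  row_norms(d)
}

entry_points  <- function(plans) unname(as.matrix(plans[, c("ep_x", "ep_y", "ep_z")]))
target_points <- function(plans) unname(as.matrix(plans[, c("tp_x", "tp_y", "tp_z")]))
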