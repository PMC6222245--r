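#' Zone configuration
#'
#' A zone configuration turns raw atlas labels into the reduced vocabulary of
#' entry and target zones used by the trajectory descriptor. It has five
#' parts:
#'
#' * `merge_map` — a complete map from raw label id to zone name. Merging
#'   several labels into one zone (e.g. hippocampus with para-hippocampus)
#'   happens here.
#' * `entry_zones` — zone names admissible as entry zones (the group
#'   of meaningful entry zones).
#' * `target_zones` — zone names admissible as clinically relevant targets.
#' * `exclusion_zones` — zone names that classify a trajectory as an outlier
#'   when they are its terminal (deepest) zone.
#' * `ignore_labels` — raw label ids skipped entirely during traversal
#'   (white matter, unknown/0).
#'
#' @param entry_zones,target_zones Character vectors of zone names.
#' @param merge_map Named character vector: `names()` are raw label ids (as
#'   strings), values are zone names.
#' @param exclusion_zones Character vector of zone names.
#' @param ignore_labels Integer vector of raw label ids.
#' @return An object of class `"zone_config"`.
#' @export
zone_config <- function(entry_zones, target_zones, merge_map,
                        exclusion_zones = character(),
                        ignore_labels = 0L) {
  entry_zones <- as.character(entry_zones)
  target_zones <- as.character(target_zones)
  exclusion_zones <- as.character(exclusion_zones)
  merge_map <- vapply(merge_map, as.character, "")
  if (is.null(names(merge_map)) || any(!nzchar(names(merge_map)))) {
    stop_format("merge_map must be named by raw label id")
  }
  known <- c(entry_zones, target_zones, exclusion_zones)
  stray <- setdiff(unique(unname(merge_map)), known)
  if (length(stray)) {
    # zones reachable by the map but never usable; harmless, keep but note
    warning("merge_map maps to zone(s) outside entry/target/exclusion sets: ",
            paste(stray, collapse = ", "), call. = FALSE)
  }
  structure(list(entry_zones = entry_zones,
                 target_zones = target_zones,
                 merge_map = merge_map,
                 exclusion_zones = exclusion_zones,
                 ignore_labels = as.integer(ignore_labels)),
            class = "zone_config")
}

#' Default zone configuration for a Desikan–Killiany-style label table
#'
#' Applies the centre's clinically motivated reductions: hippocampus and
#' para-hippocampus merge into a single target zone (one cannot be explored
#' without crossing the other); the occipital labels lingual, cuneus,
#' precuneus and pericalcarine merge into one occipital zone; the putamen
#' joins the insular zone (electrodes crossing the insula and ending in the
#' putamen belong to the insular pattern). Ventricles, brain stem and
#' cerebellum become exclusion zones; white matter and unknown labels are
#' ignored. Labels with no matching rule map to themselves and are both
#' admissible entry and target zones.
#'
#' @param label_table Data frame with `label_id`, `label_name` columns.
#' @return A [zone_config()].
#' @export
default_zone_config <- function(label_table) {
  ids <- as.integer(label_table$label_id)
  nm <- as.character(label_table$label_name)
  lnm <- tolower(nm)
  zone <- nm  # identity merge by default

  hip <- grepl("hippocamp", lnm)  # hippocampus + parahippocampal
  if (any(hip)) zone[hip] <- "hippocampus-complex"
  occ <- grepl("lingual|cuneus|pericalcarine", lnm)  # includes precuneus
  if (any(occ)) zone[occ] <- "occipital"
  insula <- grepl("insula", lnm)
  putamen <- grepl("putamen", lnm)
  if (any(insula)) {
    zone[insula] <- "insula"
    if (any(putamen)) zone[putamen] <- "insula"
  } else if (any(putamen)) {
    warning("putamen present without insula; putamen merge rule skipped",
            call. = FALSE)
  }

  excl <- grepl("ventricle|brain-?stem|cerebell", lnm)
  zone[excl] <- nm[excl]  # excluded structures keep their own name
  ign <- grepl("white|^wm\\b|unknown", lnm)

  merge_map <- stats::setNames(zone[!ign], as.character(ids[!ign]))
  usable <- sort(unique(zone[!ign & !excl]))
  zone_config(entry_zones = usable,
              target_zones = usable,
              merge_map = merge_map,
              exclusion_zones = sort(unique(zone[excl])),
              ignore_labels = c(0L, ids[ign]))
}

#' @rdname zone_config
#' @param path JSON file location.
#' @export
read_zone_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  zone_config(entry_zones = x$entry_zones,
              target_zones = x$target_zones,
              merge_map = unlist(x$merge_map),
              exclusion_zones = x$exclusion_zones %||% character(),
              ignore_labels = x$ignore_labels %||% 0L)
}

#' @rdname zone_config
#' @param cfg A `zone_config`.
#' @export
write_zone_config <- function(cfg, path) {
  json <- jsonlite::toJSON(list(entry_zones = cfg$entry_zones,
                                target_zones = cfg$target_zones,
                                merge_map = as.list(cfg$merge_map),
                                exclusion_zones = cfg$exclusion_zones,
                                ignore_labels = cfg$ignore_labels),
                           auto_unbox = TRUE, pretty = TRUE)
  write_atomic(json, path)
}
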