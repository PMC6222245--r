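#' Labelled atlas volumes
#'
#' A label volume bundles a 3-D integer grid of anatomical label ids, the
#' voxel-to-world affine (0-based voxel indices to RAS mm, the NIfTI sform
#' convention) and a lookup table mapping label ids to names. It is the
#' container used to read atlas zones along a trajectory.
#'
#' @param labels 3-D integer array of label ids (0 = unknown/background).
#' @param vox2world 4x4 affine mapping 0-based voxel index to world mm.
#' @param label_table Data frame with columns `label_id`, `label_name`; every
#'   nonzero id present in `labels` must appear.
#' @param space Coordinate-space tag, `"subject"` or `"average"`.
#' @return An object of class `"label_volume"`.
#' @export
label_volume <- function(labels, vox2world, label_table, space = "average") {
  if (length(dim(labels)) != 3) stop_format("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  vox2world <- affine_transform(vox2world)
  label_table <- as.data.frame(label_table)
  if (!all(c("label_id", "label_name") %in% names(label_table))) {
    stop_format("label_table needs columns label_id, label_name")
  }
  label_table$label_id <- as.integer(label_table$label_id)
  label_table$label_name <- as.character(label_table$label_name)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, label_table$label_id)
  if (length(missing)) {
    stop_format(paste0("label id(s) in grid absent from label_table: ",
                       paste(missing, collapse = ", ")))
  }
  structure(list(labels = labels, vox2world = vox2world,
                 label_table = label_table[c("label_id", "label_name")],
                 space = space),
            class = "label_volume")
}

#' @rdname label_volume
#' @param nifti_path NIfTI-1 file holding the integer label grid.
#' @param lut_path Two-column whitespace-separated text file
#'   (`label_id label_name`); lines starting with `#` are ignored.
#' @export
read_label_volume <- function(nifti_path, lut_path, space = "average") {
  img <- RNifti::readNifti(nifti_path)
  lut <- read_label_table(lut_path)
  label_volume(array(as.integer(round(img[])), dim = dim(img)),
               unclass(RNifti::xform(img)), lut, space = space)
}

#' @rdname label_volume
#' @param vol A `label_volume`.
#' @export
write_label_volume <- function(vol, nifti_path, lut_path) {
  img <- RNifti::asNifti(vol$labels)
  img <- RNifti::`sform<-`(img, structure(unclass(vol$vox2world), code = 2L))
  RNifti::writeNifti(img, nifti_path)
  write_atomic(paste(vol$label_table$label_id, vol$label_table$label_name),
               lut_path)
  invisible(nifti_path)
}

read_label_table <- function(lut_path) {
  lines <- readLines(lut_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) < 2)) stop_format("label table lines need 'id name'")
  data.frame(label_id = as.integer(vapply(parts, `[[`, "", 1)),
             label_name = vapply(parts, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

# Nearest-voxel label lookup for an n x 3 matrix of world-mm points.
# Points outside the grid get label 0 (the out-of-bounds convention).
lookup_labels <- function(vol, pts) {
  vox <- round(apply_affine(invert_affine(vol$vox2world), pts))
  if (is.null(dim(vox))) vox <- matrix(vox, nrow = 1)
  dm <- dim(vol$labels)
  inside <- vox[, 1] >= 0 & vox[, 1] < dm[1] &
    vox[, 2] >= 0 & vox[, 2] < dm[2] &
    vox[, 3] >= 0 & vox[, 3] < dm[3]
  out <- integer(nrow(vox))
  if (any(inside)) {
    idx <- 1 + vox[inside, 1] + dm[1] * (vox[inside, 2] + dm[2] * vox[inside, 3])
    out[inside] <- vol$labels[idx]
  }
  out
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", nrow(x$label_table), " labels, space=", x$space, "\n",
      sep = "")
  invisible(x)
}
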