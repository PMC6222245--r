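#' Affine transforms between subject and average space
#'
#' A registration is stored as a plain 4x4 numeric matrix acting on
#' homogeneous RAS coordinates in millimetres, mapping subject space to the
#' average (template) space. The file dialect is whitespace-separated text,
#' four rows of four numbers, row-major — the same layout FreeSurfer prints
#' for its talairach registrations (conversion from native FreeSurfer formats
#' is up to the caller).
#'
#' @param mat A 4x4 numeric matrix; last row must be (0, 0, 0, 1) and the
#'   upper-left 3x3 block must be invertible.
#' @return `affine_transform()` returns the validated matrix with class
#'   `"seeg_affine"`.
#' @examples
#' a <- affine_transform(diag(4))
#' apply_affine(a, c(1, 2, 3))
#' @export
affine_transform <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || !identical(dim(mat), c(4L, 4L))) {
    stop_format("affine must be a 4x4 numeric matrix")
  }
  mat <- matrix(as.numeric(mat), 4, 4)  # strip stray attributes (e.g. NIfTI)
  if (any(!is.finite(mat))) stop_format("affine contains non-finite entries")
  if (max(abs(mat[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop_format("affine last row must be (0, 0, 0, 1)")
  }
  if (abs(det(mat[1:3, 1:3])) <= 1e-12) {
    stop_format("affine is singular (|det| <= 1e-12)")
  }
  structure(unname(mat), class = "seeg_affine")
}

#' @rdname affine_transform
#' @param path Path to a text file holding the 4x4 matrix.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop_format(paste0("affine file not found: ", path))
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16) {
    stop_format(paste0("affine file ", path, " has ", length(vals),
                       " numbers; expected 16 (4x4)"))
  }
  affine_transform(matrix(vals, nrow = 4, byrow = TRUE))
}

#' @rdname affine_transform
#' @param a A `seeg_affine` (or 4x4 matrix).
#' @export
write_affine <- function(a, path) {
  a <- affine_transform(a)
  lines <- apply(a, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                         collapse = " "))
  write_atomic(lines, path)
}

#' @rdname affine_transform
#' @param pts Either a length-3 numeric vector or an n x 3 matrix of RAS mm
#'   coordinates.
#' @return `apply_affine()` returns the transformed coordinates in the same
#'   shape as `pts`; `invert_affine()` the inverse transform.
#' @export
apply_affine <- function(a, pts) {
  a <- affine_transform(a)
  single <- is.null(dim(pts))
  m <- if (single) matrix(pts, nrow = 1) else as.matrix(pts)
  if (ncol(m) != 3) stop_contract("points must have 3 columns (x, y, z)")
  out <- m %*% t(a[1:3, 1:3]) + matrix(a[1:3, 4], nrow(m), 3, byrow = TRUE)
  if (single) drop(out) else out
}

#' @rdname affine_transform
#' @export
invert_affine <- function(a) {
  a <- affine_transform(a)
  affine_transform(solve(unclass(a)))
}
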