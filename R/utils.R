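# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_seeg <- function(msg, class) {
  stop(structure(
    class = c(class, "seeg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_contract <- function(msg) stop_seeg(msg, "seeg_contract_error")
stop_parse    <- function(msg) stop_seeg(msg, "seeg_parse_error")
stop_format   <- function(msg) stop_seeg(msg, "seeg_format_error")

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic entry points route their seed through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Euclidean norms of the rows of a numeric matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Atomic file write: serialise into a sibling temp file, then rename.
write_atomic <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(text, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
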