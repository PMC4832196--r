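# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so simulation functions are pure functions of their seed and never
#' disturb the global random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# n sub-seeds, all < 2^31, drawn from the current stream
draw_seeds <- function(n) sample.int(2147483646L, n)

stop_vsdi <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared-distance grid (in pixels) from a center, rows x cols
pixel_distance <- function(n_rows, n_cols, center) {
  dr <- seq_len(n_rows) - center[1]
  dc <- seq_len(n_cols) - center[2]
  sqrt(outer(dr^2, dc^2, `+`))
}

# linear pixel index (column-major, matching R array layout)
pixel_index <- function(row, col, n_rows) (col - 1L) * n_rows + row

as_pixel_matrix <- function(pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L, byrow = TRUE)
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("row", "col")
  pixels
}

# mean over the trial axis of a [trial, frame, row, col] array, without the
# per-element overhead of apply()
trialwise_mean <- function(x, na_rm = FALSE) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], prod(d[2:4]))
  out <- colMeans(m, na.rm = na_rm)
  array(out, d[2:4])
}
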