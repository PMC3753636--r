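#' Define the TSS-relative feature grid
#'
#' The discriminative signal for promoters sits in a fixed span around the
#' TSS (default -250/+900 bp, covering core and proximal promoter
#' distances). The span is tiled with overlapping fixed-length windows
#' (default 500 bp at 50-bp stride); each candidate position yields one
#' 6-channel mean per window, flattened window-major into a feature vector
#' of dimension `D = 6 * n_windows`.
#'
#' @param span_start,span_end span limits in bp relative to the candidate
#'   TSS (0 = the TSS itself; negative = upstream on the candidate strand).
#' @param window_length window size in bp.
#' @param stride spacing of window starts in bp.
#' @return an object of class `grid_spec`.
#' @examples
#' grid_spec()           # 14 windows, D = 84
#' @export
grid_spec <- function(span_start = -250, span_end = 900,
                      window_length = 500, stride = 50) {
  if (span_end - span_start < window_length) {
    stop("grid span must cover at least one window", call. = FALSE)
  }
  window_starts <- seq.int(span_start, span_end - window_length, by = stride)
  structure(
    list(span_start = as.integer(span_start),
         span_end = as.integer(span_end),
         window_length = as.integer(window_length),
         stride = as.integer(stride),
         window_starts = as.integer(window_starts),
         n_windows = length(window_starts),
         d = 6L * length(window_starts)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "TSS-relative grid: span %+d/%+d bp, %d-bp windows at %d-bp stride (%d windows, D = %d)\n",
    x$span_start, x$span_end, x$window_length, x$stride, x$n_windows, x$d))
  invisible(x)
}

# Feature names: w<offset>.<channel>, window-major
.grid_feature_names <- function(grid) {
  as.vector(t(outer(grid$window_starts, .channels,
                    function(s, ch) sprintf("w%+d.%s", s, ch))))
}

# Feature matrix for candidate TSS positions on one strand of a profile
# index. Plus strand: the window at grid offset s spans genomic
# [p + s, p + s + w). Minus strand: grid offsets run 5'->3' along the minus
# strand, so offset s maps to the mirrored genomic window
# [p - s - w + 1, p - s + 1); with a reverse-complement-symmetric table the
# window mean there equals the mean on the reverse-complemented sequence.
# Returns list(features = n x D matrix, valid = logical n).
.grid_features <- function(idx, positions, strand, grid, min_valid = 0.9) {
  n <- length(positions)
  w <- grid$window_length
  feats <- matrix(NA_real_, n, grid$d)
  all_valid <- rep(TRUE, n)
  for (j in seq_along(grid$window_starts)) {
    s <- grid$window_starts[j]
    starts <- if (strand == "+") positions + s else positions - s - w + 1L
    wm <- .window_means(idx, starts, w)
    ok <- wm$valid_fraction >= min_valid
    all_valid <- all_valid & ok
    feats[, (6L * (j - 1L) + 1L):(6L * j)] <- wm$means
  }
  colnames(feats) <- .grid_feature_names(grid)
  list(features = feats, valid = all_valid)
}
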