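#' Annotate a sequence with per-step stiffness values
#'
#' Maps every dinucleotide step of `seq` to its six diagonal force constants,
#' producing the raw physical-property profile. Matching is case-insensitive:
#' soft-masked (lowercase) bases are ordinary bases at this stage -- repeat
#' masking is a downstream filter, not a physics concern. Steps touching any
#' base outside `{A, C, G, T}` (assembly gaps, IUPAC ambiguity codes) are
#' masked rather than raising an error, so whole-genome scans tolerate gaps.
#'
#' @param seq a single DNA string, length >= 2.
#' @param table a [stiffness_table].
#' @param origin optional region/strand identifier stored as an attribute.
#' @return a tibble of class `physical_profile` with one row per step:
#'   `pos` (0-based position of the step's first base), `valid`, and the six
#'   channel columns (NA where masked).
#' @examples
#' tab <- gen_stiffness_table(seed = 1)
#' step_series("ACGTN", tab)
#' @export
step_series <- function(seq, table, origin = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 2) stop("sequence too short (need >= 2 bases)", call. = FALSE)
  mat <- .stiffness_matrix(table)
  up <- toupper(seq)
  b1 <- substring(up, 1:(n - 1), 1:(n - 1))
  b2 <- substring(up, 2:n, 2:n)
  idx <- match(paste0(b1, b2), rownames(mat))
  values <- mat[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  values[is.na(idx), ] <- NA_real_
  out <- tibble::as_tibble(as.data.frame(values))
  out <- tibble::add_column(out,
                            pos = 0:(n - 2),
                            valid = !is.na(idx),
                            .before = 1)
  attr(out, "origin") <- origin
  attr(out, "table_checksum") <- .table_checksum(table)
  class(out) <- c("physical_profile", class(out))
  out
}

#' Average a physical profile over sliding windows
#'
#' The classifier's signal is the per-channel unweighted arithmetic mean of
#' the step values inside fixed-length windows (500 bp by default). Windows
#' are 0-based half-open bp intervals: a window `[s, s + w)` owns the
#' `w - 1` steps starting at `s .. s + w - 2`. Masked steps are excluded
#' from the mean; a window whose fraction of valid steps falls below
#' `min_valid` is flagged invalid and its means set to NA.
#'
#' @param profile a `physical_profile` from [step_series()].
#' @param window_length window size in bp (>= 2).
#' @param stride distance between consecutive window starts in bp (>= 1).
#' @param min_valid minimum fraction of unmasked steps for a window to be
#'   usable; defaults to 0.9.
#' @return a tibble of class `windowed_profile` with columns `start`, `end`,
#'   `center`, `valid_fraction`, `valid` and the six channel means. A window
#'   longer than the profile yields an empty tibble, not an error.
#' @export
window_average <- function(profile, window_length = 500, stride = 50,
                           min_valid = 0.9) {
  stopifnot(inherits(profile, "physical_profile"))
  if (window_length < 2) stop("window_length must be >= 2", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  seq_len_bp <- nrow(profile) + 1L
  idx <- .profile_index(profile)
  starts <- seq.int(0L, by = as.integer(stride),
                    length.out = max(0L, (seq_len_bp - window_length) %/%
                                           stride + 1L))
  if (seq_len_bp < window_length) starts <- integer(0)
  wm <- .window_means(idx, starts, window_length)
  out <- tibble::tibble(
    start = as.integer(starts),
    end = as.integer(starts + window_length),
    center = starts + window_length / 2,
    valid_fraction = wm$valid_fraction,
    valid = wm$valid_fraction >= min_valid
  )
  means <- wm$means
  means[!out$valid, ] <- NA_real_
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(means)))
  attr(out, "window_length") <- as.integer(window_length)
  attr(out, "stride") <- as.integer(stride)
  attr(out, "min_valid") <- min_valid
  attr(out, "origin") <- attr(profile, "origin")
  class(out) <- c("windowed_profile", class(out))
  out
}

# Prefix-sum index over a profile: O(1) window means for arbitrary starts.
# Built once per chromosome and shared by window_average and the scanner.
.profile_index <- function(profile) {
  v <- as.matrix(profile[, .channels])
  valid <- profile$valid
  v[!valid, ] <- 0
  list(
    cum = rbind(0, apply(v, 2, cumsum)),
    cum_valid = c(0, cumsum(as.integer(valid))),
    n_steps = nrow(profile)
  )
}

# Window [s, s+w) owns steps s .. s+w-2. `starts` may include out-of-range
# windows; those come back with valid_fraction 0 and NA means.
.window_means <- function(idx, starts, window_length) {
  n_win_steps <- window_length - 1L
  lo <- as.integer(starts)            # first step index owned
  hi <- lo + n_win_steps              # one past last step owned
  ok <- lo >= 0L & hi <= idx$n_steps
  lo_c <- pmax(pmin(lo, idx$n_steps), 0L)
  hi_c <- pmax(pmin(hi, idx$n_steps), 0L)
  n_valid <- idx$cum_valid[hi_c + 1L] - idx$cum_valid[lo_c + 1L]
  n_valid[!ok] <- 0
  sums <- idx$cum[hi_c + 1L, , drop = FALSE] - idx$cum[lo_c + 1L, , drop = FALSE]
  means <- sums / ifelse(n_valid > 0, n_valid, NA_real_)
  means[!ok, ] <- NA_real_
  colnames(means) <- .channels
  list(means = means, valid_fraction = n_valid / n_win_steps)
}
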