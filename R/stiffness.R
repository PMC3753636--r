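#' Construct a dinucleotide stiffness table
#'
#' A stiffness table holds, for each of the 16 dinucleotide steps, the six
#' diagonal force constants of the step's helical stiffness matrix: the
#' quadratic-energy coefficients penalising pure twist, tilt and roll
#' rotations (kcal/(mol.deg^2)) and pure shift, slide and rise translations
#' (kcal/(mol.A^2)). These parameters are consumed as input -- typically from
#' molecular-dynamics-derived tables -- never derived here.
#'
#' Because the diagonal stiffness of a step is the same read from either
#' strand, the table must satisfy reverse-complement symmetry:
#' `K(XY) == K(revcomp(XY))` channel-wise. The constructor enforces this to
#' within `tol`, and completes a table given only the 10 symmetry-unique
#' steps.
#'
#' @param x data frame with a `step` column and the six channel columns
#'   `twist`, `tilt`, `roll`, `shift`, `slide`, `rise`, one row per step
#'   (16 rows, or 10 symmetry-unique rows to be completed).
#' @param source_label free-text provenance of the constants.
#' @param tol tolerance for the reverse-complement symmetry check.
#' @return a tibble of class `stiffness_table` with 16 rows, steps in
#'   lexicographic order, and a `source_label` attribute.
#' @examples
#' tab <- gen_stiffness_table(seed = 1)
#' tab[tab$step %in% c("AC", "GT"), ]   # reverse-complement pair, equal rows
#' @export
stiffness_table <- function(x, source_label = "unspecified", tol = 1e-9) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(c("step", .channels), names(x))
  if (length(missing_cols) > 0) {
    stop("stiffness table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$step <- toupper(as.character(x$step))
  bad_step <- setdiff(x$step, .steps)
  if (length(bad_step) > 0) {
    stop("unknown dinucleotide step(s): ", paste(bad_step, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$step)) {
    stop("duplicated dinucleotide step(s): ",
         paste(unique(x$step[duplicated(x$step)]), collapse = ", "),
         call. = FALSE)
  }
  for (ch in .channels) {
    v <- x[[ch]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop(sprintf("non-positive or non-finite constant at step %s, channel %s",
                   x$step[which(bad)[1]], ch), call. = FALSE)
    }
  }
  # complete the 16 steps from the symmetry-unique ones
  absent <- setdiff(.steps, x$step)
  completable <- vapply(absent, function(s) .revcomp_step(s) %in% x$step,
                        logical(1))
  if (any(!completable)) {
    stop("missing dinucleotide step(s): ",
         paste(absent[!completable], collapse = ", "), call. = FALSE)
  }
  if (length(absent) > 0) {
    partners <- match(vapply(absent, .revcomp_step, character(1)), x$step)
    filled <- x[partners, , drop = FALSE]
    filled$step <- absent
    x <- rbind(x, filled)
  }
  x <- x[match(.steps, x$step), c("step", .channels)]
  rownames(x) <- NULL
  # symmetry check on the full table
  partner <- match(vapply(x$step, .revcomp_step, character(1)), x$step)
  for (ch in .channels) {
    dev <- abs(x[[ch]] - x[[ch]][partner])
    if (any(dev > tol)) {
      i <- which.max(dev)
      stop(sprintf(
        "reverse-complement symmetry violated at step %s, channel %s (|dK| = %g)",
        x$step[i], ch, dev[i]), call. = FALSE)
    }
  }
  out <- tibble::as_tibble(x)
  attr(out, "source_label") <- source_label
  class(out) <- c("stiffness_table", class(out))
  out
}

#' Load a stiffness table from TSV
#'
#' Expects a tab-separated file with a header naming the six channels
#' (`step  twist  tilt  roll  shift  slide  rise`); `#`-prefixed comment
#' lines are ignored. A file carrying only the 10 symmetry-unique steps is
#' completed to all 16 by reverse-complement symmetry.
#'
#' @param path path to the TSV file.
#' @param source_label provenance label; defaults to the file name.
#' @inheritParams stiffness_table
#' @return a [stiffness_table].
#' @export
load_stiffness_table <- function(path, source_label = basename(path),
                                 tol = 1e-9) {
  if (!file.exists(path)) {
    stop("stiffness table file not found: ", path, call. = FALSE)
  }
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  stiffness_table(x, source_label = source_label, tol = tol)
}

#' Path to the stiffness table shipped with the package
#'
#' The shipped table is a synthetic stand-in with physically plausible
#' magnitudes (see its header comments); published force-constant sets
#' distributed alongside deformability-based predictors can be dropped in
#' via [load_stiffness_table()].
#'
#' @return file path of the packaged TSV.
#' @export
default_stiffness_path <- function() {
  system.file("extdata", "stiffness_synthetic.tsv", package = "prostar",
              mustWork = TRUE)
}

# 16 x 6 numeric matrix view, rownames = steps; the fast-path representation
.stiffness_matrix <- function(table) {
  stopifnot(inherits(table, "stiffness_table"))
  m <- as.matrix(table[, .channels])
  rownames(m) <- table$step
  m
}

# provenance fingerprint tying trained models to the parameter set used
.table_checksum <- function(table) {
  m <- .stiffness_matrix(table)
  rlang::hash(list(round(unname(m), 12), .channels))
}

#' @export
print.stiffness_table <- function(x, ...) {
  cat("Dinucleotide stiffness table (", attr(x, "source_label"), ")\n",
      sep = "")
  NextMethod()
}
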