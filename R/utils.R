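# Shared internals: alphabet constants, reverse complement, seeded evaluation.

# canonical channel order, frozen across the whole package and all file headers
.channels <- c("twist", "tilt", "roll", "shift", "slide", "rise")
.bases <- c("A", "C", "G", "T")
.steps <- as.vector(outer(.bases, .bases, paste0))

#' Reverse complement of a DNA string, preserving case
#'
#' Soft-masking (lowercase) marks repeats, so complementation must keep case.
#' Ambiguity codes other than N are passed through N-complemented as N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

.revcomp_step <- function(step) {
  chartr("ACGT", "TGCA", paste0(substr(step, 2, 2), substr(step, 1, 1)))
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream; all generators route their randomness through this.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
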