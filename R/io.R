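# Readers/writers for the standard interchange formats. FASTA goes through
# Biostrings (BStringSet so soft-mask lowercase survives); the tabular
# formats (BED/bedGraph/TSV) through readr.

#' Read / write FASTA
#'
#' Sequences are handled as a named character vector; case is preserved so
#' soft-masking (lowercase repeats) reaches the repeat filter intact.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param genome named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file as a tibble
#'
#' BED3+ with optional `name`, `score`, `strand` columns; coordinates stay
#' 0-based half-open.
#'
#' @param path BED file path.
#' @return tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  names(x) <- cols[seq_len(min(ncol(x), 6L))]
  x
}

#' Read tag 5'-ends from BED6
#'
#' The record's biological 5'-end (start for `+`, `end - 1` for `-`)
#' becomes the tag position; the BED name column, when present, is taken
#' as the cell-line label.
#'
#' @param path BED6 file path.
#' @return tag tibble `chrom`, `pos`, `strand`, `cell_line`.
#' @export
read_tags_bed <- function(path) {
  x <- read_bed(path)
  if (!"strand" %in% names(x)) {
    stop("tag BED must have 6 columns (strand required)", call. = FALSE)
  }
  tibble::tibble(
    chrom = x$chrom,
    pos = as.integer(ifelse(x$strand == "+", x$start, x$end - 1L)),
    strand = x$strand,
    cell_line = if ("name" %in% names(x)) x$name else "all")
}

#' Read an annotated-TSS set from BED or GTF
#'
#' For BED records the TSS is the strand-aware 5'-end (start for `+`,
#' `end - 1` for `-`; start if unstranded). For GTF, `transcript` features
#' are used (all features if none are typed `transcript`).
#'
#' @param path BED or GTF/GFF path (format sniffed from the extension).
#' @return tibble `chrom`, `tss`, `strand`.
#' @export
read_tss_annotation <- function(path) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
    names(x)[1:7] <- c("chrom", "source", "feature", "start", "end",
                       "score", "strand")
    if (any(x$feature == "transcript")) {
      x <- x[x$feature == "transcript", , drop = FALSE]
    }
    # GTF is 1-based closed; convert the 5' end to 0-based
    tibble::tibble(
      chrom = x$chrom,
      tss = as.integer(ifelse(x$strand == "-", x$end - 1L, x$start - 1L)),
      strand = x$strand)
  } else {
    x <- read_bed(path)
    strand <- if ("strand" %in% names(x)) x$strand else "+"
    tibble::tibble(
      chrom = x$chrom,
      tss = as.integer(ifelse(strand == "-", x$end - 1L, x$start)),
      strand = strand)
  }
}

#' Write TSS calls as BED6
#'
#' One record per call, 1 bp wide at the predicted TSS; the BED score is
#' the comparative score scaled by 1000 and clipped to `[0, 1000]`.
#'
#' @param calls tibble from [call_tss()].
#' @param path output path.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- tibble::tibble(
    chrom = calls$chrom,
    start = calls$position,
    end = calls$position + 1L,
    name = sprintf("tss_%05d", seq_len(nrow(calls))),
    score = as.integer(pmin(pmax(round(1000 * calls$score), 0), 1000)),
    strand = calls$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write region tibbles as BED6
#'
#' @param regions region tibble from [make_regions()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$region_id, score = 0L, strand = regions$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write bedGraph tracks
#'
#' @param path bedGraph path (`chrom start end value`, 0-based half-open).
#' @return `read_bedgraph()`: tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  x[!grepl("^track", x$chrom), , drop = FALSE]
}

#' @rdname read_bedgraph
#' @param track tibble `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Export a windowed profile as per-channel bedGraph files
#'
#' Writes one bedGraph per stiffness channel for genome-browser
#' inspection, named `<prefix>.<channel>.bedgraph`.
#'
#' @param wp a `windowed_profile` from [window_average()].
#' @param prefix output path prefix.
#' @param chrom chromosome name to stamp on the records.
#' @return the written paths, invisibly.
#' @export
write_windowed_bedgraph <- function(wp, prefix, chrom = "chr") {
  paths <- vapply(.channels, function(ch) {
    p <- sprintf("%s.%s.bedgraph", prefix, ch)
    keep <- wp$valid
    write_bedgraph(tibble::tibble(chrom = chrom,
                                  start = wp$start[keep],
                                  end = wp$end[keep],
                                  value = wp[[ch]][keep]), p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Read a feature incidence table from TSV
#'
#' @param path TSV with columns `feature`, `a`, `b`, `c`, `d`.
#' @return an incidence tibble for [enrich_all()].
#' @export
read_incidence <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("feature", "a", "b", "c", "d")
  if (!all(need %in% names(x))) {
    stop("incidence TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x[, need]
}
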