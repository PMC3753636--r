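#' Deduplicate tag 5'-ends
#'
#' Collapses CAGE/RNA-seq tag records to distinct 5'-ends: one record per
#' (chromosome, position, strand) within each cell line. Removing this
#' redundancy avoids counting reverse-transcriptase/PCR amplification
#' artifacts as independent transcription-start evidence. Malformed records
#' (missing or negative positions, strand outside `+`/`-`) are dropped with
#' a warning.
#'
#' @param tags tibble with columns `chrom`, `pos` (0-based 5'-end bp),
#'   `strand`, and optionally `cell_line`.
#' @return the deduplicated tibble; the number of duplicates removed is
#'   reported via `message()`.
#' @export
dedupe_5prime <- function(tags) {
  stopifnot(is.data.frame(tags))
  if (!"cell_line" %in% names(tags)) tags$cell_line <- "all"
  ok <- !is.na(tags$chrom) & !is.na(tags$pos) & tags$pos >= 0 &
    tags$strand %in% c("+", "-")
  if (any(!ok)) {
    warning(sum(!ok), " malformed tag record(s) skipped", call. = FALSE)
    tags <- tags[ok, , drop = FALSE]
  }
  out <- dplyr::distinct(tags, .data$chrom, .data$pos, .data$strand,
                         .data$cell_line, .keep_all = TRUE)
  removed <- nrow(tags) - nrow(out)
  if (removed > 0) message(removed, " duplicate 5'-end(s) removed")
  out
}

#' Distance of tag 5'-ends from region 5'-ends
#'
#' A tag matches a region when its 5'-end lies inside the half-open
#' interval `[start, end)` AND on the same strand as the region. The
#' distance is measured from the region's biological 5' end (plus strand:
#' `start`; minus strand: `end - 1`), so it always lies in
#' `0 .. length - 1` and increases 5'->3' along the region's strand.
#' Non-matching tags are simply absent from the result.
#'
#' @param tags tag tibble (`chrom`, `pos`, `strand`, optional `cell_line`).
#' @param regions region tibble from [make_regions()].
#' @return a tibble with one row per matched (tag, region) pair:
#'   `region_id`, `chrom`, `pos`, `strand`, `cell_line`, `distance`.
#' @export
tag_distance <- function(tags, regions) {
  stopifnot(is.data.frame(tags), is.data.frame(regions))
  if (!"cell_line" %in% names(tags)) tags$cell_line <- "all"
  hits <- dplyr::inner_join(
    dplyr::select(tags, "chrom", "pos", "strand", "cell_line"),
    dplyr::select(regions, "region_id", "chrom", "start", "end",
                  region_strand = "strand"),
    by = "chrom", relationship = "many-to-many")
  hits <- dplyr::filter(hits,
                        .data$pos >= .data$start, .data$pos < .data$end,
                        .data$strand == .data$region_strand)
  dplyr::transmute(hits,
                   region_id = .data$region_id,
                   chrom = .data$chrom,
                   pos = .data$pos,
                   strand = .data$strand,
                   cell_line = .data$cell_line,
                   distance = ifelse(.data$strand == "+",
                                     .data$pos - .data$start,
                                     (.data$end - 1L) - .data$pos))
}

#' Percent-distance bin of a 5'-end distance
#'
#' Regions are partitioned into `n_bins` (default 100) equal "percent
#' distance" bins. Bins are left-open right-closed multiples of the bin
#' width `w = region_length / n_bins`, with distance 0 assigned to bin 1:
#' `bin = max(1, ceiling(distance / w))`. This is the one convention under
#' which a 1000-bp distance falls in bin 84 of a 1200-bp region, 750 bp in
#' bin 63, and 1000 bp in bin 50 of a 2000-bp region -- simultaneously.
#' If `region_length` is not divisible by `n_bins` the last bin absorbs the
#' remainder (reported via `message()`).
#'
#' @param distance bp distance(s) from the region 5'-end, in
#'   `0 .. region_length - 1`.
#' @param region_length region length in bp.
#' @param n_bins number of bins (default 100).
#' @return integer bin index/indices in `1 .. n_bins`.
#' @examples
#' bin_index(1000, 1200)  # 84
#' bin_index(1000, 2000)  # 50
#' bin_index(750, 1200)   # 63
#' @export
bin_index <- function(distance, region_length, n_bins = 100L) {
  stopifnot(region_length >= n_bins, n_bins >= 1)
  if (any(distance < 0 | distance >= region_length)) {
    stop("distance out of range [0, region_length)", call. = FALSE)
  }
  if (region_length %% n_bins != 0) {
    message("region_length not divisible by n_bins; last bin absorbs the remainder")
  }
  w <- region_length %/% n_bins
  pmin.int(as.integer(n_bins), pmax.int(1L, as.integer(ceiling(distance / w))))
}

#' Accumulate a strand-aware distance-bin profile
#'
#' For every matched (region, distinct tag 5'-end) pair, increments the
#' percent-distance bin of the tag's distance from the region 5'-end.
#' Profiles are kept separate per cell line; counts are raw increments
#' (`n_matched` records the total so per-region normalisation can be
#' applied downstream if wanted).
#'
#' @param regions region tibble; all regions must share one length.
#' @param tags deduplicated tag tibble (see [dedupe_5prime()]).
#' @param n_bins number of percent-distance bins.
#' @return a tibble of class `bin_profile` with columns `cell_line`, `bin`,
#'   `bp_lo`, `bp_hi`, `count` (all `n_bins` bins present per cell line)
#'   and attributes `n_matched`, `region_length`, `n_regions`.
#' @export
accumulate_profile <- function(regions, tags, n_bins = 100L) {
  stopifnot(is.data.frame(regions), nrow(regions) > 0)
  lens <- unique(regions$end - regions$start)
  if (length(lens) != 1) {
    stop("mixed region lengths: all regions in a profile must share one length",
         call. = FALSE)
  }
  region_length <- lens
  hits <- tag_distance(tags, regions)
  w <- region_length %/% n_bins
  grid <- tidyr::expand_grid(
    cell_line = if (nrow(hits) > 0) sort(unique(hits$cell_line)) else
      if ("cell_line" %in% names(tags) && nrow(tags) > 0)
        sort(unique(tags$cell_line)) else "all",
    bin = seq_len(n_bins))
  counted <- if (nrow(hits) > 0) {
    hits |>
      dplyr::mutate(bin = bin_index(.data$distance, region_length, n_bins)) |>
      dplyr::count(.data$cell_line, .data$bin, name = "count")
  } else {
    tibble::tibble(cell_line = character(0), bin = integer(0),
                   count = integer(0))
  }
  out <- grid |>
    dplyr::left_join(counted, by = c("cell_line", "bin")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      bp_lo = (.data$bin - 1L) * w,
      bp_hi = ifelse(.data$bin == n_bins, region_length, .data$bin * w)) |>
    dplyr::select("cell_line", "bin", "bp_lo", "bp_hi", "count")
  attr(out, "n_matched") <- nrow(hits)
  attr(out, "region_length") <- region_length
  attr(out, "n_regions") <- nrow(regions)
  attr(out, "n_bins") <- as.integer(n_bins)
  class(out) <- c("bin_profile", class(out))
  out
}

#' Re-locate region TSSs and rebuild expanded regions
#'
#' Shifts every region's TSS by `offset_bp` along its own strand (negative
#' = upstream) and rebuilds the 2000-bp expanded region centred on the new
#' TSS. Used to test whether the tag signal re-centres when predictions are
#' suspected of sitting downstream of the true start: with a -500 bp shift,
#' a tag peak previously at bin ~25 of the 2000-bp profile moves to bin
#' ~50, i.e. onto the expected TSS bin.
#'
#' @param regions region tibble carrying `tss` and `strand`.
#' @param offset_bp signed shift in bp along the region strand
#'   (default -500, i.e. 500 bp upstream).
#' @param genome optional named character vector (or named lengths) used to
#'   truncate shifted regions at chromosome edges.
#' @return a new `expanded_2000` region tibble centred on the shifted TSSs.
#' @export
relocate_tss <- function(regions, offset_bp = -500, genome = NULL) {
  stopifnot(is.data.frame(regions), all(c("tss", "strand") %in% names(regions)))
  lens <- NULL
  if (!is.null(genome)) {
    lens <- if (is.numeric(genome)) genome else nchar(genome)
  }
  shifted <- dplyr::mutate(
    regions,
    tss = .data$tss + ifelse(.data$strand == "+", offset_bp, -offset_bp))
  make_regions(dplyr::select(shifted, -dplyr::any_of(c("start", "end", "role",
                                                       "truncated"))),
               role = "expanded_2000", genome_lengths = lens)
}
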