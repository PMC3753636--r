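#' Mean per-base signal of a track over regions
#'
#' Averages a piecewise-constant signal track (bedGraph-style intervals)
#' over each region: the sum of per-base values divided by the region
#' length. Bases not covered by any track interval contribute 0 -- the
#' convention used when averaging basewise conservation or intensity over
#' a fixed-length region. Track intervals must be sorted and
#' non-overlapping per chromosome; a region on a contig absent from the
#' track is an error (a contig with no signal should carry explicit or
#' implicit zero coverage, not be missing).
#'
#' @param track tibble with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open; see [read_bedgraph()]).
#' @param regions region tibble (`chrom`, `start`, `end`).
#' @return `regions` with an added `mean_signal` column.
#' @export
mean_region_signal <- function(track, regions) {
  stopifnot(is.data.frame(track), is.data.frame(regions),
            all(c("chrom", "start", "end", "value") %in% names(track)))
  missing_contig <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(missing_contig) > 0) {
    stop("region contig(s) absent from track: ",
         paste(missing_contig, collapse = ", "), call. = FALSE)
  }
  mean_signal <- purrr::map_dbl(seq_len(nrow(regions)), function(i) {
    tr <- track[track$chrom == regions$chrom[i], , drop = FALSE]
    ov <- pmax(0, pmin(tr$end, regions$end[i]) - pmax(tr$start, regions$start[i]))
    sum(ov * tr$value) / (regions$end[i] - regions$start[i])
  })
  dplyr::mutate(regions, mean_signal = mean_signal)
}

#' Average number of clusters overlapping the regions
#'
#' Counts, for each region, the clusters (e.g. DNase I hypersensitivity
#' clusters) whose half-open interval intersects it in at least 1 bp, and
#' returns the mean count per region. Overlap detection uses interval
#' trees ([IRanges::findOverlaps()]).
#'
#' @param clusters tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @param regions region tibble.
#' @param per_region if `TRUE`, return the per-region count tibble instead
#'   of the summary mean.
#' @return mean clusters per region (scalar), or a tibble with an
#'   `n_clusters` column when `per_region = TRUE`.
#' @export
count_overlapping_clusters <- function(clusters, regions, per_region = FALSE) {
  stopifnot(is.data.frame(clusters), is.data.frame(regions))
  n <- integer(nrow(regions))
  if (nrow(clusters) > 0 && nrow(regions) > 0) {
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      cl <- clusters[clusters$chrom == ch, , drop = FALSE]
      if (nrow(cl) == 0) next
      # half-open [start, end) -> closed 1-based [start + 1, end]
      q <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
      s <- IRanges::IRanges(cl$start + 1L, cl$end)
      n[ri] <- IRanges::countOverlaps(q, s, minoverlap = 1L)
    }
  }
  if (per_region) return(dplyr::mutate(regions, n_clusters = n))
  if (nrow(regions) == 0) return(0)
  mean(n)
}

#' Fraction of regions exceeding a signal threshold in any cell line
#'
#' A region qualifies when its summarised signal (e.g. average alignment
#' density of a histone mark) strictly exceeds `threshold` in at least one
#' cell line; the statistic is the fraction of qualifying regions.
#' Reference settings in practice are thresholds of 10 and 50.
#'
#' @param signals tibble with columns `region_id`, `cell_line`, `value`.
#' @param threshold signal threshold (strict inequality).
#' @return fraction of qualifying regions, in `[0, 1]`.
#' @export
fraction_above_threshold <- function(signals, threshold) {
  stopifnot(is.data.frame(signals),
            all(c("region_id", "value") %in% names(signals)))
  if (nrow(signals) == 0) stop("empty region set", call. = FALSE)
  per_region <- signals |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(qualifies = any(.data$value > threshold),
                     .groups = "drop")
  mean(per_region$qualifies)
}
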