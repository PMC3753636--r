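#' Scan a genome for promoter-like physical profiles
#'
#' Slides the TSS-relative grid along every chromosome on both strands and,
#' at each candidate position, measures the Mahalanobis distance of the
#' local stiffness feature vector to the promoter and background reference
#' profiles. The comparative score is `d_background - d_promoter`: positive
#' when the local physics looks more promoter-like than background-like.
#' A position is labelled `"promoter"` iff its score is strictly positive
#' (a tie is conservatively `"background"`); positions whose grid overlaps
#' invalid windows (masked steps, chromosome edges) are emitted as
#' `"no_call"` with NA distances.
#'
#' @param genome named character vector of chromosome sequences (or a FASTA
#'   path, read with [read_fasta()]).
#' @param table the [stiffness_table] both references were trained with.
#' @param ref_promoter,ref_background the two [build_reference_profile()]
#'   objects; they must share the grid and the table checksum.
#' @param stride candidate spacing in bp (default 50).
#' @param min_valid minimum valid-step fraction per grid window.
#' @return a tibble with columns `chrom`, `position`, `strand`,
#'   `d_promoter`, `d_background`, `score`, `label`, ordered by chromosome,
#'   position, strand.
#' @export
scan_genome <- function(genome, table, ref_promoter, ref_background,
                        stride = 50, min_valid = 0.9) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  stopifnot(inherits(ref_promoter, "reference_profile"),
            inherits(ref_background, "reference_profile"))
  if (!identical(ref_promoter$grid, ref_background$grid)) {
    stop("promoter and background references use different grids",
         call. = FALSE)
  }
  if (!identical(ref_promoter$table_checksum, ref_background$table_checksum)) {
    stop("reference profiles were trained with different stiffness tables",
         call. = FALSE)
  }
  if (!identical(ref_promoter$table_checksum, .table_checksum(table))) {
    stop("stiffness table does not match the one the references were trained with",
         call. = FALSE)
  }
  grid <- ref_promoter$grid
  out <- purrr::map(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    if (nchar(seq) < 2) return(NULL)
    idx <- .profile_index(step_series(seq, table))
    positions <- seq.int(0L, nchar(seq) - 1L, by = as.integer(stride))
    purrr::map(c("+", "-"), function(strand) {
      gf <- .grid_features(idx, positions, strand, grid,
                           min_valid = min_valid)
      dp <- db <- rep(NA_real_, length(positions))
      if (any(gf$valid)) {
        dp[gf$valid] <- mahalanobis_dist(gf$features[gf$valid, , drop = FALSE],
                                         ref_promoter)
        db[gf$valid] <- mahalanobis_dist(gf$features[gf$valid, , drop = FALSE],
                                         ref_background)
      }
      score <- db - dp
      tibble::tibble(
        chrom = chrom, position = positions, strand = strand,
        d_promoter = dp, d_background = db, score = score,
        label = dplyr::case_when(
          !gf$valid ~ "no_call",
          score > 0 ~ "promoter",
          TRUE ~ "background"
        ))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- dplyr::arrange(out, .data$chrom, .data$position, .data$strand)
  attr(out, "stride") <- as.integer(stride)
  class(out) <- c("score_track", class(out))
  out
}

#' Call TSSs from a score track
#'
#' Greedy non-maximum suppression over the scanner's score track: local
#' score maxima (per chromosome and strand) exceeding `tau` are visited in
#' decreasing score order (ties broken by leftmost coordinate) and accepted
#' unless within `min_separation` bp of an already accepted call on the
#' same chromosome. The default separation matches the 1200-bp isolation
#' used when selecting candidate TSSs for experimental testing.
#'
#' Because the comparative score rewards placements that centre
#' promoter-like material in the (asymmetric) grid, its maximum can sit
#' slightly upstream of the best-matching TSS alignment. Each accepted
#' call is therefore refined: within `refine_radius` bp of the score peak
#' (same chromosome and strand) the position is moved to the minimum of
#' `d_promoter`, the point where the local profile best matches the
#' promoter reference.
#'
#' @param scores a tibble from [scan_genome()].
#' @param tau score threshold; only local maxima with `score > tau` are
#'   considered.
#' @param min_separation suppression radius in bp (calls exactly
#'   `min_separation` apart are both kept).
#' @param refine_radius search radius (bp) for the `d_promoter` refinement;
#'   0 disables it.
#' @return a tibble of accepted calls (`chrom`, `position`, `strand`,
#'   `d_promoter`, `d_background`, `score`, `label`) sorted by position.
#' @export
call_tss <- function(scores, tau = 0, min_separation = 1200,
                     refine_radius = 400) {
  stopifnot(is.data.frame(scores), tau >= -Inf, min_separation >= 0)
  cand <- scores |>
    dplyr::filter(.data$label != "no_call") |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(
      is_max = .data$score >= dplyr::lag(.data$score, default = -Inf) &
               .data$score >= dplyr::lead(.data$score, default = -Inf)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$is_max, .data$score > tau) |>
    dplyr::select(-"is_max") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$chrom, .data$position,
                   .data$strand)
  kept <- logical(nrow(cand))
  acc_pos <- split(numeric(0), character(0))   # per-chrom accepted positions
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    p <- cand$position[i]
    near <- acc_pos[[ch]]
    if (is.null(near) || all(abs(near - p) >= min_separation)) {
      kept[i] <- TRUE
      acc_pos[[ch]] <- c(near, p)
    }
  }
  out <- cand[kept, , drop = FALSE]
  if (refine_radius > 0 && nrow(out) > 0) {
    callable <- dplyr::filter(scores, .data$label != "no_call")
    out <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
      near <- callable[callable$chrom == out$chrom[i] &
                         callable$strand == out$strand[i] &
                         abs(callable$position - out$position[i]) <=
                           refine_radius, , drop = FALSE]
      near[which.min(near$d_promoter), , drop = FALSE]
    })
  }
  dplyr::arrange(out, .data$chrom, .data$position, .data$strand)
}

#' Apply the candidate-selection filters
#'
#' Reproduces the two sequence-level filters used to build the
#' high-confidence candidate set: a call must lie at least
#' `min_tss_distance` bp (default 1200) from every annotated TSS
#' (position-to-position, strand-ignored), and the repeat-masked fraction
#' of its 1200-bp tested region must not exceed `max_repeat_fraction`
#' (strictly more than 70% repetitive is rejected). Repeat content is read
#' from soft-masking (lowercase) in `genome`, or from an explicit `mask`
#' BED-like table of masked intervals.
#'
#' @param calls tibble of calls from [call_tss()].
#' @param annotation tibble of annotated TSSs with columns `chrom`, `tss`
#'   (see [read_tss_annotation()]).
#' @param genome named character vector of (soft-masked) chromosome
#'   sequences.
#' @param min_tss_distance minimum distance to any annotated TSS, bp.
#' @param max_repeat_fraction maximum tolerated masked fraction of the
#'   tested region.
#' @param mask optional tibble (`chrom`, `start`, `end`) of masked
#'   intervals, used instead of lowercase when supplied.
#' @return `calls` with added columns `tss_distance`, `repeat_fraction`,
#'   `kept`, `reject_reason` (NA when kept).
#' @export
filter_candidates <- function(calls, annotation, genome,
                              min_tss_distance = 1200,
                              max_repeat_fraction = 0.70, mask = NULL) {
  if (is.null(annotation)) stop("annotation is required", call. = FALSE)
  stopifnot(is.data.frame(calls), is.data.frame(annotation),
            all(c("chrom", "tss") %in% names(annotation)))
  regions <- make_regions(calls, role = "tested_1200",
                          genome_lengths = nchar(genome))
  tss_distance <- purrr::map_dbl(seq_len(nrow(calls)), function(i) {
    ann <- annotation$tss[annotation$chrom == calls$chrom[i]]
    if (length(ann) == 0) Inf else min(abs(ann - calls$position[i]))
  })
  repeat_fraction <- purrr::map_dbl(seq_len(nrow(regions)), function(i) {
    .masked_fraction(genome, regions$chrom[i], regions$start[i],
                     regions$end[i], mask = mask)
  })
  reject_reason <- dplyr::case_when(
    tss_distance < min_tss_distance ~ "too_close",
    repeat_fraction > max_repeat_fraction ~ "repeat_fraction",
    TRUE ~ NA_character_
  )
  dplyr::mutate(calls,
                tss_distance = tss_distance,
                repeat_fraction = repeat_fraction,
                kept = is.na(reject_reason),
                reject_reason = reject_reason)
}

.masked_fraction <- function(genome, chrom, start, end, mask = NULL) {
  len <- end - start
  if (len <= 0) return(0)
  if (!is.null(mask)) {
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    if (nrow(m) == 0) return(0)
    ov <- pmax(0, pmin(m$end, end) - pmax(m$start, start))
    return(sum(ov) / len)
  }
  seq <- substr(genome[[chrom]], start + 1L, end)
  mean(strsplit(seq, "", fixed = TRUE)[[1]] %in% letters)
}

#' Build candidate regions around called TSSs
#'
#' Three region roles are used downstream, all strand-aware ("upstream"
#' follows the call strand):
#' * `core_promoter` -- the -1000/+200 bp window around the predicted TSS
#'   (plus strand: `[tss - 1000, tss + 200)`; minus strand mirrored).
#' * `tested_1200` -- the same 1200-bp extent, i.e. the amplicon actually
#'   assayed; the TSS sits 1000 bp from the region's biological 5' end.
#' * `expanded_2000` -- `tss +/- 1000`, the 2000-bp window centred on the
#'   TSS used for expanded tag profiling.
#'
#' Regions that would run off a chromosome are truncated and flagged.
#'
#' @param calls tibble with columns `chrom`, `position` (or `tss`) and
#'   `strand`.
#' @param role one of `"core_promoter"`, `"tested_1200"`, `"expanded_2000"`.
#' @param genome_lengths optional named vector of chromosome lengths used
#'   for truncation.
#' @return a region tibble: `region_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `role`, `truncated`.
#' @export
make_regions <- function(calls, role = c("core_promoter", "tested_1200",
                                         "expanded_2000"),
                         genome_lengths = NULL) {
  role <- match.arg(role)
  stopifnot(is.data.frame(calls))
  tss <- if ("tss" %in% names(calls)) calls$tss else calls$position
  strand <- calls$strand
  plus <- strand == "+"
  if (role == "expanded_2000") {
    start <- tss - 1000L
    end <- tss + 1000L
  } else {
    start <- ifelse(plus, tss - 1000L, tss - 200L)
    end <- ifelse(plus, tss + 200L, tss + 1000L)
  }
  truncated <- start < 0
  start <- pmax(start, 0L)
  if (!is.null(genome_lengths)) {
    lens <- unname(genome_lengths[calls$chrom])
    truncated <- truncated | end > lens
    end <- pmin(end, lens)
  }
  if (any(truncated)) {
    warning(sum(truncated), " region(s) truncated at chromosome edges",
            call. = FALSE)
  }
  tibble::tibble(
    region_id = if ("region_id" %in% names(calls)) calls$region_id else
      sprintf("%s:%d:%s", calls$chrom, tss, strand),
    chrom = calls$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    tss = as.integer(tss),
    role = role,
    truncated = truncated
  )
}
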