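# Seeded generators producing every input the pipeline consumes, with known
# ground truth. All randomness is drawn under with_seed(), so identical
# seeds give byte-identical artifacts.

#' Generate a random, valid stiffness table
#'
#' Draws strictly positive force constants with reverse-complement symmetry
#' imposed, at physically plausible magnitudes: rotational channels (twist,
#' tilt, roll) in 0.01-0.06 kcal/(mol.deg^2), translational channels
#' (shift, slide, rise) in 0.5-3 kcal/(mol.A^2). Used throughout the test
#' suite so no externally published parameter set is ever required.
#'
#' @param seed integer RNG seed.
#' @return a [stiffness_table].
#' @export
gen_stiffness_table <- function(seed) {
  with_seed(seed, {
    unique_steps <- .steps[.steps <= vapply(.steps, .revcomp_step,
                                            character(1))]
    rot <- matrix(stats::runif(3 * length(unique_steps), 0.01, 0.06),
                  ncol = 3)
    trans <- matrix(stats::runif(3 * length(unique_steps), 0.5, 3),
                    ncol = 3)
    x <- data.frame(step = unique_steps, rot, trans)
    names(x) <- c("step", .channels)
    stiffness_table(x, source_label = sprintf("synthetic (seed %d)", seed))
  })
}

# --- first-order Markov machinery -----------------------------------------

# background chain: AT-rich with CpG depletion, loosely mimicking bulk
# vertebrate genomic composition
.bg_transition <- function() {
  f <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  p <- matrix(rep(f, each = 4), 4, 4, dimnames = list(.bases, .bases))
  p["C", "G"] <- p["C", "G"] * 0.25   # CpG depletion
  p / rowSums(p)
}

# promoter-like core target chain: GC-rich, no CpG depletion
.target_transition <- function() {
  f <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
  matrix(rep(f, each = 4), 4, 4, dimnames = list(.bases, .bases))
}

# downstream tail target chain: background base frequencies but CpG-enriched,
# i.e. distinct from background in dinucleotide structure only
.tail_transition <- function() {
  f <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  p <- matrix(rep(f, each = 4), 4, 4, dimnames = list(.bases, .bases))
  p["C", "G"] <- p["C", "G"] * 4
  p / rowSums(p)
}

.markov_stationary <- function(p) {
  e <- eigen(t(p))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  v / sum(v)
}

# expected per-step 6-vector under the chain's stationary dinucleotide law
.expected_step_mean <- function(p, mat) {
  pi0 <- .markov_stationary(p)
  f <- pi0 * p                       # f[x, y] = P(step x->y)
  steps <- as.vector(outer(.bases, .bases, paste0))   # column-major: x varies fastest
  w <- as.vector(f)
  colSums(mat[steps, , drop = FALSE] * w)
}

.markov_seq <- function(n, p, lower = FALSE) {
  pi0 <- .markov_stationary(p)
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(n)
  idx <- integer(n)
  idx[1] <- findInterval(u[1], cumsum(pi0)) + 1L
  for (i in 2:n) idx[i] <- findInterval(u[i], cum[idx[i - 1L], ]) + 1L
  s <- paste(.bases[idx], collapse = "")
  if (lower) tolower(s) else s
}

# Calibrate the mixing weight w between background and target chains so the
# expected window-mean profiles of the two classes differ by
# `promoter_effect`, measured as the per-channel-standardised Euclidean
# distance (channel SDs estimated from `sd_windows` simulated background
# windows). Caps at w = 1 with a warning when the requested effect exceeds
# what the pure target composition provides.
.promoter_mixture <- function(table, promoter_effect, window_length = 500,
                              sd_windows = 200) {
  mat <- .stiffness_matrix(table)
  p_bg <- .bg_transition()
  p_t <- .target_transition()
  wins <- t(vapply(seq_len(sd_windows), function(i) {
    prof <- step_series(.markov_seq(window_length, p_bg), table)
    colMeans(as.matrix(prof[, .channels]))
  }, numeric(6)))
  sds <- pmax(apply(wins, 2, stats::sd), 1e-12)
  m_bg <- .expected_step_mean(p_bg, mat)
  effect_of <- function(w) {
    m_w <- .expected_step_mean((1 - w) * p_bg + w * p_t, mat)
    sqrt(sum(((m_w - m_bg) / sds)^2))
  }
  if (promoter_effect <= 0) {
    return(list(w = 0, achieved_effect = 0, channel_sd = sds))
  }
  e_max <- effect_of(1)
  if (e_max < promoter_effect) {
    warning(sprintf(
      "requested promoter_effect %.2f exceeds the maximum %.2f for this table; using the pure target composition",
      promoter_effect, e_max), call. = FALSE)
    return(list(w = 1, achieved_effect = e_max, channel_sd = sds))
  }
  w <- stats::uniroot(function(w) effect_of(w) - promoter_effect,
                      c(0, 1), tol = 1e-6)$root
  list(w = w, achieved_effect = effect_of(w), channel_sd = sds)
}

# A planted promoter span is spatially structured: a "core" segment around
# the TSS mixed toward the GC-rich core target, then a downstream segment
# mixed (same weight) toward the CpG-enriched tail target, so the two
# segments differ in profile direction and two composition boundaries must
# align with the grid simultaneously. The along-span asymmetry is what
# makes plants directional:
# with a reverse-complement-symmetric stiffness table, a compositionally
# homogeneous block would have a strand-symmetric expected profile and the
# scanner could never recover strand (or sharp position).
.plant_seq <- function(w, core_len = 500L, down_len = 650L) {
  p_bg <- .bg_transition()
  core <- .markov_seq(core_len, (1 - w) * p_bg + w * .target_transition())
  down <- .markov_seq(down_len, (1 - w) * p_bg + w * .tail_transition())
  paste0(core, down)
}

#' Generate a synthetic genome with planted promoter-profile regions
#'
#' Background sequence is drawn from a first-order Markov chain (AT-rich,
#' CpG-depleted); each planted promoter replaces the -250/+900 bp span
#' around its TSS (strand-aware) with structured sequence: a 500-bp core
#' segment (-250/+250) from a chain mixed toward a GC-rich promoter-like
#' composition, then a 650-bp downstream segment mixed (at the same
#' weight) toward a CpG-enriched tail composition. The spatial asymmetry
#' makes plants directional, so strand is identifiable. The mixing weight
#' is calibrated so
#' that the expected 500-bp window-mean stiffness profile of planted spans
#' differs from background by `promoter_effect`, expressed in units of the
#' background window-mean standard deviation (per-channel standardised
#' Euclidean distance); the achieved effect is recorded on the truth table.
#' With `promoter_effect = 0` the plants are background-composed, so any
#' classifier should perform at chance. Optional soft-masked (lowercase)
#' decoy stretches exercise the repeat filter.
#'
#' @param seed integer RNG seed.
#' @param table [stiffness_table] the effect size is calibrated against.
#' @param genome_length chromosome length in bp.
#' @param n_promoters number of planted TSSs.
#' @param promoter_effect target class separation (see above).
#' @param n_decoys,decoy_length number and length of lowercase decoy
#'   stretches inserted into background sequence.
#' @param chrom chromosome name of the single synthetic contig.
#' @return a list: `genome` (named character vector), `truth` (tibble
#'   `chrom`, `tss`, `strand` with attributes `mixture_weight` and
#'   `achieved_effect`).
#' @export
gen_genome <- function(seed, table, genome_length = 100000,
                       n_promoters = 20, promoter_effect = 16,
                       n_decoys = 0, decoy_length = 900, chrom = "chrS") {
  span_lo <- -250L
  span_hi <- 900L
  span_len <- span_hi - span_lo            # 1150
  slot <- genome_length %/% n_promoters
  if (slot < span_len + 2400) {
    stop("plants don't fit: need >= ", (span_len + 2400) * n_promoters,
         " bp for ", n_promoters, " promoters", call. = FALSE)
  }
  with_seed(seed, {
    mix <- .promoter_mixture(table, promoter_effect)
    p_bg <- .bg_transition()
    seq <- .markov_seq(genome_length, p_bg)
    jitter_max <- (slot - span_len - 2400) %/% 2
    tss <- as.integer((seq_len(n_promoters) - 1L) * slot + slot %/% 2 +
                        sample(-min(jitter_max, 400):min(jitter_max, 400),
                               n_promoters, replace = TRUE))
    strand <- sample(c("+", "-"), n_promoters, replace = TRUE)
    for (i in seq_len(n_promoters)) {
      insert <- .plant_seq(mix$w)
      if (strand[i] == "+") {
        a <- tss[i] + span_lo             # genomic [a, a + span_len)
      } else {
        insert <- revcomp(insert)
        a <- tss[i] - span_hi + 1L
      }
      substr(seq, a + 1L, a + span_len) <- insert
    }
    if (n_decoys > 0) {
      # drop decoys into background slack, away from planted spans
      for (i in seq_len(n_decoys)) {
        k <- sample(n_promoters, 1)
        a <- tss[k] + 1300L + sample(0:200, 1)
        b <- min(a + decoy_length, genome_length)
        if (b > a) {
          substr(seq, a + 1L, b) <- tolower(substr(seq, a + 1L, b))
        }
      }
    }
    genome <- stats::setNames(seq, chrom)
    truth <- tibble::tibble(chrom = chrom, tss = tss, strand = strand)
    attr(truth, "mixture_weight") <- mix$w
    attr(truth, "achieved_effect") <- mix$achieved_effect
    list(genome = genome, truth = truth)
  })
}

#' Generate class-labelled training sequences
#'
#' Draws isolated training examples for [build_reference_profile()]: each
#' is a sequence exactly covering the grid span around its TSS, composed
#' with the same structured core/downstream plant model as [gen_genome()]
#' (for class `"promoter"`, at the same calibrated effect size) or from
#' the background chain. Half
#' the examples are emitted antisense (sequence reverse-complemented, TSS
#' mirrored) to exercise the strand-aware extraction path.
#'
#' @param seed integer RNG seed.
#' @param table [stiffness_table].
#' @param n_examples number of training sequences.
#' @param class `"promoter"` or `"background"`.
#' @param promoter_effect effect size, as in [gen_genome()].
#' @param grid the [grid_spec()] the examples must cover.
#' @return a tibble with columns `seq`, `tss`, `strand`.
#' @export
gen_training_set <- function(seed, table, n_examples = 200,
                             class = c("promoter", "background"),
                             promoter_effect = 16, grid = grid_spec()) {
  class <- match.arg(class)
  span_len <- grid$span_end - grid$span_start
  core_len <- min(500L, span_len)
  with_seed(seed, {
    w <- if (class == "promoter") {
      .promoter_mixture(table, promoter_effect)$w
    } else {
      0
    }
    purrr::map_dfr(seq_len(n_examples), function(i) {
      s <- if (class == "promoter") {
        .plant_seq(w, core_len = core_len, down_len = span_len - core_len)
      } else {
        .markov_seq(span_len, .bg_transition())
      }
      if (i %% 2L == 0L) {
        # antisense presentation of the same span
        tibble::tibble(seq = revcomp(s),
                       tss = span_len - 1L - (-grid$span_start),
                       strand = "-")
      } else {
        tibble::tibble(seq = s, tss = -grid$span_start, strand = "+")
      }
    })
  })
}

#' Generate synthetic tag 5'-ends over regions
#'
#' Emulates a CAGE/RNA-seq distinct-5'-end set: per region, a
#' `peak_weight` fraction of tags sits at `peak_offset` bp from the region
#' 5'-end (with optional Gaussian jitter), the remainder is uniform over
#' the region. Tags inherit the region strand except for a stated fraction
#' of opposite-strand decoys, which the strand-matching rule must discard.
#'
#' @param regions region tibble ([make_regions()]).
#' @param seed integer RNG seed.
#' @param tags_per_region tags drawn per region.
#' @param peak_offset peak distance from the region 5'-end, bp.
#' @param peak_weight fraction of tags at the peak, in `[0, 1]`.
#' @param jitter_sd SD (bp) of Gaussian jitter on peak tag positions.
#' @param opposite_strand_fraction fraction of tags flipped to the
#'   opposite strand.
#' @param cell_line label stamped on all records.
#' @return a tag tibble: `chrom`, `pos`, `strand`, `cell_line`.
#' @export
gen_tags <- function(regions, seed, tags_per_region = 50,
                     peak_offset = 1000, peak_weight = 0.8, jitter_sd = 0,
                     opposite_strand_fraction = 0,
                     cell_line = "synthetic") {
  stopifnot(is.data.frame(regions))
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      len <- regions$end[i] - regions$start[i]
      n_peak <- round(peak_weight * tags_per_region)
      d_peak <- peak_offset +
        if (jitter_sd > 0) round(stats::rnorm(n_peak, 0, jitter_sd)) else
          rep(0L, n_peak)
      d_peak <- pmin(pmax(d_peak, 0L), len - 1L)
      d_unif <- sample.int(len, tags_per_region - n_peak, replace = TRUE) - 1L
      d <- c(d_peak, d_unif)
      strand <- rep(regions$strand[i], length(d))
      n_flip <- round(opposite_strand_fraction * length(d))
      if (n_flip > 0) {
        j <- sample(length(d), n_flip)
        strand[j] <- ifelse(strand[j] == "+", "-", "+")
      }
      pos <- if (regions$strand[i] == "+") {
        regions$start[i] + d
      } else {
        regions$end[i] - 1L - d
      }
      tibble::tibble(chrom = regions$chrom[i], pos = as.integer(pos),
                     strand = strand, cell_line = cell_line)
    })
  })
}

#' Generate a feature-by-region incidence table with one planted feature
#'
#' Null features receive set counts drawn hypergeometrically around their
#' background rate (as if set regions were sampled from the background
#' pool); the planted feature's set count is inflated `fold`-fold.
#'
#' @param seed integer RNG seed.
#' @param m number of features.
#' @param planted_feature index of the enriched feature (1-based).
#' @param fold enrichment factor for the planted feature; 1 = null.
#' @param set_size number of regions in the tested set.
#' @param background_size number of background transcripts.
#' @param base_rate expected background incidence rate per feature.
#' @return an incidence tibble `feature`, `a`, `b`, `c`, `d` with
#'   attribute `planted` naming the enriched feature.
#' @export
gen_incidence <- function(seed, m = 50, planted_feature = 1, fold = 10,
                          set_size = 100, background_size = 1000,
                          base_rate = 0.1) {
  with_seed(seed, {
    cc <- stats::rbinom(m, background_size, base_rate)
    cc <- pmax(cc, 1L)                    # keep margins positive
    a <- vapply(seq_len(m), function(j) {
      if (j == planted_feature && fold != 1) {
        stats::rbinom(1, set_size, min(0.95, fold * cc[j] / background_size))
      } else {
        stats::rhyper(1, cc[j], background_size - cc[j], set_size)
      }
    }, numeric(1))
    out <- tibble::tibble(
      feature = sprintf("TF%03d", seq_len(m)),
      a = as.integer(a),
      b = as.integer(set_size - a),
      c = as.integer(cc),
      d = as.integer(background_size - cc))
    attr(out, "planted") <- sprintf("TF%03d", planted_feature)
    out
  })
}

#' Generate a piecewise-constant signal track
#'
#' Produces a bedGraph-style track of constant-value segments, the form
#' used for DNase/histone intensity and basewise conservation inputs.
#'
#' @param seed integer RNG seed.
#' @param chrom_lengths named vector of contig lengths.
#' @param segment_length segment size in bp (last segment truncated).
#' @param value_range uniform range the segment values are drawn from.
#' @return a track tibble `chrom`, `start`, `end`, `value`.
#' @export
gen_track <- function(seed, chrom_lengths, segment_length = 200,
                      value_range = c(0, 10)) {
  with_seed(seed, {
    purrr::map_dfr(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      starts <- seq.int(0L, len - 1L, by = segment_length)
      tibble::tibble(
        chrom = ch,
        start = as.integer(starts),
        end = as.integer(pmin(starts + segment_length, len)),
        value = stats::runif(length(starts), value_range[1], value_range[2]))
    })
  })
}
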