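test_that("deduplication keeps distinct (chrom, position, strand) per cell line", {
  raw <- tibble::tibble(chrom = "chr1",
                        pos = c(100L, 100L, 100L, 100L, 100L, 100L),
                        strand = c("+", "+", "+", "+", "+", "-"),
                        cell_line = "k")
  expect_message(out <- dedupe_5prime(raw), "4 duplicate")
  expect_equal(nrow(out), 2L)          # strand distinguishes
  expect_equal(nrow(dedupe_5prime(raw[0, ])), 0L)
  # same position in two cell lines is not a duplicate
  two <- raw[c(1, 2), ]
  two$cell_line <- c("k", "h")
  expect_equal(nrow(dedupe_5prime(two)), 2L)
  # malformed records dropped with a warning
  bad <- tibble::tibble(chrom = "chr1", pos = c(5L, -1L, NA),
                        strand = c("+", "+", "."), cell_line = "k")
  expect_warning(ok <- dedupe_5prime(bad), "malformed")
  expect_equal(nrow(ok), 1L)
})

test_that("tag distances are strand-matched and measured from the biological 5' end", {
  regions <- tibble::tibble(region_id = c("r+", "r-"), chrom = "chr1",
                            start = 0L, end = 1200L, strand = c("+", "-"),
                            tss = 1000L)
  tags <- tibble::tibble(chrom = "chr1", pos = c(1000L, 1000L, 199L, 1200L),
                         strand = c("+", "-", "-", "+"), cell_line = "k")
  hits <- tag_distance(tags, regions)
  plus_hits <- hits[hits$region_id == "r+", ]
  minus_hits <- hits[hits$region_id == "r-", ]
  # plus region: tag at 1000 on + matches at distance 1000; the same
  # position on - does not match the plus region
  expect_equal(plus_hits$pos, 1000L)
  expect_equal(plus_hits$distance, 1000L)
  # minus region: 5' end is end - 1 = 1199, so pos 199 lies 1000 bp along
  expect_true(199L %in% minus_hits$pos)
  expect_equal(minus_hits$distance[minus_hits$pos == 199L], 1000L)
  # pos 1200 is outside the half-open interval
  expect_false(1200L %in% hits$pos)
})

test_that("bin_index reconciles all printed geometry mappings simultaneously", {
  expect_equal(bin_index(1000, 1200, 100), 84L)
  expect_equal(bin_index(1000, 2000, 100), 50L)
  expect_equal(bin_index(750, 1200, 100), 63L)
  expect_equal(bin_index(0, 1200, 100), 1L)
  expect_equal(bin_index(1199, 1200, 100), 100L)
  expect_error(bin_index(1200, 1200, 100), "out of range")
  expect_error(bin_index(-1, 1200, 100), "out of range")
  # non-divisible lengths: last bin absorbs the remainder
  expect_message(b <- bin_index(1249, 1250, 100), "remainder")
  expect_equal(b, 100L)
})

test_that("profiles accumulate per matched pair and keep cell lines separate", {
  regions <- tibble::tibble(region_id = "r1", chrom = "c", start = 0L,
                            end = 1200L, strand = "+", tss = 1000L)
  # hand enumeration: distances 5, 14, 1195 -> bins 1, 2, 100
  tags <- tibble::tibble(chrom = "c", pos = c(5L, 14L, 1195L), strand = "+",
                         cell_line = "k")
  prof <- accumulate_profile(regions, tags)
  expect_equal(attr(prof, "n_matched"), 3L)
  expect_equal(prof$count[prof$bin == 1], 1L)
  expect_equal(prof$count[prof$bin == 2], 1L)
  expect_equal(prof$count[prof$bin == 100], 1L)
  expect_equal(sum(prof$count), 3L)
  # no matching tags: all-zero profile
  none <- accumulate_profile(regions,
                             tibble::tibble(chrom = "c", pos = 5L,
                                            strand = "-", cell_line = "k"))
  expect_equal(sum(none$count), 0L)
  expect_equal(attr(none, "n_matched"), 0L)
  # mixed region lengths are rejected
  r2 <- dplyr::bind_rows(regions,
                         tibble::tibble(region_id = "r2", chrom = "c",
                                        start = 0L, end = 2000L,
                                        strand = "+", tss = 1000L))
  expect_error(accumulate_profile(r2, tags), "mixed region lengths")
})

test_that("count conservation and shift/strand invariance hold on random inputs", {
  set.seed(55)
  for (rep in 1:10) {
    n_reg <- sample(2:5, 1)
    regions <- tibble::tibble(
      region_id = paste0("r", seq_len(n_reg)),
      chrom = "c",
      start = sort(sample.int(50000, n_reg)) + 0L,
      strand = sample(c("+", "-"), n_reg, replace = TRUE),
      tss = 0L)
    regions$end <- regions$start + 1200L
    tags <- tibble::tibble(
      chrom = "c",
      pos = sample.int(60000, 300) - 1L,
      strand = sample(c("+", "-"), 300, replace = TRUE),
      cell_line = sample(c("a", "b"), 300, replace = TRUE))
    prof <- accumulate_profile(regions, tags)
    hits <- tag_distance(tags, regions)
    expect_equal(sum(prof$count), nrow(hits))
    expect_equal(attr(prof, "n_matched"), nrow(hits))

    # translating everything by a constant leaves the profile unchanged
    shift <- 3171L
    regions2 <- dplyr::mutate(regions, start = start + shift,
                              end = end + shift)
    tags2 <- dplyr::mutate(tags, pos = pos + shift)
    prof2 <- accumulate_profile(regions2, tags2)
    expect_equal(prof$count, prof2$count)

    # reflecting regions and tags to the opposite strand around a fixed
    # genome mirror leaves the profile unchanged
    mirror <- 70000L
    regions3 <- dplyr::mutate(regions,
                              new_start = mirror - end,
                              end = mirror - start,
                              start = new_start,
                              strand = ifelse(strand == "+", "-", "+")) |>
      dplyr::select(-"new_start")
    tags3 <- dplyr::mutate(tags, pos = mirror - 1L - pos,
                           strand = ifelse(strand == "+", "-", "+"))
    prof3 <- accumulate_profile(regions3, tags3)
    expect_equal(prof$count, prof3$count)
  }
})

test_that("synthetic tag peaks land in the expected bin", {
  calls <- tibble::tibble(chrom = "c", position = c(5000L, 9000L),
                          strand = c("+", "-"))
  regions <- make_regions(calls, "tested_1200")
  tags <- gen_tags(regions, seed = 8, tags_per_region = 40,
                   peak_offset = 1000, peak_weight = 1, jitter_sd = 0)
  prof <- accumulate_profile(regions, tags)
  expect_equal(attr(prof, "n_matched"), 80L)
  expect_equal(sum(prof$count[prof$bin == 84]), 80L)
})

test_that("relocating the TSS shifts regions strand-awareness", {
  regions <- tibble::tibble(region_id = c("p", "m"), chrom = "c",
                            start = c(9000L, 9000L), end = c(11000L, 11000L),
                            strand = c("+", "-"), tss = 10000L)
  out <- relocate_tss(regions, offset_bp = -500)
  expect_equal(out$tss, c(9500L, 10500L))
  expect_equal(out$start[1], 8500L)
  expect_equal(out$end[1], 10500L)
  expect_equal(out$start[2], 9500L)
  expect_equal(out$end[2], 11500L)
  expect_true(all(out$end - out$start == 2000L))
})
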