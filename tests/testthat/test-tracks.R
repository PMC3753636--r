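test_that("mean_region_signal averages per-base values with zero for gaps", {
  regions <- tibble::tibble(region_id = "r", chrom = "c", start = 100L,
                            end = 300L, strand = "+")
  # constant coverage
  flat <- tibble::tibble(chrom = "c", start = 0L, end = 1000L, value = 2.5)
  expect_equal(mean_region_signal(flat, regions)$mean_signal, 2.5)
  # half at 2, half uncovered (counts as 0)
  half <- tibble::tibble(chrom = "c", start = 100L, end = 200L, value = 2)
  expect_equal(mean_region_signal(half, regions)$mean_signal, 1)
  # contig missing from the track is an error
  expect_error(mean_region_signal(flat,
                                  dplyr::mutate(regions, chrom = "other")),
               "absent from track")
})

test_that("mean_region_signal matches a per-base expansion oracle and is linear", {
  set.seed(66)
  for (rep in 1:10) {
    track <- gen_track(seed = rep, chrom_lengths = c(c = 5000L),
                       segment_length = 37)
    regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "c",
                              start = sample(0:3000, 2),
                              strand = "+")
    regions$end <- regions$start + sample(c(200L, 1200L), 2)
    got <- mean_region_signal(track, regions)$mean_signal
    # oracle: expand the track to one value per base, then mean
    base_vals <- numeric(5000)
    for (i in seq_len(nrow(track))) {
      base_vals[(track$start[i] + 1):track$end[i]] <- track$value[i]
    }
    want <- vapply(seq_len(nrow(regions)), function(i) {
      mean(base_vals[(regions$start[i] + 1):regions$end[i]])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    # linearity in the track values
    track3 <- dplyr::mutate(track, value = 3 * value)
    expect_equal(mean_region_signal(track3, regions)$mean_signal, 3 * got,
                 tolerance = 1e-12)
  }
})

test_that("cluster counting uses >= 1 bp intersection and averages per region", {
  regions <- tibble::tibble(region_id = paste0("r", 1:4), chrom = "c",
                            start = c(0L, 1000L, 2000L, 3000L),
                            end = c(500L, 1500L, 2500L, 3500L),
                            strand = "+")
  expect_equal(count_overlapping_clusters(regions[0, ], regions), 0)
  # one cluster overlapping 2 of 4 regions
  cl <- tibble::tibble(chrom = "c", start = 499L, end = 1001L)
  expect_equal(count_overlapping_clusters(cl, regions), 2 / 4)
  # bookended (zero-bp) contact does not count
  touch <- tibble::tibble(chrom = "c", start = 500L, end = 1000L)
  expect_equal(count_overlapping_clusters(touch, regions), 0)
})

test_that("cluster counts match an all-pairs quadratic scan on random intervals", {
  set.seed(91)
  for (rep in 1:10) {
    regions <- tibble::tibble(region_id = paste0("r", 1:20), chrom = "c",
                              start = sample(0:10000, 20), strand = "+")
    regions$end <- regions$start + sample(50:800, 20, replace = TRUE)
    clusters <- tibble::tibble(chrom = "c", start = sample(0:10000, 30))
    clusters$end <- clusters$start + sample(20:600, 30, replace = TRUE)
    got <- count_overlapping_clusters(clusters, regions, per_region = TRUE)
    want <- vapply(seq_len(nrow(regions)), function(i) {
      sum(clusters$start < regions$end[i] & clusters$end > regions$start[i])
    }, numeric(1))
    expect_equal(got$n_clusters, want)
    expect_equal(count_overlapping_clusters(clusters, regions), mean(want))
  }
})

test_that("threshold fractions use the any-cell-line rule", {
  signals <- tibble::tibble(
    region_id = c("r1", "r2", "r3", "r2", "r3"),
    cell_line = c("A", "A", "A", "B", "B"),
    value = c(12, 5, 30, 5, 2))
  expect_equal(fraction_above_threshold(signals, 10), 2 / 3)
  # a region above threshold in only one of several cell lines qualifies
  one_of <- tibble::tibble(region_id = "r", cell_line = c("A", "B", "C"),
                           value = c(1, 60, 2))
  expect_equal(fraction_above_threshold(one_of, 50), 1)
  # threshold above everything
  expect_equal(fraction_above_threshold(signals, 100), 0)
  # strict inequality at the boundary
  expect_equal(fraction_above_threshold(
    tibble::tibble(region_id = "r", cell_line = "A", value = 10), 10), 0)
  expect_error(fraction_above_threshold(signals[0, ], 10), "empty")
})
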