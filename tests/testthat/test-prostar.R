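test_that("mahalanobis distance matches closed forms and the inversion oracle", {
  # zero at the mean
  ref <- fix_refs$promoter
  expect_equal(mahalanobis_dist(ref$mean, ref), 0, tolerance = 1e-8)
  # identity covariance reduces to Euclidean distance
  r2 <- make_ref(c(0, 0), diag(2))
  expect_equal(mahalanobis_dist(c(3, 4), r2), 5)
  # explicit 2x2 diagonal inversion
  r3 <- make_ref(c(0, 0), diag(c(4, 1)))
  expect_equal(mahalanobis_dist(c(2, 1), r3), sqrt(2^2 / 4 + 1))
  expect_equal(mahalanobis_dist(c(2, 1), r3),
               oracle_mahalanobis(c(2, 1), c(0, 0), diag(c(4, 1))))
  expect_error(mahalanobis_dist(c(1, 2, 3), r2), "dimension mismatch")
})

test_that("mahalanobis distance is invariant under invertible linear maps", {
  set.seed(21)
  for (rep in 1:20) {
    d <- 4
    a <- matrix(rnorm(d * d), d)
    while (abs(det(a)) < 0.1) a <- matrix(rnorm(d * d), d)
    mu <- rnorm(d)
    l <- matrix(rnorm(d * d), d)
    sigma <- crossprod(l) + diag(0.5, d)
    x <- rnorm(d)
    d0 <- mahalanobis_dist(x, make_ref(mu, sigma))
    d1 <- mahalanobis_dist(as.vector(a %*% x),
                           make_ref(as.vector(a %*% mu), a %*% sigma %*% t(a)))
    expect_equal(d0, d1, tolerance = 1e-8)
  }
})

test_that("reference training reproduces hand-stacked feature statistics", {
  grid <- grid_spec(-250, 900, 500, 50)
  set.seed(31)
  seqs <- c(random_dna(1150), random_dna(1150))
  training <- tibble::tibble(seq = seqs, tss = 250L, strand = "+")
  ref <- suppressWarnings(
    build_reference_profile(training, fix_table, grid, "promoter"))
  # brute-force stacking: window means per example, then the midpoint
  feats <- t(vapply(seqs, function(s) {
    prof <- step_series(s, fix_table)
    starts <- grid$window_starts + 250L
    as.vector(t(oracle_window_means(prof, starts, 500L)))
  }, numeric(grid$d)))
  expect_equal(unname(ref$mean), unname(colMeans(feats)), tolerance = 1e-12)

  # degenerate set: identical copies give the feature vector itself and a
  # shrinkage-only diagonal covariance
  ten <- tibble::tibble(seq = rep(seqs[1], 10), tss = 250L, strand = "+")
  ref10 <- suppressWarnings(
    build_reference_profile(ten, fix_table, grid, "promoter"))
  expect_equal(unname(ref10$mean), unname(feats[1, ]), tolerance = 1e-12)
  expect_equal(unname(ref10$cov), rep(ref10$lambda, grid$d),
               tolerance = 1e-15)
  # the two classes trained for scanning share one grid
  expect_identical(fix_refs$promoter$grid, fix_refs$background$grid)
})

test_that("antisense training examples mirror sense feature extraction", {
  set.seed(41)
  s <- random_dna(1150)
  sense <- tibble::tibble(seq = s, tss = 250L, strand = "+")
  anti <- tibble::tibble(seq = prostar:::revcomp(s), tss = 899L, strand = "-")
  r1 <- suppressWarnings(build_reference_profile(sense, fix_table,
                                                 label = "promoter"))
  r2 <- suppressWarnings(build_reference_profile(anti, fix_table,
                                                 label = "promoter"))
  expect_equal(r1$mean, r2$mean, tolerance = 1e-9)
})

test_that("each class mean is classified as its own class", {
  rp <- fix_refs$promoter
  rb <- fix_refs$background
  expect_equal(mahalanobis_dist(rp$mean, rp), 0, tolerance = 1e-8)
  expect_gt(mahalanobis_dist(rp$mean, rb), mahalanobis_dist(rp$mean, rp))
  expect_gt(mahalanobis_dist(rb$mean, rp), mahalanobis_dist(rb$mean, rb))
})

test_that("scanning the reverse complement mirrors predictions across strands", {
  # genome length 1 mod stride, so mirrored positions stay on the lattice
  gg <- gen_genome(61, fix_table, genome_length = 7551, n_promoters = 2)
  sc_f <- scan_genome(gg$genome, fix_table, fix_refs$promoter,
                      fix_refs$background, stride = 50)
  l <- nchar(gg$genome[[1]])
  rc <- stats::setNames(prostar:::revcomp(gg$genome[[1]]), "chrS")
  sc_r <- scan_genome(rc, fix_table, fix_refs$promoter, fix_refs$background,
                      stride = 50)
  # sense prediction at p maps to the antisense prediction at L - 1 - p
  f_plus <- sc_f[sc_f$strand == "+" & sc_f$label != "no_call", ]
  r_minus <- sc_r[sc_r$strand == "-", ]
  mirrored <- l - 1L - f_plus$position
  idx <- match(mirrored, r_minus$position)
  ok <- !is.na(idx)
  expect_gt(sum(ok), 50)
  expect_equal(f_plus$score[ok], r_minus$score[idx[ok]], tolerance = 1e-6)
})

test_that("ties and reference incoherence are handled as specified", {
  # identical references: every score is exactly 0 -> conservative background
  rp <- fix_refs$promoter
  sc <- scan_genome(stats::setNames(strrep("ACGT", 600), "c"), fix_table,
                    rp, rp, stride = 200)
  callable <- sc[sc$label != "no_call", ]
  expect_true(all(callable$score == 0))
  expect_true(all(callable$label == "background"))
  # mismatched stiffness table is rejected
  other <- gen_stiffness_table(123)
  expect_error(scan_genome(stats::setNames(strrep("ACGT", 600), "c"), other,
                           rp, fix_refs$background),
               "table")
})

test_that("call_tss keeps the leftmost of tied peaks and suppresses neighbours", {
  mk <- function(pos, score) {
    tibble::tibble(chrom = "c", position = pos, strand = "+",
                   d_promoter = 1, d_background = 1 + score, score = score,
                   label = ifelse(score > 0, "promoter", "background"))
  }
  # single peak above tau
  sc1 <- mk(c(100, 200, 300), c(1, 5, 1))
  expect_equal(call_tss(sc1, tau = 0, refine_radius = 0)$position, 200)
  # two equal peaks 600 bp apart, suppression radius 1200: leftmost only
  sc2 <- mk(c(100, 200, 300, 700, 800, 900), c(1, 5, 1, 1, 5, 1))
  out2 <- call_tss(sc2, tau = 0, min_separation = 1200, refine_radius = 0)
  expect_equal(out2$position, 200)
  # peaks exactly min_separation apart are both kept
  sc3 <- mk(c(100, 200, 300, 1300, 1400, 1500), c(1, 5, 1, 1, 5, 1))
  out3 <- call_tss(sc3, tau = 0, min_separation = 1200, refine_radius = 0)
  expect_equal(out3$position, c(200, 1400))
  # sub-threshold peaks are not called
  expect_equal(nrow(call_tss(mk(c(100, 200, 300), c(0.1, 0.4, 0.1)),
                             tau = 0.5, refine_radius = 0)), 0L)
})

test_that("candidate filters enforce TSS isolation and the repeat-fraction rule", {
  genome <- c(chrA = paste0(strrep("A", 3000),
                            strrep("a", 900),         # masked 3000-3900
                            strrep("A", 8000)))
  calls <- tibble::tibble(chrom = "chrA",
                          position = c(5000L, 7399L, 3750L),
                          strand = "+",
                          score = 1)
  ann <- tibble::tibble(chrom = "chrA", tss = 6199L)
  out <- filter_candidates(calls, ann, genome, min_tss_distance = 1200,
                           max_repeat_fraction = 0.70)
  # 5000 is 1199 bp from the annotated TSS at 6199 -> too close
  expect_false(out$kept[1])
  expect_equal(out$reject_reason[1], "too_close")
  # 7399 is exactly 1200 bp away -> isolation satisfied inclusively
  expect_true(out$kept[2])
  # 3750 region [2750, 3950) contains 900/1200 = 75% lowercase
  expect_false(out$kept[3])
  expect_equal(out$reject_reason[3], "repeat_fraction")
  expect_equal(out$repeat_fraction[3], 0.75)
  # an explicit mask BED can replace soft-masking
  mask <- tibble::tibble(chrom = "chrA", start = 2750L, end = 3700L)
  out2 <- filter_candidates(calls[3, ], ann, genome, mask = mask)
  expect_equal(out2$reject_reason, "repeat_fraction")
})

test_that("candidate regions follow the strand-aware role geometry", {
  calls <- tibble::tibble(chrom = "c", position = 10000L,
                          strand = c("+", "-"))
  core <- make_regions(calls, "core_promoter")
  expect_equal(core$start, c(9000L, 9800L))
  expect_equal(core$end, c(10200L, 11000L))
  expect_true(all(core$end - core$start == 1200L))
  exp2k <- make_regions(calls, "expanded_2000")
  expect_equal(exp2k$start, c(9000L, 9000L))
  expect_equal(exp2k$end, c(11000L, 11000L))
  tested <- make_regions(calls, "tested_1200")
  expect_equal(tested$start, core$start)
  # truncation at chromosome edges warns and flags
  near_edge <- tibble::tibble(chrom = "c", position = 500L, strand = "+")
  expect_warning(tr <- make_regions(near_edge, "core_promoter",
                                    genome_lengths = c(c = 1000L)),
                 "truncated")
  expect_true(tr$truncated)
  expect_equal(c(tr$start, tr$end), c(0L, 700L))
})

test_that("identical inputs produce byte-identical prediction BED files", {
  gg <- gen_genome(71, fix_table, genome_length = 10000, n_promoters = 2)
  run <- function() {
    sc <- scan_genome(gg$genome, fix_table, fix_refs$promoter,
                      fix_refs$background, stride = 100)
    f <- tempfile(fileext = ".bed")
    write_calls_bed(call_tss(sc, tau = 0), f)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run(), run())
})
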