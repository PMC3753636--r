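# Shared fixtures and independent oracles. Everything is generated in code;
# the heavier trained references are built once per test run.

fix_table <- gen_stiffness_table(7)
fix_grid <- grid_spec()

# trained references shared by the scanner tests and the acceptance suite
fix_refs <- local({
  rp <- build_reference_profile(gen_training_set(11, fix_table, 200, "promoter"),
                                fix_table, fix_grid, "promoter")
  rb <- build_reference_profile(gen_training_set(12, fix_table, 200, "background"),
                                fix_table, fix_grid, "background")
  list(promoter = rp, background = rb)
})

# reference_profile built directly from a mean/covariance, for metric tests
make_ref <- function(mean, cov, label = "promoter") {
  structure(list(label = label, grid = NULL, mean = mean, cov = cov,
                 cov_inv = solve(cov), cov_type = "full", lambda = 0,
                 n_training = NA_integer_, n_skipped = 0L,
                 feature_names = NULL, table_checksum = "manual"),
            class = "reference_profile")
}

# explicit inversion + quadratic-form loop, independent of mahalanobis_dist
oracle_mahalanobis <- function(x, mu, sigma) {
  inv <- solve(sigma)
  v <- x - mu
  acc <- 0
  for (i in seq_along(v)) {
    for (j in seq_along(v)) acc <- acc + v[i] * inv[i, j] * v[j]
  }
  sqrt(acc)
}

# two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, hypergeometric pmf from lchoose (no dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b                     # set size (draws)
  m <- a + c                     # feature-positives in the population
  n <- b + d
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive window means: explicit per-window re-summation over the step rows
oracle_window_means <- function(profile, starts, w) {
  vals <- as.matrix(profile[, c("twist", "tilt", "roll", "shift", "slide",
                                "rise")])
  t(vapply(starts, function(s) {
    rows <- (s + 1):(s + w - 1)        # steps s .. s+w-2, 1-based rows
    ok <- profile$valid[rows]
    colMeans(vals[rows[ok], , drop = FALSE])
  }, numeric(6)))
}

random_dna <- function(n, letters_pool = c("A", "C", "G", "T")) {
  paste(sample(letters_pool, n, replace = TRUE), collapse = "")
}
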