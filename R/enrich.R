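#' Fisher's exact enrichment of one 2x2 incidence table
#'
#' Tests whether a feature (e.g. a TFBS annotation) is enriched in a region
#' set relative to a background transcript list, from the 2x2 table
#' `a` / `b` (set regions with/without the feature) vs `c` / `d`
#' (background with/without). The p-value is the exact conditional test:
#' the sum of hypergeometric probabilities of all tables with the observed
#' margins that are no more likely than the observed one (two-sided,
#' minimum-likelihood summation; one-sided alternatives available). The
#' enrichment magnitude is reported as the sample odds ratio
#' `(a d)/(b c)`, with Haldane's +0.5 added to every cell if and only if
#' any cell is zero, so the reported OR is always finite and positive.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"two.sided"` (default), `"greater"` (enrichment) or
#'   `"less"`.
#' @return a one-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @examples
#' fisher_enrichment(10, 90, 10, 890)
#' @export
fisher_enrichment <- function(a, b, c, d,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells) | cells < 0 | cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  p_value <- .fisher_p(a, b, c, d, alternative)
  if (any(cells == 0)) cells <- cells + 0.5
  odds_ratio <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  tibble::tibble(a = a, b = b, c = c, d = d,
                 odds_ratio = unname(odds_ratio), p_value = p_value)
}

# Exact conditional p: condition on margins, x = a drawn from m = a+c
# feature-positives and n = b+d negatives in k = a+b draws.
.fisher_p <- function(a, b, c, d, alternative) {
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  switch(alternative,
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]),
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control for `m` simultaneous tests: the per-test
#' threshold is `alpha / m`. With the 885 annotated TFBS families tested
#' at `alpha = 0.05` this gives 5.65e-5.
#'
#' @param alpha family-wise significance level, in (0, 1].
#' @param m number of tests, a positive integer.
#' @return the corrected per-test threshold.
#' @examples
#' bonferroni_alpha(0.05, 885)
#' @export
bonferroni_alpha <- function(alpha, m) {
  .assert_scalar_number(alpha, "alpha")
  .assert_scalar_number(m, "m")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Test every feature of an incidence table for enrichment
#'
#' Runs [fisher_enrichment()] on each feature row and flags significance at
#' the Bonferroni-corrected threshold `alpha / m`, where `m` is the number
#' of features tested. Features with a degenerate table (a zero margin)
#' are reported with NA statistics rather than aborting the family.
#'
#' @param incidence tibble with columns `feature`, `a`, `b`, `c`, `d`
#'   (see [gen_incidence()] for the synthetic form).
#' @param alpha family-wise significance level.
#' @param alternative passed to [fisher_enrichment()].
#' @return a tibble sorted by ascending p (ties by feature id) with columns
#'   `feature`, `a`..`d`, `odds_ratio`, `p_value`, `alpha_corrected`,
#'   `significant`; attributes `alpha` and `m`.
#' @export
enrich_all <- function(incidence, alpha = 0.05,
                       alternative = "two.sided") {
  stopifnot(is.data.frame(incidence),
            all(c("feature", "a", "b", "c", "d") %in% names(incidence)))
  m <- nrow(incidence)
  if (m == 0) stop("empty incidence table", call. = FALSE)
  alpha_corrected <- bonferroni_alpha(alpha, m)
  res <- purrr::pmap(incidence[, c("a", "b", "c", "d")], function(a, b, c, d) {
    tryCatch(fisher_enrichment(a, b, c, d, alternative = alternative),
             error = function(e) tibble::tibble(a = a, b = b, c = c, d = d,
                                                odds_ratio = NA_real_,
                                                p_value = NA_real_))
  })
  out <- dplyr::bind_cols(incidence["feature"], dplyr::bind_rows(res)) |>
    dplyr::mutate(alpha_corrected = alpha_corrected,
                  significant = !is.na(.data$p_value) &
                    .data$p_value < alpha_corrected) |>
    dplyr::arrange(.data$p_value, .data$feature)
  n_degenerate <- sum(is.na(out$p_value))
  if (n_degenerate > 0) {
    warning(n_degenerate, " degenerate feature table(s) reported with NA",
            call. = FALSE)
  }
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Assign regions to predictor/activity subsets
#'
#' Cross-tabulates the physical predictor's confidence call (PS+ / PS-)
#' with the luciferase activity call into the four canonical subsets:
#' 1 = PS+L+, 2 = PS+L-, 3 = PS-L+, 4 = PS-L-. A region is luciferase
#' active (L+) iff its normalised activity ratio strictly exceeds
#' `activity_fold` (default 3, the fold over negative-control sequences;
#' a stricter 10-fold cut can be requested).
#'
#' @param ps_calls tibble with columns `region_id` and `ps` (`"+"`/`"-"`).
#' @param luciferase_ratios tibble with columns `region_id` and `ratio`.
#' @param activity_fold activity threshold (strict inequality).
#' @return a tibble `region_id`, `ps`, `luc`, `subset` (1-4), `label`
#'   (e.g. `"PS+L+"`); regions without a ratio are skipped with a warning.
#' @export
assign_subsets <- function(ps_calls, luciferase_ratios, activity_fold = 3.0) {
  stopifnot(is.data.frame(ps_calls),
            all(c("region_id", "ps") %in% names(ps_calls)),
            all(c("region_id", "ratio") %in% names(luciferase_ratios)))
  merged <- dplyr::left_join(ps_calls, luciferase_ratios, by = "region_id")
  missing <- is.na(merged$ratio)
  if (any(missing)) {
    warning(sum(missing), " region(s) without a luciferase ratio skipped",
            call. = FALSE)
    merged <- merged[!missing, , drop = FALSE]
  }
  dplyr::transmute(
    merged,
    region_id = .data$region_id,
    ps = .data$ps,
    luc = ifelse(.data$ratio > activity_fold, "+", "-"),
    subset = dplyr::case_when(
      ps == "+" & luc == "+" ~ 1L,
      ps == "+" & luc == "-" ~ 2L,
      ps == "-" & luc == "+" ~ 3L,
      TRUE ~ 4L),
    label = paste0("PS", .data$ps, "L", .data$luc))
}
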