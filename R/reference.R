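#' Train a class reference profile
#'
#' A reference profile summarises one class of sequences -- known promoters
#' (positive set) or randomly selected background (negative set) -- as the
#' mean and covariance of their grid feature vectors. Candidate positions
#' are later scored by their Mahalanobis distance to each of the two class
#' profiles.
#'
#' Each training example supplies a sequence, the 0-based TSS position
#' within it, and the strand; antisense examples are handled by mirroring
#' the grid through the reverse complement before feature extraction.
#' Examples whose grid overlaps invalid windows (masked steps beyond
#' `min_valid`) are skipped with a warning.
#'
#' The covariance is the sample covariance with ridge shrinkage
#' `lambda * I`. The default `lambda` is `0.2 * trace/D` (20% of the mean
#' feature variance, floored at 1e-8): with `D = 84` heavily correlated
#' window features and training sets of a few hundred examples, the raw
#' sample covariance is near-singular and its inverse amplifies sampling
#' noise; substantial ridge shrinkage keeps the Mahalanobis metric stable.
#' With fewer than `D + 2` usable examples a full covariance is not
#' estimable at all, so the diagonal form is forced (with a warning)
#' unless `cov_type` demands otherwise.
#'
#' @param training data frame with columns `seq` (DNA string), `tss`
#'   (0-based position within `seq`) and `strand` (`"+"`/`"-"`).
#' @param table a [stiffness_table].
#' @param grid a [grid_spec()].
#' @param label class label, `"promoter"` or `"background"`.
#' @param cov_type `"auto"` (full when enough examples, else diagonal),
#'   `"full"` or `"diagonal"`.
#' @param lambda ridge shrinkage added to the covariance diagonal; `NULL`
#'   for the default described above.
#' @param min_valid minimum valid-step fraction per window.
#' @return an object of class `reference_profile`.
#' @seealso [mahalanobis_dist()], [scan_genome()]
#' @export
build_reference_profile <- function(training, table, grid = grid_spec(),
                                    label = c("promoter", "background"),
                                    cov_type = c("auto", "full", "diagonal"),
                                    lambda = NULL, min_valid = 0.9) {
  label <- match.arg(label)
  cov_type <- match.arg(cov_type)
  stopifnot(is.data.frame(training),
            all(c("seq", "tss", "strand") %in% names(training)))
  feats <- vector("list", nrow(training))
  usable <- logical(nrow(training))
  for (i in seq_len(nrow(training))) {
    prof <- step_series(training$seq[i], table)
    idx <- .profile_index(prof)
    gf <- .grid_features(idx, as.integer(training$tss[i]),
                         training$strand[i], grid, min_valid = min_valid)
    usable[i] <- gf$valid
    feats[[i]] <- gf$features
  }
  if (any(!usable)) {
    warning(sum(!usable),
            " training example(s) skipped: grid overlaps invalid windows",
            call. = FALSE)
  }
  if (!any(usable)) stop("no usable training examples", call. = FALSE)
  x <- do.call(rbind, feats[usable])
  n <- nrow(x)
  d <- grid$d
  if (cov_type == "auto") {
    cov_type <- if (n >= d + 2L) "full" else "diagonal"
    if (cov_type == "diagonal" && n < d + 2L) {
      warning(sprintf(
        "only %d usable examples for D = %d: forcing diagonal covariance",
        n, d), call. = FALSE)
    }
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- if (n > 1) crossprod(xc) / (n - 1) else matrix(0, d, d)
  tr <- sum(diag(s))
  if (is.null(lambda)) lambda <- max(0.2 * tr / d, 1e-8)
  if (cov_type == "full") {
    sigma <- s + diag(lambda, d)
    sigma_inv <- solve(sigma)
  } else {
    sigma <- diag(s) + lambda
    sigma_inv <- NULL
  }
  structure(
    list(label = label, grid = grid, mean = mu, cov = sigma,
         cov_inv = sigma_inv, cov_type = cov_type, lambda = lambda,
         n_training = n, n_skipped = sum(!usable),
         feature_names = colnames(x),
         table_checksum = .table_checksum(table)),
    class = "reference_profile")
}

#' Mahalanobis distance to a reference profile
#'
#' Computes `sqrt((x - mean)' Sigma^{-1} (x - mean))` against the trained
#' class mean and (shrunken) covariance. The covariance scaling makes the
#' comparative promoter-vs-background score insensitive to the very
#' different units and variances of the six stiffness channels.
#'
#' @param x a feature vector of length `D`, or an `n x D` matrix of feature
#'   vectors (rows scored independently).
#' @param ref a [build_reference_profile()] object.
#' @return non-negative distance(s); NA rows propagate NA.
#' @export
mahalanobis_dist <- function(x, ref) {
  stopifnot(inherits(ref, "reference_profile"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(ref$mean)) {
    stop(sprintf("feature dimension mismatch: got %d, reference has %d",
                 ncol(x), length(ref$mean)), call. = FALSE)
  }
  xc <- sweep(x, 2, ref$mean)
  d2 <- if (ref$cov_type == "full") {
    rowSums((xc %*% ref$cov_inv) * xc)
  } else {
    rowSums(sweep(xc^2, 2, ref$cov, "/"))
  }
  # quadratic form is >= 0 up to roundoff
  sqrt(pmax(d2, 0))
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf(
    "Reference profile '%s': %d training examples, D = %d (%s covariance, lambda = %.3g)\n",
    x$label, x$n_training, length(x$mean), x$cov_type, x$lambda))
  invisible(x)
}

#' Tidy a reference profile into per-window channel summaries
#'
#' @param x a `reference_profile`.
#' @param ... unused.
#' @return a tibble with one row per (window offset, channel): the class
#'   mean and the marginal standard deviation of that feature.
#' @method tidy reference_profile
#' @export
tidy.reference_profile <- function(x, ...) {
  vars <- if (x$cov_type == "full") diag(x$cov) else x$cov
  tibble::tibble(
    window_start = rep(x$grid$window_starts, each = 6L),
    channel = rep(.channels, times = x$grid$n_windows),
    mean = unname(x$mean),
    sd = sqrt(unname(vars))
  )
}

#' One-row summary of a reference profile
#'
#' @param x a `reference_profile`.
#' @param ... unused.
#' @method glance reference_profile
#' @export
glance.reference_profile <- function(x, ...) {
  tibble::tibble(label = x$label, n_training = x$n_training,
                 n_skipped = x$n_skipped, d = length(x$mean),
                 n_windows = x$grid$n_windows, cov_type = x$cov_type,
                 lambda = x$lambda, table_checksum = x$table_checksum)
}

#' Serialize / deserialize a reference profile as JSON
#'
#' The on-disk model is plain JSON (label, grid, mean, covariance,
#' shrinkage, provenance checksum) so trained models are portable and
#' inspectable.
#'
#' @param ref a `reference_profile`.
#' @param path file path.
#' @return `write_reference_profile()` returns `path` invisibly;
#'   `read_reference_profile()` returns the restored object.
#' @export
write_reference_profile <- function(ref, path) {
  stopifnot(inherits(ref, "reference_profile"))
  obj <- list(
    label = ref$label,
    grid = ref$grid[c("span_start", "span_end", "window_length", "stride")],
    mean = unname(ref$mean),
    cov_type = ref$cov_type,
    cov = if (ref$cov_type == "full") unname(ref$cov) else unname(as.numeric(ref$cov)),
    lambda = ref$lambda,
    n_training = ref$n_training,
    table_checksum = ref$table_checksum
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- grid_spec(obj$grid$span_start, obj$grid$span_end,
                    obj$grid$window_length, obj$grid$stride)
  cov <- if (obj$cov_type == "full") as.matrix(obj$cov) else as.numeric(obj$cov)
  structure(
    list(label = obj$label, grid = grid, mean = as.numeric(obj$mean),
         cov = cov,
         cov_inv = if (obj$cov_type == "full") solve(as.matrix(obj$cov)) else NULL,
         cov_type = obj$cov_type, lambda = obj$lambda,
         n_training = obj$n_training, n_skipped = 0L,
         feature_names = .grid_feature_names(grid),
         table_checksum = obj$table_checksum),
    class = "reference_profile")
}
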