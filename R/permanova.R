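# Permutation-based multivariate tests on z-scored gene metric profiles.
#
# The dissimilarity is Euclidean distance over column-standardised metrics,
# so the PERMANOVA partition SS_total = SS_between + SS_within can be
# computed exactly from the raw data matrix (sum of squared deviations from
# the grand/group centroids) instead of from an n x n distance matrix. Each
# label permutation then costs O(n p) rather than O(n^2), which keeps 999
# permutations at N ~ 2000 per group to fractions of a second on one CPU.
# The pseudo-F, R2 and permutation p are identical to the distance-matrix
# (Gower-centred) formulation for Euclidean distances.

# Column z-scores; constant columns are dropped with a warning.
#' @noRd
zscore_columns <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  assert_that(ncol(x) >= 1L, "no non-constant columns left")
  scale(x, center = TRUE, scale = TRUE)
}

# Within-group sum of squares of a centred matrix under grouping g,
# via SS_w = sum(x^2) - sum_g ||colsum_g||^2 / n_g.
#' @noRd
ss_within <- function(x, g, total_sq) {
  cs <- rowsum(x, g)
  total_sq - sum(cs^2 / as.numeric(table(g)))
}

#' PERMANOVA on z-scored metric profiles
#'
#' One-way permutational multivariate analysis of variance with Euclidean
#' distances on column-standardised data. Optionally subsamples each group
#' to a common size (seeded, without replacement) before standardisation,
#' mirroring analyses that balance groups to the smallest dataset. The
#' permutation p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`. A
#' PERMDISP dispersion companion test runs on the same standardised
#' subsample.
#'
#' @param features numeric matrix or data frame (observations x metrics).
#' @param labels group labels (at least two groups).
#' @param n_perm number of label permutations (default 999).
#' @param subsample_n per-group subsample size, `NULL` for no subsampling.
#' @param seed integer seed driving the subsample and the permutations.
#' @return object of class `permanova_result`: `pseudo_f`, `r2`, `p`,
#'   `n_perm`, `subsample_n`, `seed`, `n`, `k`, `dispersion_f`,
#'   `dispersion_p`.
#' @export
permanova <- function(features, labels, n_perm = 999L, subsample_n = NULL,
                      seed = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  assert_that(nlevels(labels) >= 2L, "need at least two groups")
  assert_that(nrow(features) == length(labels),
              "features and labels must have matching lengths")
  with_seed(seed, {
    if (!is.null(subsample_n)) {
      sizes <- table(labels)
      assert_that(all(sizes >= subsample_n),
                  "subsample_n exceeds a group's size")
      keep <- unlist(lapply(levels(labels), function(l) {
        idx <- which(labels == l)
        sample(idx, subsample_n)
      }))
      features <- features[keep, , drop = FALSE]
      labels <- droplevels(labels[keep])
    }
    x <- zscore_columns(features)
    n <- nrow(x)
    k <- nlevels(labels)
    assert_that(n - k >= 1L, "not enough observations for the residual df")
    total_sq <- sum(x^2)
    ss_t <- total_sq  # columns are centred, grand mean is 0
    ss_w <- ss_within(x, labels, total_sq)
    ss_b <- ss_t - ss_w
    f_obs <- (ss_b / (k - 1)) / (ss_w / (n - k))
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      gp <- labels[sample.int(n)]
      ss_w_p <- ss_within(x, gp, total_sq)
      f_p <- ((ss_t - ss_w_p) / (k - 1)) / (ss_w_p / (n - k))
      if (f_p >= f_obs) exceed <- exceed + 1L
    }
    disp <- permdisp_core(x, labels, n_perm = n_perm)
    structure(list(pseudo_f = f_obs, r2 = ss_b / ss_t,
                   p = (1 + exceed) / (1 + n_perm),
                   n_perm = as.integer(n_perm),
                   subsample_n = if (is.null(subsample_n)) NA_integer_
                                 else as.integer(subsample_n),
                   seed = if (is.null(seed)) NA_integer_
                          else as.integer(seed),
                   n = n, k = k,
                   dispersion_f = disp$F, dispersion_p = disp$p),
              class = "permanova_result")
  })
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_f, x$r2, x$p, x$n_perm))
  cat(sprintf("PERMDISP:  F = %.3f, p = %.4g\n",
              x$dispersion_f, x$dispersion_p))
  invisible(x)
}

# Core PERMDISP on an already-standardised matrix: distance of every
# observation to its group centroid, one-way F on those distances, and a
# permutation p obtained by reallocating the distances among groups.
#' @noRd
permdisp_core <- function(x, labels, n_perm = 999L) {
  n <- nrow(x)
  k <- nlevels(labels)
  assert_that(n - k >= 1L,
              "PERMDISP F undefined: no residual degrees of freedom")
  centroids <- rowsum(x, labels) / as.numeric(table(labels))
  dct <- sqrt(rowSums((x - centroids[as.integer(labels), , drop = FALSE])^2))
  f_stat <- function(d, g) {
    gm <- mean(d)
    means <- tapply(d, g, mean)
    ns <- tapply(d, g, length)
    ss_b <- sum(ns * (means - gm)^2)
    ss_w <- sum((d - means[as.integer(g)])^2)
    if (ss_w == 0) return(Inf)
    (ss_b / (k - 1)) / (ss_w / (n - k))
  }
  f_obs <- f_stat(dct, labels)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(dct[sample.int(n)], labels) >= f_obs) exceed <- exceed + 1L
  }
  list(F = f_obs, p = (1 + exceed) / (1 + n_perm))
}

#' PERMDISP: permutational analysis of multivariate dispersions
#'
#' Distances of observations to their group centroid in the z-scored
#' Euclidean space, compared across groups by a one-way F statistic with a
#' permutation p-value.
#'
#' @inheritParams permanova
#' @return list with `F` and `p`.
#' @export
permdisp <- function(features, labels, n_perm = 999L, seed = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  assert_that(nlevels(labels) >= 2L, "need at least two groups")
  assert_that(nrow(features) == length(labels),
              "features and labels must have matching lengths")
  with_seed(seed, {
    x <- zscore_columns(features)
    permdisp_core(x, labels, n_perm = n_perm)
  })
}
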