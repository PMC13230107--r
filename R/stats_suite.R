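# Nonparametric statistical ledger: Kruskal-Wallis with rank-based effect
# sizes, Dunn's post-hoc contrasts, Mann-Whitney with Cliff's delta,
# Holm/Benjamini-Hochberg corrections, Spearman machinery (bootstrap CI,
# rank-residualised partial correlations) and the Scheirer-Ray-Hare two-way
# rank test. All tests are two-sided.

#' Kruskal-Wallis omnibus test with rank-based effect sizes
#'
#' Wraps the tie-corrected Kruskal-Wallis H statistic and augments it with
#' the rank-based effect sizes
#' `eta2 = (H - k + 1) / (N - k)` and `epsilon2 = (H - k + 1) / (N - 1)`,
#' the proportion of rank variance attributable to groups.
#'
#' @param groups list of `k >= 2` non-empty numeric vectors.
#' @return object of class `kw_result`: `H`, `df`, `p`, `eta2`, `epsilon2`,
#'   `k`, `N`, `tie_corrected`.
#' @export
kruskal_wallis <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2L,
              "need a list of at least two groups")
  assert_that(all(lengths(groups) > 0L), "all groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  N <- length(values)
  if (length(unique(values)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- kruskal.test(values, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  es <- kw_effect_sizes(H, k, N)
  structure(list(H = H, df = k - 1L, p = p,
                 eta2 = es[["eta2"]], epsilon2 = es[["epsilon2"]],
                 k = k, N = N,
                 tie_corrected = anyDuplicated(values) > 0L),
            class = "kw_result")
}

#' Rank-based effect sizes from a Kruskal-Wallis statistic
#'
#' `eta2 = (H - k + 1) / (N - k)` and `epsilon2 = (H - k + 1) / (N - 1)`,
#' usable directly on a published H with its group count and sample size.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k number of groups.
#' @param N total sample size.
#' @return named numeric vector `eta2`, `epsilon2`.
#' @export
kw_effect_sizes <- function(H, k, N) {
  c(eta2 = (H - k + 1) / (N - k), epsilon2 = (H - k + 1) / (N - 1))
}

#' Dunn z statistic from mean ranks
#'
#' `z = (R1 - R2) / sqrt((N(N+1)/12 - tie_term/(12(N-1))) (1/n1 + 1/n2))`,
#' with `tie_term = sum(t^3 - t)` over tied value groups (0 without ties).
#' Usable directly on published mean ranks.
#'
#' @param mean_rank_1,mean_rank_2 group mean ranks on the pooled ranking.
#' @param n1,n2 group sizes.
#' @param N total sample size.
#' @param tie_term tie correction sum (default 0).
#' @return the z statistic.
#' @export
dunn_z <- function(mean_rank_1, mean_rank_2, n1, n2, N, tie_term = 0) {
  se <- sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) *
               (1 / n1 + 1 / n2))
  diff <- mean_rank_1 - mean_rank_2
  # completely tied data: zero rank variance, no separation
  if (se == 0) return(if (diff == 0) 0 else sign(diff) * Inf)
  diff / se
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.3g\n",
              x$H, x$df, x$p))
  cat(sprintf("  eta2 = %.4f, epsilon2 = %.4f (k = %d, N = %d)\n",
              x$eta2, x$epsilon2, x$k, x$N))
  invisible(x)
}

#' Effect-size label for rank-based epsilon-squared
#'
#' Thresholds: negligible (< 0.01), small (0.01-0.08), moderate (0.08-0.26),
#' large (> 0.26).
#'
#' @param epsilon2 numeric vector.
#' @return character vector of labels.
#' @export
epsilon2_label <- function(epsilon2) {
  ifelse(epsilon2 < 0.01, "negligible",
         ifelse(epsilon2 < 0.08, "small",
                ifelse(epsilon2 <= 0.26, "moderate", "large")))
}

#' Dunn's post-hoc pairwise contrasts
#'
#' Mean-rank contrasts on the pooled mid-ranks shared with the omnibus test:
#' `z = (R1 - R2) / sqrt((N(N+1)/12 - sum(T)/(12(N-1))) (1/n1 + 1/n2))` with
#' the tie term `T = t^3 - t` always applied (it vanishes without ties).
#' Two-sided normal p-values with Bonferroni and Holm adjustments over the
#' contrast family (applied to unrounded p-values); Cliff's delta,
#' magnitude and direction accompany every contrast.
#'
#' @param groups named list of numeric vectors.
#' @param labels group labels (defaults to `names(groups)`).
#' @return data frame, one row per unordered pair of groups, with columns
#'   `group_1`, `group_2`, `mean_rank_1`, `mean_rank_2`, `z`, `p_raw`,
#'   `p_bonferroni`, `p_holm`, `cliffs_delta`, `magnitude`, `direction`.
#' @export
dunn_posthoc <- function(groups, labels = names(groups)) {
  assert_that(is.list(groups) && length(groups) >= 2L,
              "need a list of at least two groups")
  assert_that(all(lengths(groups) > 0L), "all groups must be non-empty")
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  n <- lengths(groups)
  tie_counts <- table(values)
  tie_term <- sum(tie_counts^3 - tie_counts)
  idx <- combn(seq_along(groups), 2L)
  m <- ncol(idx)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- idx[1L, j]; i2 <- idx[2L, j]
    z <- dunn_z(mean_ranks[[i1]], mean_ranks[[i2]], n[i1], n[i2], N,
                tie_term = tie_term)
    cd <- cliffs_delta(groups[[i1]], groups[[i2]])
    direction <- if (cd$delta > 0) {
      paste(labels[i1], ">", labels[i2])
    } else if (cd$delta < 0) {
      paste(labels[i2], ">", labels[i1])
    } else {
      paste(labels[i1], "=", labels[i2])
    }
    data.frame(group_1 = labels[i1], group_2 = labels[i2],
               mean_rank_1 = mean_ranks[[i1]], mean_rank_2 = mean_ranks[[i2]],
               z = z, p_raw = 2 * pnorm(-abs(z)),
               cliffs_delta = cd$delta, magnitude = cd$magnitude,
               direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out$p_holm <- holm_adjust(out$p_raw)
  out[, c("group_1", "group_2", "mean_rank_1", "mean_rank_2", "z", "p_raw",
          "p_bonferroni", "p_holm", "cliffs_delta", "magnitude", "direction")]
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided. The exact distribution is enumerated when `n1 * n2 <= 400` and
#' there are no ties; otherwise the tie-corrected normal approximation (with
#' continuity correction) is used — exact enumeration is unavailable under
#' ties.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U` (number of `x > y` wins, ties counted half) and
#'   `p`.
#' @export
mann_whitney <- function(x, y) {
  assert_that(length(x) > 0L && length(y) > 0L,
              "both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Cliff's delta effect size
#'
#' `delta = (#{x_i > y_j} - #{x_i < y_j}) / (n1 n2)`, a probability-of-
#' dominance difference in `[-1, 1]`, computed via pooled ranks in
#' O(n log n). Magnitudes: negligible (|delta| < 0.147), small (< 0.33),
#' moderate (< 0.474), large (>= 0.474).
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `delta` and `magnitude`.
#' @export
cliffs_delta <- function(x, y) {
  assert_that(length(x) > 0L && length(y) > 0L,
              "both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  # U = #{x > y} + 0.5 #{x = y}
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  delta <- 2 * U / (n1 * n2) - 1
  list(delta = delta, magnitude = cliff_magnitude(delta))
}

#' @rdname cliffs_delta
#' @param delta numeric vector of Cliff's delta values.
#' @export
cliff_magnitude <- function(delta) {
  a <- abs(delta)
  ifelse(a < 0.147, "negligible",
         ifelse(a < 0.33, "small",
                ifelse(a < 0.474, "moderate", "large")))
}

#' Multiple-testing adjustments
#'
#' Holm step-down family-wise correction and Benjamini-Hochberg step-up
#' false-discovery-rate correction; output order matches input order and
#' values are capped at 1.
#'
#' @param p probabilities in `[0, 1]`.
#' @return adjusted probabilities.
#' @export
holm_adjust <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' @rdname holm_adjust
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' the asymptotic t approximation.
#'
#' @param x,y paired numeric vectors of length `>= 4`.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 4L, "need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Bootstrap percentile confidence interval for Spearman's rho
#'
#' Resamples pairs with replacement `B` times and returns the 2.5/97.5
#' percentile bounds. Degenerate resamples (constant vectors) are redrawn
#' and counted; the count is attached as attribute `"n_redrawn"`.
#'
#' @param x,y paired numeric vectors.
#' @param B number of bootstrap iterations (default 1000).
#' @param seed integer seed for reproducibility.
#' @return numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(x, y, B = 1000L, seed = NULL) {
  assert_that(length(x) == length(y), "x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 4L, "need at least 4 complete pairs")
  with_seed(seed, {
    rho_b <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) > 0 && sd(y[idx]) > 0) break
        redrawn <- redrawn + 1L
      }
      rho_b[b] <- cor(x[idx], y[idx], method = "spearman")
    }
    structure(c(q7(rho_b, 0.025), q7(rho_b, 0.975)), n_redrawn = redrawn)
  })
}

#' Partial Spearman correlation by rank residualisation
#'
#' Three steps: rank-transform all variables; regress the ranked variables
#' on the ranked covariates by least squares; Spearman-correlate the
#' residuals. The p-value uses the t approximation with degrees of freedom
#' reduced by the number of covariates. If a residual vector is constant
#' (a variable perfectly explained by the covariates) the partial
#' correlation is defined as 0.
#'
#' @param x,y paired numeric vectors.
#' @param covariates numeric matrix or data frame of covariates (full rank
#'   after rank transformation).
#' @return list with `rho`, `p`, `df`.
#' @export
partial_spearman <- function(x, y, covariates) {
  covariates <- as.matrix(covariates)
  n <- length(x)
  assert_that(length(y) == n && nrow(covariates) == n,
              "x, y and covariates must have matching lengths")
  ok <- is.finite(x) & is.finite(y) &
    apply(is.finite(covariates), 1L, all)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  q <- ncol(covariates)
  assert_that(n >= q + 4L, "too few complete observations")
  rz <- apply(covariates, 2L, rank)
  X <- cbind(1, rz)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("ranked covariates are collinear (rank-deficient)", call. = FALSE)
  }
  res_x <- qr.resid(qrX, rank(x))
  res_y <- qr.resid(qrX, rank(y))
  df <- n - 2L - q
  if (sd(res_x) < 1e-12 || sd(res_y) < 1e-12) {
    return(list(rho = 0, p = 1, df = df))
  }
  rho <- cor(res_x, res_y, method = "spearman")
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Scheirer-Ray-Hare two-way rank test
#'
#' Nonparametric extension of two-way ANOVA: global mid-ranks, sequential
#' two-way sums of squares on the ranks, and `H = SS_effect / MS_total`
#' referred to a chi-square distribution at the effect's degrees of freedom.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors with at least two levels each and at
#'   least one observation per crossed cell.
#' @return object of class `srh_result` with statistics, dfs and p-values
#'   for both main effects and the interaction.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  factor_a <- factor(factor_a)
  factor_b <- factor(factor_b)
  assert_that(nlevels(factor_a) >= 2L && nlevels(factor_b) >= 2L,
              "both factors need at least two levels")
  assert_that(length(values) == length(factor_a) &&
                length(values) == length(factor_b),
              "values and factors must have matching lengths")
  cell <- table(factor_a, factor_b)
  assert_that(all(cell >= 1L), "every factor-A x factor-B cell needs data")
  r <- rank(values)
  N <- length(r)
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) {
    zero <- list(h_factor_a = 0, h_factor_b = 0, h_interaction = 0,
                 df_a = nlevels(factor_a) - 1L,
                 df_b = nlevels(factor_b) - 1L,
                 df_ab = (nlevels(factor_a) - 1L) * (nlevels(factor_b) - 1L),
                 p_a = 1, p_b = 1, p_interaction = 1)
    return(structure(zero, class = "srh_result"))
  }
  ms_total <- ss_total / (N - 1)
  an <- anova(lm(r ~ factor_a * factor_b))
  ss <- an[["Sum Sq"]]
  df <- an[["Df"]]
  h <- ss[1:3] / ms_total
  p <- pchisq(h, df[1:3], lower.tail = FALSE)
  structure(list(h_factor_a = h[1L], h_factor_b = h[2L],
                 h_interaction = h[3L],
                 df_a = df[1L], df_b = df[2L], df_ab = df[3L],
                 p_a = p[1L], p_b = p[2L], p_interaction = p[3L]),
            class = "srh_result")
}

#' @export
print.srh_result <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank test\n")
  cat(sprintf("  factor A:    H = %.4f, df = %d, p = %.3g\n",
              x$h_factor_a, x$df_a, x$p_a))
  cat(sprintf("  factor B:    H = %.4f, df = %d, p = %.3g\n",
              x$h_factor_b, x$df_b, x$p_b))
  cat(sprintf("  interaction: H = %.4f, df = %d, p = %.3g\n",
              x$h_interaction, x$df_ab, x$p_interaction))
  invisible(x)
}
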