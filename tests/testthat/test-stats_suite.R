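test_that("Kruskal-Wallis H matches a brute-force formula oracle", {
  set.seed(101)
  for (i in 1:8) {
    groups <- lapply(1:3, function(j) round(rnorm(8, j / 4), 2))
    kw <- kruskal_wallis(groups)
    expect_equal(kw$H, oracle_kw_h(groups), tolerance = 1e-10)
    expect_equal(kw$p, pchisq(kw$H, 2, lower.tail = FALSE))
    expect_equal(kw$eta2, (kw$H - 2) / (kw$N - 3))
    expect_equal(kw$epsilon2, (kw$H - 2) / (kw$N - 1))
    if (kw$H >= kw$k - 1) expect_gte(kw$eta2, kw$epsilon2)
  }
})

test_that("degenerate Kruskal-Wallis input yields H = 0, p = 1", {
  kw <- kruskal_wallis(list(rep(2, 5), rep(2, 4), rep(2, 6)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
})

test_that("Kruskal-Wallis with two groups squares the Mann-Whitney z", {
  set.seed(103)
  x <- rnorm(18); y <- rnorm(15, 0.8)
  kw <- kruskal_wallis(list(x, y))
  # tie-corrected normal z for U, no continuity correction
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
  tt <- table(c(x, y))
  vu <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  z <- (U - n1 * n2 / 2) / sqrt(vu)
  expect_equal(kw$H, z^2, tolerance = 1e-9)
})

test_that("epsilon-squared labels follow the interpretation thresholds", {
  expect_equal(epsilon2_label(c(0.005, 0.05, 0.09, 0.2, 0.3)),
               c("negligible", "small", "moderate", "moderate", "large"))
})

test_that("Dunn contrasts recover manual z values and the null case", {
  g <- list(a = 1:10, b = 11:20, c = 21:30)
  d <- dunn_posthoc(g)
  # no ties: SE = sqrt(N(N+1)/12 * (1/10 + 1/10))
  se <- sqrt(30 * 31 / 12 * 0.2)
  expect_equal(d$z[d$group_1 == "a" & d$group_2 == "b"],
               (mean(1:10) - mean(11:20)) / se)
  expect_equal(d$p_raw, 2 * pnorm(-abs(d$z)))
  expect_true(all(d$p_holm <= d$p_bonferroni + 1e-15))
  # identical groups: z = 0, p = 1
  eq <- dunn_posthoc(list(a = rep(1, 5), b = rep(1, 5)))
  expect_equal(eq$z, 0)
  expect_equal(eq$p_raw, 1)
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("Mann-Whitney switches between exact enumeration and the
           tie-corrected approximation", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(107)
  x <- rnorm(50); y <- rnorm(50, 0.2)
  approx_p <- mann_whitney(x, y)$p  # n1*n2 > 400: approximation
  exact_p <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
  expect_lt(abs(approx_p - exact_p), 0.005)
})

test_that("Cliff's delta matches the double-loop oracle and its thresholds", {
  cd <- cliffs_delta(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cd$delta, -1)
  expect_equal(cd$magnitude, "large")
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$magnitude, "negligible")
  expect_equal(cliff_magnitude(c(0.30, 0.40, 0.50, -0.50, 0.1)),
               c("small", "moderate", "large", "large", "negligible"))
  set.seed(109)
  for (i in 1:5) {
    x <- sample(1:8, 20, TRUE); y <- sample(2:9, 15, TRUE)
    expect_equal(cliffs_delta(x, y)$delta, oracle_cliffs_delta(x, y))
  }
})

test_that("Holm and BH corrections match definition-level oracles", {
  expect_equal(holm_adjust(0.002), 0.002)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(113)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(holm_adjust(p), oracle_holm(p))
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_true(all(holm_adjust(p) >= p))
    expect_true(all(bh_adjust(p) >= p))
    # output order always matches input order
    o <- sample(20)
    expect_equal(holm_adjust(p[o]), oracle_holm(p)[o])
    expect_equal(bh_adjust(p[o]), oracle_bh(p)[o])
  }
})

test_that("Spearman machinery handles monotone and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_error(spearman(x, rep(1, 6)), "constant")
})

test_that("bootstrap confidence intervals are seeded and cover the truth", {
  set.seed(127)
  n <- 50
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  ci1 <- bootstrap_ci(x, y, B = 200, seed = 5)
  ci2 <- bootstrap_ci(x, y, B = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= spearman(x, y)$rho && spearman(x, y)$rho <= ci1[2])

  # coverage of the generating rho over seeded replications
  rho_true <- 0.6
  covered <- 0L
  for (r in 1:40) {
    set.seed(300 + r)
    xx <- rnorm(n)
    yy <- rho_true * xx + sqrt(1 - rho_true^2) * rnorm(n)
    ci <- bootstrap_ci(xx, yy, B = 200, seed = 300 + r)
    # compare on the rank scale: the bootstrap targets the Spearman rho
    target <- 6 / pi * asin(rho_true / 2)
    if (ci[1] <= target && target <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / 40, 0.85)
})

test_that("partial Spearman residualisation removes covariate structure", {
  set.seed(131)
  n <- 200
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  raw <- spearman(x, y)$rho
  ps <- partial_spearman(x, y, cbind(z))
  expect_lt(abs(ps$rho - raw), 0.05)

  # perfect confounding: y is the covariate itself
  ps2 <- partial_spearman(x, y, cbind(y))
  expect_equal(ps2$rho, 0)

  # degenerate equal inputs: collinear after adding the intercept
  v <- 1:20
  expect_error(partial_spearman(v, v, cbind(v, v)), "collinear")
})

test_that("Scheirer-Ray-Hare recovers shifts and a hand-computed table", {
  # constant response: all H zero
  s0 <- scheirer_ray_hare(rep(1, 12), rep(c("a", "b"), 6),
                          rep(c("x", "y"), each = 6))
  expect_equal(s0$h_factor_a, 0)
  expect_equal(s0$p_interaction, 1)

  # pure factor-A shift
  set.seed(137)
  a <- rep(c("lo", "hi"), each = 40)
  b <- rep(rep(c("u", "v"), each = 20), 2)
  vals <- rnorm(80) + ifelse(a == "hi", 3, 0)
  s <- scheirer_ray_hare(vals, a, b)
  expect_gt(s$h_factor_a, 10 * max(s$h_factor_b, 1e-9))
  expect_lt(s$p_a, 0.001)
  expect_gt(s$p_b, 0.05)

  # 2x2 balanced toy vs a fully manual rank two-way decomposition
  vals2 <- c(1, 2, 5, 6, 3, 4, 7, 9)
  fa <- factor(rep(c("a1", "a2"), each = 4))
  fb <- factor(rep(c("b1", "b2", "b1", "b2"), each = 2))
  s2 <- scheirer_ray_hare(vals2, fa, fb)
  r <- rank(vals2)
  ms_total <- sum((r - mean(r))^2) / 7
  cell_means <- tapply(r, list(fa, fb), mean)
  ss_a <- 4 * sum((tapply(r, fa, mean) - mean(r))^2)
  ss_b <- 4 * sum((tapply(r, fb, mean) - mean(r))^2)
  ss_cells <- 2 * sum((cell_means - mean(r))^2)
  ss_ab <- ss_cells - ss_a - ss_b
  expect_equal(s2$h_factor_a, ss_a / ms_total, tolerance = 1e-10)
  expect_equal(s2$h_factor_b, ss_b / ms_total, tolerance = 1e-10)
  expect_equal(s2$h_interaction, ss_ab / ms_total, tolerance = 1e-10)

  expect_error(scheirer_ray_hare(1:4, rep("a", 4), rep(c("x", "y"), 2)),
               "two levels")
})

test_that("PERMANOVA matches the distance-matrix oracle and vegan", {
  set.seed(139)
  x <- matrix(rnorm(40 * 4), ncol = 4)
  colnames(x) <- paste0("m", 1:4)
  g <- rep(c("A", "B"), each = 20)
  x[g == "B", 1] <- x[g == "B", 1] + 1.5
  pr <- permanova(x, g, n_perm = 499, seed = 17)

  xs <- scale(x)
  orc <- oracle_pseudo_f(dist(xs), g)
  expect_equal(pr$pseudo_f, orc$f, tolerance = 1e-9)
  expect_equal(pr$r2, orc$r2, tolerance = 1e-9)

  ad <- vegan::adonis2(dist(xs) ~ g, permutations = 499)
  expect_equal(pr$pseudo_f, ad$F[1], tolerance = 1e-6)
  expect_equal(pr$r2, ad$R2[1], tolerance = 1e-6)
  expect_lt(abs(pr$p - ad$`Pr(>F)`[1]), 0.05)
})

test_that("small-sample PERMANOVA p agrees with exhaustive enumeration", {
  set.seed(149)
  x <- matrix(rnorm(6 * 3), ncol = 3)
  g <- rep(c("A", "B"), each = 3)
  xs <- scale(x)
  d <- as.matrix(dist(xs))
  f_of <- function(lab) oracle_pseudo_f(d, lab)$f
  f_obs <- f_of(g)
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"; f_of(lab)
  })
  p_exact <- mean(fs >= f_obs - 1e-12)
  pr <- permanova(x, g, n_perm = 999, seed = 23)
  expect_equal(pr$pseudo_f, f_obs, tolerance = 1e-9)
  expect_lt(abs(pr$p - p_exact), 0.15)
})

test_that("PERMANOVA p is uniform on the permutation grid under the null", {
  ps <- vapply(1:200, function(s) {
    with_seed_val <- withr::with_seed(7000 + s, {
      x <- matrix(rnorm(24 * 3), ncol = 3)
      g <- rep(c("A", "B"), each = 12)
      permanova(x, g, n_perm = 99, seed = 7000 + s)$p
    })
    with_seed_val
  }, numeric(1))
  grid_cdf <- function(q) vapply(q, function(v) mean(ps <= v), numeric(1))
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(grid_cdf(qs) - qs)), 0.1)
})

test_that("subsampling balances groups and detection works at a 3-SD shift", {
  set.seed(151)
  x <- matrix(rnorm(150 * 5), ncol = 5)
  g <- rep(c("A", "B"), c(90, 60))
  x[g == "B", 3] <- x[g == "B", 3] + 3
  pr <- permanova(x, g, n_perm = 999, subsample_n = 50, seed = 29)
  expect_equal(pr$n, 100L)
  expect_equal(pr$p, 0.001)
  expect_error(permanova(x, g, subsample_n = 70, seed = 1),
               "exceeds a group")
  # bit-reproducible under a fixed seed
  pr2 <- permanova(x, g, n_perm = 999, subsample_n = 50, seed = 29)
  expect_identical(unclass(pr), unclass(pr2))
})

test_that("PERMDISP detects dispersion differences and matches vegan's F", {
  set.seed(157)
  x <- matrix(rnorm(120 * 4), ncol = 4)
  g <- rep(c("A", "B"), each = 60)
  x[g == "B", ] <- x[g == "B", ] * 3
  pd <- permdisp(x, g, n_perm = 499, seed = 31)
  expect_lt(pd$p, 0.01)

  xs <- scale(x)
  bd <- vegan::betadisper(dist(xs), g, type = "centroid")
  f_vegan <- anova(bd)$`F value`[1]
  expect_equal(pd$F, f_vegan, tolerance = 1e-6)

  # equal dispersion: typically non-significant
  set.seed(163)
  xn <- matrix(rnorm(120 * 4), ncol = 4)
  pdn <- permdisp(xn, g, n_perm = 499, seed = 37)
  expect_gt(pdn$p, 0.05)

  expect_error(permdisp(x[1:2, ], c("A", "B"), seed = 1), "residual")
})

test_that("effect-size helpers work directly on published statistics", {
  es <- kw_effect_sizes(H = 12, k = 3, N = 60)
  expect_equal(unname(es["eta2"]), 10 / 57)
  expect_equal(unname(es["epsilon2"]), 10 / 59)
  expect_equal(dunn_z(10, 20, 12, 12, 24, tie_term = 0),
               -10 / sqrt(24 * 25 / 12 * (2 / 12)))
})
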