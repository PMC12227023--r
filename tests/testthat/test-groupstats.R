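test_that("mid-ranks handle ties and always sum to N(N+1)/2", {
  expect_equal(ranks_with_ties(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(ranks_with_ties(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4))
  expect_equal(ranks_with_ties(rep(7, 5)), rep(3, 5))
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- sample(1:6, 15, replace = TRUE)
      expect_equal(sum(ranks_with_ties(x)), 15 * 16 / 2)
    }
  })
  expect_error(ranks_with_ties(c(1, NA)), "finite")
})

test_that("Kruskal-Wallis matches the exact-permutation oracle's statistic", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  got <- kruskal_wallis(groups)
  # independent oracle: enumerate all 1680 assignments of the 9 ranks
  oracle_h <- function(r1, r2, r3) {
    12 / (9 * 10) * (sum(r1)^2 / 3 + sum(r2)^2 / 3 + sum(r3)^2 / 3) - 3 * 10
  }
  ranks <- 1:9
  hs <- c()
  for (c1 in asplit(combn(9, 3), 2)) {
    rest <- setdiff(1:9, c1)
    for (c2 in asplit(combn(rest, 3), 2)) {
      c3 <- setdiff(rest, c2)
      hs <- c(hs, oracle_h(ranks[c1], ranks[c2], ranks[c3]))
    }
  }
  h_obs <- oracle_h(1:3, 4:6, 7:9)
  expect_length(hs, 1680L)
  expect_equal(got$H, h_obs, tolerance = 1e-12)
  expect_equal(got$df, 2L)
  # implemented p is the chi-square upper tail of the same statistic
  expect_equal(got$p, pchisq(h_obs, 2, lower.tail = FALSE), tolerance = 1e-12)
  # enumeration sanity: perfect separation is the extreme of the null set
  expect_equal(mean(hs >= h_obs - 1e-12), 6 / 1680)
})

test_that("Kruskal-Wallis agrees with the reference implementation under ties", {
  withr::with_seed(31, {
    for (i in 1:10) {
      groups <- lapply(1:4, function(g) sample(1:8, sample(4:12, 1),
                                               replace = TRUE) / 2)
      names(groups) <- letters[1:4]
      got <- kruskal_wallis(groups)
      ref <- stats::kruskal.test(groups)
      expect_equal(got$H, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
      expect_equal(got$df, unname(ref$parameter))
    }
  })
})

test_that("Kruskal-Wallis degenerate and error contracts hold", {
  res <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
  expect_error(kruskal_wallis(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(kruskal_wallis(list(a = c(1, 2))), "2 groups")
  # df is k - 1: the seven-cue design gives 6
  seven <- setNames(lapply(1:7, function(i) rnorm(5)), paste0("g", 1:7))
  expect_equal(kruskal_wallis(seven)$df, 6L)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    groups <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
    h0 <- kruskal_wallis(groups)$H
    for (f in list(function(x) exp(x), function(x) x^3,
                   function(x) atan(x) * 10)) {
      expect_equal(kruskal_wallis(lapply(groups, f))$H, h0, tolerance = 1e-12)
    }
  })
})

test_that("with two groups KW equals the squared rank-sum deviate", {
  withr::with_seed(17, {
    for (i in 1:10) {
      xi <- sample(1:10, 9, replace = TRUE) / 3
      xj <- sample(1:10, 7, replace = TRUE) / 3
      ni <- length(xi); nj <- length(xj); m <- ni + nj
      r <- rank(c(xi, xj))
      Tj <- sum(r[(ni + 1):m])
      ET <- nj * (m + 1) / 2
      VarT <- ni * nj / (m * (m - 1)) * (sum(r^2) - m * (m + 1)^2 / 4)
      z2 <- (Tj - ET)^2 / VarT
      expect_equal(kruskal_wallis(list(a = xi, b = xj))$H, z2,
                   tolerance = 1e-9)
    }
  })
})

test_that("DSCF pairwise moments match exhaustive rank-sum enumeration", {
  enumerate_moments <- function(xi, xj) {
    pooled <- c(xi, xj)
    r <- rank(pooled)
    m <- length(pooled)
    nj <- length(xj)
    sums <- combn(m, nj, function(idx) sum(r[idx]))
    c(mean = mean(sums), var = mean((sums - mean(sums))^2))
  }
  check_pair <- function(groups, g1, g2, k) {
    res <- dscf_pairwise(groups)
    row <- res[res$group1 == g1 & res$group2 == g2, ]
    xi <- groups[[g1]]; xj <- groups[[g2]]
    mom <- enumerate_moments(xi, xj)
    r <- rank(c(xi, xj))
    Tj <- sum(r[(length(xi) + 1):length(r)])
    W_expected <- sqrt(2) * (Tj - mom["mean"]) / sqrt(mom["var"])
    expect_equal(row$W, unname(W_expected), tolerance = 1e-9)
    expect_equal(row$p, ptukey(abs(row$W), k, Inf, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # distinct values, n = 4 + 4 (70 splits per pair)
  g <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8), c = c(10, 12, 14, 16))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
    check_pair(g, pair[1], pair[2], k = 3)
  # heavy ties: the variance formula is the exact permutation variance
  gt <- list(a = c(1, 2, 2, 3), b = c(2, 4, 4, 5), c = c(2, 2, 3, 3))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
    check_pair(gt, pair[1], pair[2], k = 3)
})

test_that("DSCF symmetry, invariance and degenerate contracts hold", {
  # identical groups: rank sum equals its expectation exactly
  res <- dscf_pairwise(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(res$W, 0)
  expect_equal(res$p, 1)
  # all pooled values tied: zero variance, flagged
  degen <- dscf_pairwise(list(a = c(3, 3), b = c(3, 3), c = c(1, 2)))
  row <- degen[degen$group1 == "a" & degen$group2 == "b", ]
  expect_true(row$degenerate)
  expect_equal(row$p, 1)
  # shift invariance and pair-order symmetry
  g <- list(a = c(1, 5, 9, 2), b = c(3, 7, 11, 4), c = c(0, 6, 13, 8))
  r1 <- dscf_pairwise(g)
  r2 <- dscf_pairwise(lapply(g, function(x) x + 100))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  swapped <- dscf_pairwise(g[c("b", "a", "c")])
  p_ab <- r1$p[r1$group1 == "a" & r1$group2 == "b"]
  p_ba <- swapped$p[swapped$group1 == "b" & swapped$group2 == "a"]
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
  # a pair count check for the full seven-cue design
  seven <- setNames(lapply(1:7, function(i) rnorm(4)), paste0("g", 1:7))
  expect_equal(nrow(dscf_pairwise(seven)), 21L)
})

test_that("DSCF familywise adjustment is never anti-conservative", {
  withr::with_seed(23, {
    for (i in 1:25) {
      k <- sample(3:6, 1)
      groups <- setNames(lapply(1:k, function(g) rnorm(sample(4:10, 1), g / 2)),
                         paste0("g", 1:k))
      res <- dscf_pairwise(groups)
      unadj <- 2 * pnorm(abs(res$W) / sqrt(2), lower.tail = FALSE)
      expect_true(all(res$p >= unadj - 1e-12))
    }
  })
})

test_that("Levene statistic matches the reference implementation", {
  withr::with_seed(41, {
    for (i in 1:8) {
      groups <- list(a = rnorm(10, sd = 1), b = rnorm(12, sd = 3),
                     c = rnorm(9, sd = 0.5))
      got <- levene_test(groups)
      y <- unlist(groups)
      g <- factor(rep(names(groups), lengths(groups)))
      ref <- car::leveneTest(y, g, center = mean)
      expect_equal(got$W, ref$`F value`[1], tolerance = 1e-9)
      expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
      # Brown-Forsythe variant
      got_m <- levene_test(groups, center = "median")
      ref_m <- car::leveneTest(y, g, center = median)
      expect_equal(got_m$W, ref_m$`F value`[1], tolerance = 1e-9)
    }
  })
})

test_that("Levene is location-invariant and degenerates gracefully", {
  g <- list(a = c(1, 2, 3, 5), b = c(2, 4, 8, 9))
  shifted <- list(a = g$a + 10, b = g$b - 3)
  expect_equal(levene_test(g)$W, levene_test(shifted)$W, tolerance = 1e-12)
  # exact translations of each other: identical deviations, W = 0
  trans <- list(a = c(1, 2, 5), b = c(11, 12, 15))
  res <- levene_test(trans)
  expect_equal(res$W, 0)
  expect_equal(res$p, 1)
  # all deviations identical across and within groups
  degen <- levene_test(list(a = c(1, 3), b = c(4, 6)))
  expect_equal(degen$W, 0)
  expect_true(degen$degenerate)
})

test_that("Shapiro-Wilk wrapper behaves over its domain", {
  n <- 50
  ideal <- qnorm(((1:n) - 0.5) / n)
  res <- shapiro_wilk(ideal)
  expect_gt(res$W, 0.99)
  bimodal <- c(rnorm(20, 0, 0.01), rnorm(20, 10, 0.01))
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)
  withr::with_seed(6, {
    for (i in 1:5) {
      w <- shapiro_wilk(rnorm(sample(3:100, 1)))$W
      expect_true(w > 0 && w <= 1)
    }
  })
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
})

test_that("IQR outlier labeling follows the interpolated-quartile convention", {
  # Q1 = 2, Q3 = 4, fences [-1, 7]: only 100 is outside
  expect_identical(iqr_outliers(c(1, 2, 3, 4, 100)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(iqr_outliers(rep(3.3, 6)), rep(FALSE, 6))
  withr::with_seed(19, {
    x <- rnorm(30)
    expect_identical(iqr_outliers(2.5 * x + 7), iqr_outliers(x))
  })
  expect_warning(flags <- iqr_outliers(c(1, 2, 3)), "fewer than 4")
  expect_identical(flags, rep(FALSE, 3))
})

test_that("main-effect workflow gates pairwise comparisons on significance", {
  withr::with_seed(77, {
    mk_summaries <- function(means) {
      do.call(rbind, lapply(seq_along(means), function(i) tibble::tibble(
        participant_id = sprintf("P%02d", 1:10),
        cue = names(means)[i], direction = "focus",
        n_used_pv = 10L, n_used_fa = 10L,
        mean_pv = rnorm(10, 6), sd_pv = 0.5,
        mean_fa = rnorm(10, means[i], 0.05), sd_fa = 0.05,
        gain = 1, sd_defined = TRUE
      )))
    }
    means <- setNames(c(1.46, 1.46, 1.2, 1.07, 0.9, 0.82, 0.5),
                      names(default_gain_table()))
    inf <- main_effect_workflow(mk_summaries(means), "fa", "focus")
    expect_s3_class(inf, "group_inference")
    expect_equal(inf$kw$df, 6L)
    expect_lt(inf$kw$p, 0.05)
    expect_equal(nrow(inf$pairwise), 21L)
    expect_true(is.finite(inf$assumptions$levene$p))  # assumptions recorded
    expect_length(inf$assumptions$shapiro, 7L)
    # constant data: degenerate KW, no pairwise stage
    const <- mk_summaries(means)
    const$mean_fa <- 1.0
    inf0 <- main_effect_workflow(const, "fa", "focus")
    expect_null(inf0$pairwise)
    expect_match(inf0$pairwise_reason, "not significant")
  })
})
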