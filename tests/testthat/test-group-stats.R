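# Shapiro-Wilk wrapper, Kruskal-Wallis + Dunn, box descriptives, cohort stats

test_that("normality check separates Gaussian from skewed samples", {
  gauss <- qnorm(ppoints(50))          # exact standard-normal quantiles
  res <- normality_check(gauss)
  expect_gt(res$p, 0.05)
  expect_lte(res$W, 1)
  set.seed(51)
  skewed <- exp(rnorm(50))
  expect_lt(normality_check(skewed)$p, 0.05)
  expect_error(normality_check(rep(3, 10)), "constant")
})

test_that("Kruskal-Wallis H matches the brute-force rank formula", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  res <- kruskal_wallis(groups)
  # manual: ranks 1..9, mean ranks 2, 5, 8
  H_manual <- 12 / (9 * 10) * (3 * 2^2 + 3 * 5^2 + 3 * 8^2) - 3 * 10
  expect_equal(res$H, H_manual, tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$p, pchisq(H_manual, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(nrow(res$pairwise), 3L)  # g(g-1)/2
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rnorm(30)
  lab <- rep(1:3, 10)
  h1 <- kruskal_wallis(x, lab)$H
  h2 <- kruskal_wallis(exp(x), lab)$H
  h3 <- kruskal_wallis(x^3, lab)$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("two-group separation monotonically strengthens the evidence", {
  set.seed(53)
  base <- rnorm(15)
  p_at_shift <- vapply(c(0.5, 1.5, 3), function(d) {
    kruskal_wallis(list(base, base + d))$p
  }, numeric(1))
  expect_true(all(diff(p_at_shift) < 0))
})

test_that("Dunn z matches the hand formula with tie correction", {
  set.seed(54)
  groups <- list(a = round(rnorm(4), 1), b = round(rnorm(4) + 1, 1),
                 c = round(rnorm(4) - 0.5, 1))
  res <- kruskal_wallis(groups, adjustment = "bonferroni")
  x <- unlist(groups); lab <- rep(names(groups), each = 4)
  r <- rank(x)
  rbar <- tapply(r, lab, mean)
  N <- 12
  ties <- table(x)
  V <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  for (row in seq_len(nrow(res$pairwise))) {
    i <- res$pairwise$group_i[row]; j <- res$pairwise$group_j[row]
    z_manual <- (rbar[i] - rbar[j]) / sqrt(V * (1 / 4 + 1 / 4))
    expect_equal(res$pairwise$z[row], unname(z_manual), tolerance = 1e-12)
    expect_equal(res$pairwise$p_adjusted[row],
                 min(1, res$pairwise$p_raw[row] * 3), tolerance = 1e-12)
  }
  # adjustment monotonicity
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
})

test_that("equal groups give zero z and unit adjusted p", {
  res <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$z, rep(0, 3))
  expect_equal(res$p_adjusted, rep(1, 3))
  # direction consistency for two groups
  res2 <- kruskal_wallis(list(lo = c(1, 2, 3), hi = c(10, 11, 12)),
                         adjustment = "none")
  expect_lt(res2$pairwise$z[1], 0)  # lower mean rank first
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "degenerate")
})

test_that("box descriptives follow the sort-based quantile convention", {
  b <- describe_box(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$minimum, 1)
  expect_equal(b$maximum, 5); expect_equal(b$lower_quartile, 2)
  expect_equal(b$upper_quartile, 4)
  single <- describe_box(7.5)
  expect_true(all(unlist(single) == 7.5))
  set.seed(55)
  x <- rnorm(37)
  bx <- describe_box(x)
  q_ref <- unname(quantile(sort(x), c(0.25, 0.5, 0.75), type = 7))
  expect_equal(c(bx$lower_quartile, bx$median, bx$upper_quartile), q_ref)
  expect_true(bx$minimum <= bx$lower_quartile &&
                bx$lower_quartile <= bx$median &&
                bx$median <= bx$upper_quartile &&
                bx$upper_quartile <= bx$maximum)
  # permutation invariance
  bx2 <- describe_box(sample(x))
  expect_identical(bx, bx2)
})

test_that("cohort descriptives recompute the reference cohort summary", {
  tab <- cohort_fixture()
  expect_identical(nrow(tab), 13L)
  st <- descriptive_cohort(tab)
  expect_equal(round(st$mean[st$variable == "age_years"], 2), 12.62)
  expect_equal(round(st$sd[st$variable == "age_years"], 2), 4.05)
  expect_equal(round(st$mean[st$variable == "height_cm"], 2), 160.62)
  expect_equal(round(st$sd[st$variable == "height_cm"], 2), 5.32)
  expect_equal(round(st$mean[st$variable == "bcs"], 2), 3.31)
  expect_equal(round(st$sd[st$variable == "bcs"], 2), 0.48)
  expect_error(descriptive_cohort(tab[0, ]), "empty")
})

test_that("compact letters share a letter iff groups do not differ", {
  pw <- data.frame(group_i = c("a", "a", "b"), group_j = c("b", "c", "c"),
                   p_adjusted = c(0.01, 0.8, 0.02))
  cld <- compact_letters(pw, c("a", "b", "c"))
  expect_true(cld["a"] != cld["b"])   # differ: no shared letter
  expect_true(grepl(substr(cld["a"], 1, 1), cld["c"]) ||
                any(strsplit(cld["a"], "")[[1]] %in% strsplit(cld["c"], "")[[1]]))
  none <- compact_letters(data.frame(group_i = "a", group_j = "b",
                                     p_adjusted = 0.9), c("a", "b"))
  expect_identical(unname(none), c("a", "a"))
})
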