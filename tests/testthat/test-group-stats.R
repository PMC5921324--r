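# Inferential machinery: permutation test, ANCOVA, partial correlation,
# demographics, normality, multiplicity.

make_tables <- function(seed = 1, n = 10, p = 12) {
  set.seed(seed)
  X <- matrix(rexp(n * p), n, p)
  regional_metric_table(X, metric = "MK")
}

test_that("duplicated groups give zero differences and p = 1", {
  tab <- make_tables(1)
  pt <- gm_permutation_test(tab, tab, grid = c(0.1, 0.3), n_perm = 19, seed = 2)
  expect_equal(pt$Cp$diff, c(0, 0))
  expect_equal(pt$Lp$diff, c(0, 0))
  expect_equal(pt$Cp$p, c(1, 1))
  expect_equal(nrow(pt$significant_ranges$Cp), 0)
})

test_that("permutation p is bounded below by 1/(n_perm + 1)", {
  set.seed(3)
  a <- regional_metric_table(matrix(rexp(60), 6, 10))
  b <- regional_metric_table(matrix(rexp(60, rate = 4), 6, 10))
  pt <- gm_permutation_test(a, b, grid = 0.2, n_perm = 24, seed = 1)
  expect_gte(min(pt$Cp$p, pt$Lp$p), 1 / 25)
  expect_lte(max(pt$Cp$p, pt$Lp$p), 1)
})

test_that("permutation test validates its inputs", {
  tab <- make_tables(1)
  tiny_a <- regional_metric_table(matrix(rexp(36), 3, 12))
  tiny_b <- regional_metric_table(matrix(rexp(24), 2, 12))
  expect_error(gm_permutation_test(tab, tab, n_perm = 0), "n_perm")
  expect_error(gm_permutation_test(tiny_a, tiny_b, grid = 0.2, n_perm = 5),
               "6 subjects")
  other <- regional_metric_table(matrix(rexp(40), 10, 4))
  expect_error(gm_permutation_test(tab, other, n_perm = 5), "region labels")
})

test_that("permutation pipeline detects a real effect in the study cohort", {
  co <- generate_gm_cohort(test_cohort(seed = 21))
  pt <- gm_permutation_test(co$tables$MK$patients, co$tables$MK$controls,
                            grid = seq(0.10, 0.30, 0.05), n_perm = 99,
                            seed = 5)
  # patients built with attenuated clustering: Cp down, weighted Lp up
  expect_true(all(pt$Cp$diff < 0))
  expect_true(all(pt$Lp$diff > 0))
  expect_true(mean(pt$Cp$p < 0.05) > 0.5)
})

test_that("ANCOVA with no covariates reduces exactly to the pooled t-test", {
  set.seed(4)
  v <- rnorm(30); g <- rep(c("a", "b"), 15)
  an <- ancova_group_effect(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
})

test_that("constant covariates are dropped; collinear ones are an error", {
  set.seed(5)
  v <- rnorm(24); g <- rep(c("a", "b"), each = 12)
  expect_message(an <- ancova_group_effect(v, g, age = rep(70, 24)),
                 "constant")
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # sex identical to group: group effect not estimable
  expect_error(ancova_group_effect(v, g, sex = g), "collinear")
})

test_that("ANCOVA detects a 3-SD group shift and adjusts for covariates", {
  set.seed(6)
  n <- 40
  g <- rep(c("patient", "control"), each = n / 2)
  age <- rnorm(n, 70, 8)
  v <- 0.05 * age + rnorm(n) + ifelse(g == "patient", 3, 0)
  an <- ancova_group_effect(v, g, age = age,
                            sex = sample(c("F", "M"), n, replace = TRUE))
  expect_lt(an$p, 0.001)
  expect_setequal(an$covariates, c("age", "sex"))
})

test_that("ANCOVA p-values are approximately uniform under the null", {
  set.seed(7)
  ps <- replicate(400, {
    g <- rep(c("a", "b"), each = 10)
    ancova_group_effect(rnorm(20), g, age = rnorm(20, 70, 5))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("partial correlation equals Pearson without covariates", {
  set.seed(8)
  x <- rnorm(25); y <- rnorm(25)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)
})

test_that("degenerate residuals are flagged not-evaluable", {
  set.seed(9)
  z <- rnorm(20)
  y <- 2 * z + 1          # exactly linear in the covariate
  x <- rnorm(20)
  pc <- partial_correlation(x, y, covariates = data.frame(z = z))
  expect_false(pc$evaluable)
  expect_true(is.na(pc$r))
})

test_that("partial correlation is invariant to affine covariate changes", {
  set.seed(10)
  z <- rnorm(30); x <- z + rnorm(30); y <- -z + rnorm(30)
  p1 <- partial_correlation(x, y, data.frame(z = z))
  p2 <- partial_correlation(x, y, data.frame(z = 5 * z - 100))
  expect_equal(p1$r, p2$r, tolerance = 1e-12)
})

test_that("partial correlation recovers an injected effect under confounding", {
  set.seed(11)
  est <- replicate(40, {
    n <- 200
    age <- rnorm(n)
    u <- rnorm(n)
    # x, y share the latent u after removing age: true partial r = 0.5
    x <- age + u + rnorm(n)
    y <- -age + u + rnorm(n)
    partial_correlation(x, y, data.frame(age = age))$r
  })
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("demographics table reproduces the printed 2x2 chi-square", {
  cov <- data.frame(
    group = rep(c("patient", "control"), c(21, 19)),
    sex = c(rep(c("F", "M"), c(12, 9)), rep(c("F", "M"), c(9, 10))),
    age = c(rnorm(21, 74, 7), rnorm(19, 70, 8))
  )
  out <- demographics_compare(cov, continuous = "age")
  sex_row <- out[out$variable == "sex", ]
  # frozen from the closed-form continuity-corrected chi-square on the
  # printed counts ((12,9),(9,10))
  expect_equal(sex_row$p, 0.7632854, tolerance = 1e-6)
})

test_that("identical groups give t = 0, p = 1; huge shifts give tiny p", {
  cov <- data.frame(group = rep(c("a", "b"), each = 10),
                    age = rep(c(60, 65, 70, 75, 80), 4),
                    sex = rep(c("F", "M"), 10))
  out <- demographics_compare(cov, continuous = "age")
  expect_equal(out$statistic[out$variable == "age"], 0)
  expect_equal(out$p[out$variable == "age"], 1)

  set.seed(12)
  cov2 <- data.frame(group = rep(c("a", "b"), each = 15),
                     age = c(rnorm(15), rnorm(15) + 10), sex = "F")
  out2 <- demographics_compare(cov2, continuous = "age")
  expect_lt(out2$p[out2$variable == "age"], 1e-6)
})

test_that("normality check rejects exponential data and flags constants", {
  set.seed(13)
  rej <- vapply(1:10, function(i) {
    x <- c(rexp(200), rnorm(200))
    g <- rep(c("exp", "norm"), each = 200)
    out <- normality_check(x, g)
    out$p[out$group == "exp"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)

  out <- normality_check(c(rep(1, 5), rnorm(5)), rep(c("c", "n"), each = 5))
  expect_true(out$degenerate[out$group == "c"])
})

test_that("p-value adjustment matches the brute-force step-up procedure", {
  bh_oracle <- function(p) { # direct BH step-up definition
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bonferroni"),
               c(0.04, 0.08, 0.12, 0.16))
  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")
  set.seed(14)
  for (r in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(adjust_pvalues(p), bh_oracle(p), tolerance = 1e-12)
  }
})
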