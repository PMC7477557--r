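test_that("adjusted R-squared follows its definition", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_lte(adjusted_r2(0, 50, 3), 0)
  expect_equal(adjusted_r2(0.5, 102, 1), 0.495)
  expect_error(adjusted_r2(0.5, 4, 3), "n > k")
})

test_that("stepwise regression recovers a planted main effect", {
  set.seed(11)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.1)
  fit <- stepwise_lm(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(fit$selected_terms, "x1")
  expect_gt(fit$coefficients[["x1"]], 1.9)
  expect_lt(fit$coefficients[["x1"]], 2.1)
  expect_gt(fit$adj_r2, 0.99)
})

test_that("stepwise regression reaches an interaction through its parents", {
  set.seed(12)
  n <- 400
  # positive-valued predictors so the product correlates with its parents
  x1 <- runif(n, 0.5, 1.5); x2 <- runif(n, 0.5, 1.5)
  y <- 3 * x1 * x2 + rnorm(n, 0, 0.05)
  fit <- stepwise_lm(y, data.frame(x1 = x1, x2 = x2))
  expect_true("x1:x2" %in% fit$selected_terms)
  expect_true(all(c("x1", "x2") %in% fit$selected_terms))  # hierarchy
})

test_that("stepwise entry rate under the null tracks p_enter per candidate", {
  runs <- 60
  entered <- 0
  for (s in 1:runs) {
    set.seed(1000 + s)
    y <- rnorm(300)
    fit <- stepwise_lm(y, data.frame(a = rnorm(300), b = rnorm(300),
                                     c = rnorm(300)))
    if (length(fit$selected_terms) > 0) entered <- entered + 1
  }
  # P(any of 3 independent candidates enters) = 1 - 0.95^3 ~ 0.143
  expect_gt(entered / runs, 0.143 - 2.5 * sqrt(0.143 * 0.857 / runs))
  expect_lt(entered / runs, 0.143 + 2.5 * sqrt(0.143 * 0.857 / runs))
})

test_that("stepwise regression rejects degenerate designs", {
  expect_error(stepwise_lm(rnorm(50), data.frame(a = rep(1, 50))),
               "constant")
  expect_error(stepwise_lm(rnorm(5),
                           data.frame(a = rnorm(5), b = rnorm(5),
                                      c = rnorm(5))),
               "too few")
})

test_that("one-way ANOVA matches the brute-force decomposition", {
  groups <- list(a = c(6.1, 5.8, 6.4, 6.0), b = c(7.2, 7.0, 6.8),
                 c = c(5.1, 5.4, 5.0, 5.2, 5.3))
  res <- anova_oneway(groups)
  expect_equal(res$F, anova_F_oracle(groups), tolerance = 1e-10)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 9)
  expect_equal(unname(res$means), vapply(groups, mean, numeric(1),
                                         USE.NAMES = FALSE))

  # identical groups: no between-group signal
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_lt(anova_oneway(same)$F, 1e-10)
  expect_gt(anova_oneway(same)$p_value, 0.999)

  # perfect separation with zero within-group variance
  sep <- anova_oneway(list(a = c(0, 0, 0), b = c(1, 1, 1)))
  expect_true(is.infinite(sep$F) || sep$F > 1e10)
  expect_lt(sep$p_value, 1e-10)

  expect_error(anova_oneway(list(a = 1:3)), "2 groups")
})

test_that("ANOVA with two groups squares the pooled t statistic", {
  set.seed(13)
  x <- rnorm(20, 1); y <- rnorm(25, 1.4)
  res <- anova_oneway(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey HSD matches the pooled-t closed form for two groups", {
  set.seed(14)
  x <- rnorm(15, 0); y <- rnorm(22, 0.8)
  tk <- tukey_hsd(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  # for k = 2 the studentized range q equals t * sqrt(2)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(abs(tk$diff), abs(mean(x) - mean(y)), tolerance = 1e-12)
})

test_that("Tukey HSD flags exactly the shifted group and is conservative", {
  set.seed(15)
  groups <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50),
                 d = rnorm(50, 5))  # one group shifted by 5 SD
  tk <- tukey_hsd(groups)
  expect_equal(nrow(tk), 6)  # all unordered pairs once
  sig <- tk[tk$significant, ]
  expect_equal(nrow(sig), 3)
  expect_true(all(apply(sig[, c("group_a", "group_b")], 1,
                        function(r) "d" %in% r)))
  # identical groups -> nothing significant
  same <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  expect_false(any(tukey_hsd(same)$significant))
  # conservativeness: adjusted p >= unadjusted pairwise p
  for (i in seq_len(nrow(tk))) {
    pa <- tk$group_a[i]; pb <- tk$group_b[i]
    praw <- t.test(groups[[pa]], groups[[pb]], var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[i] + 1e-12, praw * 0.999)
  }
})

test_that("two-sample KS statistic equals the ECDF supremum and is symmetric", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1, 3))$D, 0.5)
  set.seed(16)
  a <- rnorm(200); b <- rnorm(150, 0.3)
  expect_equal(ks_two_sample(a, b)$D, ks_two_sample(b, a)$D)
  expect_equal(ks_two_sample(a, b)$D, ks_D_oracle(a, b), tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), a), "nonempty")
})

test_that("MAD outlier flags follow the scaled-MAD rule", {
  expect_equal(mad_outliers(c(1, 1, 1, 100)), c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(mad_outliers(rep(3, 10))))
  set.seed(17)
  x <- rnorm(1000)
  expect_lt(mean(mad_outliers(x)), 0.01)
  # agreement with the explicit formula on a generic sample
  y <- rlnorm(200)
  manual <- abs(y - median(y)) / (1.4826 * median(abs(y - median(y)))) > 3
  expect_equal(mad_outliers(y), manual)
  expect_error(mad_outliers(c(1, 2)), "at least 3")
})
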