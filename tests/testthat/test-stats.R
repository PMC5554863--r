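test_that("pooled two-sample t matches the hand-computed fixture", {
  out <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  # pooled s^2 = 1, se = sqrt(2/3), t = -3/se
  expect_equal(out$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(out$statistic, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
})

test_that("paired t on identical vectors is t = 0, p = 1", {
  out <- paired_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
})

test_that("RM-ANOVA equals aov and the 2-condition case equals paired t^2", {
  withr::with_seed(10, {
    tab <- tidyr::expand_grid(subject = paste0("s", 1:6),
                              condition = c("day1", "day2", "day3"))
    tab$value <- rnorm(nrow(tab)) +
      rep(c(0, 0.5, 0.2), times = 6) +
      rep(rnorm(6), each = 3)
  })
  out <- rm_anova_oneway(tab)
  ref <- summary(stats::aov(value ~ condition + Error(subject / condition),
                            data = tab))
  fref <- ref[["Error: subject:condition"]][[1]]["condition", "F value"]
  expect_equal(out$statistic, fref, tolerance = 1e-10)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 10)

  two <- tab[tab$condition != "day3", ]
  f2 <- rm_anova_oneway(two)
  t2 <- paired_ttest(two$value[two$condition == "day1"],
                     two$value[two$condition == "day2"])
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p.value, t2$p.value, tolerance = 1e-10)
})

test_that("pearson_cor returns r, R^2 and the classical test", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.2, 2.9, 5.1, 7.4, 12.5)
  out <- pearson_cor(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$estimate, r_hand, tolerance = 1e-12)
  expect_equal(out$r.squared, r_hand^2, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), y[1:3]), "zero variance")
})

test_that("permutation test matches exhaustive enumeration at n = 4 + 4", {
  x <- c(0.3, 1.2, 2.1, 0.8)
  y <- c(1.9, 2.4, 3.1, 2.2)
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  splits <- utils::combn(8, 4)
  stats_all <- apply(splits, 2, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p_exact <- mean(abs(stats_all) >= abs(obs) - 1e-12)
  out <- permutation_test(x, y, n_perm = 20000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(out$p.value - p_exact), 2 * se + 2 / 20000)
})

test_that("degenerate and identical inputs give p = 1", {
  expect_equal(permutation_test(rep(2, 4), rep(2, 4), n_perm = 99)$p.value, 1)
  x <- c(1, 2, 3, 4)
  expect_equal(permutation_test(x, x, n_perm = 999, paired = TRUE)$p.value, 1)
})

test_that("permutation p-values are reproducible and super-uniform under the null", {
  x <- rnorm(10)
  y <- rnorm(10)
  p1 <- permutation_test(x, y, n_perm = 200, seed = 5)
  p2 <- permutation_test(x, y, n_perm = 200, seed = 5)
  expect_identical(p1, p2)

  withr::with_seed(2024, {
    pvals <- vapply(1:400, function(i) {
      a <- rnorm(8)
      b <- rnorm(8)
      permutation_test(a, b, n_perm = 200, seed = i)$p.value
    }, numeric(1))
  })
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= alpha), alpha + 0.05)
  }
})

test_that("BH step-up matches the worked example and the brute-force oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(out$rejected))
  expect_true(all(bh_fdr(rep(1, 6))$rejected == FALSE))
  expect_equal(nrow(bh_fdr(numeric(0))), 0)

  withr::with_seed(909, {
    for (rep in 1:50) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      q <- runif(1, 0.01, 0.2)
      out <- bh_fdr(p, q)
      expect_identical(out$rejected, oracle_bh(p, q))
      expect_identical(out$rejected, out$p.adjusted <= q)
    }
  })
})

test_that("BH rejections are monotone in q", {
  withr::with_seed(910, {
    p <- runif(30)^2
  })
  r1 <- bh_fdr(p, 0.02)$rejected
  r2 <- bh_fdr(p, 0.10)$rejected
  expect_true(all(r2[r1]))
})

test_that("a 1x1 grid contrast reduces to permutation_test + bh_fdr", {
  withr::with_seed(31, {
    df <- tidyr::expand_grid(node = c("a", "b"), gamma = 1, omega = 1,
                             condition = c("d1", "d2"), subject = 1:6)
    df$value <- rnorm(nrow(df)) + ifelse(df$node == "a" &
                                           df$condition == "d2", 2, 0)
  })
  out <- grid_contrast(df, n_perm = 500, q = 0.05, seed = 12)
  expect_equal(nrow(out), 2)
  seeds <- comdyn:::derive_seeds(12, 2)
  manual <- vapply(c("a", "b"), function(nd) {
    g <- df[df$node == nd, ]
    permutation_test(g$value[g$condition == "d1"],
                     g$value[g$condition == "d2"],
                     n_perm = 500,
                     seed = seeds[match(nd, c("a", "b"))])$p.value
  }, numeric(1))
  expect_equal(out$p.value, unname(manual[out$node]))
  expect_identical(out$rejected, bh_fdr(out$p.value, 0.05)$rejected)
})

test_that("grid_contrast finds a planted whole-grid effect and reports consistency", {
  withr::with_seed(32, {
    grid <- tidyr::expand_grid(gamma = c(0.95, 1, 1.05),
                               omega = c(0.95, 1.05))
    df <- tidyr::expand_grid(node = paste0("n", 1:6),
                             gamma = unique(grid$gamma),
                             omega = unique(grid$omega),
                             condition = c("d1", "d2"), subject = 1:10)
    df$value <- 0.1 + rnorm(nrow(df), 0, 0.02) +
      ifelse(df$node == "n3" & df$condition == "d2", 0.08, 0)
  })
  out <- grid_contrast(df, n_perm = 500, q = 0.05, seed = 13)
  cons <- consistent_nodes(out)
  expect_true(cons$consistent[cons$node == "n3"])
  expect_equal(cons$direction[cons$node == "n3"], -1)  # d1 < d2
  # drop one node's entire grid cell
  incomplete <- df[!(df$node == "n1" & df$gamma == 0.95 &
                       df$omega == 0.95), ]
  expect_error(grid_contrast(incomplete, n_perm = 10), "missing grid cells")
})
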