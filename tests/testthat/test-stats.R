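# Statistical battery: KS screen, Mann-Whitney vs the exhaustive oracle,
# the group screen, PCA relevance, and Bland-Altman agreement.

test_that("KS screen is calibrated on normal draws and powerful on bimodal ones", {
  set.seed(31)
  ps <- replicate(100, ks_normality(rnorm(1000)))
  expect_gte(mean(ps > 0.05), 0.9)
  expect_true(all(ps >= 0 & ps <= 1))
  bim <- c(rnorm(100, -5), rnorm(100, 5))
  expect_lt(ks_normality(bim), 0.001)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("Mann-Whitney reproduces hand-enumerated and degenerate cases", {
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 20, 30)), 0.1)
  expect_equal(mann_whitney(c(10, 20, 30), c(1, 2, 3)), 0.1)
  expect_equal(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1,
               tolerance = 0.05)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney equals the exhaustive permutation oracle on tie-free samples", {
  set.seed(41)
  for (case in 1:50) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    repeat {
      a <- round(runif(na, 0, 100), 3)
      b <- round(runif(nb, 0, 100), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    expect_lt(abs(mann_whitney(a, b) - perm_mw_oracle(a, b)), 1e-9)
  }
  # fixed grid: every pair of disjoint 4-element integer sets drawn from
  # a small universe
  grid <- utils::combn(8, 4)
  for (j in seq_len(ncol(grid))) {
    a <- grid[, j]
    b <- setdiff(1:8, a)
    expect_lt(abs(mann_whitney(a, b) - perm_mw_oracle(a, b)), 1e-9)
  }
})

test_that("a feature equal to the group indicator screens out with r = 1", {
  set.seed(51)
  n <- 24
  df <- data.frame(subject_id = sprintf("S%02d", 1:n),
                   group = rep(c("ms", "control"), each = n / 2),
                   stage = "basal")
  for (nm in feature_names()) df[[nm]] <- rnorm(n)
  df$di_rr_mean <- as.integer(df$group == "ms")  # perfect association
  sc <- feature_screen(df)
  row <- sc[sc$feature == "di_rr_mean", ]
  expect_equal(row$pearson_r, 1, tolerance = 1e-9)
  expect_true(row$significant)
  expect_lt(row$mw_p, 0.001)
  expect_equal(nrow(sc), 30)
  expect_true(all(sc$mw_p >= 0 & sc$mw_p <= 1, na.rm = TRUE))
  expect_true(all(abs(sc$pearson_r) <= 1, na.rm = TRUE))
  # Holm adjustment only raises p-values
  sch <- feature_screen(df, adjust = "holm")
  expect_true(all(sch$mw_p >= sc$mw_p - 1e-12, na.rm = TRUE))
})

test_that("point-biserial r equals the direct covariance formula", {
  set.seed(52)
  v <- rnorm(30)
  ind <- rep(c(0, 1), 15)
  direct <- cov(v, ind) / (sd(v) * sd(ind))
  expect_equal(unname(cor.test(v, ind)$estimate), direct, tolerance = 1e-12)
})

test_that("PCA relevance: orthonormal loadings, vacuous threshold, noise feature dropped", {
  set.seed(61)
  n <- 200
  common <- rnorm(n)
  x <- cbind(f1 = common + rnorm(n, sd = 0.1),
             f2 = -common + rnorm(n, sd = 0.1),
             f3 = rnorm(n))
  pr <- pca_relevance(x, n_components = 1)
  expect_lt(abs(pr$loadings["f3", 1]), 0.2)
  expect_setequal(pr$retained, c("f1", "f2"))
  # orthonormality of the full rotation
  rot <- pr$loadings
  expect_equal(t(rot) %*% rot, diag(ncol(rot)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # threshold zero retains everything
  expect_length(pca_relevance(x, coefficient_threshold = 0,
                              n_components = 3)$retained, 3)
  # reconstruction from all components reproduces the z-scored data
  z <- scale(x)
  scores <- z %*% rot
  expect_equal(scores %*% t(rot), z, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA retention honors both the fixed-count and cumulative-variance rules", {
  set.seed(62)
  sp <- cohort_spec(n_ms = 8, n_control = 6, stages = "basal",
                    duration = 10, sample_rate = 250, seed = 8)
  feats <- cohort_features(generate_cohort(sp), use_truth = TRUE)
  fixed <- pca_relevance(feats, n_components = 13)
  expect_equal(fixed$n_components, min(13, length(fixed$explained)))
  cum <- pca_relevance(feats, cum_var = 0.9)
  expect_gte(sum(cum$explained[seq_len(cum$n_components)]), 0.9)
  expect_lte(length(cum$retained), 30)
})

test_that("Bland-Altman reproduces the hand-computed example exactly", {
  ref <- c(0, 10, 20, 30)
  tst <- c(1, 9, 21, 29)                  # d = +1, -1, +1, -1
  ba <- bland_altman(ref, tst, matching_tolerance = 5)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(4 / 3))
  expect_equal(unname(ba$limits), c(-1, 1) * 1.96 * sqrt(4 / 3))
  expect_equal(round(unname(ba$limits["upper"]), 4), 2.2632)
})

test_that("Bland-Altman handles identity, unmatched marks and failures", {
  ba <- bland_altman(c(0, 100, 200), c(0, 100, 200))
  expect_equal(ba$mean_difference, 0)
  expect_equal(unname(ba$limits), c(0, 0))
  ba2 <- bland_altman(c(0, 100, 200, 500), c(2, 101, 203))
  expect_equal(ba2$n_pairs, 3)
  expect_equal(ba2$n_unmatched_reference, 1)
  expect_error(bland_altman(c(0, 100), c(500, 600), 50), "matched")
})

test_that("Bland-Altman limits widen monotonically with injected jitter", {
  set.seed(71)
  ref <- seq(0, 60000, by = 800)
  widths <- vapply(c(1, 4, 10), function(sdj) {
    tst <- ref + rnorm(length(ref), 0, sdj)
    ba <- bland_altman(ref, tst)
    unname(diff(ba$limits))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
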