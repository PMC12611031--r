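# Classifier back-ends: RBF-SVM, RobustBoost, signal windowing and CNN.

test_that("SVM separates well-separated clouds and stalls on contradictions", {
  cl <- gauss_clouds(20, dist = 2, sd = 0.1, seed = 1)
  m <- train_svm_rbf(cl$x, cl$y)
  expect_equal(mean(predict(m, cl$x) == cl$y), 1)
  # identical rows with conflicting labels: at most chance on those rows
  x2 <- matrix(rep(c(0.5, 0.5), 10), ncol = 2, byrow = TRUE)
  y2 <- rep(c("control", "ms"), 5)
  m2 <- train_svm_rbf(rbind(cl$x, x2), c(cl$y, y2))
  expect_lte(mean(predict(m2, x2) == y2), 0.5)
  expect_error(train_svm_rbf(cl$x, rep("ms", nrow(cl$x))), "single-class")
})

test_that("SVM standardization statistics come from the training data only", {
  cl <- gauss_clouds(20, dist = 2, sd = 0.1, seed = 2)
  m <- train_svm_rbf(cl$x, cl$y)
  expect_equal(m$center, colMeans(cl$x))
  shifted <- cl$x + 100          # grossly off-scale test data
  expect_length(predict(m, shifted), nrow(shifted))
})

test_that("RobustBoost drives training error to zero on separable data", {
  set.seed(4)
  n <- 60
  x <- matrix(runif(2 * n), ncol = 2)
  x <- x[abs(x[, 1] + x[, 2] - 1) > 0.08, , drop = FALSE]
  y <- ifelse(x[, 1] + x[, 2] > 1, "ms", "control")
  m <- train_robustboost(x, y, boost_config(robustness_target = 0.01))
  expect_equal(mean(predict(m, x) != y), 0)
  expect_lte(n_learners(m), 100)
})

test_that("a single boosting cycle reduces to one tree's prediction", {
  cl <- gauss_clouds(15, dist = 2, sd = 0.3, seed = 5)
  m <- train_robustboost(cl$x, cl$y, boost_config(n_cycles = 1))
  expect_equal(n_learners(m), 1)
  tree_pred <- msecg:::.tree_pm1(m$trees[[1]], cl$x)
  expect_equal(as.character(predict(m, cl$x)),
               ifelse(tree_pred == 1, "ms", "control"))
})

test_that("RobustBoost tolerates 20% flipped labels within 5 accuracy points", {
  cfg <- boost_config(max_depth = 1, robustness_target = 0.05,
                      time_step = "adaptive")
  gaps <- vapply(1:5, function(rep) {
    set.seed(100 + rep)
    d <- 10; n_side <- 500
    mu <- rep(2 / sqrt(d), d)
    xtr <- rbind(sweep(matrix(rnorm(n_side * d), ncol = d), 2, mu, "-"),
                 sweep(matrix(rnorm(n_side * d), ncol = d), 2, mu, "+"))
    ytr <- rep(c("control", "ms"), each = n_side)
    xte <- rbind(sweep(matrix(rnorm(500 * d), ncol = d), 2, mu, "-"),
                 sweep(matrix(rnorm(500 * d), ncol = d), 2, mu, "+"))
    yte <- rep(c("control", "ms"), each = 500)
    clean <- mean(predict(train_robustboost(xtr, ytr, cfg, seed = rep),
                          xte) == yte)
    yf <- ytr
    fl <- sample(2 * n_side, round(0.2 * 2 * n_side))
    yf[fl] <- ifelse(ytr[fl] == "ms", "control", "ms")
    noisy <- mean(predict(train_robustboost(xtr, yf, cfg, seed = rep),
                          xte) == yte)
    clean - noisy
  }, numeric(1))
  expect_lt(max(gaps), 0.05)
})

test_that("the AdaBoost fallback trains and predicts behind the same interface", {
  cl <- gauss_clouds(20, dist = 2, sd = 0.2, seed = 6)
  m <- train_robustboost(cl$x, cl$y, boost_config(method = "ada"))
  expect_s3_class(m, "ms_boost")
  expect_gte(mean(predict(m, cl$x) == cl$y), 0.95)
  expect_length(predict(m, cl$x[0, , drop = FALSE]), 0)
})

test_that("fixed seeds give identical boosted ensembles", {
  cl <- gauss_clouds(15, dist = 2, sd = 0.3, seed = 7)
  m1 <- train_robustboost(cl$x, cl$y, seed = 9)
  m2 <- train_robustboost(cl$x, cl$y, seed = 9)
  expect_identical(m1$alphas, m2$alphas)
  expect_identical(predict(m1, cl$x, type = "score"),
                   predict(m2, cl$x, type = "score"))
})

# --- windowing ------------------------------------------------------------

test_that("windowing partitions the truncated signal exactly", {
  e <- quick_record(duration = 10, fs = 100)
  ws <- window_signal(e$record, 300)
  wl <- dim(ws$windows)[2]
  expect_equal(wl, 1000 %/% 300)
  expect_equal(n_windows(ws), 300)
  for (lead in 1:2) {
    expect_identical(as.numeric(ws$windows[lead, , ]),
                     as.numeric(e$record$samples[lead, seq_len(300 * wl)]))
  }
  expect_error(window_signal(e$record, 10000), "shorter")
})

test_that("15 minutes at 1 kHz splits into 300 windows of 3000 samples", {
  # shape arithmetic only: a lightweight record with the right length
  rec <- ecg_record(matrix(0, nrow = 1, ncol = 900000,
                           dimnames = list("I")), 1000, "I")
  rec$samples[1, 1] <- 1
  ws <- window_signal(rec, 300)
  expect_equal(dim(ws$windows), c(1, 3000, 300))
})

# --- CNN ------------------------------------------------------------------

test_that("the gather-map convolution matches a direct nested-loop oracle", {
  set.seed(1)
  H <- 2; W <- 12; B <- 3
  spec <- cnn_spec(conv1_filters = 4, conv2_filters = 3)
  net <- msecg:::.cnn_init(spec, H, W)
  batch <- array(rnorm(H * W * B), c(H, W, B))
  fw <- msecg:::.cnn_forward(batch, net, keep_cache = TRUE)
  g1 <- net$g1
  for (b in seq_len(B)) {
    ref <- naive_conv_same(batch[, , b], net$W1, g1, net$b1)
    got <- array(fw$c1$Y[((b - 1) * g1$P + 1):(b * g1$P), ],
                 c(H, W, spec$conv1_filters))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("conv1 with one input channel counts 2600 trainable parameters", {
  e <- quick_record(duration = 4, fs = 100, seed = 2)
  ws <- window_signal(e$record, 8)
  e2 <- quick_record(duration = 4, fs = 100, seed = 3)
  e2$record$subject_id <- "S02"; e2$record$group <- "ms"
  ws2 <- window_signal(e2$record, 8)
  ws2$label[] <- "ms"
  both <- bind_windows(ws, ws2)
  m <- train_cnn(both, spec = cnn_spec(max_epochs = 1), seed = 1)
  counts <- cnn_n_params(m)
  expect_equal(unname(counts["conv1"]), (5 * 5 * 1) * 100 + 100)
  expect_equal(unname(counts["conv1"]), 2600)
})

test_that("softmax probabilities sum to one and predictions have the right shape", {
  e <- quick_record(duration = 4, fs = 100, seed = 4)
  ws <- window_signal(e$record, 8)
  e2 <- quick_record(duration = 4, fs = 100, seed = 5)
  e2$record$subject_id <- "S02"; e2$record$group <- "ms"
  ws2 <- window_signal(e2$record, 8)
  both <- bind_windows(ws, ws2)
  m <- train_cnn(both, spec = cnn_spec(conv1_filters = 6, conv2_filters = 4,
                                       max_epochs = 1), seed = 2)
  pr <- predict(m, both)
  expect_equal(dim(pr$prob), c(n_windows(both), 2))
  expect_equal(unname(rowSums(pr$prob)), rep(1, n_windows(both)),
               tolerance = 1e-9)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  empty <- predict(m, both$windows[, , 0, drop = FALSE])
  expect_length(empty$label, 0)
})

test_that("the stepped learning-rate schedule follows the declared drops", {
  spec <- cnn_spec()
  expect_equal(vapply(1:8, function(e) cnn_lr(spec, e), 0),
               rep(1e-4, 8))
  expect_equal(cnn_lr(spec, 9), 1e-5)
  expect_equal(cnn_lr(spec, 17), 1e-6)
})

test_that("subject overlap between train and declared test set is a hard error", {
  e <- quick_record(duration = 4, fs = 100, seed = 6)
  ws <- window_signal(e$record, 8)
  e2 <- quick_record(duration = 4, fs = 100, seed = 7)
  e2$record$subject_id <- "S02"; e2$record$group <- "ms"
  both <- bind_windows(ws, window_signal(e2$record, 8))
  expect_error(train_cnn(both, spec = cnn_spec(max_epochs = 1),
                         test_subjects = "S01"),
               "isolation")
})

test_that("majority vote aggregates window labels per subject", {
  labs <- factor(c(rep("ms", 299), "control", rep("control", 3)),
                 levels = c("control", "ms"))
  subj <- c(rep("A", 300), rep("B", 3))
  v <- vote_subjects(labs, subj)
  expect_equal(as.character(v[["A"]]), "ms")
  expect_equal(as.character(v[["B"]]), "control")
})
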