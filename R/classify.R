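# Feature-based classifier back-ends: RBF-kernel SVM and RobustBoost over
# tree learners. Both present the same train/predict surface and share the
# {control, ms} label convention with "ms" as the positive class.

.check_xy <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("control", "ms"))
  if (anyNA(y)) stop("labels must be 'control' or 'ms'")
  if (nrow(x) != length(y)) stop("nrow(x) must match length(y)")
  if (length(unique(y)) < 2) stop("single-class input: need both classes")
  if (min(table(y)) < 2) stop("need at least 2 examples per class")
  list(x = x, y = y)
}

# median-heuristic RBF kernel scale on z-scored features
.median_heuristic <- function(x) {
  n <- nrow(x)
  if (n > 200) x <- x[sample.int(n, 200), , drop = FALSE]
  d <- stats::dist(x)
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s == 0) 1 else s
}

#' Train an RBF-kernel support vector machine
#'
#' Features are z-scored with training-set statistics (stored in the model
#' and re-applied at prediction, so no information flows from test data).
#' The kernel scale defaults to the median heuristic -- the median pairwise
#' Euclidean distance between standardized training points -- and the box
#' constraint to 1.
#'
#' @param x Numeric feature matrix or data frame (rows = examples).
#' @param y Labels, `"control"`/`"ms"`.
#' @param kernel_scale RBF length scale; `NULL` for the median heuristic.
#' @param box_constraint SVM cost parameter C.
#' @return An object of class `ms_svm`.
#' @export
train_svm_rbf <- function(x, y, kernel_scale = NULL, box_constraint = 1) {
  d <- .check_xy(x, y)
  ctr <- colMeans(d$x)
  scl <- apply(d$x, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- scale(d$x, ctr, scl)
  if (is.null(kernel_scale)) kernel_scale <- .median_heuristic(xs)
  fit <- e1071::svm(xs, d$y, kernel = "radial",
                    gamma = 1 / (2 * kernel_scale^2),
                    cost = box_constraint, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 kernel_scale = kernel_scale,
                 box_constraint = box_constraint),
            class = "ms_svm")
}

#' @export
predict.ms_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata)) || nrow(newdata) == 0) return(factor(
    character(0), levels = c("control", "ms")))
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  stats::predict(object$fit, xs)
}

#' RobustBoost configuration
#'
#' @param n_cycles Maximum number of boosting cycles (the algorithm
#'   self-terminates when its internal time variable reaches 1).
#' @param base_learner Only `"tree"` is supported (shallow rpart trees).
#' @param robustness_target Target classification error in `[0, 1)`; sets
#'   the initial potential of the boost-by-majority schedule.
#' @param max_depth Depth of the base trees.
#' @param method `"robust"` for RobustBoost, `"ada"` for a plain AdaBoost
#'   fallback behind the same interface.
#' @param time_step How the boost-by-majority time variable advances per
#'   cycle. `"cycle_paced"` (default) spreads the advance over the cycle
#'   budget, so a run actually uses on the order of `n_cycles` learners --
#'   the regime in which the algorithm is reported to perform best.
#'   `"adaptive"` takes the largest admissible step each cycle
#'   (the continuous-time limit): runs self-terminate as soon as the
#'   error goal is secured, and on label-noisy data the time variable
#'   stalls before the endgame, which is what makes the algorithm give
#'   up on unfittable examples instead of chasing them.
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(n_cycles = 100, base_learner = "tree",
                         robustness_target = 0.1, max_depth = 3,
                         method = c("robust", "ada"),
                         time_step = c("cycle_paced", "adaptive")) {
  stopifnot(n_cycles >= 1, identical(base_learner, "tree"),
            robustness_target >= 0, robustness_target < 1)
  structure(list(n_cycles = as.integer(n_cycles), base_learner = base_learner,
                 robustness_target = robustness_target,
                 max_depth = max_depth, method = match.arg(method),
                 time_step = match.arg(time_step)),
            class = "boost_config")
}

# RobustBoost schedule: sigma(t)^2 = (sigma_f^2 + 1) e^{2(1-t)} - 1,
# mu(t) = (theta - 2 rho) e^{1-t} + 2 rho, with rho fixed so the mean
# potential at t = 0 equals the error goal. Potential of a margin m at
# time t is 1 - pnorm((m - mu(t)) / sigma(t)).
.rb_sigma <- function(t, sigma_f) sqrt((sigma_f^2 + 1) * exp(2 * (1 - t)) - 1)
.rb_mu <- function(t, theta, rho) (theta - 2 * rho) * exp(1 - t) + 2 * rho
.rb_potential <- function(m, t, theta, rho, sigma_f) {
  1 - stats::pnorm((m - .rb_mu(t, theta, rho)) / .rb_sigma(t, sigma_f))
}

# Weak-learner contract: leaves must hold at least `min_leaf_frac` of the
# sample, so a base tree cannot memorize isolated (possibly mislabelled)
# points -- boosting robustness presupposes genuinely weak learners.
.fit_weighted_tree <- function(x, y01, w, max_depth, min_leaf_frac = 0.05) {
  df <- as.data.frame(x)
  df$.y <- factor(y01)
  mb <- max(2L, round(min_leaf_frac * nrow(df)))
  rpart::rpart(.y ~ ., data = df, weights = w / mean(w), method = "class",
               control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                              minsplit = 2L * mb,
                                              minbucket = mb, xval = 0))
}

.tree_pm1 <- function(tree, x) {
  cls <- as.character(stats::predict(tree, as.data.frame(x), type = "class"))
  ifelse(cls == "1", 1, -1)
}

#' Train a RobustBoost (or AdaBoost) tree ensemble
#'
#' RobustBoost is a boost-by-majority approximation designed to tolerate
#' label noise. Each example carries a margin; examples are re-weighted by
#' a Gaussian window centered on a drifting target margin `mu(t)`, where
#' the "boosting time" `t` advances from 0 to 1 over the run. Each cycle
#' fits a depth-limited tree to the weighted data and takes the largest
#' joint step `(dt, alpha)` that keeps the average potential from
#' increasing, with `alpha` solving the zero-edge equation at the advanced
#' time. Training self-terminates when `t` reaches 1, when no admissible
#' step exists, or after `n_cycles` cycles.
#'
#' @param x Feature matrix or data frame.
#' @param y Labels `"control"`/`"ms"`.
#' @param config A [boost_config()].
#' @param seed Seed for tie-breaking reproducibility in tree fitting.
#' @return An object of class `ms_boost`.
#' @export
train_robustboost <- function(x, y, config = boost_config(), seed = 1) {
  d <- .check_xy(x, y)
  y01 <- as.integer(d$y == "ms")        # tree target
  ypm <- ifelse(y01 == 1, 1, -1)
  n <- length(ypm)
  trees <- list()
  alphas <- numeric(0)

  .with_seed(.mix_seed(seed, "boost"), {
    if (config$method == "ada") {
      w <- rep(1 / n, n)
      for (k in seq_len(config$n_cycles)) {
        tree <- .fit_weighted_tree(d$x, y01, w, config$max_depth)
        h <- .tree_pm1(tree, d$x)
        err <- sum(w[h != ypm])
        if (err >= 0.5) break
        err <- max(err, 1e-10)
        a <- 0.5 * log((1 - err) / err)
        trees[[length(trees) + 1L]] <- tree
        alphas <- c(alphas, a)
        w <- w * exp(-a * ypm * h)
        w <- w / sum(w)
        if (err <= 1e-9) break
      }
    } else {
      sigma_f <- 0.1
      theta <- 0
      eps <- max(config$robustness_target, 1e-4)
      s0 <- .rb_sigma(0, sigma_f)
      rho <- (s0 * stats::qnorm(1 - eps) + theta * exp(1)) /
        (2 * (exp(1) - 1))
      m <- numeric(n)
      t <- 0
      # discretization of the continuous boost-by-majority process: the
      # per-cycle margin step is bounded; the time step either takes the
      # largest admissible value (adaptive) or is additionally capped so
      # the cycle budget paces the schedule (cycle_paced)
      alpha_cap <- 0.3
      dt_cap <- if (config$time_step == "cycle_paced")
        2 / config$n_cycles else Inf
      for (k in seq_len(config$n_cycles)) {
        if (t >= 1) break
        w <- exp(-(m - .rb_mu(t, theta, rho))^2 /
                   (2 * .rb_sigma(t, sigma_f)^2))
        if (sum(w) <= 0) break
        tree <- .fit_weighted_tree(d$x, y01, w / sum(w), config$max_depth)
        h <- .tree_pm1(tree, d$x)
        edge0 <- sum(w * ypm * h) / sum(w)
        if (edge0 <= 1e-12) break          # weak learner no better than chance
        pot_now <- mean(.rb_potential(m, t, theta, rho, sigma_f))
        # for a given time step, the zero-edge alpha is the minimizer of
        # the mean potential at the advanced time
        step_for <- function(dt) {
          t2 <- t + dt
          g <- function(a) {
            w2 <- exp(-(m + a * ypm * h - .rb_mu(t2, theta, rho))^2 /
                        (2 * .rb_sigma(t2, sigma_f)^2))
            sum(w2 * ypm * h)
          }
          if (g(0) <= 0) return(NULL)
          a <- if (g(alpha_cap) > 0) alpha_cap else
            stats::uniroot(g, c(0, alpha_cap), tol = 1e-8)$root
          pot <- mean(.rb_potential(m + a * ypm * h, t2, theta, rho, sigma_f))
          list(alpha = a, pot = pot)
        }
        # largest admissible time step by bisection
        dt_lo <- 0; dt_hi <- min(dt_cap, 1 - t)
        best <- NULL
        cand <- step_for(dt_hi)
        if (!is.null(cand) && cand$pot <= pot_now + 1e-12) {
          best <- c(cand, dt = dt_hi)
        } else {
          for (it in 1:25) {
            dt_mid <- (dt_lo + dt_hi) / 2
            cand <- step_for(dt_mid)
            if (!is.null(cand) && cand$pot <= pot_now + 1e-12) {
              best <- c(cand, dt = dt_mid)
              dt_lo <- dt_mid
            } else dt_hi <- dt_mid
          }
        }
        if (is.null(best) || best$alpha <= 1e-10) break
        trees[[length(trees) + 1L]] <- tree
        alphas <- c(alphas, best$alpha)
        m <- m + best$alpha * ypm * h
        t <- t + best$dt
      }
    }
  })
  if (!length(trees)) stop("boosting produced no usable base learner")
  structure(list(trees = trees, alphas = alphas, config = config),
            class = "ms_boost")
}

#' @export
predict.ms_boost <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(if (type == "class") factor(character(0),
                                       levels = c("control", "ms"))
           else numeric(0))
  }
  score <- numeric(nrow(newdata))
  for (k in seq_along(object$trees)) {
    score <- score + object$alphas[k] * .tree_pm1(object$trees[[k]], newdata)
  }
  if (type == "score") return(score)
  factor(ifelse(score >= 0, "ms", "control"), levels = c("control", "ms"))
}

#' Number of base learners in a boosted ensemble
#' @param model An `ms_boost` model.
#' @export
n_learners <- function(model) length(model$trees)
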