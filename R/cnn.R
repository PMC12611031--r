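# A small two-stage convolutional network for raw windowed ECG segments,
# implemented directly in R with im2col gathers and BLAS matrix products.
# Architecture (10 layers in the counting convention used throughout):
# input -> conv(100 @ 5x5, same) -> ReLU -> maxpool 2x2 ->
# conv(100 @ 8x8, same) -> ReLU -> maxpool 2x2 -> fully-connected ->
# softmax -> 2-class output. Trained with SGD + momentum, a stepped
# learning-rate schedule and L2 weight decay.
#
# Windows are presented as (n_leads x window_length) single-channel
# images. With 2-lead input the lead dimension is smaller than the kernel
# height; under same-padding the kernel rows that can never overlap the
# input are inert -- they exist as parameters but receive no gradient.
# Pooling blocks are clipped at the boundaries.

#' CNN architecture and training hyperparameters
#'
#' Defaults: two convolutional stages (100 filters of 5x5, then 100 of
#' 8x8), each followed by ReLU and 2x2 max-pooling; SGD with momentum
#' 0.9; initial learning rate 1e-4 multiplied by 0.1 every 8 epochs; L2
#' regularization 4e-4; at most 5 epochs; mini-batches of 30.
#'
#' @param conv1_filters,conv1_kernel First convolution stage.
#' @param conv2_filters,conv2_kernel Second convolution stage.
#' @param pool Pooling block size (applied with stride equal to its size,
#'   clipped at input boundaries).
#' @param initial_lr,lr_drop_factor,lr_drop_period Stepped learning-rate
#'   schedule: `lr(e) = initial_lr * lr_drop_factor^floor((e-1)/lr_drop_period)`.
#' @param l2 L2 regularization (weight decay) factor.
#' @param max_epochs,batch_size Training length and mini-batch size.
#' @param momentum SGD momentum coefficient.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv1_filters = 100, conv1_kernel = c(5, 5),
                     conv2_filters = 100, conv2_kernel = c(8, 8),
                     pool = c(2, 2), initial_lr = 1e-4,
                     lr_drop_factor = 0.1, lr_drop_period = 8,
                     l2 = 4e-4, max_epochs = 5, batch_size = 30,
                     momentum = 0.9) {
  stopifnot(conv1_filters > 0, conv2_filters > 0,
            all(conv1_kernel > 0), all(conv2_kernel > 0), all(pool > 0),
            initial_lr > 0, lr_drop_factor > 0, lr_drop_period > 0,
            l2 >= 0, max_epochs > 0, batch_size > 0,
            momentum >= 0, momentum < 1)
  structure(list(conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
                 conv2_filters = conv2_filters, conv2_kernel = conv2_kernel,
                 pool = pool, initial_lr = initial_lr,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = lr_drop_period, l2 = l2,
                 max_epochs = max_epochs, batch_size = batch_size,
                 momentum = momentum, n_layers = 10L),
            class = "cnn_spec")
}

#' Learning rate at a given epoch under the stepped schedule
#'
#' @param spec A [cnn_spec()].
#' @param epoch Epoch number (1-based).
#' @export
cnn_lr <- function(spec, epoch) {
  spec$initial_lr * spec$lr_drop_factor^((epoch - 1) %/% spec$lr_drop_period)
}

# ---------------------------------------------------------------------------
# geometry: same-padded convolution expressed as a gather (im2col) map

.conv_geom <- function(H, W, C, kh, kw) {
  pad_top <- (kh - 1L) %/% 2L
  pad_left <- (kw - 1L) %/% 2L
  Hp <- H + kh - 1L
  Wp <- W + kw - 1L
  in_row <- function(r) seq_len(H) + r - 1L - pad_top
  in_col <- function(cc) seq_len(W) + cc - 1L - pad_left
  used_r <- which(vapply(seq_len(kh),
                         function(r) any(in_row(r) >= 1 & in_row(r) <= H),
                         TRUE))
  used_c <- which(vapply(seq_len(kw),
                         function(cc) any(in_col(cc) >= 1 & in_col(cc) <= W),
                         TRUE))
  P <- H * W
  K <- length(used_r) * length(used_c) * C
  # gather map into the zero-padded (Hp x Wp x C) grid, entry order
  # (used_r fastest, then used_c, then channel) to match weight layout
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  M <- matrix(0L, nrow = P, ncol = K)
  k <- 0L
  for (ch in seq_len(C)) {
    off_ch <- (ch - 1L) * Hp * Wp
    for (cc in used_c) {
      for (r in used_r) {
        k <- k + 1L
        M[, k] <- off_ch + (j + cc - 2L) * Hp + (i + r - 1L)
      }
    }
  }
  # crop map: original (i, j, ch) -> padded linear row
  crop <- integer(P * C)
  k <- 0L
  for (ch in seq_len(C)) {
    off_ch <- (ch - 1L) * Hp * Wp
    for (jj in seq_len(W)) {
      for (ii in seq_len(H)) {
        k <- k + 1L
        crop[k] <- off_ch + (jj + pad_left - 1L) * Hp + (ii + pad_top)
      }
    }
  }
  list(H = H, W = W, C = C, kh = kh, kw = kw, Hp = Hp, Wp = Wp,
       used_r = used_r, used_c = used_c, P = P, K = K, M = M, crop = crop)
}

# clipped max-pool geometry on an (H x W) grid
.pool_geom <- function(H, W, ph, pw) {
  H2 <- ceiling(H / ph)
  W2 <- ceiling(W / pw)
  P2 <- H2 * W2
  i2 <- rep(seq_len(H2), times = W2)
  j2 <- rep(seq_len(W2), each = H2)
  M4 <- matrix(NA_integer_, nrow = P2, ncol = ph * pw)
  k <- 0L
  for (b in seq_len(pw)) {
    for (a in seq_len(ph)) {
      k <- k + 1L
      ii <- (i2 - 1L) * ph + a
      jj <- (j2 - 1L) * pw + b
      ok <- ii <= H & jj <= W
      M4[ok, k] <- (jj[ok] - 1L) * H + ii[ok]
    }
  }
  list(H = H, W = W, H2 = H2, W2 = W2, P2 = P2, M4 = M4)
}

# activation layout everywhere: matrix (P*B) x F, position fastest within
# each batch element

# (P*B) x C activation -> zero-padded (Hp*Wp*C) x B matrix
.to_padded <- function(A, geom, B) {
  P <- geom$P; C <- geom$C
  a <- array(A, dim = c(P, B, C))
  Xin <- matrix(aperm(a, c(1, 3, 2)), nrow = P * C, ncol = B)
  Xp <- matrix(0, nrow = geom$Hp * geom$Wp * C, ncol = B)
  Xp[geom$crop, ] <- Xin
  Xp
}

.conv_forward <- function(Xp, geom, W_eff, bias, B) {
  P <- geom$P; K <- geom$K
  Ag <- Xp[as.vector(geom$M), , drop = FALSE]         # (P*K) x B
  Xcol <- matrix(aperm(array(Ag, dim = c(P, K, B)), c(1, 3, 2)),
                 nrow = P * B, ncol = K)
  Y <- Xcol %*% W_eff
  Y <- Y + rep(bias, each = P * B)
  list(Y = Y, Xcol = Xcol)
}

.conv_backward <- function(dY, cache, geom, W_eff, B, input_grad = TRUE) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXp <- NULL
  if (input_grad) {
    dXcol <- tcrossprod(dY, W_eff)                    # (P*B) x K
    P <- geom$P
    dXp <- matrix(0, nrow = geom$Hp * geom$Wp * geom$C, ncol = B)
    for (k in seq_len(geom$K)) {
      rows <- geom$M[, k]
      dXp[rows, ] <- dXp[rows, ] + matrix(dXcol[, k], nrow = P, ncol = B)
    }
  }
  list(dW = dW, db = db, dXp = dXp)
}

# padded input gradient -> previous layer's (P*B) x C layout
.from_padded <- function(dXp, geom, B) {
  P <- geom$P; C <- geom$C
  dXin <- dXp[geom$crop, , drop = FALSE]              # (P*C) x B
  matrix(aperm(array(dXin, dim = c(P, C, B)), c(1, 3, 2)),
         nrow = P * B, ncol = C)
}

.pool_forward <- function(A, pg, B, F) {
  P <- pg$H * pg$W
  nk <- ncol(pg$M4)
  idx <- vector("list", nk)
  Y <- matrix(-Inf, nrow = pg$P2 * B, ncol = F)
  am <- matrix(1L, nrow = pg$P2 * B, ncol = F)
  boff <- rep((seq_len(B) - 1L) * P, each = pg$P2)
  for (k in seq_len(nk)) {
    mk <- pg$M4[, k]
    rows <- rep(mk, times = B) + boff                 # NA where clipped
    idx[[k]] <- rows
    ok <- !is.na(rows)
    vals <- matrix(-Inf, nrow = pg$P2 * B, ncol = F)
    vals[ok, ] <- A[rows[ok], , drop = FALSE]
    upd <- vals > Y
    am[upd] <- k
    Y[upd] <- vals[upd]
  }
  list(Y = Y, am = am, idx = idx)
}

.pool_backward <- function(dY, cache, pg, B, F) {
  P <- pg$H * pg$W
  dA <- matrix(0, nrow = P * B, ncol = F)
  for (k in seq_along(cache$idx)) {
    contrib <- dY * (cache$am == k)
    rows <- cache$idx[[k]]
    ok <- !is.na(rows)
    if (!any(ok)) next
    dA[rows[ok], ] <- dA[rows[ok], ] + contrib[ok, , drop = FALSE]
  }
  dA
}

# flatten (P2*B) x F -> D x B feature matrix (D = P2 * F)
.flatten <- function(A, P2, F, B) {
  matrix(aperm(array(A, dim = c(P2, B, F)), c(1, 3, 2)),
         nrow = P2 * F, ncol = B)
}

.unflatten <- function(Xf, P2, F, B) {
  matrix(aperm(array(Xf, dim = c(P2, F, B)), c(1, 3, 2)),
         nrow = P2 * B, ncol = F)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass for a batch of windows (H x W x B array, normalized)
.cnn_forward <- function(batch, net, keep_cache = FALSE) {
  B <- dim(batch)[3]
  g1 <- net$g1; g2 <- net$g2; p1 <- net$p1; p2 <- net$p2
  Xp1 <- matrix(0, nrow = g1$Hp * g1$Wp, ncol = B)
  Xp1[g1$crop, ] <- matrix(batch, nrow = g1$P, ncol = B)
  c1 <- .conv_forward(Xp1, g1, net$W1, net$b1, B)
  A1 <- pmax(c1$Y, 0)
  q1 <- .pool_forward(A1, p1, B, ncol(A1))
  Xp2 <- .to_padded(q1$Y, g2, B)
  c2 <- .conv_forward(Xp2, g2, net$W2, net$b2, B)
  A2 <- pmax(c2$Y, 0)
  q2 <- .pool_forward(A2, p2, B, ncol(A2))
  Xf <- .flatten(q2$Y, p2$P2, ncol(A2), B)
  Z <- crossprod(Xf, net$Wf) + rep(net$bf, each = B)
  Pr <- .softmax_rows(Z)
  out <- list(prob = Pr, B = B)
  if (keep_cache) {
    out <- c(out, list(c1 = c1, A1 = A1, q1 = q1, c2 = c2, A2 = A2,
                       q2 = q2, Xf = Xf))
  }
  out
}

.cnn_init <- function(spec, H, W) {
  g1 <- .conv_geom(H, W, 1L, spec$conv1_kernel[1], spec$conv1_kernel[2])
  p1 <- .pool_geom(H, W, spec$pool[1], spec$pool[2])
  g2 <- .conv_geom(p1$H2, p1$W2, spec$conv1_filters,
                   spec$conv2_kernel[1], spec$conv2_kernel[2])
  p2 <- .pool_geom(p1$H2, p1$W2, spec$pool[1], spec$pool[2])
  D <- p2$P2 * spec$conv2_filters
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                nr, nc)
  list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, D = D,
       W1 = he(g1$K, spec$conv1_filters), b1 = numeric(spec$conv1_filters),
       W2 = he(g2$K, spec$conv2_filters), b2 = numeric(spec$conv2_filters),
       Wf = he(D, 2L), bf = numeric(2L))
}

#' Train the CNN on a set of labelled signal windows
#'
#' Enforces subject-wise isolation: if any training window belongs to a
#' subject declared in `test_subjects`, training stops with an error (this
#' is an assertion, never a warning). Inputs are normalized per lead by
#' the training set's mean and standard deviation; the normalization is
#' stored in the model and re-applied at prediction.
#'
#' @param train_windows A `window_set` (see [window_signal()]).
#' @param labels Optional factor of window labels; defaults to the labels
#'   carried by the window set.
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param test_subjects Character vector of subject ids reserved for
#'   testing; overlap with training subjects is a hard error.
#' @param verbose Print per-epoch loss.
#' @return An object of class `ms_cnn`.
#' @export
train_cnn <- function(train_windows, labels = NULL, spec = cnn_spec(),
                      seed = 1, test_subjects = character(), verbose = FALSE) {
  stopifnot(inherits(train_windows, "window_set"),
            inherits(spec, "cnn_spec"))
  overlap <- intersect(unique(train_windows$subject), test_subjects)
  if (length(overlap)) {
    stop("subject-wise isolation violated: training windows contain ",
         "reserved test subject(s): ", paste(overlap, collapse = ", "))
  }
  y <- if (is.null(labels)) train_windows$label else
    factor(labels, levels = c("control", "ms"))
  if (anyNA(y) || length(unique(y)) < 2) {
    stop("need windows from both classes to train")
  }
  arr <- train_windows$windows
  H <- dim(arr)[1]; W <- dim(arr)[2]; N <- dim(arr)[3]
  # per-lead zero-center / unit-sd normalization from training windows
  mu <- apply(arr, 1, mean)
  sdv <- apply(arr, 1, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  arr <- (arr - array(mu, dim = dim(arr))) / array(sdv, dim = dim(arr))
  Y <- cbind(y == "control", y == "ms") * 1

  .with_seed(.mix_seed(seed, "cnn"), {
    net <- .cnn_init(spec, H, W)
    vel <- list(W1 = net$W1 * 0, b1 = net$b1 * 0, W2 = net$W2 * 0,
                b2 = net$b2 * 0, Wf = net$Wf * 0, bf = net$bf * 0)
    losses <- numeric(0)
    for (epoch in seq_len(spec$max_epochs)) {
      lr <- cnn_lr(spec, epoch)
      ord <- sample.int(N)
      ep_loss <- 0; n_batch <- 0
      for (start in seq(1, N, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, N)]
        B <- length(idx)
        if (B < 2) next
        fw <- .cnn_forward(arr[, , idx, drop = FALSE], net,
                           keep_cache = TRUE)
        Pr <- fw$prob
        Yb <- Y[idx, , drop = FALSE]
        ep_loss <- ep_loss - mean(log(rowSums(Pr * Yb) + 1e-12))
        n_batch <- n_batch + 1
        dZ <- (Pr - Yb) / B                            # B x 2
        gWf <- fw$Xf %*% dZ + spec$l2 * net$Wf
        gbf <- colSums(dZ)
        dXf <- tcrossprod(net$Wf, dZ)                  # D x B
        dQ2 <- .unflatten(dXf, net$p2$P2, spec$conv2_filters, B)
        dA2 <- .pool_backward(dQ2, fw$q2, net$p2, B, spec$conv2_filters)
        dC2 <- dA2 * (fw$A2 > 0)
        bk2 <- .conv_backward(dC2, fw$c2, net$g2, net$W2, B,
                              input_grad = TRUE)
        gW2 <- bk2$dW + spec$l2 * net$W2
        dQ1 <- .from_padded(bk2$dXp, net$g2, B)
        dA1 <- .pool_backward(dQ1, fw$q1, net$p1, B, spec$conv1_filters)
        dC1 <- dA1 * (fw$A1 > 0)
        bk1 <- .conv_backward(dC1, fw$c1, net$g1, net$W1, B,
                              input_grad = FALSE)
        gW1 <- bk1$dW + spec$l2 * net$W1
        for (nm in c("W1", "b1", "W2", "b2", "Wf", "bf")) {
          g <- switch(nm, W1 = gW1, b1 = bk1$db, W2 = gW2, b2 = bk2$db,
                      Wf = gWf, bf = gbf)
          vel[[nm]] <- spec$momentum * vel[[nm]] - lr * g
          net[[nm]] <- net[[nm]] + vel[[nm]]
        }
      }
      losses <- c(losses, ep_loss / max(n_batch, 1))
      if (verbose) message(sprintf("epoch %d: lr %.2g loss %.4f",
                                   epoch, lr, losses[epoch]))
    }
    structure(list(net = net, spec = spec, H = H, W = W, mu = mu, sd = sdv,
                   lead_names = train_windows$lead_names,
                   classes = c("control", "ms"), losses = losses,
                   seed = seed),
              class = "ms_cnn")
  })
}

#' Predict window classes (and probabilities) with a trained CNN
#'
#' @param object An `ms_cnn` model.
#' @param newdata A `window_set` or an `H x W x N` array.
#' @param ... Unused.
#' @return List with `prob` (N x 2 matrix of softmax probabilities,
#'   columns `control`/`ms`) and `label` (factor of window labels).
#' @export
predict.ms_cnn <- function(object, newdata, ...) {
  arr <- if (inherits(newdata, "window_set")) newdata$windows else newdata
  if (is.null(dim(arr)) || length(dim(arr)) != 3) {
    stop("newdata must be a window_set or a 3-d array")
  }
  N <- dim(arr)[3]
  if (N == 0) {
    return(list(prob = matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, object$classes)),
                label = factor(character(0), levels = object$classes)))
  }
  if (dim(arr)[1] != object$H || dim(arr)[2] != object$W) {
    stop("window shape mismatch: model expects ", object$H, " x ", object$W)
  }
  arr <- (arr - array(object$mu, dim = dim(arr))) /
    array(object$sd, dim = dim(arr))
  probs <- matrix(NA_real_, N, 2, dimnames = list(NULL, object$classes))
  for (start in seq(1, N, by = 256)) {
    idx <- start:min(start + 255, N)
    fw <- .cnn_forward(arr[, , idx, drop = FALSE], object$net)
    probs[idx, ] <- fw$prob
  }
  list(prob = probs,
       label = factor(object$classes[max.col(probs)],
                      levels = object$classes))
}

#' Aggregate per-window predictions to per-subject labels
#'
#' Majority vote over each subject's windows; ties go to the positive
#' (`"ms"`) class.
#'
#' @param labels Factor of per-window predicted labels.
#' @param subjects Character vector of per-window subject ids.
#' @return Named factor of per-subject labels.
#' @export
vote_subjects <- function(labels, subjects) {
  stopifnot(length(labels) == length(subjects))
  subj <- unique(subjects)
  out <- vapply(subj, function(s) {
    v <- labels[subjects == s]
    if (sum(v == "ms") * 2 >= length(v)) "ms" else "control"
  }, character(1))
  factor(stats::setNames(out, subj), levels = c("control", "ms"))
}

#' Trainable parameter count of a CNN model
#'
#' Counts the full declared kernel tensors (including same-padding kernel
#' entries that never overlap a small input and are therefore inert).
#'
#' @param model An `ms_cnn` model.
#' @return Named vector of per-layer and total counts.
#' @export
cnn_n_params <- function(model) {
  sp <- model$spec
  conv1 <- prod(sp$conv1_kernel) * 1 * sp$conv1_filters + sp$conv1_filters
  conv2 <- prod(sp$conv2_kernel) * sp$conv1_filters * sp$conv2_filters +
    sp$conv2_filters
  fc <- model$net$D * 2 + 2
  c(conv1 = conv1, conv2 = conv2, fc = fc, total = conv1 + conv2 + fc)
}
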