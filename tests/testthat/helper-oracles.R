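# Independent oracles and small fixture builders shared across tests.

# Exhaustive-permutation two-sided Mann-Whitney p-value: enumerate every
# assignment of the pooled sample to group A, compare rank-sum deviations
# from the null mean. Exact for tie-free data.
perm_mw_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(na)]) - na * (n + 1) / 2)
  combos <- utils::combn(n, na)
  stat <- abs(colSums(matrix(r[combos], nrow = na)) - na * (n + 1) / 2)
  mean(stat >= obs - 1e-12)
}

# direct nested-loop 2-d convolution with same padding and clipped kernel
# rows/columns, matching the package's gather-map layout (C = 1)
naive_conv_same <- function(img, W_eff, geom, bias) {
  H <- geom$H; W <- geom$W
  pt <- (geom$kh - 1) %/% 2
  pl <- (geom$kw - 1) %/% 2
  out <- array(0, c(H, W, ncol(W_eff)))
  for (f in seq_len(ncol(W_eff))) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0; k <- 0
    for (cc in geom$used_c) for (r in geom$used_r) {
      k <- k + 1
      ii <- i + r - 1 - pt; jj <- j + cc - 1 - pl
      v <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) img[ii, jj] else 0
      acc <- acc + v * W_eff[k, f]
    }
    out[i, j, f] <- acc + bias[f]
  }
  out
}

# small clean record with known subject parameters
quick_record <- function(duration = 10, fs = 500, hr = 60, seed = 42,
                         params = NULL) {
  spec <- cohort_spec(duration = duration, sample_rate = fs,
                      base_heart_rate = hr, seed = seed)
  generate_record(spec, "S01", "control", "basal", params = params)
}

# two well-separated Gaussian clouds in `d` dimensions
gauss_clouds <- function(n_side, d = 2, dist = 2, sd = 0.1, seed = 1) {
  set.seed(seed)
  mu <- rep(dist / 2 / sqrt(d), d)
  x <- rbind(sweep(matrix(rnorm(n_side * d, sd = sd), ncol = d), 2, mu, "-"),
             sweep(matrix(rnorm(n_side * d, sd = sd), ncol = d), 2, mu, "+"))
  list(x = x, y = rep(c("control", "ms"), each = n_side))
}
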