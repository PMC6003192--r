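# Geometric fixtures and brute-force oracles used across the suite.

# filled disc of radius r (pixels) on a (2r + 2*pad + 1)^2 canvas
disc_mask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  cc <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  ((x - cc)^2 + (y - cc)^2 <= r^2) * 1L
}

# two discs of radius R whose overlap neck has the given half-width
two_disc_mask <- function(R = 20, neck_halfwidth = 10) {
  off <- sqrt(R^2 - neck_halfwidth^2)
  W <- as.integer(4 * R + 2 * off + 10)
  H <- as.integer(4 * R)
  cy <- H / 2
  cx1 <- 2 * R
  cx2 <- cx1 + 2 * off
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  y <- matrix(seq_len(H), H, W)
  (((x - cx1)^2 + (y - cy)^2 <= R^2) |
   ((x - cx2)^2 + (y - cy)^2 <= R^2)) * 1L
}

# axis-aligned filled rectangle as a label map
rect_labels <- function(h, w, pad = 5) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- 1L
  m
}

random_gray <- function(h, w, seed) {
  withr::with_seed(seed, matrix(as.numeric(sample(0:255, h * w, replace = TRUE)),
                                h, w))
}

# brute-force dense 2-D convolution with replicated borders
oracle_conv2 <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  r <- (nrow(k) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (a in -r:r) {
        y <- min(max(i + a, 1), H)
        for (b in -r:r) {
          x <- min(max(j + b, 1), W)
          acc <- acc + m[y, x] * k[a + r + 1, b + r + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# naive O(H W r^2) windowed mean/sd threshold oracle
oracle_phansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  v <- img / 255
  H <- nrow(v); W <- ncol(v)
  off <- expand.grid(a = -radius:radius, b = -radius:radius)
  off <- off[off$a^2 + off$b^2 <= radius^2, ]
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ys <- i + off$a; xs <- j + off$b
      ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
      w <- v[cbind(ys[ok], xs[ok])]
      m <- mean(w)
      s <- sqrt(max(mean(w^2) - m^2, 0))
      thr <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[i, j] <- as.integer(v[i, j] > thr)
    }
  }
  out
}

clean_spec <- function(i) {
  synthetic_ear_spec(n_ears = 3 + (i %% 4), noise_sd = 0,
                     background_gradient = 0, reflection_probability = 0,
                     seed = 100 + i)
}
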