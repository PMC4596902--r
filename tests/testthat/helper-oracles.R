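# shape rasterizers and independently coded oracles used across the tests

# disk of radius r (pixel centres), with `pad` background pixels around it
rasterize_disk <- function(r, pad = 4) {
  xs <- -(r + pad):(r + pad)
  outer(xs, xs, function(y, x) x^2 + y^2 <= r^2)
}

# axis-aligned or rotated solid ellipse with semi-axes a >= b
rasterize_ellipse <- function(a, b, angle = 0, pad = 4) {
  r <- ceiling(max(a, b)) + pad
  xs <- -r:r
  outer(xs, xs, function(y, x) {
    u <- (x * cos(angle) + y * sin(angle)) / a
    v <- (-x * sin(angle) + y * cos(angle)) / b
    u^2 + v^2 <= 1
  })
}

rasterize_rect <- function(w, h, pad = 4) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# object geometry of the single object in a mask (no opening, no area filter)
geom_of_mask <- function(mask) {
  lab <- open_and_label(mask, min_area = 1, opening_radius = 0)
  stopifnot(nrow(lab$objects) == 1L)
  object_geometry(lab, 1L)
}

features_of_mask <- function(mask, ...) {
  lab <- open_and_label(mask, min_area = 1, opening_radius = 0)
  compute_feature_table(lab, ...)
}

# --- independent brute-force threshold evaluator ---------------------------
# Loops over every candidate threshold and evaluates the mean separating-edge
# contrast directly from the raw 4-adjacent pairs; no (lo, hi) tabulation.
brute_force_threshold <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  p <- c(m[, -nc], m[-nr, ])
  q <- c(m[, -1], m[-1, ])
  best_s <- NA_integer_
  best <- -Inf
  for (s in 0:254) {
    sep <- pmin(p, q) <= s & s < pmax(p, q)
    if (!any(sep)) next
    contrast <- mean(pmin(abs(p[sep] - s), abs(q[sep] - s)))
    if (contrast > best + 1e-12) {
      best <- contrast
      best_s <- s
    }
  }
  best_s
}

# --- independent Crofton chord counter (rle-based, per scan line) ----------
crofton_oracle <- function(mask, directions = 4) {
  runs_in <- function(v) {
    r <- rle(v)
    sum(r$values)
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  c0 <- sum(vapply(seq_len(nr), function(i) runs_in(mask[i, ]), numeric(1)))
  c90 <- sum(vapply(seq_len(nc), function(j) runs_in(mask[, j]), numeric(1)))
  if (directions == 2) {
    return((pi / 2) * (c0 + c90))
  }
  diag_runs <- function(m) {
    idx <- row(m) + col(m)
    sum(vapply(split(as.vector(m), as.vector(idx)), runs_in, numeric(1)))
  }
  c45 <- diag_runs(mask)
  c135 <- diag_runs(mask[nrow(mask):1, , drop = FALSE])
  (pi / 4) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

# --- independent SMD pairing oracle -----------------------------------------
# Re-derives the equal-angle radius resampling from the boundary pixel set and
# pairs point i with point i + N directly.
smd_oracle <- function(g, n_points = 360L) {
  bx <- g$boundary$x - g$centroid["x"]
  by <- g$boundary$y - g$centroid["y"]
  r <- sqrt(bx^2 + by^2)
  ang <- atan2(by, bx)
  agg <- tapply(r, ang, mean)
  a <- as.numeric(names(agg))
  o <- order(a)
  a <- a[o]
  rr <- as.numeric(agg)[o]
  theta <- seq(-pi, pi, length.out = n_points + 1L)[-(n_points + 1L)]
  rs <- stats::approx(
    c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi),
    c(rr[length(rr)], rr, rr[1]),
    xout = theta, rule = 2
  )$y
  n_half <- n_points %/% 2L
  mean(abs(rs[seq_len(n_half)] - rs[seq_len(n_half) + n_half]))
}

# simulated 11-feature table mimicking the collinearity structure of real
# bunch morphometry: one latent size factor driving the dimensional features,
# with P_conv and FD_max nearly deterministic in it
simulate_collinear_features <- function(n = 4000, seed = 99) {
  withr::with_seed(seed, {
    s <- rnorm(n)
    shape <- rnorm(n)
    data.frame(
      A = s + 0.30 * rnorm(n),
      A_conv = s + 0.35 * rnorm(n),
      CMA = 0.2 * shape + rnorm(n),
      FD_max = s + 0.045 * rnorm(n),
      FD_min = s + 0.25 * rnorm(n),
      P_conv = s + 0.030 * rnorm(n),
      SF_comp = 0.5 * shape + rnorm(n),
      SF_conv = 0.4 * shape + rnorm(n),
      SF_elong = 0.6 * shape + rnorm(n),
      SF_sfer = 0.5 * s + 0.8 * rnorm(n),
      SMD = 0.5 * shape + rnorm(n)
    )
  })
}

# two-Gaussian training set at Mahalanobis distance `delta` along the first
# coordinate, optionally with extra uninformative noise dimensions
simulate_two_gaussians <- function(n_per_class, delta = 4, p_noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x_shoot <- cbind(rnorm(n_per_class, mean = delta), rnorm(n_per_class))
    x_non <- cbind(rnorm(n_per_class, mean = 0), rnorm(n_per_class))
    x <- rbind(x_shoot, x_non)
    colnames(x) <- c("f1", "f2")
    if (p_noise > 0) {
      nz <- matrix(rnorm(2 * n_per_class * p_noise), ncol = p_noise)
      colnames(nz) <- paste0("noise", seq_len(p_noise))
      x <- cbind(x, nz)
    }
    d <- as.data.frame(x)
    d$class <- rep(c("shoot", "non-shoot"), each = n_per_class)
    d
  })
}
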