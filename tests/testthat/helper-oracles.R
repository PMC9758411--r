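# Independent oracles used to check the package's own computations.
# These deliberately use brute force or textbook routes, never the code
# paths under test.

# Brute-force grid search for the geometric circle objective
# sum (d_i - r)^2, refined coarse-to-fine down to ~1e-5 mm resolution.
oracle_grid_circle <- function(pts, n_grid = 25L) {
  m <- as.matrix(pts[, c("x", "y")])
  x <- m[, 1]; y <- m[, 2]
  span <- max(diff(range(x)), diff(range(y)))
  cx <- mean(x); cy <- mean(y)
  r <- mean(sqrt((x - cx)^2 + (y - cy)^2))
  h <- 2 * span
  obj_of <- function(cxs, cys, rs) {
    g <- expand.grid(cx = cxs, cy = cys, r = rs)
    d <- sqrt(outer(g$cx, x, function(c1, xx) (xx - c1)^2) +
                outer(g$cy, y, function(c2, yy) (yy - c2)^2))
    obj <- rowSums((d - g$r)^2)
    g[which.min(obj), ]
  }
  while (h > 5e-5) {
    cxs <- seq(cx - h, cx + h, length.out = n_grid)
    cys <- seq(cy - h, cy + h, length.out = n_grid)
    rs <- seq(max(1e-3, r - h), r + h, length.out = n_grid)
    best <- obj_of(cxs, cys, rs)
    cx <- best$cx; cy <- best$cy; r <- best$r
    # halve the search window each stage: slow enough not to lose the
    # shallow valley of short-arc objectives
    h <- h / 2
  }
  list(cx = cx, cy = cy, r = r)
}

# Geometric circle objective for a fit-like object.
circle_objective <- function(fit, pts) {
  m <- as.matrix(pts[, c("x", "y")])
  d <- sqrt((m[, 1] - fit$cx)^2 + (m[, 2] - fit$cy)^2)
  sum((d - fit$r)^2)
}

# Points on a circle/arc with radial Gaussian noise.
circle_points <- function(n, cx = 0, cy = 0, r = 1, arc_deg = 360,
                          start_deg = 0, sigma = 0) {
  th <- (start_deg + seq(0, arc_deg, length.out = n)) * pi / 180
  rr <- r + stats::rnorm(n, 0, sigma)
  tibble::tibble(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# ICC(3,k) consistency of the k-rater average via two-way ANOVA mean
# squares, the classical route alpha must reproduce exactly.
oracle_icc3k <- function(m) {
  long <- data.frame(
    value = as.vector(m),
    case = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(value ~ case + rater, data = long))[[1]]
  msc <- tab["case", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msc - mse) / msc
}

# Two-sided Monte Carlo permutation test on the difference in means.
oracle_perm_p <- function(x, y, n_perm = 1e5) {
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), nx)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Realise a sample of size n with exact mean m and exact SD s, so pooled
# summaries can be checked against concatenated raw data.
exact_sample <- function(n, m, s) {
  if (n == 1) return(m)
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}

oracle_pool_raw <- function(records) {
  raw <- unlist(Map(exact_sample, records$n, records$mean_deg, records$sd_deg))
  list(n_total = length(raw), mean = mean(raw), sd = stats::sd(raw))
}

# Vectorised Welch p-values for many replicate pairs held in columns.
welch_p_matrix <- function(xm, ym) {
  nx <- nrow(xm); ny <- nrow(ym)
  mx <- colMeans(xm); my <- colMeans(ym)
  vx <- apply(xm, 2, stats::var); vy <- apply(ym, 2, stats::var)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}
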