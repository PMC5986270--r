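# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: slopes come from lm(), window scans are written
# as plain loops, and the Boltzmann oracle is a coarse grid search refined
# with optim().

# Exhaustive sliding-window scan: for every start sample whose window fits
# inside the segment, fit lm() over the samples in [t_i, t_i + window_s]
# and return the window with maximal |slope| (earliest wins ties).
oracle_max_slope <- function(t, y, window_s) {
  eps <- 1e-9 * max(1, abs(t[length(t)]))
  best <- NULL
  for (i in seq_along(t)) {
    if (t[i] + window_s > t[length(t)] + eps) next
    j <- which(t >= t[i] - eps & t <= t[i] + window_s + eps)
    if (length(j) < 3) next
    fit <- stats::lm(y[j] ~ t[j])
    sl <- unname(stats::coef(fit)[2])
    if (is.na(sl)) sl <- 0
    if (is.null(best) || abs(sl) > abs(best$slope)) {
      best <- list(slope = sl, window = c(t[j[1]], t[j[length(j)]]))
    }
  }
  best
}

# Closed-form OLS slope (per second).
oracle_ols_slope <- function(t, y) {
  tm <- mean(t); ym <- mean(y)
  sum((t - tm) * (y - ym)) / sum((t - tm)^2)
}

# Brute-force Boltzmann least squares: coarse parameter grid around the
# data ranges, then Nelder-Mead refinement of the sum of squares.
oracle_boltzmann <- function(pH, value) {
  f <- function(p) sum((value - ((p[1] - p[2]) / (1 + exp((pH - p[3]) / p[4])) + p[2])))^2
  sse <- function(p) {
    pred <- (p[1] - p[2]) / (1 + exp((pH - p[3]) / p[4])) + p[2]
    sum((value - pred)^2)
  }
  best <- NULL
  for (a1 in quantile(value, c(0.9, 1)) + c(0, 0.1))
    for (a2 in quantile(value, c(0, 0.1)) - c(0, 0.1))
      for (x0 in seq(min(pH), max(pH), length.out = 9))
        for (dx in c(0.2, 0.4, 0.6, 1)) {
          p <- c(a1, a2, x0, dx)
          if (is.null(best) || sse(p) < sse(best)) best <- p
        }
  opt <- stats::optim(best, sse, control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, sse, control = list(maxit = 5000, reltol = 1e-14))
  list(A1 = opt$par[1], A2 = opt$par[2], x0 = opt$par[3], dx = opt$par[4])
}

# Draw a filled disk into a matrix (used to build image fixtures in code).
draw_disk <- function(m, cx, cy, r, value = 200) {
  nr <- nrow(m); nc <- ncol(m)
  xs <- max(1, floor(cx - r)):min(nr, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(nc, ceiling(cy + r))
  sel <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
  block <- m[xs, ys, drop = FALSE]
  block[sel] <- value
  m[xs, ys] <- block
  m
}

# Draw a filled axis-aligned rectangle.
draw_rect <- function(m, x0, y0, w, h, value = 200) {
  m[x0:(x0 + w - 1), y0:(y0 + h - 1)] <- value
  m
}
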