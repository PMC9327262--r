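# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (brute force, explicit convolution,
# closed form) kept free of any package internals.

# Convex hull area by gift wrapping plus the shoelace formula.
hull_area_oracle <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- start
  current <- start
  repeat {
    candidate <- if (current == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == current) next
      cr <- cross(pts[current, ], pts[candidate, ], pts[j, ])
      if (candidate == current || cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[current, ])^2) >
             sum((pts[candidate, ] - pts[current, ])^2))) {
        candidate <- j
      }
    }
    current <- candidate
    if (current == start) break
    hull <- c(hull, current)
    if (length(hull) > n) stop("gift wrap failed to terminate")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  if (length(hull) < 3) return(0)
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Double boxcar convolution (full, zero-padding ignored by restricting the
# comparison to interior samples where the truncated and full filters agree).
kz_conv_oracle <- function(x, m, k = 2) {
  box <- rep(1 / m, m)
  kern <- box
  if (k > 1) {
    for (i in 2:k) {
      # full convolution of current kernel with the boxcar
      kern <- stats::convolve(kern, rev(box), type = "open")
    }
  }
  stats::filter(x, kern, sides = 2)
}

# Trapezoidal time-average of a sampled speed series.
trapz_mean_speed_oracle <- function(t, vx, vy) {
  sp <- sqrt(vx^2 + vy^2)
  dt <- diff(t)
  sum(dt * (sp[-length(sp)] + sp[-1]) / 2) / (t[length(t)] - t[1])
}

# Per-bin alternation counting by an explicit loop.
overlap_oracle <- function(bin, hand, t, n_targets) {
  total <- 0L
  for (b in unique(bin)) {
    idx <- which(bin == b)
    idx <- idx[order(t[idx])]
    h <- hand[idx]
    if (length(h) > 1) {
      for (i in 2:length(h)) if (h[i] != h[i - 1]) total <- total + 1L
    }
  }
  100 * total / n_targets
}

# Gap-model predictions by an explicit loop.
gap_oracle <- function(contact_times, window = 10, scaling = 0.965) {
  g <- diff(sort(contact_times))
  preds <- errs <- numeric(0)
  for (i in seq_along(g)) {
    if (i <= window) next
    p <- scaling * mean(g[(i - window):(i - 1)])
    preds <- c(preds, p)
    errs <- c(errs, 100 * (p - g[i]) / mean(g))
  }
  list(predicted = preds, errors_pct = errs,
       median_error_pct = median(errs),
       iqr_pct = IQR(errs, type = 7))
}

# Closed-form simple-regression slope.
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Pooled two-sample t-test from the textbook formulas.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (mean(a) - mean(b)) / se
  df <- na + nb - 2
  list(difference = mean(a) - mean(b),
       p = 2 * pt(-abs(tstat), df),
       ci = mean(a) - mean(b) + c(-1, 1) * qt(0.975, df) * se)
}
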