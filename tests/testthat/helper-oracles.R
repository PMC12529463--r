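# Independent brute-force oracles, deliberately written as naive loops and
# textbook formulas so they share no code path with the package.

# Distance from an interior point to each of the four wall segments of the
# square [0, L]^2, measured explicitly as point-to-segment distances.
oracle_wall_segment_distances <- function(p, L) {
  segs <- list(
    left = rbind(c(0, 0), c(0, L)),
    right = rbind(c(L, 0), c(L, L)),
    bottom = rbind(c(0, 0), c(L, 0)),
    top = rbind(c(0, L), c(L, L))
  )
  point_seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    proj <- a + t * ab
    sqrt(sum((p - proj)^2))
  }
  vapply(segs, function(s) point_seg(p, s[1, ], s[2, ]), numeric(1))
}

oracle_axis_distance <- function(p, L, axis) {
  d <- oracle_wall_segment_distances(p, L)
  if (axis == "x") min(d["left"], d["right"]) else min(d["bottom"], d["top"])
}

oracle_two_wall_sum <- function(p, L) {
  oracle_axis_distance(p, L, "x") + oracle_axis_distance(p, L, "y")
}

oracle_nearest_wall <- function(p, L) {
  min(oracle_wall_segment_distances(p, L))
}

# Naive per-sample loops for the trial metrics.
oracle_boundary_bias_two_wall <- function(target, response, L, floor = 0.1) {
  ratio <- numeric(2)
  for (ax in 1:2) {
    num <- min(target[ax], L - target[ax])
    den <- max(min(response[ax], L - response[ax]), floor)
    ratio[ax] <- num / den
  }
  mean(ratio)
}

oracle_bpi <- function(bee, act, L, center, floor = 0.1) {
  f <- if (center == "median") median else mean
  out <- numeric(2)
  for (ax in 1:2) {
    bd <- apply(bee, 1, function(r) min(r[ax], L - r[ax]))
    ad <- apply(act, 1, function(r) min(r[ax], L - r[ax]))
    out[ax] <- f(bd) / max(f(ad), floor)
  }
  mean(out)
}

oracle_occupancy <- function(points, L, q) {
  n_in <- 0
  for (i in seq_len(nrow(points))) {
    d <- min(oracle_wall_segment_distances(points[i, ], L))
    if (d < q * L) n_in <- n_in + 1
  }
  n_in / nrow(points)
}

# Textbook one-sample t-test.
oracle_t_test <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Pooled two-sample t-test from sums.
oracle_t_test2 <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Classic Levene via explicit deviation ANOVA sums.
oracle_levene <- function(values, group) {
  group <- as.character(group)
  gl <- unique(group)
  z <- numeric(length(values))
  for (g in gl) {
    sel <- group == g
    z[sel] <- abs(values[sel] - mean(values[sel]))
  }
  k <- length(gl)
  N <- length(values)
  zbar <- mean(z)
  ssb <- sum(vapply(gl, function(g) sum(group == g) * (mean(z[group == g]) - zbar)^2,
                    numeric(1)))
  ssw <- sum(vapply(gl, function(g) sum((z[group == g] - mean(z[group == g]))^2),
                    numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k,
       p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# OLS via the normal equations.
oracle_ols <- function(X, y) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  t <- drop(beta) / se
  list(beta = drop(beta), se = se, t = t, p = 2 * pt(-abs(t), df))
}

# Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Zellner-Siow one-sample Bayes factor via the g-prior mixture integral
# (independent of the package's noncentral-t route).
oracle_bf01 <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  num <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  dens <- function(g) {
    (1 + n * g)^(-1 / 2) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }
  den <- integrate(dens, 0, Inf, rel.tol = 1e-12)$value
  num / den
}
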