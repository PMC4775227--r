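# Independent brute-force oracles used to cross-check the closed-form models.

# fraction of DNA bound, solved by bisection on the bound complex in the full
# mass-action system P + D <=> PD, K = [P][D]/[PD]
bound_fraction_bisection <- function(p_total, d_total, kd) {
  if (d_total == 0) return(p_total / (p_total + kd))
  lo <- 0
  hi <- min(p_total, d_total)
  f <- function(b) (p_total - b) * (d_total - b) - kd * b
  for (i in 1:200) {                # run to ulp resolution; no early break
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / d_total
}

# free monomer of 2M <=> D (K = [M]^2/[D]), solved by bisection on [M]
monomer_bisection <- function(c_total, kd, tol = 1e-16) {
  if (c_total == 0) return(0)
  lo <- 0; hi <- c_total
  f <- function(m) m + 2 * m^2 / kd - c_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(c_total, 1)) break
  }
  (lo + hi) / 2
}

# dense grid search over the two component areas of one spectrum at fixed
# shared parameters; returns the minimal SSE found
area_grid_sse <- function(mz, intensity, mu1, mu2, sigma, a_max, n = 81) {
  grid <- seq(0, a_max, length.out = n)
  best <- Inf
  g1 <- stats::dnorm(mz, mu1, sigma)
  g2 <- stats::dnorm(mz, mu2, sigma)
  for (a1 in grid) {
    res0 <- intensity - a1 * g1
    sse <- vapply(grid, function(a2) sum((res0 - a2 * g2)^2), numeric(1))
    best <- min(best, min(sse))
  }
  best
}

# ordinary least squares slope by brute-force grid refinement, for checking
# the Arrhenius regression
slope_grid_search <- function(x, y, lo, hi, levels = 8, n = 41) {
  for (l in seq_len(levels)) {
    grid <- seq(lo, hi, length.out = n)
    sse <- vapply(grid, function(s) {
      b0 <- mean(y - s * x)
      sum((y - b0 - s * x)^2)
    }, numeric(1))
    i <- which.min(sse)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, n)]
  }
  grid[i]
}

# default generating truth shared by recovery tests
TRUE_MU1 <- 1001.8
TRUE_MU2 <- 1004.6
TRUE_SIGMA <- 0.5
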