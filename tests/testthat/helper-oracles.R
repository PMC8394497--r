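# Independent brute-force oracles, written directly from the feature and
# procedure definitions (loops and explicit sums, no shared code with the
# package implementations).

# percentile with linear interpolation between order statistics
oracle_percentile <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_signal_features <- function(v, n_bins = 64) {
  n <- length(v)
  mu <- sum(v) / n
  s <- sqrt(sum((v - mu)^2) / (n - 1))
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  skew <- if (m2 > 0) m3 / m2^(3 / 2) else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    counts <- numeric(n_bins)
    for (x in v) {
      b <- floor((x - lo) / (hi - lo) * n_bins) + 1
      if (b > n_bins) b <- n_bins
      counts[b] <- counts[b] + 1
    }
    p <- counts / n
    entropy <- 0
    energy <- 0
    for (pi in p) {
      if (pi > 0) entropy <- entropy - pi * log2(pi)
      energy <- energy + pi^2
    }
  } else {
    entropy <- 0; energy <- 1
  }
  p5 <- oracle_percentile(v, 0.05)
  p95 <- oracle_percentile(v, 0.95)
  central <- v[v >= p5 & v <= p95]
  mu_c <- mean(central)
  s_c <- if (length(central) > 1) sqrt(sum((central - mu_c)^2) /
                                         (length(central) - 1)) else 0
  med <- oracle_percentile(v, 0.5)
  c(mean = mu, sd = s, icv = s / mu, skewness = skew, kurtosis = kurt,
    entropy = entropy, energy = energy,
    p0.01 = oracle_percentile(v, 0.0001), p1 = oracle_percentile(v, 0.01),
    p5 = p5, p25 = oracle_percentile(v, 0.25), p50 = med,
    p75 = oracle_percentile(v, 0.75), p95 = p95,
    p99 = oracle_percentile(v, 0.99),
    p99.99 = oracle_percentile(v, 0.9999),
    mean_central90 = mu_c, sd_central90 = s_c,
    icv_central90 = s_c / mu_c,
    precision_range = p95 - p5,
    min = lo, max = hi, range = hi - lo,
    mad = oracle_percentile(abs(v - med), 0.5),
    p_below_2sd = sum(v < mu - 2 * s) / n,
    p_below_3sd = sum(v < mu - 3 * s) / n,
    p_above_2sd = sum(v > mu + 2 * s) / n,
    p_above_3sd = sum(v > mu + 3 * s) / n)
}

# intensity-weighted second central moment tensor by direct summation
oracle_mass_scatter <- function(coords, w) {
  W <- 0; cx <- 0; cy <- 0; cz <- 0
  for (i in seq_len(nrow(coords))) {
    W <- W + w[i]
    cx <- cx + w[i] * coords[i, 1]
    cy <- cy + w[i] * coords[i, 2]
    cz <- cz + w[i] * coords[i, 3]
  }
  cx <- cx / W; cy <- cy / W; cz <- cz / W
  m <- c(ms_xx = 0, ms_yy = 0, ms_zz = 0, ms_xy = 0, ms_xz = 0, ms_yz = 0)
  for (i in seq_len(nrow(coords))) {
    dx <- coords[i, 1] - cx; dy <- coords[i, 2] - cy; dz <- coords[i, 3] - cz
    m["ms_xx"] <- m["ms_xx"] + w[i] * dx * dx
    m["ms_yy"] <- m["ms_yy"] + w[i] * dy * dy
    m["ms_zz"] <- m["ms_zz"] + w[i] * dz * dz
    m["ms_xy"] <- m["ms_xy"] + w[i] * dx * dy
    m["ms_xz"] <- m["ms_xz"] + w[i] * dx * dz
    m["ms_yz"] <- m["ms_yz"] + w[i] * dy * dz
  }
  m / W
}

# step-up FDR adjustment by explicit loop
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(n, nx)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# small phantom specs shared across tests: quiet = no noise, no natural
# asymmetry, no planted effect; effectless but noisy; strongly planted
quiet_spec <- function(...) {
  phantom_spec(n_mcis = 2, n_mcip = 2, noise_sd = 0, s0_sd = 0,
               t2_between_sd = 0, asym_sd = 0,
               effect_map = data.frame(pair = integer(),
                                       t2_shift_ms = numeric(),
                                       asym_shift_ms = numeric()),
               ...)
}

null_spec <- function(...) {
  phantom_spec(effect_map = data.frame(pair = integer(),
                                       t2_shift_ms = numeric(),
                                       asym_shift_ms = numeric()),
               ...)
}

planted_spec <- function(t2_shift = 12, asym_shift = 20, ...) {
  phantom_spec(effect_map = data.frame(pair = 1, t2_shift_ms = t2_shift,
                                       asym_shift_ms = asym_shift), ...)
}
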