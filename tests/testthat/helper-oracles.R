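# independent brute-force oracles and small raster builders used across tests

# rasterized disk label mask (single label 1) in an n x n frame
disk_mask <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  cc <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, "+"))
  matrix(as.integer(d <= r), n, n)
}

# axis-aligned ellipse mask with semi-axes a (cols) and b (rows)
ellipse_mask <- function(a, b, pad = 10L) {
  nr <- 2L * ceiling(b) + 2L * pad + 1L
  nc <- 2L * ceiling(a) + 2L * pad + 1L
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  xs <- matrix(rep(seq_len(nr), nc), nr, nc)
  ys <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  matrix(as.integer(((ys - cc) / a)^2 + ((xs - cr) / b)^2 <= 1), nr, nc)
}

# closed-form Pearson correlation via the sum formula
pearson_sum_formula <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# two-tailed Welch p by numerical integration of the t density
welch_p_numeric <- function(tstat, df) {
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  2 * integrate(dens, abs(tstat), Inf, rel.tol = 1e-13)$value
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r_obs <- rank(pooled)
  u_obs <- sum(r_obs[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sample KS p by full enumeration of group assignments
ks_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ks_d <- function(xi, yi) {
    grid <- sort(unique(pooled))
    max(abs(ecdf(xi)(grid) - ecdf(yi)(grid)))
  }
  d_obs <- ks_d(x, y)
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2L, function(idx) ks_d(pooled[idx], pooled[-idx]))
  mean(ds >= d_obs - 1e-12)
}

# constant-channel image field matching a label mask's dimensions
flat_field <- function(labels, values) {
  chans <- lapply(values, function(v)
    matrix(v, nrow(labels), ncol(labels)))
  image_field(chans)
}
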