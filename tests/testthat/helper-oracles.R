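# Independent oracles used to freeze expected values. Each is coded from
# the definition of the operation, not from the package implementation.

# iterative median polish (additive overall + row + column fit)
oracleMedianPolish <- function(m, tol = 1e-9, maxiter = 500) {
  t_all <- 0
  r_eff <- rep(0, nrow(m))
  c_eff <- rep(0, ncol(m))
  z <- m
  oldsum <- 0
  for (it in seq_len(maxiter)) {
    rdelta <- apply(z, 1, stats::median, na.rm = TRUE)
    z <- z - rdelta
    r_eff <- r_eff + rdelta
    delta <- stats::median(c_eff)
    c_eff <- c_eff - delta
    t_all <- t_all + delta
    cdelta <- apply(z, 2, stats::median, na.rm = TRUE)
    z <- sweep(z, 2, cdelta)
    c_eff <- c_eff + cdelta
    delta <- stats::median(r_eff)
    r_eff <- r_eff - delta
    t_all <- t_all + delta
    newsum <- sum(abs(z), na.rm = TRUE)
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) break
    oldsum <- newsum
  }
  list(overall = t_all, row = r_eff, col = c_eff,
       summary = t_all + c_eff)
}

# BH step-up by brute force: adjusted_(i) = min over k >= i of p_(k)*m/k
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, p[o[k]] * m / k)
    adj[o[i]] <- min(1, best)
  }
  adj
}

# topological overlap by triple loop
oracleTOM <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# isotonic least squares by exhaustive enumeration of block partitions:
# the optimum is piecewise constant with non-decreasing block means
oraclePAVA <- function(v) {
  n <- length(v)
  if (n == 1) return(v)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    f <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- mean(v[idx])
      f[idx] <- means[b]
    }
    if (all(diff(means) >= -1e-12)) {
      sse <- sum((f - v)^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        best <- f
      }
    }
  }
  best
}

# exact two-sided rank-sum p by full enumeration of member subsets,
# using the doubling rule of the exact Wilcoxon test
oracleRanksumEnum <- function(x, member) {
  G <- length(x)
  m <- sum(member)
  rk <- rank(x)
  u_of <- function(idx) sum(rk[idx]) - m * (m + 1) / 2
  u_obs <- u_of(which(member))
  combos <- utils::combn(G, m)
  u_all <- apply(combos, 2, u_of)
  mu <- m * (G - m) / 2
  if (u_obs > mu) p <- 2 * mean(u_all >= u_obs)
  else p <- 2 * mean(u_all <= u_obs)
  min(1, p)
}

# plain pooled-variance fold-change-threshold t-test (no moderation)
oracleThresholdT <- function(case, ref, fc = 1.2) {
  n1 <- length(case)
  n2 <- length(ref)
  lfc <- mean(case) - mean(ref)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(ref)) / d
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  stat <- (abs(lfc) - log2(fc)) / se
  stats::pt(stat, df = d, lower.tail = FALSE)
}
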