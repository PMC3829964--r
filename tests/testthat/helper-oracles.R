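# Independent oracles used to cross-check the implementation. These are
# deliberately naive/direct renderings of the definitions and never call
# the code paths they verify.

# Benjamini-Hochberg step-up, straight from the definition:
# adj at sorted position i = min over j >= i of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenvalue
# construction.
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (b - a) / 2 * e$values[ord] + (a + b) / 2,
       w = (b - a) / 2 * 2 * e$vectors[1, ord]^2)
}

# CDF of the studentized range (k groups, df error degrees of freedom) by
# double numerical integration: outer over the scale s = sqrt(chi2_df/df),
# inner over the location of the range of k standard normals.
ptukey_oracle <- function(q, k, df) {
  if (q <= 0) return(0)
  shi <- 1 + 12 / sqrt(2 * df)
  slo <- max(1e-9, 1 - 12 / sqrt(2 * df))
  gs <- gauss_legendre(160, slo, shi)
  gz <- gauss_legendre(220, -9, 9 + q * shi)
  fs <- exp((1 - df / 2) * log(2) + (df / 2) * log(df) +
              (df - 1) * log(gs$x) - df * gs$x^2 / 2 - lgamma(df / 2))
  inner <- vapply(gs$x, function(s) {
    x <- q * s
    k * sum(gz$w * stats::dnorm(gz$x) *
              (stats::pnorm(gz$x) - stats::pnorm(gz$x - x))^(k - 1))
  }, numeric(1))
  sum(gs$w * fs * inner)
}

# SNK step-down re-implemented with the integration oracle as the critical
# decision: a stretch is significant when 1 - CDF(q_obs) <= alpha.
# Returns the homogeneous subsets as a canonically sorted list of sorted
# integer vectors (original group indices).
snk_oracle <- function(means, n, mse, df_error, alpha = 0.05) {
  k <- length(means)
  n_h <- if (length(n) == 1L) n else length(n) / sum(1 / n)
  ord <- order(means)
  m <- means[ord]
  se <- sqrt(mse / n_h)
  nonsig <- list()
  contained <- function(i, j)
    any(vapply(nonsig, function(s) i >= s[1] && j <= s[2], logical(1)))
  for (r in seq(k, 2L)) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      if (contained(i, j)) next
      q_obs <- (m[j] - m[i]) / se
      if (1 - ptukey_oracle(q_obs, r, df_error) > alpha)
        nonsig[[length(nonsig) + 1L]] <- c(i, j)
    }
  }
  covered <- rep(FALSE, k)
  for (s in nonsig) covered[s[1]:s[2]] <- TRUE
  stretches <- c(nonsig, lapply(which(!covered), function(p) c(p, p)))
  subs <- lapply(stretches, function(s) sort(ord[s[1]:s[2]]))
  canonical_subsets(subs)
}

canonical_subsets <- function(subs) {
  subs <- lapply(subs, sort)
  subs[order(vapply(subs, `[`, numeric(1), 1L),
             vapply(subs, function(s) s[length(s)], numeric(1)))]
}

# Pearson chi-square statistic straight from sum((O - E)^2 / E).
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Exact permutation p-value for the one-way F test: fraction of all
# distinct label permutations with F at least as large as observed.
anova_perm_oracle <- function(x, g) {
  g <- factor(g)
  f_stat <- function(lab) {
    gm <- tapply(x, lab, mean)
    n <- tabulate(lab)
    ssb <- sum(n * (gm - mean(x))^2)
    ssw <- sum((x - gm[lab])^2)
    (ssb / (nlevels(lab) - 1)) / (ssw / (length(x) - nlevels(lab)))
  }
  f_obs <- f_stat(g)
  perms <- perms_of(seq_along(x))
  fs <- apply(perms, 1L, function(idx) f_stat(g[idx]))
  mean(fs >= f_obs - 1e-12)
}

# Exact permutation p-value for |t| of the pooled two-sample test.
ttest_perm_oracle <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(all_v), n1)
  t_of <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  t_obs <- abs(t_of(x, y))
  ts <- apply(idx, 2L, function(i) abs(t_of(all_v[i], all_v[-i])))
  mean(ts >= t_obs - 1e-12)
}

perms_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
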