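# Independent brute-force oracles: literal, loop-based transcriptions of the
# defining formulas, kept free of the package's vectorized implementations so
# that agreement is evidence, not tautology.

oracle_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# BestKeeper: per-gene SD, per-sample geometric-mean index, correlations,
# mean of the two rankings
oracle_bestkeeper <- function(cq) {
  n <- nrow(cq); G <- ncol(cq)
  sd_g <- numeric(G)
  for (g in seq_len(G)) sd_g[g] <- oracle_sd(cq[, g])
  bki <- numeric(n)
  for (s in seq_len(n)) bki[s] <- prod(cq[s, ])^(1 / G)
  r <- numeric(G)
  for (g in seq_len(G)) r[g] <- oracle_pearson(cq[, g], bki)
  sd_rank <- rank(sd_g, ties.method = "average")
  r_rank <- rank(-r, ties.method = "average")
  list(sd = sd_g, bki = bki, r = r,
       p = oracle_pearson_p(r, n),
       mean_rank_score = (sd_rank + r_rank) / 2)
}

# comparative delta-Cq: SD of pairwise differences, averaged per gene
oracle_deltacq <- function(cq) {
  G <- ncol(cq)
  pair_sd <- matrix(0, G, G)
  for (g in seq_len(G)) {
    for (h in seq_len(G)) {
      if (g != h) pair_sd[g, h] <- oracle_sd(cq[, g] - cq[, h])
    }
  }
  mean_sd <- numeric(G)
  for (g in seq_len(G)) mean_sd[g] <- sum(pair_sd[g, -g]) / (G - 1)
  list(pair_sd = pair_sd, mean_sd = mean_sd)
}

# geNorm M with efficiency 2: mean SD of pairwise log2 expression ratios
oracle_genorm_m <- function(cq) {
  G <- ncol(cq)
  m <- numeric(G)
  for (g in seq_len(G)) {
    sds <- numeric(0)
    for (h in seq_len(G)) {
      if (h == g) next
      # log2 of quantity ratio q_g / q_h with q = 2^-Cq
      log_ratio <- (-cq[, g]) - (-cq[, h])
      sds <- c(sds, oracle_sd(log_ratio))
    }
    m[g] <- sum(sds) / (G - 1)
  }
  m
}

# NormFinder: per-group double centering, bias-corrected intra-group
# variances, shrunken group deviations, rho = mean(|d~| + sqrt(var(d~)))
oracle_normfinder <- function(cq, groups) {
  n <- nrow(cq); G <- ncol(cq)
  grps <- unique(groups); k <- length(grps)
  xc <- cq
  for (s in seq_len(n)) xc[s, ] <- cq[s, ] - sum(cq[s, ]) / G
  u <- matrix(0, k, G); d <- matrix(0, k, G)
  sig <- matrix(0, k, G); vard <- matrix(0, k, G)
  for (a in seq_len(k)) {
    rows <- which(groups == grps[a]); na <- length(rows)
    for (g in seq_len(G)) {
      gga <- sum(xc[rows, g]) / na
      u[a, g] <- sum((xc[rows, g] - gga)^2) / (na - 1)
      d[a, g] <- gga - sum(xc[, g]) / n
    }
    S <- sum(u[a, ])
    for (g in seq_len(G)) {
      sig[a, g] <- max(0, G / (G - 2) * (u[a, g] - S / (G * (G - 1))))
      vard[a, g] <- sig[a, g] / na
    }
  }
  gamma2 <- sum(d^2) / ((k - 1) * (G - 1)) - sum(vard) / (k * G)
  rho <- numeric(G)
  if (gamma2 > 0) {
    for (g in seq_len(G)) {
      acc <- 0
      for (a in seq_len(k)) {
        shr <- gamma2 / (gamma2 + vard[a, g])
        acc <- acc + abs(d[a, g] * shr) + sqrt(vard[a, g] * shr)
      }
      rho[g] <- acc / k
    }
  } else {
    for (g in seq_len(G)) rho[g] <- sum(sqrt(vard[, g])) / k
  }
  list(rho = rho, d = d, intra_var = sig, gamma2 = max(0, gamma2))
}

# geNorm pairwise variation V(n/n+1) by direct enumeration
oracle_genorm_v <- function(cq, order_best_first) {
  lq <- sweep(-cq, 2L, -colMeans(cq))  # log2 quantities, E = 2
  lq <- lq[, order_best_first, drop = FALSE]
  G <- ncol(lq)
  v <- numeric(G - 2L)
  for (nn in 2:(G - 1L)) {
    nf_n <- apply(lq[, 1:nn, drop = FALSE], 1L, function(x) sum(x) / nn)
    nf_n1 <- apply(lq[, 1:(nn + 1L), drop = FALSE], 1L, function(x) sum(x) / (nn + 1L))
    v[nn - 1L] <- oracle_sd(nf_n - nf_n1)
  }
  v
}
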