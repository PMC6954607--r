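# Brute-force oracles kept deliberately naive: explicit double loops over
# gene pairs (geNorm) and an explicit two-way ANOVA decomposition
# (NormFinder), independent of the vectorized implementations.

genorm_m_oracle <- function(m) {
  n <- nrow(m)
  M <- numeric(n)
  for (i in seq_len(n)) {
    vs <- c()
    for (k in seq_len(n)) {
      if (k == i) next
      vs <- c(vs, sd(m[i, ] - m[k, ]))
    }
    M[i] <- mean(vs)
  }
  setNames(M, rownames(m))
}

normfinder_oracle <- function(m, groups) {
  I <- nrow(m)
  glev <- unique(groups)
  G <- length(glev)
  v <- sig2 <- d <- matrix(0, I, G)
  ng <- numeric(G)
  for (gi in seq_len(G)) {
    xg <- m[, groups == glev[gi], drop = FALSE]
    ng[gi] <- ncol(xg)
    for (i in seq_len(I)) {
      res <- numeric(ncol(xg))
      for (j in seq_len(ncol(xg)))
        res[j] <- xg[i, j] - mean(xg[i, ]) - mean(xg[, j]) + mean(xg)
      v[i, gi] <- sum(res^2) / (ncol(xg) - 1)
    }
    sig2[, gi] <- pmax(0, v[, gi] - mean(v[, gi]) / (I - 1))
    for (i in seq_len(I))
      d[i, gi] <- (mean(xg[i, ]) - mean(m[i, ])) - (mean(xg) - mean(m))
  }
  rho <- numeric(I)
  inter <- numeric(I)
  for (i in seq_len(I)) {
    mpg <- mean(sig2[i, ] / ng)
    tau2 <- max(0, var(d[i, ]) - mpg)
    gam <- if (tau2 + mpg > 0) tau2 / (tau2 + mpg) else 0
    rho[i] <- mean(abs(d[i, ] * gam) + sqrt(sig2[i, ] / ng))
    inter[i] <- mean(abs(d[i, ] * gam))
  }
  list(stability = rho, intergroup = inter, sigma2 = sig2, raw_v = v)
}
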