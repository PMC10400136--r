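# Independent reference implementations used only to cross-check package
# results. They deliberately share no code with the package internals.

# Two-tailed Fisher p by explicit enumeration over all tables with the
# observed margins, probabilities from log-binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Classical product-limit estimator, no-truncation case, plain loop.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    died <- sum(time == ut[i] & event == 1)
    s <- s * (1 - died / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Newton-Raphson maximiser of the Cox partial likelihood; continuous times
# (no ties), no delayed entry. Returns the coefficient vector.
oracle_cox <- function(time, event, X, tol = 1e-12, max_iter = 60) {
  X <- as.matrix(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- rep(0, p)
  rev_cumsum <- function(v) rev(cumsum(rev(v)))
  for (it in seq_len(max_iter)) {
    w <- exp(drop(X %*% beta))
    S0 <- rev_cumsum(w)
    S1 <- apply(X * w, 2, rev_cumsum)
    if (p == 1) S1 <- matrix(S1, ncol = 1)
    xbar <- S1 / S0
    ev <- event == 1
    U <- colSums(X[ev, , drop = FALSE] - xbar[ev, , drop = FALSE])
    I <- matrix(0, p, p)
    for (j in seq_len(p)) {
      for (k in j:p) {
        S2jk <- rev_cumsum(w * X[, j] * X[, k])
        I[j, k] <- I[k, j] <- sum((S2jk / S0 - xbar[, j] * xbar[, k])[ev])
      }
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Brute-force large-scale transition count: explicit per-arm loop applying
# the merge / drop-short / adjacent-pair definition.
oracle_lst <- function(segments, genome, min_seg = 10e6, smooth_below = 3e6) {
  arms <- genome_arms(genome)
  total <- 0L
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    s <- segments[segments$chrom == a$chrom &
                    segments$start >= a$arm_start &
                    segments$end <= a$arm_end, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) == 0) next
    # merge adjacent identical states
    merged <- s[1, , drop = FALSE]
    if (nrow(s) > 1) {
      for (j in 2:nrow(s)) {
        last <- nrow(merged)
        if (s$total_cn[j] == merged$total_cn[last] &&
            s$minor_cn[j] == merged$minor_cn[last]) {
          merged$end[last] <- s$end[j]
        } else {
          merged <- rbind(merged, s[j, , drop = FALSE])
        }
      }
    }
    len <- merged$end - merged$start
    merged <- merged[len >= smooth_below, , drop = FALSE]
    len <- merged$end - merged$start
    if (nrow(merged) < 2) next
    for (j in 2:nrow(merged)) {
      state_differs <- merged$total_cn[j] != merged$total_cn[j - 1] ||
        merged$minor_cn[j] != merged$minor_cn[j - 1]
      if (state_differs && len[j] >= min_seg && len[j - 1] >= min_seg) {
        total <- total + 1L
      }
    }
  }
  total
}

# Brute-force interstitial LOH segment count (>15 Mb, chromosome not LOH
# end to end).
oracle_loh_count <- function(segments, genome) {
  n <- 0L
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    loh <- s$minor_cn == 0 & s$total_cn >= 1
    whole <- all(loh)
    n <- n + sum(loh & (s$end - s$start) > 15e6 & !whole)
  }
  n
}
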