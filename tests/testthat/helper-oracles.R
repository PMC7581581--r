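# Independent oracles used across the suite. These deliberately reimplement
# the checked quantities by the most direct route (loops, sort-based
# medians, per-cell enumeration) so they share no code with the package.

# coefficient as 20 * mean stage over an explicit per-cell vector
oracle_coefficient <- function(counts) {
  cells <- rep(1:5, times = counts)
  20 * mean(cells)
}

# per-pixel disk-neighbourhood median via explicit loops; reflection
# padding with the border pixel included in the mirror
oracle_disk_median <- function(m, radius) {
  h <- nrow(m); w <- ncol(m)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0L, h, w)
  for (r in 1:h) for (c in 1:w) {
    vals <- c()
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        vals <- c(vals, m[reflect(r + dr, h), reflect(c + dc, w)])
      }
    }
    out[r, c] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# GG epsilon through the eigenvalues of the centred covariance
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  cent <- diag(k) - 1 / k
  lam <- eigen(cent %*% S %*% cent, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  min(1, max(1 / (k - 1), sum(lam)^2 / ((k - 1) * sum(lam^2))))
}

# small paired dataset in the long format mixed_anova expects
make_paired_data <- function(n, delta = 0, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    base <- rnorm(n, 4, 0.4)
    data.frame(
      specimen_id = rep(sprintf("s%03d", 1:n), each = 2),
      background = rep(c("white", "black"), n),
      y = as.vector(rbind(base + rnorm(n, 0, sd),
                          base + delta + rnorm(n, 0, sd)))
    )
  })
}
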