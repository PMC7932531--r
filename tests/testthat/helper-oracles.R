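# Independent brute-force oracles used by several test files.

# exhaustive within-row permutation p for the Friedman statistic, k = 3
brute_friedman_p <- function(X) {
  n <- nrow(X); k <- ncol(X)
  sf <- function(M) {
    R <- t(apply(M, 1, rank))
    12 / (n * k * (k + 1)) * sum((colSums(R) - n * (k + 1) / 2)^2)
  }
  obs <- sf(X)
  pk <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- rep(1L, n); count <- 0; total <- 0
  repeat {
    M <- t(vapply(seq_len(n), function(i) X[i, pk[idx[i], ]], numeric(k)))
    if (sf(M) >= obs - 1e-9) count <- count + 1
    total <- total + 1
    j <- 1
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 6L) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > n) break
  }
  count / total
}

# exhaustive 2^n sign-flip p for the Wilcoxon signed-rank statistic
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

table_of <- function(X) {
  as_area_table(data.frame(subject = seq_len(nrow(X)), side = "left",
                           A = X[, 1], B = X[, 2], C = X[, 3]))
}
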