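# Independent brute-force oracles, deliberately written with scalar loops
# and first-principles formulas so they share no code path with the package.

brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

brute_sfc <- function(mat) {
  R <- ncol(mat)
  out <- diag(R)
  for (m in seq_len(R - 1)) for (n in (m + 1):R) {
    r <- brute_pearson(mat[, m], mat[, n])
    out[m, n] <- r; out[n, m] <- r
  }
  out
}

brute_dfc <- function(mat, window_frames, step_frames) {
  starts <- seq(1, nrow(mat) - window_frames + 1, by = step_frames)
  lapply(starts, function(s)
    brute_sfc(mat[s:(s + window_frames - 1), , drop = FALSE]))
}

brute_dncd <- function(slices, i, j, n) {
  a <- slices[[i]][n, -n]
  b <- slices[[j]][n, -n]
  1 - abs(brute_pearson(a, b))
}

brute_tdncd <- function(slices) {
  T_ <- length(slices); R <- nrow(slices[[1]])
  out <- matrix(0, R, T_ - 1)
  for (n in seq_len(R)) for (d in seq_len(T_ - 1)) {
    acc <- 0
    for (i in seq_len(T_ - d)) acc <- acc + brute_dncd(slices, i, i + d, n)
    out[n, d] <- acc / (T_ - d)
  }
  out
}

brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Normal CDF through the complementary error function (pracma), so the
# Stouffer check does not reuse stats::pnorm.
erfc_pnorm <- function(z) 0.5 * pracma::erfc(-z / sqrt(2))

brute_stouffer <- function(p, sign, n_total) {
  k <- length(p)
  z <- numeric(k)
  for (i in seq_len(k)) z[i] <- sign[i] * qnorm(1 - p[i] / 2)
  w <- sqrt(n_total)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z = zc, p = 2 * (1 - erfc_pnorm(abs(zc))))
}

# Mann-Whitney AUC from first principles (pair counting).
brute_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  wins <- 0
  for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}
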