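# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most literal formulation of
# each quantity (loops, exhaustive enumeration) and never call the package
# code paths they check.

# elementwise-accumulation MAPE
oracle_mape <- function(y_true, y_pred) {
  acc <- 0
  for (i in seq_along(y_true)) {
    acc <- acc + abs(y_true[i] - y_pred[i]) / abs(y_true[i])
  }
  100 * acc / length(y_true)
}

# closed-form OLS slope
oracle_ols_slope <- function(x, y) {
  (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
}

# Shapley values for one row by exhaustive enumeration over all p!
# feature orderings, with a single-reference value function
oracle_shapley_row <- function(predict_fun, x, ref) {
  p <- length(x)
  perms <- gtools_permutations(p)
  phi <- numeric(p)
  for (m in seq_len(nrow(perms))) {
    z <- ref
    v_prev <- predict_fun(matrix(z, 1, dimnames = list(NULL, names(x))))
    for (s in seq_len(p)) {
      j <- perms[m, s]
      z[j] <- x[j]
      v_now <- predict_fun(matrix(z, 1, dimnames = list(NULL, names(x))))
      phi[j] <- phi[j] + (v_now - v_prev)
      v_prev <- v_now
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# tie-corrected Friedman chi-square computed from first principles
oracle_friedman_stat <- function(M) {
  n <- nrow(M); k <- ncol(M)
  r <- t(apply(M, 1, rank))
  S <- 12 / (n * k * (k + 1)) * sum((colSums(r) - n * (k + 1) / 2)^2)
  C <- 1 - sum(sapply(seq_len(n), function(i) {
    t <- table(r[i, ]); sum(t^3 - t)
  })) / (n * k * (k^2 - 1))
  if (C == 0) return(0)
  S / C
}

# exact null of the Friedman statistic by enumerating all within-row rank
# permutations ((k!)^n points); returns P(stat >= observed)
oracle_friedman_exact_p <- function(M) {
  n <- nrow(M); k <- ncol(M)
  perms <- gtools_permutations(k)
  obs <- oracle_friedman_stat(M)
  idx <- rep(1L, n)
  total <- 0; ge <- 0
  repeat {
    Mp <- t(sapply(seq_len(n), function(i) M[i, perms[idx[i], ]]))
    s <- oracle_friedman_stat(Mp)
    total <- total + 1
    if (s >= obs - 1e-9) ge <- ge + 1
    j <- 1
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= nrow(perms)) break
      idx[j] <- 1L
      j <- j + 1
    }
    if (j > n) break
  }
  ge / total
}

# exact signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= W + 1e-9)
  p_ge <- mean(ws >= W - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge, less = p_le)
}

# brute-force interval aggregation of a watch stream for one feature
oracle_watch_cell <- function(sample_times, values, prev_t, t, fun) {
  sel <- sample_times > prev_t & sample_times <= t
  if (!any(sel)) return(NA_real_)
  fun(values[sel])
}
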