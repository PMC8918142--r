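# Brute-force oracles, independent of the package implementations.

# Classical Kendall tau-a by direct pair enumeration.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      s <- s + sign(x[i] - x[k]) * sign(y[i] - y[k])
    }
  }
  2 * s / (n * (n - 1))
}

# Harrell concordance by direct enumeration of orderable pairs: the pair is
# usable when the smaller observed time belongs to an event; concordant
# when the higher score accompanies the smaller time; score ties count 0.5.
oracle_concordance <- function(score, time, status) {
  n <- length(score)
  num <- den <- 0
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      if (time[i] == time[k]) next
      early <- if (time[i] < time[k]) i else k
      late <- if (time[i] < time[k]) k else i
      if (status[early] != 1) next
      den <- den + 1
      if (score[early] > score[late]) num <- num + 1
      else if (score[early] == score[late]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Breslow log partial likelihood at beta = 0: -sum over events of
# log(#{k : V_k >= V_i}).
oracle_pll0 <- function(time, status) {
  s <- 0
  for (i in which(status == 1)) {
    s <- s - log(sum(time >= time[i]))
  }
  s
}

# Small random censored dataset (continuous times; no ties unless asked).
random_surv_data <- function(n, p = 1, cens_rate = 0.3, tie_grid = NULL) {
  tt <- rexp(n)
  if (!is.null(tie_grid)) tt <- sample(tie_grid, n, replace = TRUE)
  cc <- if (cens_rate > 0) rexp(n, rate = cens_rate / (1 - cens_rate)) else Inf
  list(x = matrix(rnorm(n * p), n, p),
       time = pmin(tt, cc),
       status = as.integer(tt <= cc))
}

# Unweighted distance correlation by the direct double-centering formula.
oracle_dcor <- function(u, v) {
  n <- length(u)
  A <- abs(outer(u, u, "-")); B <- abs(outer(v, v, "-"))
  ctr <- function(M) M - rowMeans(M)[row(M)] - colMeans(M)[col(M)] + mean(M)
  A <- ctr(A); B <- ctr(B)
  d2 <- mean(A * B); du <- mean(A * A); dv <- mean(B * B)
  if (du <= 0 || dv <= 0) return(0)
  sqrt(max(d2, 0) / sqrt(du * dv))
}
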