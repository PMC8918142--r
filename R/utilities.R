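#' Marginal screening utilities
#'
#' Per-feature association statistics between one covariate column and a
#' right-censored survival outcome. Each returns a non-negative utility;
#' features are ranked by descending utility in [screen_features()].
#'
#' \describe{
#'   \item{`utility_pl`}{maximized marginal Cox log partial likelihood,
#'     reported as \eqn{\ell_j(\hat\beta_j) - \ell_j(0) \ge 0} (Breslow
#'     ties; the shared \eqn{\ell_j(0)} does not affect the ranking).}
#'   \item{`utility_sis`}{absolute Pearson correlation of the feature with
#'     log observed time (censoring ignored, as the ad hoc original does);
#'     `log_time = FALSE` uses the raw time.}
#'   \item{`utility_fast`}{feature aberration at survival times: with the
#'     column standardized, \eqn{|n^{-1}\sum_{i:\delta_i=1}(x_{ij} -
#'     \bar x_j(V_i))|} where \eqn{\bar x_j(t)} is the at-risk mean over
#'     subjects with \eqn{V_k \ge t}.}
#'   \item{`utility_cindex`}{|Harrell's C - 0.5| of the feature as a risk
#'     score, so protective and hazardous features rank symmetrically.}
#' }
#'
#' @param x one covariate column.
#' @param time observed times.
#' @param status event indicators.
#' @param log_time use log(time) for the correlation screen.
#' @param standardize standardize the column in the FAST statistic.
#' @return single non-negative utility value.
#' @name marginal_utilities
NULL

#' @rdname marginal_utilities
#' @export
utility_pl <- function(x, time, status) {
  if (stats::sd(x) == 0) return(0)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, status) ~ x, ties = "breslow")),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    warning("marginal Cox fit failed; utility set to 0", call. = FALSE)
    return(0)
  }
  max(fit$loglik[2] - fit$loglik[1], 0)
}

#' @rdname marginal_utilities
#' @export
utility_sis <- function(x, time, log_time = TRUE) {
  y <- if (log_time) log(time) else time
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(x, y))
}

#' @rdname marginal_utilities
#' @export
utility_fast <- function(x, time, status, standardize = TRUE) {
  if (sum(status) == 0) return(0)
  if (standardize) {
    s <- stats::sd(x)
    if (s == 0) return(0)
    x <- (x - mean(x)) / s
  }
  rm_at <- risk_set_means(matrix(x, ncol = 1), time)
  abs(sum((x - rm_at)[status == 1]) / length(x))
}

# At-risk means per subject for each column: row i of the result is the mean
# of the column over {k : time_k >= time_i}.
risk_set_means <- function(xm, time) {
  n <- nrow(xm)
  ord <- order(time, decreasing = TRUE)
  cs <- apply(xm[ord, , drop = FALSE], 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(xm))
  n_ge <- n + 1L - rank(time, ties.method = "min")   # #{k: time_k >= time_i}
  cs[n_ge, , drop = FALSE] / n_ge
}

#' @rdname marginal_utilities
#' @export
utility_cindex <- function(x, time, status) {
  cc <- harrell_c(x, time, status)
  if (is.na(cc)) {
    warning("no usable pairs for concordance; utility set to 0", call. = FALSE)
    return(0)
  }
  abs(cc - 0.5)
}

#' IPCW Kendall's tau screening utility
#'
#' Inverse probability-of-censoring weighted Kendall rank correlation
#' between a covariate and the survival time:
#' \deqn{\hat\tau_j = \frac{2}{n(n-1)} \sum_{i<k}
#'   \frac{\Delta_{ik}}{\hat G(\tilde V_{ik}-)^2}
#'   \mathrm{sign}(x_{ij}-x_{kj})\,\mathrm{sign}(V_i-V_k),}
#' where \eqn{\tilde V_{ik} = \min(V_i, V_k)} and \eqn{\Delta_{ik}} is the
#' event indicator of the pair's earlier subject (0 on tied observed times
#' unless both are events; tied times contribute 0 regardless through the
#' sign). Pair weights are capped at `weight_cap`; pairs with
#' \eqn{\hat G(\tilde V-) = 0} are dropped and counted in the diagnostics.
#' With no censoring the statistic reduces to classical Kendall's tau.
#' The utility is \eqn{|\hat\tau_j|}.
#'
#' @param x one covariate column.
#' @param time,status observed times and event indicators.
#' @param G a [censoring_km()] fit (computed from `time`/`status` when
#'   missing).
#' @param weight_cap maximum pair weight; default `1 / 0.05^2` (G floor
#'   0.05).
#' @return non-negative utility `|tau|`.
#' @export
utility_ipcw_tau <- function(x, time, status, G = censoring_km(time, status),
                             weight_cap = 400) {
  M <- ipcw_pair_matrix(time, status, G, weight_cap)
  abs(ipcw_tau_from_pairs(x, M))
}

# Signed, weighted pair matrix shared across features:
# M[i,k] = Delta_ik * w_ik * sign(V_i - V_k), diagonal zero.
# tau_j = sum(M * sign(outer(x_j, x_j, "-"))) / (n (n-1)).
ipcw_pair_matrix <- function(time, status, G = censoring_km(time, status),
                             weight_cap = 400) {
  n <- length(time)
  vmin <- outer(time, time, pmin)
  g2 <- matrix(G$G_minus(vmin)^2, n, n)
  w <- ifelse(g2 > 0, pmin(1 / g2, weight_cap), 0)
  dropped <- (sum(g2 == 0) - sum(diag(g2) == 0)) / 2
  if (any(1 / g2[g2 > 0] > weight_cap)) {
    message("IPCW weight cap (", weight_cap, ") binding for some pairs")
  }
  st <- as.integer(status)
  earlier_i <- outer(time, time, "<")
  di <- matrix(st, n, n)
  delta_pair <- ifelse(earlier_i, di,
                       ifelse(t(earlier_i), t(di), di * t(di)))
  M <- delta_pair * w * sign(outer(time, time, "-"))
  diag(M) <- 0
  attr(M, "dropped_pairs") <- dropped
  M
}

ipcw_tau_from_pairs <- function(x, M) {
  n <- length(x)
  sum(M * sign(outer(x, x, "-"))) / (n * (n - 1))
}

#' Censored distance-correlation screening utilities
#'
#' `utility_rcdcs` (robust censored distance correlation) replaces the
#' covariate by its empirical CDF value (average ranks over n) and the
#' outcome by the Kaplan-Meier CDF of T evaluated at the observed time, then
#' takes their [dist_cor()].
#'
#' `utility_crcdcs` (composite variant) averages, over a quantile grid, the
#' weighted distance correlation between the covariate ECDF and the
#' indicator \eqn{1\{V_i > \hat t_q\}} of exceeding the KM quantile
#' \eqn{\hat t_q}, with redistribute-to-the-right subject weights
#' \eqn{w_i = \delta_i / \hat G(V_i-)} (normalized; censored subjects get
#' weight 0, their mass shifted rightwards through the IPCW correction).
#' Quantiles above the reach of the KM CDF are dropped with a warning.
#'
#' @param x one covariate column.
#' @param time,status observed times and event indicators.
#' @param quantiles quantile grid inside (0,1); default `c(.25, .5, .75)`.
#' @param G a [censoring_km()] fit.
#' @return non-negative utility.
#' @export
utility_rcdcs <- function(x, time, status) {
  if (sum(status) == 0) {
    warning("all observations censored; degenerate KM, utility 0",
            call. = FALSE)
    return(0)
  }
  u <- rank(x, ties.method = "average") / length(x)
  v <- 1 - event_km(time, status)(time)
  dist_cor(u, v)
}

#' @rdname utility_rcdcs
#' @export
utility_crcdcs <- function(x, time, status, quantiles = c(0.25, 0.5, 0.75),
                           G = censoring_km(time, status)) {
  stopifnot(all(quantiles > 0), all(quantiles < 1))
  if (sum(status) == 0) {
    warning("all observations censored; utility 0", call. = FALSE)
    return(0)
  }
  u <- rank(x, ties.method = "average") / length(x)
  w <- status / G$G_minus(time)
  vals <- vapply(quantiles, function(q) {
    tq <- km_quantile(time, status, q)
    if (is.na(tq)) {
      warning(sprintf("KM CDF does not reach q = %.2f; quantile dropped", q),
              call. = FALSE)
      return(NA_real_)
    }
    dist_cor(u, as.numeric(time > tq), w)
  }, 0)
  if (all(is.na(vals))) return(0)
  mean(vals, na.rm = TRUE)
}
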