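#' Weighted sample distance correlation
#'
#' Sample distance correlation of two univariate samples via double-centered
#' absolute-difference matrices. Optional non-negative observation weights
#' make rows and columns contribute proportionally to the normalized
#' weights; equal weights recover the classical unweighted statistic.
#'
#' @param u,v numeric vectors of equal length (n >= 2).
#' @param w optional non-negative weights.
#' @return distance correlation in \[0, 1\]; 0 when either distance variance
#'   vanishes.
#' @export
dist_cor <- function(u, v, w = NULL) {
  n <- length(u)
  stopifnot(length(v) == n, n >= 2)
  pre <- dcor_precompute(v, w)
  dcor_apply(u, pre)
}

# Precompute the centered distance matrix and distance variance of v, so a
# screen over many u-columns pays the v-side cost once.
dcor_precompute <- function(v, w = NULL) {
  n <- length(v)
  if (is.null(w)) w <- rep(1, n)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("weights must not all be zero", call. = FALSE)
  w <- w / sum(w)
  B <- w_center(abs(outer(v, v, "-")), w)
  W2 <- outer(w, w)
  list(Bc = B, w = w, W2 = W2, dvar_v = sum(W2 * B * B))
}

dcor_apply <- function(u, pre) {
  A <- w_center(abs(outer(u, u, "-")), pre$w)
  dvar_u <- sum(pre$W2 * A * A)
  if (dvar_u <= 0 || pre$dvar_v <= 0) return(0)
  dcov2 <- sum(pre$W2 * A * pre$Bc)
  sqrt(max(dcov2, 0) / sqrt(dvar_u * pre$dvar_v))
}

# Weighted double centering of a symmetric matrix.
w_center <- function(M, w) {
  rm <- as.vector(M %*% w)
  gm <- sum(w * rm)
  M - outer(rm, rep(1, length(w))) - outer(rep(1, length(w)), rm) + gm
}
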