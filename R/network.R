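#' Nonparanormal (Winsorized ECDF probit) transformation
#'
#' Per column: the empirical CDF value `rank / (n + 1)` (average ranks) is
#' Winsorized to \eqn{[\delta_n, 1 - \delta_n]} with
#' \eqn{\delta_n = 1 / (4 n^{1/4} \sqrt{\pi \log n})} and mapped through the
#' standard-normal quantile function. The output is a monotone transform of
#' each input column (Spearman correlation 1), making heavy-tailed or skewed
#' marginals Gaussian so a Gaussian graphical model can be estimated.
#'
#' @param x numeric matrix (n >= 3 rows).
#' @return matrix of the same dimension.
#' @export
npn_transform <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 3)
  delta_n <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning(sum(const), " constant column(s) transformed to zeros",
            call. = FALSE)
  }
  out <- apply(x, 2, function(col) {
    f <- rank(col, ties.method = "average") / (n + 1)
    stats::qnorm(pmin(pmax(f, delta_n), 1 - delta_n))
  })
  out[, const] <- 0
  dimnames(out) <- dimnames(x)
  out
}

#' Sparse conditional-dependence graph by neighborhood selection
#'
#' Meinshausen-Buhlmann estimation: each standardized column is regressed
#' on all others by the lasso at penalty `lambda`; an edge (j,k) is present
#' under `rule = "or"` when either regression assigns the other a nonzero
#' coefficient, under `"and"` when both do. The default penalty is
#' \eqn{c\sqrt{\log p / n}} with `c = 2`, which puts the null-correlation
#' entry threshold at roughly 3.5 standard errors so spurious edges are
#' rare while moderate partial correlations are retained.
#'
#' @param x numeric matrix; columns are standardized internally.
#' @param lambda lasso penalty (glmnet scale); default
#'   `lambda_c * sqrt(log(p) / n)`.
#' @param rule `"or"` (default) or `"and"`.
#' @param lambda_c constant for the default penalty.
#' @return object of class `mb_graph`: `adjacency` (symmetric 0/1 matrix,
#'   zero diagonal), `lambda_used`, `rule`, `n_edges`.
#' @export
mb_graph <- function(x, lambda = NULL, rule = c("or", "and"), lambda_c = 2) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(p >= 2)
  if (is.null(lambda)) lambda <- lambda_c * sqrt(log(p) / n)
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  if (lambda == 0 && p > n) {
    stop("lambda = 0 with p > n is unidentifiable; use a positive penalty",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  xs <- scale(x)
  xs[, sds == 0] <- 0
  nb <- matrix(FALSE, p, p)
  # short decreasing path into the target penalty helps glmnet warm starts
  path <- lambda * c(8, 4, 2, 1)
  for (j in seq_len(p)) {
    if (sds[j] == 0) next
    fit <- glmnet::glmnet(xs[, -j, drop = FALSE], xs[, j],
                          lambda = path, standardize = FALSE,
                          intercept = FALSE)
    cf <- as.vector(fit$beta[, ncol(fit$beta)])
    nb[j, -j] <- cf != 0
  }
  adj <- if (rule == "or") (nb | t(nb)) else (nb & t(nb))
  adj <- adj * 1
  diag(adj) <- 0
  dimnames(adj) <- list(colnames(x), colnames(x))
  structure(list(adjacency = adj, lambda_used = lambda, rule = rule,
                 n_edges = sum(adj) / 2),
            class = "mb_graph")
}

#' @export
print.mb_graph <- function(x, ...) {
  cat(sprintf("Neighborhood-selection graph: %d nodes, %d edges (rule %s, lambda %.4g)\n",
              ncol(x$adjacency), x$n_edges, x$rule, x$lambda_used))
  invisible(x)
}

#' Row-stochastic random-walk matrix of a graph
#'
#' Row j spreads unit mass uniformly over the neighbors of feature j;
#' isolated features receive a self-loop so every row sums to one.
#'
#' @param graph an [mb_graph()] or a symmetric 0/1 adjacency matrix.
#' @return row-stochastic p x p matrix.
#' @export
random_walk_matrix <- function(graph) {
  A <- if (inherits(graph, "mb_graph")) graph$adjacency else as.matrix(graph)
  deg <- rowSums(A)
  W <- A / pmax(deg, 1)
  iso <- which(deg == 0)
  W[cbind(iso, iso)] <- 1
  W
}

#' Network smoothing of screening utilities
#'
#' Convex combination of the raw utilities with their random-walk smoothing
#' over the feature graph (a PageRank-style Markov update):
#' \deqn{u \leftarrow (1-\alpha)\,|\tau| + \alpha\, W u,}
#' iterated `iterations` times starting from \eqn{u = |\tau|}. `alpha = 0`
#' or an empty graph leaves the utilities unchanged.
#'
#' @param tau_abs non-negative utility vector (e.g. |IPCW tau|).
#' @param graph an [mb_graph()] or adjacency matrix.
#' @param alpha mixing weight in \[0, 1\]; default 0.5.
#' @param iterations number of smoothing sweeps; default 1.
#' @return non-negative smoothed utility vector.
#' @export
adjust_utilities <- function(tau_abs, graph, alpha = 0.5, iterations = 1) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  W <- random_walk_matrix(graph)
  stopifnot(length(tau_abs) == nrow(W))
  u <- tau_abs
  for (i in seq_len(iterations)) {
    u <- (1 - alpha) * tau_abs + alpha * drop(W %*% u)
  }
  u
}

#' Network-adjusted IPCW-tau screening (NPN-MB and MB)
#'
#' Full network-screening pipeline: compute |IPCW Kendall tau| utilities,
#' estimate a sparse feature graph by neighborhood selection on the
#' nonparanormal-transformed covariates (`variant = "npn"`; the NPN-MB
#' method) or on the raw standardized covariates (`variant = "raw"`; MB),
#' smooth the utilities over the graph with [adjust_utilities()], and rank.
#'
#' @param x covariates / [survival_data()] / `sim_cohort`.
#' @param time,status outcome vectors when `x` is a matrix.
#' @param variant `"npn"` or `"raw"`.
#' @param alpha,iterations smoothing parameters (see [adjust_utilities()]).
#' @param lambda,rule,lambda_c graph parameters (see [mb_graph()]).
#' @param pre_cap estimate the graph on the top-`pre_cap` features by raw
#'   utility only (others stay isolated); `NULL` (default) uses all
#'   features.
#' @param tau optional precomputed |IPCW tau| utility vector (must match
#'   `ncol(x)`); avoids recomputing the O(n^2 p) statistic when several
#'   methods share it.
#' @param weight_cap IPCW pair-weight cap.
#' @return a `feature_ranking` with graph diagnostics attached.
#' @export
screen_network <- function(x, time = NULL, status = NULL,
                           variant = c("npn", "raw"),
                           alpha = 0.5, iterations = 1,
                           lambda = NULL, rule = "or", lambda_c = 2,
                           pre_cap = NULL, tau = NULL, weight_cap = 400) {
  variant <- match.arg(variant)
  data <- as_survival_data(x, time, status)
  p <- ncol(data$x)
  if (is.null(tau)) {
    tau <- screen_features(data, method = "ipcw_tau",
                           weight_cap = weight_cap)$utility
  }
  stopifnot(length(tau) == p, all(tau >= 0))
  xg <- if (variant == "npn") npn_transform(data$x) else data$x
  if (!is.null(pre_cap) && pre_cap < p) {
    keep <- order(-tau, seq_along(tau))[seq_len(pre_cap)]
    sub <- mb_graph(xg[, keep, drop = FALSE], lambda = lambda, rule = rule,
                    lambda_c = lambda_c)
    adj <- matrix(0, p, p)
    adj[keep, keep] <- sub$adjacency
    graph <- structure(list(adjacency = adj, lambda_used = sub$lambda_used,
                            rule = rule, n_edges = sub$n_edges),
                       class = "mb_graph")
  } else {
    graph <- mb_graph(xg, lambda = lambda, rule = rule, lambda_c = lambda_c)
  }
  u <- adjust_utilities(tau, graph, alpha = alpha, iterations = iterations)
  names(u) <- colnames(data$x)
  method <- if (variant == "npn") "npn_mb" else "mb"
  new_feature_ranking(u, method, colnames(data$x),
                      diagnostics = list(n_edges = graph$n_edges,
                                         lambda = graph$lambda_used,
                                         alpha = alpha,
                                         iterations = iterations,
                                         graph = graph))
}
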