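#' Minimum model size
#'
#' Smallest number of top-ranked features needed to cover every true
#' predictor: the maximum (1-based) rank attained by any member of `truth`.
#' Lower is better; the attainable floor is `length(truth)`.
#'
#' @param ranking a `feature_ranking` or an integer permutation of feature
#'   indices in rank order.
#' @param truth non-empty integer set of true feature indices.
#' @return positive integer.
#' @export
mms <- function(ranking, truth) {
  ord <- if (inherits(ranking, "feature_ranking")) ranking$order else ranking
  stopifnot(length(truth) >= 1)
  pos <- match(truth, ord)
  if (anyNA(pos)) {
    stop("some 'truth' indices are not in the ranking", call. = FALSE)
  }
  max(pos)
}

#' Set-similarity measures
#'
#' `overlap_coefficient(a, b)` is \eqn{|A \cap B| / \min(|A|, |B|)};
#' `jaccard_index(a, b)` is \eqn{|A \cap B| / |A \cup B|}.
#'
#' @param a,b index sets (vectors; duplicates ignored).
#' @return value in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("sets must be non-empty", call. = FALSE)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' @rdname overlap_coefficient
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0) {
    stop("at least one set must be non-empty", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise method-similarity matrix
#'
#' Jaccard similarity of the top-`model_size` feature sets selected by each
#' pair of rankings over the same feature universe.
#'
#' @param rankings named list of `feature_ranking` objects.
#' @param model_size model size at which the top sets are compared;
#'   clipped to p with a warning when larger.
#' @return symmetric matrix with unit diagonal.
#' @export
method_similarity <- function(rankings, model_size = 500) {
  stopifnot(length(rankings) >= 2)
  p <- length(rankings[[1]]$utility)
  if (model_size > p) {
    warning("model_size > p; clipped to ", p, call. = FALSE)
    model_size <- p
  }
  tops <- lapply(rankings, top_features, k = model_size)
  m <- length(tops)
  out <- diag(1, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      out[i, j] <- out[j, i] <- jaccard_index(tops[[i]], tops[[j]])
    }
  }
  nm <- names(rankings)
  if (is.null(nm)) nm <- vapply(rankings, function(r) r$method, "")
  dimnames(out) <- list(nm, nm)
  out
}

#' Harrell's concordance index
#'
#' Probability that, among pairs orderable under right censoring (the
#' smaller observed time is an event), the subject with the higher risk
#' score fails earlier. Score ties count one half.
#'
#' @param score risk scores (higher = predicted to fail earlier).
#' @param time,status observed times and event indicators.
#' @return concordance in \[0, 1\]; `NA` with a warning when no pair is
#'   orderable.
#' @export
harrell_c <- function(score, time, status) {
  fit <- survival::concordance(survival::Surv(time, status) ~ score,
                               reverse = TRUE)
  cc <- unname(fit$concordance)
  if (!is.finite(cc)) {
    warning("no usable pairs; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  cc
}

#' Cox log partial likelihood at fixed coefficients
#'
#' Evaluates the Breslow-tie log partial likelihood
#' \eqn{\ell(\beta) = \sum_{i: \delta_i = 1} [\eta_i -
#' \log \sum_{k: V_k \ge V_i} e^{\eta_k}]} at supplied coefficients, with
#' no fitting. At \eqn{\beta = 0} this is \eqn{-\sum_{events}
#' \log(\mathrm{risk\ set\ size})}.
#'
#' @param beta coefficient vector (length = ncol(x)).
#' @param x covariate matrix.
#' @param time,status observed times and event indicators.
#' @return log partial likelihood (real).
#' @export
cox_pll <- function(beta, x, time, status) {
  x <- as.matrix(x)
  stopifnot(length(beta) == ncol(x))
  eta <- drop(x %*% beta)
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor", call. = FALSE)
  }
  ord <- order(time)
  eta_o <- eta[ord]
  t_o <- time[ord]
  s_o <- status[ord]
  m <- max(eta_o)
  # reverse cumulative risk sums; tied times share the risk set of the
  # first index of their block
  rs <- rev(cumsum(rev(exp(eta_o - m))))
  first_of_block <- match(t_o, t_o)
  ev <- s_o == 1
  sum(eta_o[ev] - (log(rs[first_of_block[ev]]) + m))
}

#' Test-set Cox deviance
#'
#' \eqn{D = -2(\ell(\hat\beta) - \ell(0))} evaluated on a test set, where
#' \eqn{\ell} is the Breslow log partial likelihood ([cox_pll()]). Zero for
#' the null coefficient vector; negative when the fitted model beats the
#' null on the test data.
#'
#' @param beta fitted coefficient vector (estimated on disjoint training
#'   data; the caller's contract).
#' @param x,time,status the test set.
#' @return deviance value.
#' @export
cox_deviance <- function(beta, x, time, status) {
  -2 * (cox_pll(beta, x, time, status) -
          cox_pll(rep(0, ncol(as.matrix(x))), x, time, status))
}
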