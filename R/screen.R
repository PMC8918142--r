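#' Screen features by a marginal or network-adjusted utility
#'
#' The central fitting function of the package: computes a per-feature
#' screening utility over all columns of a covariate table against a
#' right-censored outcome and returns the induced ranking. Shared
#' ingredients (the censoring Kaplan-Meier \eqn{\hat G}, the event-time KM,
#' the IPCW pair weights) are computed once per data set.
#'
#' Methods: `"pl"` (marginal Cox partial likelihood), `"sis"` (Pearson
#' correlation with log time), `"fast"` (feature aberration at survival
#' times), `"rcdcs"` / `"crcdcs"` (censored distance correlation and its
#' composite-quantile variant), `"cindex"` (Harrell concordance),
#' `"ipcw_tau"` (IPCW Kendall's tau), and the network-adjusted
#' `"npn_mb"` / `"mb"` (IPCW-tau smoothed over a graph estimated by
#' neighborhood selection on nonparanormal-transformed or raw covariates;
#' see [screen_network()]).
#'
#' @param x covariate matrix (samples x features), a [survival_data()]
#'   object, or a [simulate_cohort()] result.
#' @param time,status outcome vectors (ignored when `x` carries them).
#' @param method screening method tag.
#' @param ... method options passed through: `weight_cap`, `quantiles`,
#'   `log_time`, and for the network methods `alpha`, `iterations`,
#'   `lambda`, `rule`, `pre_cap`, `tau`.
#' @return An object of class `feature_ranking`: `utility` (named
#'   non-negative vector), `order` (feature indices by descending utility,
#'   ties broken by ascending index), `method`, `diagnostics`.
#' @examples
#' set.seed(1)
#' sc <- sim_scenario("sim1", n = 120, p = 30, censoring = NULL,
#'                    contamination = 0)
#' coh <- simulate_cohort(sc, seed = 2)
#' rk <- screen_features(coh, method = "ipcw_tau")
#' head(summary(rk)$ranking)
#' @export
screen_features <- function(x, time = NULL, status = NULL,
                            method = c("ipcw_tau", "pl", "sis", "fast",
                                       "cindex", "rcdcs", "crcdcs",
                                       "npn_mb", "mb"),
                            ...) {
  method <- match.arg(method)
  data <- as_survival_data(x, time, status)
  if (method %in% c("npn_mb", "mb")) {
    return(screen_network(data,
                          variant = if (method == "npn_mb") "npn" else "raw",
                          ...))
  }
  opts <- list(...)
  xm <- data$x
  tm <- data$time
  st <- data$status
  p <- ncol(xm)
  diagnostics <- list()

  utility <- switch(method,
    sis = {
      y <- if (isFALSE(opts$log_time)) tm else log(tm)
      sds <- apply(xm, 2, stats::sd)
      u <- abs(suppressWarnings(as.vector(stats::cor(xm, y))))
      u[sds == 0 | !is.finite(u)] <- 0
      u
    },
    pl = apply(xm, 2, utility_pl, time = tm, status = st),
    fast = {
      sds <- apply(xm, 2, stats::sd)
      xs <- scale(xm)
      xs[, sds == 0] <- 0
      rm_at <- risk_set_means(xs, tm)
      abs(colSums((xs - rm_at)[st == 1, , drop = FALSE]) / nrow(xs))
    },
    cindex = apply(xm, 2, utility_cindex, time = tm, status = st),
    ipcw_tau = {
      G <- censoring_km(tm, st)
      cap <- if (is.null(opts$weight_cap)) 400 else opts$weight_cap
      M <- ipcw_pair_matrix(tm, st, G, cap)
      diagnostics$dropped_pairs <- attr(M, "dropped_pairs")
      abs(apply(xm, 2, function(col) ipcw_tau_from_pairs(col, M)))
    },
    rcdcs = {
      v <- 1 - event_km(tm, st)(tm)
      pre <- dcor_precompute(v)
      n <- nrow(xm)
      apply(xm, 2, function(col) {
        dcor_apply(rank(col, ties.method = "average") / n, pre)
      })
    },
    crcdcs = {
      G <- censoring_km(tm, st)
      qs <- if (is.null(opts$quantiles)) c(0.25, 0.5, 0.75) else opts$quantiles
      w <- st / G$G_minus(tm)
      n <- nrow(xm)
      pres <- list()
      for (q in qs) {
        tq <- km_quantile(tm, st, q)
        if (is.na(tq)) {
          warning(sprintf("KM CDF does not reach q = %.2f; quantile dropped",
                          q), call. = FALSE)
          next
        }
        pres[[length(pres) + 1]] <- dcor_precompute(as.numeric(tm > tq), w)
      }
      if (length(pres) == 0) rep(0, p) else {
        apply(xm, 2, function(col) {
          u <- rank(col, ties.method = "average") / n
          mean(vapply(pres, function(pre) dcor_apply(u, pre), 0))
        })
      }
    })

  new_feature_ranking(utility, method, colnames(xm), diagnostics)
}

new_feature_ranking <- function(utility, method, feature_names = NULL,
                                diagnostics = list()) {
  utility <- as.vector(utility)
  if (!is.null(feature_names)) names(utility) <- feature_names
  structure(list(utility = utility,
                 order = order(-utility, seq_along(utility)),
                 method = method,
                 diagnostics = diagnostics),
            class = "feature_ranking")
}

#' Top-ranked features of a screening
#'
#' @param ranking a `feature_ranking`.
#' @param k model size.
#' @return integer vector of the k top feature indices, in rank order.
#' @export
top_features <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"), k >= 1)
  ranking$order[seq_len(min(k, length(ranking$order)))]
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Feature ranking (%s): %d features\n", x$method,
              length(x$utility)))
  top <- x$order[seq_len(min(n, length(x$order)))]
  nm <- names(x$utility)
  if (is.null(nm)) nm <- paste0("f", seq_along(x$utility))
  cat("  top:", paste(sprintf("%s (%.4g)", nm[top], x$utility[top]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.feature_ranking <- function(object, n = 20, ...) {
  top <- object$order[seq_len(min(n, length(object$order)))]
  nm <- names(object$utility)
  if (is.null(nm)) nm <- paste0("f", seq_along(object$utility))
  out <- list(method = object$method,
              ranking = data.frame(rank = seq_along(top),
                                   feature = nm[top],
                                   index = top,
                                   utility = object$utility[top],
                                   row.names = NULL),
              diagnostics = object$diagnostics)
  class(out) <- "summary.feature_ranking"
  out
}

#' @export
print.summary.feature_ranking <- function(x, ...) {
  cat(sprintf("Screening method: %s\n", x$method))
  print(x$ranking)
  invisible(x)
}

#' @export
plot.feature_ranking <- function(x, n = length(x$utility), highlight = NULL,
                                 ...) {
  u <- x$utility[x$order][seq_len(min(n, length(x$utility)))]
  plot(seq_along(u), u, type = "h", xlab = "rank", ylab = "utility",
       main = sprintf("Screening utilities (%s)", x$method), ...)
  if (!is.null(highlight)) {
    pos <- match(highlight, x$order)
    pos <- pos[!is.na(pos) & pos <= length(u)]
    graphics::points(pos, u[pos], col = 2, pch = 19)
  }
  invisible(x)
}
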