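#' Gene-network covariance structures for the covariate simulator
#'
#' Builds the correlation matrix (and generating adjacency) of the simulated
#' covariates. `"ar1"` gives the first-order autoregressive correlation
#' \eqn{\rho^{|j-k|}} with a chain adjacency. The four graph structures
#' follow the usual graphical-model generator convention: a 0/1 adjacency
#' \eqn{A} is built per structure, the precision matrix is
#' \eqn{\Omega = v A + (|\lambda_{\min}(vA)| + 0.1 + u) I}, and the
#' covariance is \eqn{\Omega^{-1}} rescaled to unit diagonal.
#'
#' Structures:
#' \describe{
#'   \item{band}{edge when `|j - k| <= bandwidth`.}
#'   \item{hub}{consecutive groups of `group_size`; the first member of each
#'     group is linked to the rest (the last group may be shorter).}
#'   \item{cluster}{consecutive groups of `group_size` with independent
#'     within-group edges at probability `edge_prob`.}
#'   \item{scale_free}{preferential attachment adding `attach_m` edges per
#'     node (via \pkg{igraph}).}
#' }
#'
#' `cluster` and `scale_free` consume random numbers; call under a seed (or
#' pass `seed`) for reproducibility.
#'
#' @param structure one of `"ar1"`, `"band"`, `"hub"`, `"cluster"`,
#'   `"scale_free"`.
#' @param p feature count (>= 2).
#' @param rho AR(1) correlation in (-1, 1).
#' @param bandwidth band half-width (band structure).
#' @param group_size group size for hub/cluster structures.
#' @param edge_prob within-group edge probability (cluster).
#' @param attach_m edges attached per node (scale_free).
#' @param offdiag_v precision off-diagonal magnitude \eqn{v}.
#' @param diag_u additional diagonal boost \eqn{u}.
#' @param seed optional integer seed for the stochastic structures.
#' @return A list of class `network_covariance` with `covariance` (p x p,
#'   unit diagonal, positive definite), `edges` (two-column matrix, j < k),
#'   and `structure`.
#' @export
network_covariance <- function(structure = c("ar1", "band", "hub", "cluster",
                                             "scale_free"),
                               p, rho = 0.5, bandwidth = 1, group_size = 20,
                               edge_prob = 0.3, attach_m = 1,
                               offdiag_v = 0.3, diag_u = 0.1, seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(p >= 2)
  if (!is.null(seed)) set.seed(seed)

  if (structure == "ar1") {
    stopifnot(abs(rho) < 1)
    covmat <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
    edges <- cbind(seq_len(p - 1), 2:p)
    return(structure(list(covariance = covmat, edges = edges,
                          structure = structure),
                     class = "network_covariance"))
  }

  edges <- switch(structure,
    band = {
      stopifnot(bandwidth >= 1)
      do.call(rbind, lapply(seq_len(p - 1), function(j) {
        k <- (j + 1):min(p, j + bandwidth)
        cbind(j, k)
      }))
    },
    hub = {
      stopifnot(group_size >= 2)
      grp <- split(seq_len(p), ceiling(seq_len(p) / group_size))
      do.call(rbind, lapply(grp, function(g) {
        if (length(g) < 2) return(NULL)
        cbind(g[1], g[-1])
      }))
    },
    cluster = {
      stopifnot(group_size >= 2, edge_prob > 0, edge_prob <= 1)
      grp <- split(seq_len(p), ceiling(seq_len(p) / group_size))
      do.call(rbind, lapply(grp, function(g) {
        if (length(g) < 2) return(NULL)
        pairs <- t(utils::combn(g, 2))
        pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
      }))
    },
    scale_free = {
      stopifnot(attach_m >= 1)
      g <- igraph::sample_pa(p, m = attach_m, directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    })
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  dimnames(edges) <- NULL

  A <- matrix(0, p, p)
  A[edges] <- 1
  A[edges[, 2:1, drop = FALSE]] <- 1

  vA <- offdiag_v * A
  lam_min <- min(eigen(vA, symmetric = TRUE, only.values = TRUE)$values)
  omega <- vA + diag(abs(lam_min) + 0.1 + diag_u, p)
  covmat <- chol2inv(chol(omega))
  covmat <- stats::cov2cor(covmat)
  # PD by construction; a failed Cholesky here indicates an internal error
  ch <- tryCatch(chol(covmat), error = function(e) {
    stop("internal error: generated covariance for structure '", structure,
         "' is not positive definite", call. = FALSE)
  })

  structure(list(covariance = covmat, edges = edges, structure = structure),
            class = "network_covariance")
}

#' Draw correlated Gaussian covariates
#'
#' Rows are i.i.d. mean-zero multivariate normal with the supplied
#' covariance (Cholesky factorization).
#'
#' @param n number of subjects.
#' @param covariance positive-definite p x p matrix, or a
#'   [network_covariance()] object.
#' @param seed optional integer seed.
#' @return An `n x p` numeric matrix.
#' @export
draw_covariates <- function(n, covariance, seed = NULL) {
  if (inherits(covariance, "network_covariance")) {
    covariance <- covariance$covariance
  }
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(covariance)
  R <- tryCatch(chol(covariance), error = function(e) {
    stop("Cholesky factorization of the covariance failed: ",
         conditionMessage(e), call. = FALSE)
  })
  matrix(stats::rnorm(n * p), n, p) %*% R
}

#' Heavy-tailed covariate contamination
#'
#' With probability `prob`, independently per entry (or per subject row when
#' `unit = "subject"`), an observed covariate value is replaced by an
#' independent draw from a Student-t distribution with `df` degrees of
#' freedom, emulating outlier-corrupted measurements.
#'
#' @param x numeric matrix.
#' @param prob contamination probability in \[0, 1\]; default 0.1.
#' @param df t-distribution degrees of freedom; default 2.
#' @param unit `"entry"` (default) or `"subject"` (whole rows replaced).
#' @param seed optional integer seed.
#' @return A list with `x` (contaminated matrix) and `mask` (logical matrix
#'   marking replaced entries).
#' @export
contaminate <- function(x, prob = 0.1, df = 2,
                        unit = c("entry", "subject"), seed = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(prob), prob >= 0, prob <= 1, df > 0)
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  if (prob == 0) {
    return(list(x = x, mask = matrix(FALSE, nrow(x), ncol(x))))
  }
  mask <- if (unit == "entry") {
    matrix(stats::runif(length(x)) < prob, nrow(x), ncol(x))
  } else {
    rows <- stats::runif(nrow(x)) < prob
    matrix(rows, nrow(x), ncol(x))
  }
  x[mask] <- stats::rt(sum(mask), df = df)
  list(x = x, mask = mask)
}
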