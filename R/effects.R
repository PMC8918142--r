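#' Effect specification: coefficients and per-feature link functions
#'
#' Houses the sparse coefficient vector \eqn{\beta_0} of the simulated
#' transformation model together with a per-feature link tag. The linear
#' predictor is \eqn{\eta_i = \sum_j g_j(x_{ij})} where `linear` means
#' \eqn{g_j(x) = \beta_j x}, `abs` means \eqn{\beta_j |x|}, `square` means
#' \eqn{\beta_j x^2} and `indicator_positive` means \eqn{\beta_j 1(x > 0)}.
#'
#' @param beta numeric coefficient vector.
#' @param links character vector of link tags, recycled to `length(beta)`.
#' @return An object of class `effect_spec` with elements `beta`, `links`
#'   and `truth` (indices of nonzero coefficients).
#' @export
effect_spec <- function(beta, links = "linear") {
  stopifnot(is.numeric(beta), length(beta) >= 1)
  links <- rep_len(as.character(links), length(beta))
  ok <- c("linear", "abs", "square", "indicator_positive")
  if (!all(links %in% ok)) {
    stop("unknown link tag(s): ", paste(setdiff(links, ok), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(beta = beta, links = links, truth = which(beta != 0)),
    class = "effect_spec"
  )
}

#' Sparse coefficient vectors of the built-in simulation designs
#'
#' `sim_beta("sim1")` returns the 2,000-dimensional sparse vector with 14
#' nonzero entries used by the first (and second) simulation design;
#' `sim_beta("sim3")` the \eqn{\pm 1.5} vector of the network-structure
#' design (15 nonzero entries as printed). `sim_links()` returns the sim-1
#' coefficients with the nonlinear links of the second design: features 1
#' and 2 act through \eqn{|x|}, feature 4 through \eqn{x^2}, feature 5
#' through \eqn{1(x>0)}, all others linearly.
#'
#' @param scenario `"sim1"` or `"sim3"`.
#' @param p total feature count; trailing coefficients are zero. Default 2000.
#' @return An [effect_spec()].
#' @export
sim_beta <- function(scenario = c("sim1", "sim3"), p = 2000) {
  scenario <- match.arg(scenario)
  head25 <- switch(scenario,
    sim1 = c(-1, -0.9, 0.5, 0.8, 0.6, rep(0, 5),
             0.3, 0.7, -0.8, -0.5, -1, rep(0, 5),
             -2, 1, 0, -0.5, -2),
    sim3 = c(-1.5, -1.5, 1.5, 1.5, 1.5, rep(0, 5),
             1.5, 1.5, -1.5, -1.5, -1.5, rep(0, 5),
             -1.5, 1.5, 1.5, -1.5, -1.5))
  if (p < length(head25)) {
    stop("'p' must be at least ", length(head25), call. = FALSE)
  }
  effect_spec(c(head25, rep(0, p - length(head25))))
}

#' @rdname sim_beta
#' @export
sim_links <- function(p = 2000) {
  eff <- sim_beta("sim1", p = p)
  eff$links[c(1, 2)] <- "abs"
  eff$links[4] <- "square"
  eff$links[5] <- "indicator_positive"
  eff
}

#' Linear predictor under per-feature links
#'
#' Computes \eqn{\eta_i = \sum_j g_j(x_{ij})} for an [effect_spec()]. With
#' all-linear links this is the ordinary matrix product \eqn{X\beta}.
#'
#' @param x numeric matrix, one row per subject.
#' @param effects an [effect_spec()].
#' @return numeric vector of length `nrow(x)`.
#' @export
linear_predictor <- function(x, effects) {
  x <- as.matrix(x)
  if (ncol(x) != length(effects$beta)) {
    stop("ncol(x) (", ncol(x), ") != length(beta) (", length(effects$beta), ")",
         call. = FALSE)
  }
  eta <- drop(x[, effects$links == "linear", drop = FALSE] %*%
                effects$beta[effects$links == "linear"])
  for (j in which(effects$links != "linear")) {
    gj <- switch(effects$links[j],
                 abs = abs(x[, j]),
                 square = x[, j]^2,
                 indicator_positive = as.numeric(x[, j] > 0))
    eta <- eta + effects$beta[j] * gj
  }
  eta
}
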