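#' Survival screening input container
#'
#' Couples a samples-by-features covariate table with right-censored
#' outcomes: observed time `V = min(T, C)` and event indicator
#' `delta = 1{T <= C}`.
#'
#' @param x numeric matrix or data frame (samples x features).
#' @param time positive observed times.
#' @param status event indicators, 1 = event, 0 = censored.
#' @return object of class `survival_data` with elements `x`, `time`,
#'   `status`.
#' @export
survival_data <- function(x, time, status) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  time <- as.numeric(time)
  status <- as.integer(status)
  n <- nrow(x)
  if (length(time) != n || length(status) != n) {
    stop("'time' and 'status' must have one entry per row of 'x'",
         call. = FALSE)
  }
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(x) || anyNA(time) || anyNA(status)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (any(time <= 0)) stop("'time' must be strictly positive", call. = FALSE)
  if (!all(status %in% c(0L, 1L))) {
    stop("'status' must be 0/1", call. = FALSE)
  }
  if (sum(status) == 0) stop("need at least one event", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, time = time, status = status),
            class = "survival_data")
}

# Accept survival_data, sim_cohort, or raw pieces uniformly.
as_survival_data <- function(x, time = NULL, status = NULL) {
  if (inherits(x, "survival_data")) return(x)
  if (inherits(x, "sim_cohort")) return(survival_data(x$x, x$time, x$status))
  survival_data(x, time, status)
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("Survival data: n = %d, p = %d, events = %d (%.1f%% censored)\n",
              nrow(x$x), ncol(x$x), sum(x$status),
              100 * mean(x$status == 0)))
  invisible(x)
}

#' Kaplan-Meier estimate of the censoring survivor function
#'
#' Estimates \eqn{\hat G(t) = P(C > t)} by the Kaplan-Meier method with the
#' roles of events and censorings reversed. At a tied time, deaths precede
#' censorings in the risk-set bookkeeping: the risk set for a censoring at
#' time t excludes subjects who died at t.
#'
#' @param time observed times.
#' @param status event indicators (1 = event; 0 = censored, i.e. the
#'   "event" of the censoring distribution).
#' @return object of class `censor_km` with fields `time` (jump grid),
#'   `surv`, and evaluators `G(t)` (right-continuous) and `G_minus(t)`
#'   (left limit).
#' @export
censoring_km <- function(time, status) {
  stopifnot(length(time) == length(status), all(time > 0))
  status <- as.integer(status)
  if (all(status == 0L)) {
    warning("all observations censored; G-hat drops to 0", call. = FALSE)
  }
  ut <- sort(unique(time))
  d_death <- vapply(ut, function(t) sum(time == t & status == 1L), 0)
  d_cens <- vapply(ut, function(t) sum(time == t & status == 0L), 0)
  n_tot <- vapply(ut, function(t) sum(time >= t), 0)
  at_risk <- n_tot - d_death          # deaths at t leave before censorings
  haz <- ifelse(d_cens > 0, d_cens / at_risk, 0)
  surv <- cumprod(1 - haz)
  G <- stats::stepfun(ut, c(1, surv), right = FALSE)
  G_minus <- stats::stepfun(ut, c(1, surv), right = TRUE)
  structure(list(time = ut, surv = surv, G = G, G_minus = G_minus,
                 n = length(time)),
            class = "censor_km")
}

#' @export
print.censor_km <- function(x, ...) {
  cat(sprintf("Censoring Kaplan-Meier: %d subjects, %d jump times, G(max) = %.3f\n",
              x$n, length(x$time), min(x$surv)))
  invisible(x)
}

# Kaplan-Meier of the event-time distribution as a right-continuous survivor
# step function (wraps survival::survfit).
event_km <- function(time, status) {
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
}

# Leftmost time at which the KM CDF of T reaches probability q; NA when the
# KM plateaus below q.
km_quantile <- function(time, status, q) {
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  cdf <- 1 - fit$surv
  idx <- which(cdf >= q - 1e-12)
  if (length(idx) == 0) return(NA_real_)
  fit$time[min(idx)]
}
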