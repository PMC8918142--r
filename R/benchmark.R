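#' Replication benchmark of screening methods
#'
#' Repeats, for `replications` simulated cohorts: screen with each method,
#' record the minimum model size and the overlap-coefficient curve of the
#' top-k set with the truth over `size_grid`, optionally the held-out
#' c-index curve (1:1 train/test split, ridge-stabilized Cox refit on the
#' top-k screened training features, Harrell's C on the test half) and the
#' pairwise method-similarity matrix at `similarity_size`. Censoring is
#' calibrated once for the scenario and reused across replications;
#' replication r uses seed `seed + r`.
#'
#' @param config a [sim_scenario()].
#' @param methods character vector of method tags (see
#'   [screen_features()]).
#' @param replications number of replications (study scale is 200; scale
#'   down for quick runs).
#' @param size_grid model sizes for the metric curves.
#' @param seed master integer seed.
#' @param cindex compute held-out c-index curves (costly).
#' @param cindex_insample if `TRUE` the c-index is computed on the training
#'   half instead of the held-out half.
#' @param similarity_size model size for the similarity matrix (`NULL`
#'   disables).
#' @param ridge_penalty ridge penalty of the refit Cox model.
#' @param calibration_draws Monte-Carlo size for censoring calibration.
#' @param ... extra options passed to [screen_features()].
#' @return object of class `screen_benchmark`: `mms` (replications x
#'   methods matrix), `overlap` (mean curve matrix, sizes x methods),
#'   `cindex` (ditto or NULL), `similarity` (mean matrix or NULL),
#'   `size_grid`, `config`, `failures`.
#' @export
run_benchmark <- function(config, methods = c("ipcw_tau", "npn_mb"),
                          replications = 20,
                          size_grid = seq(25, 500, by = 25),
                          seed = 1, cindex = FALSE, cindex_insample = FALSE,
                          similarity_size = NULL, ridge_penalty = 1e-4,
                          calibration_draws = 200000, ...) {
  stopifnot(inherits(config, "sim_scenario"), replications >= 1)
  config <- resolve_censoring(config, mc_draws = calibration_draws,
                              seed = seed)
  if (deterministic_structure(config)) {
    config[["net_cache"]] <- scenario_covariance(config)
  }
  size_grid <- size_grid[size_grid <= config$p]
  nm <- methods
  mms_mat <- matrix(NA_real_, replications, length(nm),
                    dimnames = list(NULL, nm))
  ov_sum <- matrix(0, length(size_grid), length(nm),
                   dimnames = list(size_grid, nm))
  ci_sum <- matrix(0, length(size_grid), length(nm),
                   dimnames = list(size_grid, nm))
  sim_sum <- NULL
  failures <- 0L
  ok_reps <- 0L

  for (r in seq_len(replications)) {
    res <- tryCatch({
      coh <- simulate_cohort(config, seed = seed + r)
      data <- as_survival_data(coh)
      tau <- if (any(methods %in% c("ipcw_tau", "npn_mb", "mb"))) {
        screen_features(data, method = "ipcw_tau")$utility
      } else NULL
      rankings <- lapply(methods, function(m) {
        if (m == "ipcw_tau") {
          new_feature_ranking(tau, "ipcw_tau", colnames(data$x))
        } else if (m %in% c("npn_mb", "mb")) {
          screen_features(data, method = m, tau = tau, ...)
        } else {
          screen_features(data, method = m, ...)
        }
      })
      names(rankings) <- methods
      list(coh = coh, data = data, rankings = rankings)
    }, error = function(e) {
      warning(sprintf("replication %d failed: %s", r, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > max(1, 0.1 * replications)) {
        stop("more than 10% of replications failed; aborting", call. = FALSE)
      }
      next
    }
    ok_reps <- ok_reps + 1L
    truth <- res$coh$truth
    for (m in seq_along(methods)) {
      rk <- res$rankings[[m]]
      mms_mat[r, m] <- mms(rk, truth)
      ov_sum[, m] <- ov_sum[, m] + vapply(size_grid, function(k) {
        overlap_coefficient(top_features(rk, k), truth)
      }, 0)
    }
    if (cindex) {
      ci_sum <- ci_sum + cindex_curves(res$data, res$rankings, size_grid,
                                       ridge_penalty, cindex_insample)
    }
    if (!is.null(similarity_size) && length(methods) >= 2) {
      sm <- method_similarity(res$rankings, similarity_size)
      sim_sum <- if (is.null(sim_sum)) sm else sim_sum + sm
    }
  }
  if (ok_reps == 0) stop("all replications failed", call. = FALSE)

  structure(list(mms = mms_mat,
                 overlap = ov_sum / ok_reps,
                 cindex = if (cindex) ci_sum / ok_reps else NULL,
                 similarity = if (!is.null(sim_sum)) sim_sum / ok_reps else NULL,
                 size_grid = size_grid, config = config,
                 replications = replications, failures = failures,
                 seed = seed),
            class = "screen_benchmark")
}

# Held-out (or in-sample) concordance per model size: 1:1 split, ridge Cox
# refit on the top-k screened training features, Harrell's C on the
# evaluation half.
cindex_curves <- function(data, rankings, size_grid, ridge_penalty,
                          insample = FALSE) {
  n <- nrow(data$x)
  tr <- sample(n, floor(n / 2))
  te <- if (insample) tr else setdiff(seq_len(n), tr)
  out <- matrix(NA_real_, length(size_grid), length(rankings))
  for (m in seq_along(rankings)) {
    ord <- rankings[[m]]$order
    for (i in seq_along(size_grid)) {
      k <- size_grid[i]
      feats <- ord[seq_len(k)]
      beta <- ridge_cox_fit(data$x[tr, feats, drop = FALSE],
                            data$time[tr], data$status[tr], ridge_penalty)
      sc <- drop(data$x[te, feats, drop = FALSE] %*% beta)
      out[i, m] <- harrell_c(sc, data$time[te], data$status[te])
    }
  }
  out
}

# Ridge Cox coefficients at a fixed penalty. When glmnet cannot converge at
# the requested penalty (small n, many features), the penalty is escalated
# 100-fold, up to twice, before giving up with the null coefficients.
ridge_cox_fit <- function(x, time, status, penalty = 1e-2) {
  y <- survival::Surv(time, status)
  for (lam in penalty * c(1, 100, 10000)) {
    converged <- TRUE
    fit <- withCallingHandlers(
      tryCatch(glmnet::glmnet(x, y, family = "cox", alpha = 0, lambda = lam,
                              standardize = FALSE),
               error = function(e) NULL),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (!is.null(fit) && converged) return(as.vector(fit$beta))
  }
  rep(0, ncol(x))
}

#' @export
print.screen_benchmark <- function(x, ...) {
  cat(sprintf("Screening benchmark: %s (%s), %d replications (%d failed)\n",
              x$config$scenario, x$config$structure, x$replications,
              x$failures))
  cat("Median MMS by method:\n")
  print(apply(x$mms, 2, stats::median, na.rm = TRUE))
  invisible(x)
}

#' @export
plot.screen_benchmark <- function(x, what = c("overlap", "cindex", "mms"),
                                  ...) {
  what <- match.arg(what)
  if (what == "mms") {
    graphics::boxplot(x$mms, ylab = "minimum model size", ...)
  } else {
    m <- x[[what]]
    if (is.null(m)) stop("benchmark was run without ", what, call. = FALSE)
    graphics::matplot(x$size_grid, m, type = "l", lty = 1,
                      xlab = "model size", ylab = what, ...)
    graphics::legend("bottomright", legend = colnames(m), col = seq_len(ncol(m)),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
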