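#' Load an expression + clinical dataset
#'
#' Reads a samples-by-features expression table (TSV or CSV; first column =
#' sample id) and a clinical table (sample id, observed time, event
#' indicator), inner-joins them on sample id, drops rows with missing or
#' non-positive times or missing status, and removes zero-variance features.
#' Dropped counts and removed features are reported via `message()`.
#'
#' @param expression path to the expression table.
#' @param clinical path to the clinical table.
#' @return a [survival_data()] with sample ids as row names.
#' @export
load_dataset <- function(expression, clinical) {
  expr <- read_table_auto(expression)
  clin <- read_table_auto(clinical)
  if (ncol(clin) < 3) {
    stop("clinical table needs at least 3 columns: id, time, status",
         call. = FALSE)
  }
  ids_e <- as.character(expr[[1]])
  ids_c <- as.character(clin[[1]])
  common <- intersect(ids_e, ids_c)
  if (length(common) == 0) {
    stop("no overlapping sample ids between expression and clinical tables",
         call. = FALSE)
  }
  expr <- expr[match(common, ids_e), -1, drop = FALSE]
  clin <- clin[match(common, ids_c), , drop = FALSE]
  for (j in seq_along(expr)) {
    if (!is.numeric(expr[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(expr[[j]]))))[1]
      stop(sprintf("non-numeric expression value in column '%s', sample '%s'",
                   names(expr)[j], common[bad]), call. = FALSE)
    }
  }
  time <- suppressWarnings(as.numeric(clin[[2]]))
  status <- suppressWarnings(as.numeric(clin[[3]]))
  keep <- !is.na(time) & time > 0 & status %in% c(0, 1)
  if (any(!keep)) {
    message("dropped ", sum(!keep), " sample(s) with missing/invalid ",
            "time or status")
  }
  xm <- as.matrix(expr[keep, , drop = FALSE])
  rownames(xm) <- common[keep]
  sds <- apply(xm, 2, stats::sd)
  if (any(sds == 0)) {
    message("removed ", sum(sds == 0), " zero-variance feature(s): ",
            paste(utils::head(colnames(xm)[sds == 0], 5), collapse = ", "),
            if (sum(sds == 0) > 5) ", ..." else "")
    xm <- xm[, sds > 0, drop = FALSE]
  }
  survival_data(xm, time[keep], status[keep])
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Marginal-Cox prefilter
#'
#' Fits a univariate Cox model per feature and keeps the `k` features with
#' the smallest Wald p-values (ties broken by feature id). Features whose
#' marginal fit fails are assigned p = 1 and reported. `k >= p` returns the
#' data unchanged.
#'
#' @param data a [survival_data()].
#' @param k number of features to retain.
#' @return a reduced [survival_data()]; attribute `"kept"` holds the
#'   retained column indices of the input.
#' @export
prefilter_cox <- function(data, k) {
  stopifnot(inherits(data, "survival_data"), k >= 1)
  p <- ncol(data$x)
  if (k >= p) {
    out <- data
    attr(out, "kept") <- seq_len(p)
    return(out)
  }
  ss <- survival::Surv(data$time, data$status)
  pvals <- apply(data$x, 2, function(col) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(ss ~ col, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients) ||
        anyNA(diag(fit$var)) || any(diag(fit$var) <= 0)) {
      return(1)
    }
    z2 <- fit$coefficients[1]^2 / fit$var[1, 1]
    stats::pchisq(z2, df = 1, lower.tail = FALSE)
  })
  n_failed <- sum(pvals >= 1)
  if (n_failed > 0) {
    message(n_failed, " feature(s) with failed/degenerate marginal fits ",
            "assigned p = 1")
  }
  kept <- order(pvals, seq_len(p))[seq_len(k)]
  kept <- sort(kept)
  out <- survival_data(data$x[, kept, drop = FALSE], data$time, data$status)
  attr(out, "kept") <- kept
  out
}

#' Sparse Cox fitters
#'
#' Fitters conform to the contract `function(x, time, status)` returning a
#' coefficient vector over the columns of `x`. `fitter_ridge()` is the
#' shipped default, a ridge-stabilized Cox fit via \pkg{glmnet};
#' `fitter_null()` returns all-zero coefficients (the null model);
#' `fitter_mcp()` is an adapter slot for an external minimax-concave-penalty
#' solver — pass the solver as `solve_fn` (e.g. a wrapper around
#' `ncvreg::ncvsurv`), otherwise calling the fitter signals an error with
#' guidance.
#'
#' @param penalty ridge penalty.
#' @param solve_fn external MCP solver `function(x, time, status)`.
#' @return a fitter function.
#' @export
fitter_ridge <- function(penalty = 1e-2) {
  force(penalty)
  function(x, time, status) ridge_cox_fit(x, time, status, penalty)
}

#' @rdname fitter_ridge
#' @export
fitter_null <- function() {
  function(x, time, status) rep(0, ncol(as.matrix(x)))
}

#' @rdname fitter_ridge
#' @export
fitter_mcp <- function(solve_fn = NULL) {
  if (is.null(solve_fn)) {
    function(x, time, status) {
      stop("no MCP solver bundled; supply fitter_mcp(solve_fn = ) with a ",
           "function(x, time, status) -> coefficients (e.g. wrapping ",
           "ncvreg::ncvsurv)", call. = FALSE)
    }
  } else {
    solve_fn
  }
}

#' Screen, hard-threshold and fit on training data
#'
#' Ranks features on the training data, keeps the top `top_d`, delegates
#' the penalized Cox fit to the fitter, and embeds the coefficients back
#' into the full feature space. NOSF (number of selected features) counts
#' coefficients above 1e-8 in magnitude.
#'
#' @param train a [survival_data()].
#' @param method screening method tag.
#' @param top_d hard-threshold model size.
#' @param fitter a fitter function (see [fitter_ridge()]).
#' @param ... options passed to [screen_features()].
#' @return list with `beta` (full-length coefficients), `selected`
#'   (top-`top_d` indices), `nosf`.
#' @export
screen_threshold_fit <- function(train, method = "ipcw_tau", top_d = 50,
                                 fitter = fitter_ridge(), ...) {
  train <- as_survival_data(train)
  p <- ncol(train$x)
  top_d <- min(top_d, p)
  rk <- screen_features(train, method = method, ...)
  sel <- top_features(rk, top_d)
  beta_sel <- fitter(train$x[, sel, drop = FALSE], train$time, train$status)
  beta <- rep(0, p)
  beta[sel] <- beta_sel
  list(beta = beta, selected = sel, nosf = sum(abs(beta) > 1e-8),
       ranking = rk)
}

#' Repeated-split screening and prediction pipeline
#'
#' The real-data protocol: for each of `n_splits` seeded random splits at
#' `train_fraction`, prefilter features by marginal Cox p-value on the
#' training portion only (set `paper_protocol = TRUE` to prefilter once on
#' the whole data before splitting, for comparability with whole-data
#' protocols), screen and fit on the training set, and evaluate test-set
#' Cox deviance and Harrell's c-index. When `top_d` is a grid, the size
#' maximizing the median held-out c-index is selected and results reported
#' at that size. Medians across completed splits summarize the report.
#'
#' @param data a [survival_data()].
#' @param method screening method tag.
#' @param prefilter_k marginal-Cox prefilter size (default 2000).
#' @param top_d hard-threshold size or grid (default `seq(10, 300, 10)`).
#' @param n_splits number of random splits (default 5).
#' @param train_fraction training proportion (default 0.8).
#' @param fitter a fitter function.
#' @param paper_protocol prefilter on the whole data before splitting.
#' @param seed master integer seed; split s uses `seed + s`.
#' @param ... options passed to [screen_features()].
#' @return object of class `split_report`: `per_split` data frame (split,
#'   top_d, cindex, deviance, nosf), `chosen_d`, `medians`, `grid_medians`,
#'   plus per-split fitted coefficients at the chosen size
#'   (`coefficients`, named by feature) and the per-split prefiltered
#'   feature indices (`kept_features`).
#' @export
evaluate_splits <- function(data, method = "ipcw_tau", prefilter_k = 2000,
                            top_d = seq(10, 300, by = 10), n_splits = 5,
                            train_fraction = 0.8, fitter = fitter_ridge(),
                            paper_protocol = FALSE, seed = 1, ...) {
  data <- as_survival_data(data)
  stopifnot(train_fraction > 0, train_fraction < 1, n_splits >= 1)
  n <- nrow(data$x)
  grid <- sort(unique(pmin(top_d, ncol(data$x))))

  if (paper_protocol) data_all <- prefilter_cox(data, prefilter_k)

  rows <- list()
  failed <- 0L
  for (s in seq_len(n_splits)) {
    res <- tryCatch({
      set.seed(seed + s)
      tr_idx <- sort(sample(n, floor(n * train_fraction)))
      te_idx <- setdiff(seq_len(n), tr_idx)
      base <- if (paper_protocol) data_all else data
      train0 <- survival_data(base$x[tr_idx, , drop = FALSE],
                              base$time[tr_idx], base$status[tr_idx])
      train <- if (paper_protocol) {
        attr(train0, "kept") <- seq_len(ncol(train0$x)); train0
      } else {
        prefilter_cox(train0, prefilter_k)
      }
      kept <- attr(train, "kept")
      x_te <- base$x[te_idx, kept, drop = FALSE]
      t_te <- base$time[te_idx]
      s_te <- base$status[te_idx]
      rk <- screen_features(train, method = method, ...)
      per_d <- lapply(grid, function(d) {
        sel <- top_features(rk, d)
        beta_sel <- fitter(train$x[, sel, drop = FALSE],
                           train$time, train$status)
        beta <- rep(0, ncol(train$x))
        beta[sel] <- beta_sel
        sc <- drop(x_te %*% beta)
        list(row = data.frame(split = s, top_d = d,
                              cindex = harrell_c(sc, t_te, s_te),
                              deviance = cox_deviance(beta, x_te, t_te, s_te),
                              nosf = sum(abs(beta) > 1e-8)),
             coefficients = stats::setNames(beta_sel, colnames(train$x)[sel]))
      })
      list(rows = do.call(rbind, lapply(per_d, `[[`, "row")),
           coefficients = stats::setNames(lapply(per_d, `[[`, "coefficients"),
                                          grid),
           kept = kept)
    }, error = function(e) {
      warning(sprintf("split %d failed: %s", s, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- failed + 1L else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("all splits failed", call. = FALSE)
  per_split_grid <- do.call(rbind, lapply(rows, `[[`, "rows"))

  grid_medians <- stats::aggregate(cbind(cindex, deviance, nosf) ~ top_d,
                                   data = per_split_grid, FUN = stats::median)
  chosen_d <- grid_medians$top_d[which.max(grid_medians$cindex)]
  per_split <- per_split_grid[per_split_grid$top_d == chosen_d, , drop = FALSE]
  medians <- c(cindex = stats::median(per_split$cindex),
               deviance = stats::median(per_split$deviance),
               nosf = stats::median(per_split$nosf))
  coefs <- lapply(rows, function(r) r$coefficients[[as.character(chosen_d)]])
  structure(list(per_split = per_split, per_split_grid = per_split_grid,
                 grid_medians = grid_medians, chosen_d = chosen_d,
                 medians = medians, method = method, n_splits = n_splits,
                 failed = failed, seed = seed,
                 paper_protocol = paper_protocol,
                 coefficients = coefs,
                 kept_features = lapply(rows, `[[`, "kept")),
            class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("Repeated-split report (%s): %d split(s), %d failed\n",
              x$method, x$n_splits, x$failed))
  cat(sprintf("  selected model size: %d\n", x$chosen_d))
  cat(sprintf("  median c-index: %.3f | median deviance: %.3f | median NOSF: %g\n",
              x$medians["cindex"], x$medians["deviance"], x$medians["nosf"]))
  invisible(x)
}
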