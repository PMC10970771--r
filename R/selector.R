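#' Standardize an expression matrix and center a binary response
#'
#' Builds the selector input: features (miRNAs) become columns of `X`,
#' scaled to mean 0 and standard deviation 1 (denominator n - 1); the 0/1
#' response is centered to `Yc = Y - mean(Y)`. Zero-variance features are
#' dropped with a warning.
#'
#' @param normalized a `normalized_matrix` or plain miRNA x sample value
#'   matrix.
#' @param labels binary response: a 0/1 numeric vector, or a factor /
#'   character vector with exactly two levels (the second level is coded 1).
#' @return object of class `selector_input`: list with `X` (samples x
#'   features), `Y`, `Yc`, `feature_ids`, `dropped`.
#' @export
standardize <- function(normalized, labels) {
  values <- norm_values(normalized)
  stopifnot(length(labels) == ncol(values))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be coded 0/1")
    y <- as.integer(labels)
  } else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("labels must have exactly two classes")
    y <- as.integer(as.character(labels) == lv[2L])
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 2L) stop("each class needs at least two samples")

  X <- t(values)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance feature(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(list(X = X, Y = y, Yc = y - mean(y),
                 feature_ids = colnames(X), dropped = dropped),
            class = "selector_input")
}

#' Uniform grid of selector constraint levels
#'
#' The tuning parameter delta ranges over `n_points` uniformly spaced
#' cut-points on `(0, delta_max]` where `delta_max = max_j |X_j' Yc|`, the
#' level at which the selector solution degenerates to exactly zero:
#' `delta_i = i * delta_max / n_points`.
#'
#' @param input a `selector_input`.
#' @param n_points number of grid points (default 15).
#' @return increasing numeric vector with attribute `delta_max`.
#' @export
delta_grid <- function(input, n_points = 15L) {
  stopifnot(n_points >= 1L)
  dmax <- max(abs(drop(crossprod(input$X, input$Yc))))
  if (dmax == 0) stop("response is orthogonal to every feature")
  structure(seq_len(n_points) * dmax / n_points, delta_max = dmax)
}

#' Selector solution path and shrink-to-zero ranking
#'
#' Solves the Dantzig selector at every grid delta and ranks features by
#' their shrink-to-zero order: the largest grid delta at which a feature's
#' coefficient is still active (`|beta| > tol`). The last feature to shrink
#' to zero is the most important. Ties are broken by the coefficient
#' magnitude at the tied delta, then by the marginal score `|X_j' Yc|`.
#'
#' @param input a `selector_input`.
#' @param grid increasing vector of deltas, as from [delta_grid()].
#' @param tol active-set tolerance on standardized coefficients.
#' @return object of class `selector_path`: list with `delta_grid`,
#'   `delta_max`, `coefs` (feature x delta), `shrink_delta` (NA = never
#'   active), `ranking` (feature ids, most important first), `support_size`.
#' @export
solution_path <- function(input, grid, tol = 1e-8) {
  stopifnot(all(diff(grid) > 0) || length(grid) == 1L)
  p <- ncol(input$X)
  coefs <- matrix(0, p, length(grid),
                  dimnames = list(input$feature_ids, signif(grid, 6)))
  for (i in seq_along(grid)) {
    coefs[, i] <- dantzig_solve(input, grid[i])
  }
  active <- active_mask(coefs, tol)
  shrink_idx <- apply(active, 1, function(a) if (any(a)) max(which(a)) else NA_integer_)
  shrink_delta <- ifelse(is.na(shrink_idx), NA_real_, grid[shrink_idx])

  score <- abs(drop(crossprod(input$X, input$Yc)))
  act <- which(!is.na(shrink_idx))
  coef_at_shrink <- rep(NA_real_, p)
  coef_at_shrink[act] <- abs(coefs[cbind(act, shrink_idx[act])])
  ord <- act[order(-shrink_idx[act], -coef_at_shrink[act], -score[act])]

  structure(list(delta_grid = grid,
                 delta_max = attr(grid, "delta_max") %||% max(grid),
                 coefs = coefs,
                 shrink_delta = shrink_delta,
                 ranking = input$feature_ids[ord],
                 support_size = colSums(active)),
            class = "selector_path")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Active-set classification. On degenerate optimal faces an interior-point
# solver returns the analytic center, smearing tiny mass (orders of
# magnitude below the genuine coefficients) over inactive features; a
# feature therefore counts as active only when its coefficient clears both
# the absolute tolerance and a small fraction of the column's largest
# coefficient.
active_mask <- function(coefs, tol = 1e-8, rel = 1e-3) {
  if (is.matrix(coefs)) {
    cut <- pmax(tol, rel * apply(abs(coefs), 2, max))
    sweep(abs(coefs), 2, cut, ">")
  } else {
    abs(coefs) > max(tol, rel * max(abs(coefs)))
  }
}

stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k) stop("k exceeds the size of the smallest class")
  fold <- integer(length(y))
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated tuning of the selector constraint level
#'
#' Stratified k-fold cross-validation over the delta grid: for each fold and
#' each delta the selector is run on the training rows (response recentered
#' within the fold), a ridge-stabilized logistic regression on the selected
#' features scores the held-out rows, and the per-delta test AUCs are
#' averaged. If no feature is selected the fold contributes AUC 0.5. The
#' best delta maximizes the mean AUC, ties resolved toward the larger delta
#' (stronger shrinkage).
#'
#' @param input a `selector_input`.
#' @param grid delta grid from [delta_grid()].
#' @param k number of folds.
#' @param seed integer seed controlling the fold assignment.
#' @param tol active-set tolerance.
#' @param ridge ridge stabilizer for the within-fold logistic fits.
#' @return object of class `cv_tuning`: list with `fold_assignments`,
#'   `auc` (delta x fold), `mean_auc`, `best_delta`.
#' @export
cv_tune <- function(input, grid, k = 5L, seed = 1L, tol = 1e-8,
                    ridge = 1e-6) {
  fold <- stratified_folds(input$Y, k, seed)
  auc_mat <- matrix(NA_real_, length(grid), k,
                    dimnames = list(signif(grid, 6), paste0("fold", 1:k)))
  for (fd in seq_len(k)) {
    tr <- fold != fd
    Xtr <- input$X[tr, , drop = FALSE]
    ytr <- input$Y[tr]
    sub <- list(X = Xtr, Yc = ytr - mean(ytr))
    for (i in seq_along(grid)) {
      beta <- dantzig_solve(sub, grid[i])
      sel <- which(active_mask(beta, tol))
      if (!length(sel)) {
        auc_mat[i, fd] <- 0.5
        next
      }
      fit <- fit_logistic(Xtr[, sel, drop = FALSE], ytr, ridge = ridge)
      scores <- drop(cbind(1, input$X[!tr, sel, drop = FALSE]) %*%
                       fit$coefficients)
      auc_mat[i, fd] <- auc_mw(scores, input$Y[!tr])
    }
  }
  mean_auc <- rowMeans(auc_mat)
  best <- max(which(mean_auc == max(mean_auc)))   # ties -> larger delta
  structure(list(fold_assignments = fold, auc = auc_mat,
                 mean_auc = mean_auc, best_delta = grid[best],
                 best_index = best),
            class = "cv_tuning")
}

#' Final candidate selection and ranking on the full data
#'
#' Recomputes the solution path on the full data over the grid points at and
#' above the cross-validated best delta, takes the features active at the
#' best delta as candidates ordered by shrink-to-zero rank, and fits a final
#' logistic regression on them.
#'
#' @param input a `selector_input`.
#' @param best_delta tuned constraint level, a grid point.
#' @param grid the full delta grid.
#' @param tol active-set tolerance.
#' @param ridge ridge stabilizer for the final logistic fit (0 = plain ML,
#'   falling back to a tiny ridge under perfect separation).
#' @return list with `candidates` (ranked ids, most important first),
#'   `path` (restricted `selector_path`), `model` (final logistic fit or
#'   NULL when no candidate survives).
#' @export
final_selection <- function(input, best_delta, grid, tol = 1e-8,
                            ridge = 0) {
  upper <- grid[grid >= best_delta - 1e-12]
  path <- solution_path(input, structure(upper, delta_max = attr(grid, "delta_max")), tol = tol)
  at_best <- active_mask(path$coefs[, 1], tol)
  candidates <- path$ranking[path$ranking %in% input$feature_ids[at_best]]
  if (!length(candidates)) {
    warning("no candidate active at the tuned delta")
    return(list(candidates = character(0), path = path, model = NULL))
  }
  Xc <- input$X[, candidates, drop = FALSE]
  model <- tryCatch(fit_logistic(Xc, input$Y, ridge = ridge),
                    error = function(e) fit_logistic(Xc, input$Y, ridge = 1e-6))
  list(candidates = candidates, path = path, model = model)
}
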