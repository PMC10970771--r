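#' Dementia indicator from the MoCA total score
#'
#' Dementia in Parkinson's disease is defined by a total Montreal Cognitive
#' Assessment score of 21 or less; mild cognitive impairment spans 22-25 and
#' normal cognition 26-30.
#'
#' @param moca_total numeric MoCA total score(s) on the 0-30 scale.
#' @return integer vector, 1 = dementia (MoCA <= 21), 0 otherwise.
#' @export
dementia_label <- function(moca_total) {
  if (any(is.na(moca_total)) || any(moca_total < 0 | moca_total > 30)) {
    stop("MoCA total scores must lie in [0, 30]")
  }
  as.integer(moca_total <= 21)
}

#' Maximum-likelihood logistic regression
#'
#' Fits a binomial GLM with intercept by iteratively reweighted least
#' squares. With `ridge = 0` the fit is delegated to [stats::glm()]
#' (convergence tolerance 1e-10, up to 100 iterations) and perfect
#' separation raises an error; with `ridge > 0` a ridge-penalized IRLS is
#' used (penalty excluded from the intercept) so that separated small folds
#' still yield finite coefficients. The reported log-likelihood and AIC are
#' always the unpenalized ones, with `AIC = 2 * n_params - 2 * logL`.
#'
#' @param X predictor matrix or data frame (no intercept column).
#' @param y binary 0/1 response.
#' @param ridge non-negative L2 penalty on the non-intercept coefficients.
#' @return object of class `model_spec`: list with `coefficients` (named,
#'   intercept first), `logL`, `AIC`, `n_params`, `converged`, `predictors`.
#' @export
fit_logistic <- function(X, y, ridge = 0) {
  if (is.null(X)) X <- matrix(numeric(0), length(y), 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (ncol(X) && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (ncol(X)) {
    const <- apply(X, 2, function(v) stats::sd(v) == 0)
    if (any(const)) stop("constant predictor(s): ",
                         paste(colnames(X)[const], collapse = ", "))
  }

  if (ridge == 0) {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                     family = stats::binomial(),
                     control = list(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    cf <- fit$coefficients
    if (sep_warn && max(abs(cf)) > 12) {
      stop("perfect separation detected; refit with ridge > 0")
    }
    if (!fit$converged) stop("logistic fit did not converge")
  } else {
    Z <- cbind(`(Intercept)` = 1, X)
    pvec <- c(0, rep(ridge, ncol(X)))
    cf <- numeric(ncol(Z))
    for (it in 1:100) {
      eta <- drop(Z %*% cf)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(Z, Z * w) + diag(pvec, ncol(Z))
      g <- drop(crossprod(Z, y - mu)) - pvec * cf
      step <- solve(H, g)
      cf <- cf + step
      if (max(abs(step)) < 1e-8) break
    }
    names(cf) <- colnames(Z)
  }
  eta <- drop(cbind(1, X) %*% cf)
  logL <- sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))  # overflow-safe
  k <- length(cf)
  structure(list(coefficients = cf, logL = logL, AIC = 2 * k - 2 * logL,
                 n_params = k, converged = TRUE, predictors = colnames(X),
                 ridge = ridge),
            class = "model_spec")
}

#' @export
predict.model_spec <- function(object, newdata, type = c("link", "response"),
                               ...) {
  type <- match.arg(type)
  Z <- cbind(1, as.matrix(as.data.frame(newdata)[, object$predictors,
                                                 drop = FALSE]))
  eta <- drop(Z %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' Exhaustive smallest-AIC model reduction
#'
#' Fits a logistic regression for every non-empty subset of the candidate
#' predictors and returns the model with the smallest AIC. Ties are resolved
#' toward fewer predictors, then lexicographically. Subsets whose fit fails
#' (e.g. perfect separation) are skipped and recorded.
#'
#' @param X predictor matrix or data frame holding all candidates.
#' @param y binary 0/1 response.
#' @param candidates character vector of candidate columns (default: all).
#' @param ridge passed to [fit_logistic()].
#' @return the winning `model_spec`, with attributes `aic_table` (one row
#'   per subset) and `skipped` (failed subsets).
#' @export
reduce_by_aic <- function(X, y, candidates = colnames(as.data.frame(X)),
                          ridge = 0) {
  X <- as.data.frame(X)
  stopifnot(length(candidates) >= 1L, length(candidates) <= 20L,
            all(candidates %in% colnames(X)))
  subsets <- unlist(lapply(seq_along(candidates), function(m) {
    utils::combn(candidates, m, simplify = FALSE)
  }), recursive = FALSE)
  rows <- list(); fits <- list(); skipped <- character(0)
  for (i in seq_along(subsets)) {
    vars <- subsets[[i]]
    key <- paste(vars, collapse = "+")
    fit <- tryCatch(fit_logistic(X[, vars, drop = FALSE], y, ridge = ridge),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, key)
      next
    }
    fits[[key]] <- fit
    rows[[key]] <- data.frame(subset = key, size = length(vars),
                              AIC = fit$AIC, logL = fit$logL)
  }
  if (!length(fits)) stop("every candidate subset failed to fit")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(tab$AIC, tab$size, tab$subset)
  best <- fits[[tab$subset[ord[1]]]]
  attr(best, "aic_table") <- tab[ord, ]
  attr(best, "skipped") <- skipped
  best
}

#' Stratified train/test split
#'
#' Splits subjects into a training and a test side, stratified by the binary
#' response so both sides keep the class mix; deterministic under `seed`.
#'
#' @param y binary response vector.
#' @param train_frac fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  train <- integer(0)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    train <- c(train, idx[seq_len(round(train_frac * length(idx)))])
  }
  train <- sort(train)
  test <- setdiff(seq_along(y), train)
  for (side in list(y[train], y[test])) {
    if (length(unique(side)) < 2L || min(table(side)) < 2L) {
      stop("each split side needs at least two subjects of each class")
    }
  }
  list(train = train, test = test)
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a random case outscores a random control, ties counted
#' one half.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.numeric(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with the maximal sensitivity + specificity operating point
#'
#' The AUC is the Mann-Whitney statistic (ties count 1/2). The operating
#' threshold is chosen over all finite cut-points (each observed score,
#' classification rule `score >= threshold` = positive, plus the
#' all-negative cut above the maximum) to maximize sensitivity +
#' specificity; ties are resolved toward higher specificity, then toward
#' the higher threshold.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels (1 = case).
#' @return object of class `roc_result`: list with `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cuts <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(cuts, function(th) mean(pos >= th), 1)
  spec <- vapply(cuts, function(th) mean(neg < th), 1)
  j <- sens + spec
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.max(cuts[best])]
  th <- cuts[best]
  acc <- (sum(pos >= th) + sum(neg < th)) / length(scores)
  structure(list(auc = auc_mw(scores, labels), threshold = th,
                 sensitivity = sens[best], specificity = spec[best],
                 accuracy = acc),
            class = "roc_result")
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples cases and controls separately with replacement (so every
#' resample keeps both classes), evaluates `metric_fn(scores, labels)` on
#' each, and returns the percentile interval.
#'
#' @param metric_fn function of `(scores, labels)` returning one number.
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `level`, `B`, `replicates`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 2000L, level = 0.95,
                         seed = 1L) {
  stopifnot(B >= 100L, level > 0, level < 1)
  labels <- as.numeric(labels)
  ip <- which(labels == 1)
  io <- which(labels == 0)
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  reps <- vapply(seq_len(B), function(i) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(io, length(io), replace = TRUE))
    metric_fn(scores[idx], labels[idx])
  }, 1)
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, B = B, replicates = reps)
}

default_variable_sets <- function() {
  list(
    "ratio"                 = "ratio",
    "age"                   = "age",
    "updrs3"                = "updrs3",
    "ratio + age"           = c("ratio", "age"),
    "ratio + updrs3"        = c("ratio", "updrs3"),
    "age + updrs3"          = c("age", "updrs3"),
    "ratio + age + updrs3"  = c("ratio", "age", "updrs3")
  )
}

#' Out-of-sample ROC comparison of logistic variable sets
#'
#' For each variable set, a logistic regression is trained on the stratified
#' 70% side and its ROC (AUC, and sensitivity/specificity/accuracy at the
#' maximal sens + spec operating point) is evaluated on the held-out 30%,
#' with stratified percentile bootstrap confidence intervals.
#'
#' @param cohort data frame with the response column `dementia` (0/1) and
#'   every predictor named by the variable sets (e.g. `ratio`, `age`,
#'   `updrs3`).
#' @param variable_sets named list of character vectors; default: the seven
#'   combinations of ratio, age and UPDRS III.
#' @param seed integer seed (controls split and bootstrap).
#' @param train_frac training fraction.
#' @param B bootstrap replicates.
#' @return data frame, one row per variable set, with point estimates and
#'   95% CIs; attribute `split` records the partition.
#' @export
model_comparison_table <- function(cohort,
                                   variable_sets = default_variable_sets(),
                                   seed = 1L, train_frac = 0.7, B = 2000L) {
  stopifnot("dementia" %in% colnames(cohort))
  y <- cohort$dementia
  sp <- split_train_test(y, train_frac, seed = derive_seed(seed, "split"))
  rows <- lapply(seq_along(variable_sets), function(i) {
    vars <- variable_sets[[i]]
    fit <- fit_logistic(cohort[sp$train, vars, drop = FALSE], y[sp$train])
    scores <- predict(fit, cohort[sp$test, , drop = FALSE])
    roc <- roc_analysis(scores, y[sp$test])
    ci_of <- function(fn, stage) {
      bootstrap_ci(fn, scores, y[sp$test], B = B,
                   seed = derive_seed(seed, paste0(stage, i)))
    }
    ci_auc <- ci_of(auc_mw, "auc")
    ci_sen <- ci_of(function(s, l) roc_analysis(s, l)$sensitivity, "sens")
    ci_spe <- ci_of(function(s, l) roc_analysis(s, l)$specificity, "spec")
    ci_acc <- ci_of(function(s, l) roc_analysis(s, l)$accuracy, "acc")
    data.frame(
      variables = names(variable_sets)[i],
      auc = roc$auc, auc_lo = ci_auc$lower, auc_hi = ci_auc$upper,
      specificity = roc$specificity, spec_lo = ci_spe$lower, spec_hi = ci_spe$upper,
      sensitivity = roc$sensitivity, sens_lo = ci_sen$lower, sens_hi = ci_sen$upper,
      accuracy = roc$accuracy, acc_lo = ci_acc$lower, acc_hi = ci_acc$upper
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "split") <- sp
  out
}
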