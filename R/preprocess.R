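#' Replace missing count entries by zero
#'
#' Missing entries in a raw count matrix (entries the sequencing pipeline
#' reported as absent rather than as an observed zero) are approximated as
#' zero counts before normalization; nothing else is changed.
#'
#' @param counts miRNA x sample matrix of non-negative counts, `NA` = missing.
#' @return the same matrix with every `NA` replaced by 0.
#' @export
impute_missing <- function(counts) {
  stopifnot(is.matrix(counts))
  if (anyNA(counts)) {
    counts[is.na(counts)] <- if (is.integer(counts)) 0L else 0
  }
  counts
}

#' TMM normalization factors
#'
#' Per-sample scaling factors from the weighted trimmed mean of per-miRNA
#' log2 expression ratios (M-values) against a reference sample, the
#' trimmed-mean-of-M-values (TMM) method of Robinson & Oshlack. The
#' computation is delegated to [edgeR::calcNormFactors()] with its canonical
#' trim fractions (30% of M-values, 5% of A-values) and precision weights
#' equal to the inverse asymptotic variance of M; the reference sample is
#' the one whose upper quartile (of counts-per-million) is closest to the
#' mean upper quartile. Factors are rescaled to geometric mean 1.
#'
#' @param counts miRNA x sample matrix of non-negative counts (no missing).
#' @param reference_sample optional column index or name of the reference.
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, reference_sample = NULL) {
  stopifnot(is.matrix(counts), !anyNA(counts))
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  if (is.character(reference_sample)) {
    reference_sample <- match(reference_sample, colnames(counts))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              refColumn = reference_sample)
  names(f) <- colnames(counts)
  f
}

#' TMM-normalized log2 expression
#'
#' Converts counts to log2 counts-per-million on the TMM-effective library,
#' with a +1 pseudocount:
#' `value(g, s) = log2(count(g, s) / (libsize_s * f_s) * 1e6 + 1)`.
#'
#' @param counts miRNA x sample count matrix (no missing entries).
#' @param factors per-sample positive TMM factors, as from [tmm_factors()].
#' @return object of class `normalized_matrix`: a list with `values`
#'   (log2 matrix), `tmm_factors` and `lib_sizes`.
#' @export
normalize_log2 <- function(counts, factors) {
  stopifnot(is.matrix(counts), length(factors) == ncol(counts),
            all(factors > 0))
  lib <- colSums(counts)
  eff <- lib * factors
  values <- log2(sweep(counts, 2, eff, "/") * 1e6 + 1)
  structure(list(values = values, tmm_factors = factors, lib_sizes = lib),
            class = "normalized_matrix")
}

norm_values <- function(x) {
  if (inherits(x, "normalized_matrix")) x$values else x
}

#' Trim the lowest expressed miRNAs per batch
#'
#' Within each batch, miRNAs are ranked by their mean normalized log2 value
#' and the bottom fraction `q` forms that batch's low-expression set; the
#' union of the per-batch sets is removed from the matrix.
#'
#' @param normalized a `normalized_matrix` or a plain log2 value matrix.
#' @param batches per-sample batch labels (length = number of samples).
#' @param q fraction trimmed per batch, in `[0, 1)`.
#' @return the input with trimmed rows removed; attribute `trimmed` lists
#'   the removed miRNA ids (per batch and union).
#' @export
trim_low_expressed <- function(normalized, batches, q = 0.10) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q >= 1) {
    stop("q must be a single fraction in [0, 1)")
  }
  values <- norm_values(normalized)
  stopifnot(length(batches) == ncol(values))
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  n_cut <- floor(q * nrow(values))
  per_batch <- lapply(split(seq_along(batches), batches), function(cols) {
    m <- rowMeans(values[, cols, drop = FALSE])
    if (n_cut == 0) character(0) else ids[order(m)[seq_len(n_cut)]]
  })
  drop_ids <- unique(unlist(per_batch, use.names = FALSE))
  keep <- !(ids %in% drop_ids)
  out <- if (inherits(normalized, "normalized_matrix")) {
    normalized$values <- values[keep, , drop = FALSE]
    normalized
  } else {
    values[keep, , drop = FALSE]
  }
  attr(out, "trimmed") <- list(per_batch = per_batch, union = drop_ids)
  out
}

#' Remove per-batch location shifts
#'
#' For every miRNA, each batch's values are mean-centered and then shifted
#' back to the pooled per-miRNA mean, removing a location-only batch effect
#' while leaving the pooled mean unchanged. Batches with a single sample
#' are passed through unadjusted with a warning.
#'
#' @param normalized a `normalized_matrix` or a plain log2 value matrix.
#' @param batches per-sample batch labels.
#' @return input with adjusted values.
#' @export
batch_adjust <- function(normalized, batches) {
  values <- norm_values(normalized)
  stopifnot(length(batches) == ncol(values))
  idx <- split(seq_along(batches), batches)
  if (length(idx) > 1L) {
    singles <- names(idx)[vapply(idx, length, 1L) == 1L]
    if (length(singles)) {
      warning("batch(es) with a single sample left unadjusted: ",
              paste(singles, collapse = ", "))
    }
    pooled <- rowMeans(values)
    for (cols in idx) {
      if (length(cols) < 2L) next
      bm <- rowMeans(values[, cols, drop = FALSE])
      values[, cols] <- values[, cols, drop = FALSE] - bm + pooled
    }
  }
  if (inherits(normalized, "normalized_matrix")) {
    normalized$values <- values
    normalized
  } else {
    values
  }
}

#' Group fold change on the linear scale
#'
#' The per-miRNA log2 fold change between two groups, computed as the log2
#' ratio of linear-scale group means: the normalized log2 values are mapped
#' back to counts-per-million (`2^value - 1`), averaged within each group,
#' and the case/control ratio is taken on the log2 scale. A zero control
#' mean yields `NA` for that miRNA.
#'
#' @param normalized a `normalized_matrix` or a plain log2 value matrix.
#' @param groups per-sample group labels.
#' @param case_label,control_label the two groups compared (case over
#'   control, i.e. positive values mean higher in `case_label`).
#' @return named numeric vector of log2 fold changes.
#' @export
fold_change <- function(normalized, groups, case_label, control_label) {
  values <- norm_values(normalized)
  stopifnot(length(groups) == ncol(values))
  ci <- which(groups == case_label)
  ki <- which(groups == control_label)
  if (!length(ci) || !length(ki)) stop("both groups must be non-empty")
  linear <- 2^values - 1
  mc <- rowMeans(linear[, ci, drop = FALSE])
  mk <- rowMeans(linear[, ki, drop = FALSE])
  out <- ifelse(mk > 0, log2(mc / mk), NA_real_)
  names(out) <- rownames(values)
  out
}
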