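#' Kruskal-Wallis omnibus test
#'
#' Nonparametric one-way comparison of two or more groups based on
#' mid-ranks, with the standard tie correction and a chi-square
#' approximation on `groups - 1` degrees of freedom (as implemented by
#' [stats::kruskal.test()]).
#'
#' @param values numeric observations.
#' @param groups group labels (same length).
#' @return list with `H` (tie-corrected statistic), `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (all(values == values[1])) {
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' All pairwise group comparisons on the joint mid-ranks following a
#' Kruskal-Wallis test:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal
#' p-values, and a multiply-by-m (Bonferroni-style) adjustment capped at 1;
#' adjusted values at or above 0.9999 are displayed as "> 0.9999" in the
#' `label` column, matching the reporting convention of common GUI
#' statistics software. Holm's step-down adjustment is available.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return data frame with `group1`, `group2`, `mean_rank_diff`, `z`, `p`,
#'   `p_adj`, `label`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  tie <- table(values)
  Ttie <- sum(tie^3 - tie) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - Ttie) * (1 / n[[i]] + 1 / n[[j]]))
    diff <- rb[[i]] - rb[[j]]
    z <- if (se > 0) diff / se else 0
    data.frame(group1 = i, group2 = j, mean_rank_diff = diff, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bonferroni") {
    pmin(1, length(pairs) * out$p)
  } else {
    stats::p.adjust(out$p, method = "holm")
  }
  out$label <- ifelse(out$p_adj >= 0.9999, "> 0.9999",
                      formatC(out$p_adj, digits = 4, format = "f"))
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Tie-aware Spearman correlation: the Pearson correlation of mid-ranks,
#' with a two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (`|r| = 1` gives p = 0). Incomplete pairs are
#' dropped; zero variance in either vector yields `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Correlation of the miRNA ratio with MoCA total and domain scores
#'
#' One Spearman correlation per cognitive score (MoCA total plus the seven
#' domains: visuospatial, naming, attention, language, abstraction, memory,
#' orientation) against the target/reference miRNA ratio, computed within
#' the Parkinson's disease patients (healthy controls excluded). No
#' multiplicity adjustment is applied, matching the tabular presentation
#' convention for this analysis.
#'
#' @param cohort data frame with columns `group`, `ratio`, `moca_total` and
#'   `moca_<domain>` for the seven domains.
#' @param hc_label label of the healthy-control group to exclude.
#' @return data frame with `domain`, `spearman_r`, `p_value`, `n`.
#' @export
domain_correlation_table <- function(cohort, hc_label = "HC") {
  pd <- cohort[cohort$group != hc_label, , drop = FALSE]
  if (!nrow(pd)) stop("no PD patients in the cohort")
  doms <- c("total", "visuospatial", "naming", "attention", "language",
            "abstraction", "memory", "orientation")
  cols <- c("moca_total", paste0("moca_", doms[-1]))
  stopifnot(all(cols %in% colnames(pd)), "ratio" %in% colnames(pd))
  rows <- lapply(seq_along(doms), function(i) {
    sp <- spearman_cor(pd$ratio, pd[[cols[i]]])
    data.frame(domain = doms[i], spearman_r = sp$r, p_value = sp$p_value,
               n = sp$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
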