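#' Poisson concentration estimate from droplet counts
#'
#' In droplet digital PCR the sample is partitioned into droplets of volume
#' `V_d`; template molecules land in droplets as a Poisson process, so the
#' undiluted concentration is recovered from the positive-droplet fraction:
#' `c = -ln(1 - k/N) / V_d * D`, with `D` the dilution factor applied before
#' partitioning. Saturated wells (`k = N`) carry no finite estimate and
#' raise an error.
#'
#' @param positive number of positive droplets `k` (vectorized).
#' @param total total accepted droplets `N`.
#' @param dilution dilution factor `D >= 1`.
#' @param droplet_volume droplet volume in microliters (default 0.85 nL).
#' @return concentration in copies per microliter of the undiluted sample.
#' @examples
#' concentration(5000, 10000)  # ln(2) / 0.00085 ~ 815.47 copies/uL
#' @export
concentration <- function(positive, total, dilution = 1,
                          droplet_volume = 0.85e-3) {
  stopifnot(all(total >= 1), all(dilution >= 1), all(droplet_volume > 0))
  if (any(positive < 0 | positive > total)) {
    stop("positive droplets must satisfy 0 <= k <= N")
  }
  if (any(positive == total)) stop("saturated well (k = N)")
  -log(1 - positive / total) / droplet_volume * dilution
}

#' Quality control of ddPCR wells
#'
#' A well passes when the accepted droplet count exceeds `min_droplets`
#' (10,000 by convention) and the positive droplet count exceeds
#' `min_positives` (3). Failing wells are flagged, never dropped. The
#' thresholds are applied to droplet counts by default; `unit =
#' "concentration"` instead applies them to the diluted concentration in
#' copies/uL.
#'
#' @param wells data frame with columns `total_droplets`,
#'   `positive_droplets`, and (for the concentration unit) `dilution`.
#' @param min_droplets,min_positives QC thresholds.
#' @param unit `"counts"` (default) or `"concentration"`.
#' @param droplet_volume droplet volume in microliters.
#' @return the input with logical `qc_pass` and character `qc_flags`
#'   columns added.
#' @export
qc_pass <- function(wells, min_droplets = 10000, min_positives = 3,
                    unit = c("counts", "concentration"),
                    droplet_volume = 0.85e-3) {
  unit <- match.arg(unit)
  N <- wells$total_droplets
  k <- wells$positive_droplets
  if (unit == "counts") {
    low_d <- !(N > min_droplets)
    low_p <- !(k > min_positives)
  } else {
    conc_diluted <- ifelse(k < N, -log(1 - k / N) / droplet_volume, Inf)
    low_d <- !(N > min_droplets)          # droplet floor stays a count
    low_p <- !(conc_diluted > min_positives)
  }
  flags <- character(nrow(wells))
  flags[low_d] <- "low_droplets"
  flags[low_p] <- trimws(paste(flags[low_p], "low_positives"))
  wells$qc_pass <- !(low_d | low_p)
  wells$qc_flags <- flags
  wells
}

#' Target/reference miRNA ratio per sample
#'
#' For each sample, the undiluted (back-diluted) concentration of the
#' target assay is divided by that of the reference assay, using exactly
#' one QC-passing well per assay. Samples missing a passing well for either
#' assay, or with a zero reference concentration, are excluded with a
#' recorded reason.
#'
#' @param wells data frame with columns `sample_id`, `assay`, `dilution`,
#'   `total_droplets`, `positive_droplets` (QC columns added if absent).
#' @param target,reference assay names.
#' @param droplet_volume droplet volume in microliters.
#' @param ... passed to [qc_pass()].
#' @return data frame (class `ratio_table`) with one row per retained
#'   sample: `sample_id`, `conc_target`, `conc_reference`, `ratio`,
#'   `qc_flags`; attribute `excluded` maps dropped samples to reasons.
#' @export
sample_ratios <- function(wells, target = "miR-203a-3p",
                          reference = "miR-16-5p",
                          droplet_volume = 0.85e-3, ...) {
  if (is.null(wells$qc_pass)) wells <- qc_pass(wells, ...)
  sids <- unique(wells$sample_id)
  pick <- function(assay) {
    w <- wells[wells$assay == assay & wells$qc_pass, , drop = FALSE]
    w <- w[!duplicated(w$sample_id), , drop = FALSE]  # one well per assay
    w[match(sids, w$sample_id), , drop = FALSE]
  }
  wt <- pick(target)
  wr <- pick(reference)
  excluded <- character(0)
  miss_t <- is.na(wt$sample_id)
  miss_r <- is.na(wr$sample_id)
  excluded[sids[miss_t]] <- paste0("no QC-passing well for ", target)
  excluded[sids[miss_r & !miss_t]] <- paste0("no QC-passing well for ",
                                             reference)
  keep <- !(miss_t | miss_r)
  ct <- cr <- rep(NA_real_, length(sids))
  if (any(keep)) {
    ct[keep] <- concentration(wt$positive_droplets[keep],
                              wt$total_droplets[keep],
                              wt$dilution[keep], droplet_volume)
    cr[keep] <- concentration(wr$positive_droplets[keep],
                              wr$total_droplets[keep],
                              wr$dilution[keep], droplet_volume)
  }
  zero_ref <- keep & cr == 0
  excluded[sids[zero_ref]] <- "zero reference concentration"
  keep <- keep & !zero_ref
  flags <- trimws(paste(wt$qc_flags, wr$qc_flags))
  out <- data.frame(sample_id = sids[keep], conc_target = ct[keep],
                    conc_reference = cr[keep],
                    ratio = ct[keep] / cr[keep],
                    qc_flags = flags[keep])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Extraction-efficiency robustness check
#'
#' The reference miRNA over the exogenous spike-in (miR-16-5p / UniSp6)
#' should not differ between study groups if RNA extraction efficiency is
#' uniform; a Kruskal-Wallis test across groups flags `p < alpha` as an
#' extraction-robustness warning.
#'
#' @param wells ddPCR well table (see [sample_ratios()]).
#' @param groups named vector mapping `sample_id` to group label.
#' @param reference,spike_in assay names.
#' @param alpha warning level.
#' @param ... passed to [sample_ratios()].
#' @return list with `ratios` (per-sample reference/spike-in table), `H`,
#'   `p_value`, `warning` (logical).
#' @export
extraction_check <- function(wells, groups, reference = "miR-16-5p",
                             spike_in = "UniSp6", alpha = 0.05, ...) {
  tab <- sample_ratios(wells, target = reference, reference = spike_in, ...)
  g <- groups[tab$sample_id]
  kw <- kruskal_wallis(tab$ratio, g)
  list(ratios = tab, H = kw$H, p_value = kw$p_value,
       warning = is.finite(kw$p_value) && kw$p_value < alpha)
}

#' IQR outlier rule within groups
#'
#' Flags, within each group, values above `Q3 + 1.5 IQR` or below
#' `Q1 - 1.5 IQR`, with quartiles from linear-interpolation quantiles
#' (R type 7). Flagged values are meant to be excluded from downstream
#' statistics but retained in records.
#'
#' @param values numeric vector.
#' @param groups group labels (same length); a single group is allowed via
#'   a constant label.
#' @param k fence multiplier (1.5).
#' @return logical vector, `TRUE` = outlier.
#' @export
iqr_outliers <- function(values, groups = rep("all", length(values)),
                         k = 1.5) {
  stopifnot(length(values) == length(groups))
  out <- logical(length(values))
  for (idx in split(seq_along(values), groups)) {
    v <- values[idx]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
    iqr <- q[2] - q[1]
    out[idx] <- !is.na(v) & (v > q[2] + k * iqr | v < q[1] - k * iqr)
  }
  out
}
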