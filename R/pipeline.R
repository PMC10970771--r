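#' Run the discovery phase end to end
#'
#' Missing-value imputation, TMM normalization, log2 CPM transform,
#' per-batch low-expression trimming, batch location adjustment,
#' standardization on the contrast samples, delta-grid construction,
#' cross-validated tuning of the Dantzig-type selector and final
#' shrink-to-zero candidate ranking, followed by per-candidate group fold
#' changes and Kruskal-Wallis/Dunn comparisons across all study groups.
#'
#' @param counts miRNA x sample count matrix (`NA` = missing).
#' @param samples data frame with `sample_id`, `group`, `batch` matching
#'   the count matrix columns.
#' @param contrast length-2 character vector `(control, case)` defining the
#'   selection contrast (default PDND vs PD-MCI).
#' @param q_trim per-batch low-expression trim fraction.
#' @param grid_points number of delta grid points.
#' @param k cross-validation folds.
#' @param seed integer seed (fanned out to stages via [derive_seed()]).
#' @param ridge ridge stabilizer for within-CV logistic fits.
#' @return list (class `discovery_report`) with `normalized`, `trimmed`,
#'   `grid`, `cv`, `selection`, `candidates`, `fold_changes`,
#'   `group_tests`.
#' @export
run_discovery <- function(counts, samples, contrast = c("PDND", "PD-MCI"),
                          q_trim = 0.10, grid_points = 15L, k = 5L,
                          seed = 1L, ridge = 1e-6) {
  stopifnot(is.matrix(counts))
  if (!all(c("sample_id", "group", "batch") %in% colnames(samples))) {
    stop("preprocess: sample sheet must have sample_id, group, batch")
  }
  if (!setequal(colnames(counts), samples$sample_id)) {
    stop("preprocess: count columns and sample sheet disagree")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]

  imputed <- impute_missing(counts)
  f <- tmm_factors(imputed)
  norm <- normalize_log2(imputed, f)
  trimmed <- trim_low_expressed(norm, samples$batch, q = q_trim)
  adjusted <- batch_adjust(trimmed, samples$batch)

  in_contrast <- samples$group %in% contrast
  if (sum(samples$group == contrast[1]) < 2 ||
      sum(samples$group == contrast[2]) < 2) {
    stop("selector: both contrast groups need >= 2 samples")
  }
  labels <- as.integer(samples$group[in_contrast] == contrast[2])
  input <- standardize(adjusted$values[, in_contrast, drop = FALSE], labels)
  grid <- delta_grid(input, n_points = grid_points)
  cv <- cv_tune(input, grid, k = k, seed = derive_seed(seed, "cv"),
                ridge = ridge)
  sel <- final_selection(input, cv$best_delta, grid)

  cand <- sel$candidates
  fc <- if (length(cand)) {
    fold_change(adjusted$values[cand, in_contrast, drop = FALSE],
                samples$group[in_contrast], contrast[2], contrast[1])
  } else numeric(0)
  group_tests <- lapply(cand, function(id) {
    v <- adjusted$values[id, ]
    list(kruskal = kruskal_wallis(v, samples$group),
         dunn = dunn_posthoc(v, samples$group))
  })
  names(group_tests) <- cand

  structure(list(normalized = norm, trimmed = attr(trimmed, "trimmed"),
                 adjusted = adjusted, grid = grid, cv = cv, selection = sel,
                 candidates = cand, fold_changes = fc,
                 group_tests = group_tests, contrast = contrast),
            class = "discovery_report")
}

#' Run the validation phase end to end
#'
#' Poisson quantification of every well, QC, the target/reference ratio per
#' sample, the extraction-efficiency check (reference / spike-in), the IQR
#' outlier rule within groups, Kruskal-Wallis with Dunn's post hoc on the
#' ratio across groups, the MoCA domain correlation table (PD patients,
#' outliers excluded), and the out-of-sample logistic model comparison.
#'
#' @param wells ddPCR well table (see [sample_ratios()]).
#' @param cohort clinical table from [generate_validation()] (or matching
#'   real data).
#' @param seed integer seed.
#' @param B bootstrap replicates for the model table.
#' @param outlier_rule apply the IQR rule (default TRUE).
#' @param target,reference assay names.
#' @return list (class `validation_report`) with `ratios`, `extraction`,
#'   `group_test`, `dunn`, `correlations`, `model_table`, `cohort`
#'   (annotated: `ratio`, `outlier`, `dementia`).
#' @export
run_validation <- function(wells, cohort, seed = 1L, B = 2000L,
                           outlier_rule = TRUE,
                           target = "miR-203a-3p", reference = "miR-16-5p") {
  ratios <- sample_ratios(wells, target = target, reference = reference)
  if (!nrow(ratios)) stop("quantify: no sample passed ddPCR quality control")
  groups <- stats::setNames(cohort$group, cohort$sample_id)
  extraction <- extraction_check(wells, groups, reference = reference)

  cohort <- merge(cohort, ratios[, c("sample_id", "ratio")], by = "sample_id",
                  sort = FALSE)
  cohort$outlier <- if (outlier_rule) {
    iqr_outliers(cohort$ratio, cohort$group)
  } else rep(FALSE, nrow(cohort))
  clean <- cohort[!cohort$outlier, , drop = FALSE]

  group_test <- kruskal_wallis(clean$ratio, clean$group)
  dunn <- dunn_posthoc(clean$ratio, clean$group)
  correlations <- domain_correlation_table(clean)

  pd <- clean[clean$group != "HC", , drop = FALSE]
  pd$dementia <- dementia_label(pd$moca_total)
  model_table <- model_comparison_table(pd, seed = derive_seed(seed, "models"),
                                        B = B)
  cohort$dementia <- ifelse(cohort$group == "HC", NA_integer_,
                            dementia_label(cohort$moca_total))
  structure(list(ratios = ratios, extraction = extraction,
                 group_test = group_test, dunn = dunn,
                 correlations = correlations, model_table = model_table,
                 cohort = cohort),
            class = "validation_report")
}
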