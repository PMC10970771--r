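#' Discovery-phase simulation design
#'
#' Parameters of the synthetic supersaturated small-RNA-seq count matrix:
#' four study groups sequenced in two batches, negative-binomial counts
#' over a heavy-tailed miRNA abundance profile, optional planted
#' group-discriminative miRNAs, a per-batch multiplicative log2 bias, and
#' missing entries recorded as absent (not zero).
#'
#' @param n_per_group named integer vector of samples per group (default
#'   40/37/23/23 for HC/PDND/PD-MCI/PDD).
#' @param p_mirnas number of miRNAs (~2600 in plasma small-RNA-seq).
#' @param batch_sizes sizes of the two sequencing runs (must sum to the
#'   total sample count).
#' @param planted list of `list(index =, pair = c(ref, shifted), log2fc =)`:
#'   the `shifted` group's mean for miRNA `index` is scaled by
#'   `2^log2fc` relative to baseline.
#' @param libsize_range span of per-sample total reads.
#' @param dispersion negative-binomial overdispersion (NB size = 1 /
#'   dispersion).
#' @param batch_log2_shift SD of the per-batch per-miRNA log2 bias.
#' @param missing_rate fraction of entries dropped to missing, in `[0, 1)`.
#' @param seed integer seed.
#' @return object of class `discovery_design`.
#' @export
discovery_design <- function(n_per_group = c(HC = 40, PDND = 37,
                                             `PD-MCI` = 23, PDD = 23),
                             p_mirnas = 2600,
                             batch_sizes = c(53, 70),
                             planted = list(),
                             libsize_range = c(8e5, 2e6),
                             dispersion = 0.3,
                             batch_log2_shift = 0.3,
                             missing_rate = 0.02,
                             seed = 1L) {
  stopifnot(all(n_per_group >= 2), length(batch_sizes) == 2L,
            sum(batch_sizes) == sum(n_per_group),
            dispersion > 0, missing_rate >= 0, missing_rate < 1,
            libsize_range[1] > 0, diff(libsize_range) >= 0)
  for (pl in planted) {
    if (pl$index > p_mirnas) stop("planted index exceeds p_mirnas")
    if (!all(pl$pair %in% names(n_per_group))) stop("unknown group in planted pair")
    if (!is.finite(pl$log2fc)) stop("planted effect must be finite")
  }
  structure(list(n_per_group = n_per_group, p_mirnas = p_mirnas,
                 batch_sizes = batch_sizes, planted = planted,
                 libsize_range = libsize_range, dispersion = dispersion,
                 batch_log2_shift = batch_log2_shift,
                 missing_rate = missing_rate, seed = seed),
            class = "discovery_design")
}

#' Generate a synthetic discovery count matrix
#'
#' Baseline miRNA abundances are drawn once from a log-normal profile
#' (heavy right tail, mimicking the dominance of a few plasma miRNAs) and
#' scaled to per-sample library sizes; counts are negative-binomial around
#' those means, with a per-batch per-miRNA multiplicative log2 bias drawn
#' once per batch (location-only batch effect) and planted log2 mean
#' shifts on the designated miRNAs. Missing entries are `NA`, not zero.
#' Fully reproducible from `design$seed`.
#'
#' @param design a [discovery_design()].
#' @return list with `counts` (miRNA x sample integer matrix with `NA`
#'   missing) and `samples` (data frame: `sample_id`, `group`, `batch`).
#' @export
generate_discovery <- function(design) {
  stopifnot(inherits(design, "discovery_design"))
  rs <- local_seed(design$seed)
  on.exit(restore_seed(rs))

  p <- design$p_mirnas
  groups <- rep(names(design$n_per_group), design$n_per_group)
  n <- length(groups)
  sample_id <- sprintf("S%03d", seq_len(n))
  batch <- character(n)
  ord <- sample(n)
  batch[ord[seq_len(design$batch_sizes[1])]] <- "batch1"
  batch[batch == ""] <- "batch2"

  base <- stats::rlnorm(p, meanlog = 0, sdlog = 2)
  prop <- base / sum(base)
  lib <- stats::runif(n, design$libsize_range[1], design$libsize_range[2])
  shift <- list(batch1 = 2^stats::rnorm(p, 0, design$batch_log2_shift),
                batch2 = 2^stats::rnorm(p, 0, design$batch_log2_shift))

  effect <- matrix(1, p, n)
  for (pl in design$planted) {
    effect[pl$index, groups == pl$pair[2]] <- 2^pl$log2fc
  }

  counts <- matrix(0L, p, n,
                   dimnames = list(sprintf("miR-%04d", seq_len(p)), sample_id))
  for (s in seq_len(n)) {
    mu <- prop * lib[s] * shift[[batch[s]]] * effect[, s]
    counts[, s] <- as.integer(stats::rnbinom(p, size = 1 / design$dispersion,
                                             mu = mu))
  }
  if (design$missing_rate > 0) {
    miss <- stats::runif(p * n) < design$missing_rate
    counts[miss] <- NA_integer_
  }
  list(counts = counts,
       samples = data.frame(sample_id = sample_id, group = groups,
                            batch = batch))
}

# Printed group parameters of the validation cohort: target/reference ratio
# mean/SD, and clinical covariates (mean +/- SD, or median +/- IQR for the
# scale scores). Order: HC, PDND, PD-MCI, PDD.
validation_defaults <- function() {
  g <- c("HC", "PDND", "PD-MCI", "PDD")
  list(
    groups = g,
    ratio_mean = stats::setNames(c(1.21e-3, 1.03e-3, 8.66e-4, 1.68e-3), g),
    ratio_sd   = stats::setNames(c(6.42e-4, 5.89e-4, 5.65e-4, 1.01e-3), g),
    age_mean   = stats::setNames(c(66.67, 69.67, 70.13, 75.20), g),
    age_sd     = stats::setNames(c(5.14, 7.03, 6.75, 6.92), g),
    male_frac  = stats::setNames(c(0.5667, 0.5667, 0.5333, 0.4667), g),
    edu_mean   = stats::setNames(c(14.13, 14.13, 11.47, 10.73), g),
    edu_sd     = stats::setNames(c(4.13, 2.79, 4.75, 4.64), g),
    onset_mean = stats::setNames(c(NA, 63.53, 64.13, 67.37), g),
    onset_sd   = stats::setNames(c(NA, 7.96, 7.96, 8.71), g),
    dur_mean   = stats::setNames(c(NA, 7.10, 6.90, 7.23), g),
    dur_sd     = stats::setNames(c(NA, 3.91, 3.07, 4.75), g),
    ledd_mean  = stats::setNames(c(NA, 682.54, 747.78, 765.82), g),
    ledd_sd    = stats::setNames(c(NA, 438.75, 398.03, 419.36), g),
    hy_median  = stats::setNames(c(NA, 2, 2, 3), g),
    hy_iqr     = stats::setNames(c(NA, 1, 1, 2), g),
    updrs_median = stats::setNames(c(NA, 13, 18.5, 27), g),
    updrs_iqr  = stats::setNames(c(NA, 12, 9, 22), g),
    moca_median = stats::setNames(c(28, 28, 23, 17.5), g),
    moca_iqr   = stats::setNames(c(2, 1.25, 1, 7), g),
    moca_band  = list(HC = c(26, 30), PDND = c(26, 30),
                      `PD-MCI` = c(22, 25), PDD = c(0, 21))
  )
}

# MoCA domain maxima (visuospatial/executive 5, naming 3, attention 6,
# language 3, abstraction 2, delayed recall 5, orientation 6; total 30).
moca_domain_max <- c(visuospatial = 5, naming = 3, attention = 6,
                     language = 3, abstraction = 2, memory = 5,
                     orientation = 6)

#' Validation-phase simulation design
#'
#' Parameters of the synthetic ddPCR validation cohort. Group ratio means
#' and SDs, covariate means/SDs and median/IQR scale scores default to the
#' published values of the validation cohort; per-subject true ratios are
#' drawn from a moment-matched lognormal per group.
#'
#' @param n_per_group subjects per group (default 30).
#' @param params list in the shape of the internal defaults; entries can be
#'   overridden selectively via `...` replacing fields of that list.
#' @param reference_conc_range copies/uL span of the undiluted reference
#'   miRNA (miR-16-5p).
#' @param droplets_per_well accepted droplets per well.
#' @param dilution_target,dilution_reference dilution factors (1:10 and
#'   1:320).
#' @param dilution_spike dilution of the spike-in assay well.
#' @param spike_conc,spike_cv undiluted spike-in (UniSp6) concentration and
#'   its lognormal coefficient of variation across extractions.
#' @param droplet_volume_ul droplet volume in microliters (0.85 nL).
#' @param seed integer seed.
#' @param ... named overrides of `params` entries.
#' @return object of class `validation_design`.
#' @export
validation_design <- function(n_per_group = 30L,
                              params = validation_defaults(),
                              reference_conc_range = c(2e4, 2e5),
                              droplets_per_well = 16000L,
                              dilution_target = 10,
                              dilution_reference = 320,
                              dilution_spike = 100,
                              spike_conc = 5e4,
                              spike_cv = 0.10,
                              droplet_volume_ul = 0.85e-3,
                              seed = 1L, ...) {
  over <- list(...)
  for (nm in names(over)) params[[nm]] <- over[[nm]]
  stopifnot(n_per_group >= 2, droplets_per_well >= 1,
            dilution_target >= 1, dilution_reference >= 1,
            droplet_volume_ul > 0,
            all(params$ratio_mean > 0), all(params$ratio_sd >= 0))
  structure(list(n_per_group = n_per_group, params = params,
                 reference_conc_range = reference_conc_range,
                 droplets_per_well = droplets_per_well,
                 dilution_target = dilution_target,
                 dilution_reference = dilution_reference,
                 dilution_spike = dilution_spike,
                 spike_conc = spike_conc, spike_cv = spike_cv,
                 droplet_volume_ul = droplet_volume_ul, seed = seed),
            class = "validation_design")
}

# Lognormal parameters matched to a target mean and SD by moments.
lognormal_moments <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Draw from a normal parameterized by median and IQR (sd = IQR / 1.349,
# the normal quartile spread), then round and clip to the legal range.
draw_median_iqr <- function(n, median, iqr, lo, hi, digits = 0) {
  v <- stats::rnorm(n, median, iqr / 1.349)
  pmin(pmax(round(v, digits), lo), hi)
}

#' Simulate one ddPCR well
#'
#' The inverse of the Poisson quantification: droplets are occupied
#' independently, so the positive count is
#' `Binomial(N, 1 - exp(-(c / D) * V_d))`.
#'
#' @param conc undiluted concentration in copies/uL (>= 0).
#' @param dilution dilution factor `D >= 1`.
#' @param n_droplets accepted droplets `N >= 1`.
#' @param droplet_volume droplet volume in microliters.
#' @param seed optional integer seed for a standalone draw.
#' @return integer count of positive droplets.
#' @export
simulate_well <- function(conc, dilution = 1, n_droplets = 16000L,
                          droplet_volume = 0.85e-3, seed = NULL) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  stopifnot(all(dilution >= 1), all(n_droplets >= 1), droplet_volume > 0)
  if (!is.null(seed)) {
    rs <- local_seed(seed)
    on.exit(restore_seed(rs))
  }
  pr <- 1 - exp(-(conc / dilution) * droplet_volume)
  stats::rbinom(length(conc), n_droplets, pr)
}

#' Generate a synthetic ddPCR validation cohort
#'
#' Per subject: a true target/reference ratio is drawn from the group's
#' moment-matched lognormal, the undiluted reference concentration from
#' `reference_conc_range`, and the target concentration as ratio x
#' reference; one well per assay is simulated with [simulate_well()] at the
#' design dilutions. Clinical covariates follow the per-group parameters;
#' MoCA totals are clipped to the group's diagnostic band and domain scores
#' are allocated by sampling the total deficit without replacement across
#' the seven domains (so domains always sum to the total). PD-specific
#' fields are `NA` for healthy controls.
#'
#' @param design a [validation_design()].
#' @return list with `wells` (data frame: `sample_id`, `assay`, `dilution`,
#'   `total_droplets`, `positive_droplets`) and `cohort` (one row per
#'   subject with group, covariates and MoCA scores; the measured ratio is
#'   added downstream by [sample_ratios()]); `truth` records the generating
#'   ratios and concentrations.
#' @export
generate_validation <- function(design) {
  stopifnot(inherits(design, "validation_design"))
  rs <- local_seed(design$seed)
  on.exit(restore_seed(rs))
  pp <- design$params
  ng <- design$n_per_group
  n <- ng * length(pp$groups)
  grp <- rep(pp$groups, each = ng)
  sid <- sprintf("V%03d", seq_len(n))

  ratio <- numeric(n); moca <- numeric(n)
  age <- numeric(n); sex <- integer(n); edu <- numeric(n)
  onset <- rep(NA_real_, n); dur <- rep(NA_real_, n)
  ledd <- rep(NA_real_, n); hy <- rep(NA_real_, n); up3 <- rep(NA_real_, n)

  for (g in pp$groups) {
    idx <- which(grp == g)
    m <- pp$ratio_mean[[g]]; s <- pp$ratio_sd[[g]]
    ratio[idx] <- if (s > 0) {
      lp <- lognormal_moments(m, s)
      stats::rlnorm(length(idx), lp$meanlog, lp$sdlog)
    } else rep(m, length(idx))
    age[idx] <- round(stats::rnorm(length(idx), pp$age_mean[[g]],
                                   pp$age_sd[[g]]))
    sex[idx] <- stats::rbinom(length(idx), 1, pp$male_frac[[g]])
    edu[idx] <- pmax(0, round(stats::rnorm(length(idx), pp$edu_mean[[g]],
                                           pp$edu_sd[[g]])))
    band <- pp$moca_band[[g]]
    moca[idx] <- draw_median_iqr(length(idx), pp$moca_median[[g]],
                                 pp$moca_iqr[[g]], band[1], band[2])
    if (g != "HC") {
      onset[idx] <- round(stats::rnorm(length(idx), pp$onset_mean[[g]],
                                       pp$onset_sd[[g]]))
      dur[idx] <- pmax(0.5, round(stats::rnorm(length(idx), pp$dur_mean[[g]],
                                               pp$dur_sd[[g]]), 1))
      ledd[idx] <- pmax(0, round(stats::rnorm(length(idx), pp$ledd_mean[[g]],
                                              pp$ledd_sd[[g]])))
      hy[idx] <- draw_median_iqr(length(idx), pp$hy_median[[g]],
                                 pp$hy_iqr[[g]], 1, 5)
      up3[idx] <- draw_median_iqr(length(idx), pp$updrs_median[[g]],
                                  pp$updrs_iqr[[g]], 0, 108)
    }
  }

  dom <- t(vapply(moca, function(tt) {
    deficit <- 30 - tt
    pool <- rep(seq_along(moca_domain_max), moca_domain_max)
    lost <- tabulate(sample(pool, deficit), nbins = 7)
    moca_domain_max - lost
  }, numeric(7)))
  colnames(dom) <- paste0("moca_", names(moca_domain_max))

  conc_ref <- stats::runif(n, design$reference_conc_range[1],
                           design$reference_conc_range[2])
  conc_tgt <- ratio * conc_ref
  lsp <- lognormal_moments(design$spike_conc,
                           design$spike_cv * design$spike_conc)
  conc_spk <- stats::rlnorm(n, lsp$meanlog, lsp$sdlog)

  mk_wells <- function(assay, conc, dilution) {
    data.frame(sample_id = sid, assay = assay, dilution = dilution,
               total_droplets = design$droplets_per_well,
               positive_droplets = simulate_well(conc, dilution,
                                                 design$droplets_per_well,
                                                 design$droplet_volume_ul))
  }
  wells <- rbind(mk_wells("miR-203a-3p", conc_tgt, design$dilution_target),
                 mk_wells("miR-16-5p", conc_ref, design$dilution_reference),
                 mk_wells("UniSp6", conc_spk, design$dilution_spike))

  cohort <- data.frame(sample_id = sid, group = grp, age = age, sex = sex,
                       education = edu, onset_age = onset, duration = dur,
                       hy = hy, updrs3 = up3, ledd = ledd,
                       moca_total = moca)
  cohort <- cbind(cohort, as.data.frame(dom))
  list(wells = wells, cohort = cohort,
       truth = data.frame(sample_id = sid, ratio = ratio,
                          conc_target = conc_tgt, conc_reference = conc_ref,
                          conc_spike = conc_spk))
}
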