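test_that("generators are deterministic under a fixed seed", {
  d <- discovery_design(n_per_group = c(HC = 5, PDND = 6, `PD-MCI` = 5,
                                        PDD = 4),
                        p_mirnas = 50, batch_sizes = c(9, 11), seed = 33)
  g1 <- generate_discovery(d)
  g2 <- generate_discovery(d)
  expect_identical(g1, g2)
  v1 <- generate_validation(small_validation(seed = 12))
  v2 <- generate_validation(small_validation(seed = 12))
  expect_identical(v1, v2)
  expect_identical(simulate_well(100, 10, 5000, seed = 2),
                   simulate_well(100, 10, 5000, seed = 2))
  # and the RNG stream of the session is left untouched
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(generate_discovery(d)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("design validation rejects inconsistent configurations", {
  expect_error(discovery_design(p_mirnas = 10,
                                planted = list(list(index = 11,
                                                    pair = c("PDND", "PDD"),
                                                    log2fc = 1)),
                                batch_sizes = c(60, 63)),
               "planted index")
  expect_error(discovery_design(batch_sizes = c(10, 10)), "batch_sizes")
  expect_error(validation_design(droplets_per_well = 0), "droplets_per_well")
  expect_error(simulate_well(-1, 1, 100), "non-negative")
})

test_that("no planted signal means centered fold changes", {
  d <- discovery_design(n_per_group = c(HC = 2, PDND = 100, `PD-MCI` = 100,
                                        PDD = 2),
                        p_mirnas = 300, batch_sizes = c(100, 104),
                        missing_rate = 0, seed = 44)
  g <- generate_discovery(d)
  f <- tmm_factors(impute_missing(g$counts))
  nm <- normalize_log2(impute_missing(g$counts), f)
  fc <- fold_change(nm, g$samples$group, "PD-MCI", "PDND")
  expect_lt(abs(median(fc, na.rm = TRUE)), 0.05)
})

test_that("a planted log2 effect is recovered by the fold-change statistic", {
  est <- vapply(1:6, function(s) {
    d <- discovery_design(n_per_group = c(HC = 2, PDND = 200,
                                          `PD-MCI` = 200, PDD = 2),
                          p_mirnas = 200, batch_sizes = c(200, 204),
                          planted = list(list(index = 7,
                                              pair = c("PDND", "PD-MCI"),
                                              log2fc = 1.0)),
                          missing_rate = 0, seed = 500 + s)
    g <- generate_discovery(d)
    f <- tmm_factors(impute_missing(g$counts))
    nm <- normalize_log2(impute_missing(g$counts), f)
    fold_change(nm, g$samples$group, "PD-MCI", "PDND")[[7]]
  }, 1)
  expect_lt(abs(mean(est) - 1.0), 0.15)
})

test_that("missingness is stored as absent, at the requested rate", {
  d <- discovery_design(n_per_group = c(HC = 10, PDND = 10, `PD-MCI` = 10,
                                        PDD = 10),
                        p_mirnas = 400, batch_sizes = c(20, 20),
                        missing_rate = 0.05, seed = 3)
  g <- generate_discovery(d)
  expect_gt(mean(is.na(g$counts)), 0.03)
  expect_lt(mean(is.na(g$counts)), 0.07)
  expect_identical(sort(unique(g$samples$batch)), c("batch1", "batch2"))
  expect_equal(unname(table(g$samples$batch)), c(20, 20), ignore_attr = TRUE)
})

test_that("validation ratios match the printed group parameters", {
  v <- generate_validation(validation_design(n_per_group = 30, seed = 77))
  rt <- sample_ratios(v$wells)
  expect_equal(nrow(rt), 120)          # all wells pass QC at these designs
  g <- setNames(v$cohort$group, v$cohort$sample_id)[rt$sample_id]
  pp <- pdmir:::validation_defaults()
  for (grp in c("HC", "PDND", "PD-MCI", "PDD")) {
    m <- mean(rt$ratio[g == grp])
    se <- pp$ratio_sd[[grp]] / sqrt(30)
    expect_lt(abs(m - pp$ratio_mean[[grp]]), 3 * se)
  }
  # degenerate SD: every recovered ratio equals the mean up to droplet noise
  v0 <- generate_validation(validation_design(
    n_per_group = 6, seed = 5,
    ratio_sd = setNames(rep(0, 4), c("HC", "PDND", "PD-MCI", "PDD"))))
  rt0 <- sample_ratios(v0$wells)
  g0 <- setNames(v0$cohort$group, v0$cohort$sample_id)[rt0$sample_id]
  for (grp in unique(g0)) {
    r <- rt0$ratio[g0 == grp]
    expect_lt(stats::sd(r) / mean(r), 0.15)
  }
})

test_that("MoCA totals respect group bands and domains sum to the total", {
  v <- generate_validation(validation_design(n_per_group = 20, seed = 9))
  co <- v$cohort
  expect_true(all(co$moca_total[co$group %in% c("HC", "PDND")] >= 26))
  expect_true(all(co$moca_total[co$group == "PD-MCI"] %in% 22:25))
  expect_true(all(co$moca_total[co$group == "PDD"] <= 21))
  dom <- as.matrix(co[, grep("^moca_", names(co))[-1]])
  expect_equal(unname(rowSums(dom)), co$moca_total)
  maxes <- c(5, 3, 6, 3, 2, 5, 6)
  expect_true(all(sweep(dom, 2, maxes, "<=")))
  expect_true(all(dom >= 0))
  # PD-specific fields are absent for controls, present for patients
  expect_true(all(is.na(co$updrs3[co$group == "HC"])))
  expect_true(all(!is.na(co$updrs3[co$group != "HC"])))
})

test_that("droplet occupancy matches the Poisson closed form", {
  # concentration chosen so the per-droplet mean is ln 2: occupancy 1/2
  conc <- log(2) / 0.85e-3
  fr <- vapply(1:50, function(s) {
    simulate_well(conc, 1, 10000, seed = s) / 10000
  }, 1)
  expect_lt(abs(mean(fr) - 0.5), 3 * 0.005 / sqrt(50))
  expect_identical(simulate_well(0, 1, 500, seed = 1), 0L)
})

test_that("generated ratios reproduce the analytic group-separation AUC", {
  pp <- pdmir:::validation_defaults()
  lp1 <- pdmir:::lognormal_moments(pp$ratio_mean[["PDD"]],
                                   pp$ratio_sd[["PDD"]])
  lp2 <- pdmir:::lognormal_moments(pp$ratio_mean[["PD-MCI"]],
                                   pp$ratio_sd[["PD-MCI"]])
  analytic <- pnorm((lp1$meanlog - lp2$meanlog) /
                      sqrt(lp1$sdlog^2 + lp2$sdlog^2))
  set.seed(606)
  r1 <- rlnorm(2000, lp1$meanlog, lp1$sdlog)
  r2 <- rlnorm(2000, lp2$meanlog, lp2$sdlog)
  emp <- auc_mw(c(r1, r2), rep(c(1, 0), each = 2000))
  expect_lt(abs(emp - analytic), 0.01)
})
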