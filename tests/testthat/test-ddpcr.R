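test_that("Poisson concentration follows the closed form", {
  expect_equal(concentration(0, 10000), 0)
  expect_equal(concentration(5000, 10000), log(2) / 0.85e-3,
               tolerance = 1e-12)
  expect_equal(concentration(5000, 10000, dilution = 10),
               10 * concentration(5000, 10000))
  # strictly increasing in k, scale-equivariant in 1/V_d
  ks <- 1:9 * 1000
  expect_true(all(diff(concentration(ks, 10000)) > 0))
  expect_equal(concentration(3000, 10000, droplet_volume = 0.425e-3),
               2 * concentration(3000, 10000))
  expect_error(concentration(10000, 10000), "saturated")
  expect_error(concentration(10001, 10000), "0 <= k <= N")
})

test_that("QC thresholds flag low droplet and positive counts", {
  w <- data.frame(sample_id = c("a", "b", "c"),
                  assay = "miR-203a-3p",
                  dilution = 10,
                  total_droplets = c(12000, 9000, 12000),
                  positive_droplets = c(50, 50, 2))
  out <- qc_pass(w)
  expect_identical(out$qc_pass, c(TRUE, FALSE, FALSE))
  expect_identical(out$qc_flags, c("", "low_droplets", "low_positives"))
})

test_that("sample ratios divide back-diluted concentrations", {
  # wells engineered so undiluted target = 1, reference = 1000 copies/uL
  mk <- function(conc, dilution) {
    pr <- 1 - exp(-(conc / dilution) * 0.85e-3)
    as.integer(round(2e6 * pr))
  }
  w <- data.frame(
    sample_id = "s1",
    assay = c("miR-203a-3p", "miR-16-5p"),
    dilution = c(1, 1),
    total_droplets = 2e6,
    positive_droplets = c(mk(1, 1), mk(1000, 1)))
  rt <- sample_ratios(w)
  expect_equal(rt$ratio, 1e-3, tolerance = 2e-3)
  # rescaling both dilutions (same diluted fluid measured) keeps the ratio
  w2 <- w; w2$dilution <- c(2, 2)
  expect_equal(sample_ratios(w2)$ratio, 2 * rt$ratio / 2,
               tolerance = 1e-12)
  # zero reference concentration excludes the sample with a reason
  # (QC positive-count floor lifted so the zero-count well is quantified)
  w3 <- w; w3$positive_droplets[2] <- 0L
  rt3 <- sample_ratios(w3, min_positives = -1)
  expect_equal(nrow(rt3), 0)
  expect_match(attr(rt3, "excluded")[["s1"]], "zero reference")
  # QC-failing assay well excludes the sample
  w4 <- w; w4$total_droplets <- c(2e6, 5000)
  rt4 <- sample_ratios(w4)
  expect_equal(nrow(rt4), 0)
  expect_match(attr(rt4, "excluded")[["s1"]], "miR-16-5p")
})

test_that("simulate -> quantify round trip recovers the concentration", {
  for (conc in c(800, 2500)) {
    bias <- mean(vapply(1:3, function(s) {
      k <- simulate_well(conc, dilution = 10, n_droplets = 1e6, seed = 40 + s)
      abs(concentration(k, 1e6, dilution = 10) - conc) / conc
    }, 1))
    expect_lt(bias, 0.01)
  }
  # bias shrinks with droplet count
  est_at <- function(n) {
    mean(vapply(1:10, function(s) {
      k <- simulate_well(300, 1, n, seed = 100 + s)
      abs(concentration(k, n) - 300) / 300
    }, 1))
  }
  expect_lt(est_at(1e6), est_at(1e4))
  expect_identical(simulate_well(0, 1, 1000, seed = 1), 0L)
})

test_that("extraction check reacts to shifted efficiency only", {
  v <- generate_validation(small_validation(seed = 8))
  groups <- setNames(v$cohort$group, v$cohort$sample_id)
  chk <- extraction_check(v$wells, groups)
  expect_false(chk$warning)          # uniform efficiency by construction
  # shifting one group's reference concentration 3x triggers the warning
  w <- v$wells
  pdd <- names(groups)[groups == "PDD"]
  sel <- w$assay == "miR-16-5p" & w$sample_id %in% pdd
  w$positive_droplets[sel] <- pmin(w$total_droplets[sel] - 1L,
                                   w$positive_droplets[sel] * 3L)
  chk2 <- extraction_check(w, groups)
  expect_true(chk2$warning)
  # identical ratios across groups: H = 0, no warning
  w0 <- v$wells
  w0$positive_droplets <- ifelse(w0$assay == "miR-16-5p", 2000L,
                                 ifelse(w0$assay == "UniSp6", 4000L, 500L))
  chk0 <- extraction_check(w0, groups)
  expect_equal(chk0$H, 0)
  expect_false(chk0$warning)
})

test_that("IQR outlier rule uses linear-interpolation quartiles per group", {
  v <- c(1, 2, 3, 4, 100)
  expect_identical(iqr_outliers(v), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # hand check of the fence: Q1 = 2, Q3 = 4, upper fence 7
  expect_false(iqr_outliers(c(1, 2, 3, 4, 7))[5])
  expect_true(iqr_outliers(c(1, 2, 3, 4, 7.01))[5])
  expect_false(any(iqr_outliers(rep(5, 6))))
  expect_false(any(iqr_outliers(c(-2, -1, 0, 1, 2))))
  # affine invariance with positive scale, per group
  set.seed(9)
  x <- rnorm(40); g <- rep(c("a", "b"), 20)
  expect_identical(iqr_outliers(x, g), iqr_outliers(3 * x + 7, g))
  # grouping is local: an outlier in one group is flagged there only
  y <- c(1, 2, 3, 4, 100, 90, 95, 100, 105, 110)
  gg <- rep(c("a", "b"), each = 5)
  expect_identical(which(iqr_outliers(y, gg)), 5L)
})

test_that("extraction-efficiency warning keeps its nominal false-positive rate", {
  warns <- vapply(1:60, function(s) {
    v <- generate_validation(small_validation(seed = 400 + s))
    groups <- setNames(v$cohort$group, v$cohort$sample_id)
    extraction_check(v$wells, groups)$warning
  }, TRUE)
  expect_lte(mean(warns), 0.12)        # ~alpha plus binomial noise
})
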