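test_that("gaussian kde recovers the standard normal density and integrates to 1", {
  x <- withr::with_seed(1L, rnorm(1000))
  kde <- gaussian_kde(x)
  at0 <- kde$density[which.min(abs(kde$grid))]
  expect_equal(at0, dnorm(0), tolerance = 0.03 / dnorm(0))
  expect_equal(trapezoid_integral <- sum(diff(kde$grid) *
                 (head(kde$density, -1) + tail(kde$density, -1)) / 2),
               1, tolerance = 1e-3)
  # grid spans beyond the data by at least 3 bandwidths
  expect_lte(kde$grid[1], min(x) - 3 * kde$bandwidth)
  expect_gte(kde$grid[length(kde$grid)], max(x) + 3 * kde$bandwidth)
  # scaling identity: scores and bandwidth x10 -> density / 10
  kde10 <- gaussian_kde(10 * x, bandwidth = 10 * kde$bandwidth)
  expect_equal(kde10$density, kde$density / 10, tolerance = 1e-10)
  # degenerate scores refuse a Silverman bandwidth
  expect_error(gaussian_kde(rep(2, 5)), "empirical ROC")
})

test_that("empirical ROC AUC equals Mann-Whitney pair counting with half ties", {
  expect_equal(empirical_roc(c(1, 2, 3), c(4, 5, 6))$auc, 1)
  expect_equal(empirical_roc(c(1, 3), c(2, 4))$auc, 0.75)
  expect_equal(empirical_roc(c(1, 2), c(2, 3))$auc, 0.875)
  expect_error(empirical_roc(numeric(0), 1), "at least one")
  # property: 200 random instances up to n = 50, incl. ties via rounding
  withr::with_seed(42L, {
    for (i in 1:200) {
      m <- sample(1:50, 1); n <- sample(1:50, 1)
      controls <- round(rnorm(m), sample(0:2, 1))
      cases <- round(rnorm(n, 0.5), sample(0:2, 1))
      expect_equal(empirical_roc(controls, cases)$auc,
                   brute_force_auc(controls, cases))
    }
  })
})

test_that("empirical ROC/AUC is invariant under strictly increasing transforms", {
  withr::with_seed(5L, {
    controls <- rnorm(30); cases <- rnorm(20, 1)
    base <- empirical_roc(controls, cases)
    for (f in list(function(x) exp(x), function(x) x^3 + 2 * x,
                   function(x) qlogis(plogis(x)))) {
      tr <- empirical_roc(f(controls), f(cases))
      expect_equal(tr$auc, base$auc)
      expect_equal(tr$fpr, base$fpr)
      expect_equal(tr$tpr, base$tpr)
    }
  })
})

test_that("label swap complements the AUC and preserves the ROC length", {
  withr::with_seed(8L, {
    controls <- rnorm(100); cases <- rnorm(100, 1)
    expect_equal(empirical_roc(cases, controls)$auc,
                 1 - empirical_roc(controls, cases)$auc)
    expect_equal(auc_inference(cases, controls)$auc,
                 1 - auc_inference(controls, cases)$auc)
    expect_equal(roc_length(cases, controls), roc_length(controls, cases),
                 tolerance = 1e-10)
  })
})

test_that("smooth ROC AUC matches the binormal closed form", {
  withr::with_seed(31L, {
    expect_equal(smooth_roc(rnorm(500), rnorm(500, 10))$auc, 1,
                 tolerance = 0.001)
    pooled <- rnorm(1000)
    expect_equal(smooth_roc(pooled[1:500], pooled[501:1000])$auc, 0.5,
                 tolerance = 0.04)
    expect_equal(smooth_roc(rnorm(2000), rnorm(2000, 1.19))$auc,
                 pnorm(1.19 / sqrt(2)), tolerance = 0.02)
  })
  # curve is a monotone polyline from (0,0) to (1,1)
  sr <- withr::with_seed(2L, smooth_roc(rnorm(50), rnorm(50, 1)))
  expect_equal(sr$fpr[1], 0); expect_equal(sr$tpr[1], 0)
  expect_equal(sr$fpr[length(sr$fpr)], 1)
  expect_equal(sr$tpr[length(sr$tpr)], 1)
  expect_true(all(diff(sr$fpr) >= 0))
  expect_true(all(diff(sr$tpr) >= 0))
})

test_that("ROC length hits its analytic anchors and agrees with the polyline", {
  withr::with_seed(101L, {
    controls <- rnorm(500); sep_cases <- rnorm(500, 10)
    expect_equal(roc_length(controls, sep_cases), 2, tolerance = 0.05)
    expect_equal(roc_length(rnorm(500), rnorm(500)), sqrt(2),
                 tolerance = 0.05)
    bimodal <- c(rnorm(250, -3), rnorm(250, 3))
    controls2 <- rnorm(500)
    expect_gt(roc_length(controls2, bimodal), 1.6)
    expect_equal(smooth_roc(controls2, bimodal)$auc, 0.5, tolerance = 0.15)
    # threshold-integral and polyline arc length agree
    for (case_set in list(sep_cases, bimodal)) {
      expect_equal(roc_length(controls, case_set),
                   smooth_roc(controls, case_set)$length, tolerance = 1e-3)
    }
  })
})

test_that("ROC length stays in [sqrt(2), 2] and grows with binormal separation", {
  lens <- numeric(0); aucs <- numeric(0)
  for (delta in c(0, 0.5, 1, 2, 4, 8)) {
    res <- withr::with_seed(500L + round(10 * delta), {
      controls <- rnorm(2000); cases <- rnorm(2000, delta)
      c(roc_length(controls, cases), smooth_roc(controls, cases)$auc)
    })
    lens <- c(lens, res[1]); aucs <- c(aucs, res[2])
  }
  expect_true(all(lens >= sqrt(2) - 0.01 & lens <= 2 + 0.01))
  expect_true(all(diff(lens) > 0))
  expect_true(all(diff(aucs) > 0))
  expect_equal(lens[1], sqrt(2), tolerance = 0.05)
  expect_equal(lens[6], 2, tolerance = 0.05)
})

test_that("marker shape classification applies the length/AUC rule", {
  expect_equal(classify_marker_shape(2.0, 0.95)$label, "monotone")
  expect_equal(classify_marker_shape(2.0, 0.05)$label, "monotone")
  expect_equal(classify_marker_shape(1.96, 0.9)$label, "monotone")
  expect_equal(classify_marker_shape(1.7, 0.50)$label, "non_monotone")
  expect_equal(classify_marker_shape(1.5, 0.70)$label, "neither")
  expect_equal(classify_marker_shape(1.7, 0.75)$label, "neither")
  expect_equal(classify_marker_shape(2.0, 0.5)$label, "non_monotone")
  # end-to-end: separated marker is monotone, bimodal marker is non-monotone
  withr::with_seed(77L, {
    expect_equal(classify_marker(rnorm(500), rnorm(500, 10))$label,
                 "monotone")
    expect_equal(classify_marker(rnorm(500),
                                 c(rnorm(250, -3), rnorm(250, 3)))$label,
                 "non_monotone")
  })
})

test_that("DeLong inference matches pROC and a bootstrap oracle", {
  skip_if_not_installed("pROC")
  withr::with_seed(13L, {
    controls <- rnorm(40); cases <- rnorm(25, 0.8)
    mine <- auc_inference(controls, cases)
    ref <- pROC::roc(response = rep(c(0, 1), c(40, 25)),
                     predictor = c(controls, cases), quiet = TRUE,
                     direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
    expect_equal(mine$se, sqrt(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(mine$ci_low, max(ci[1], 0), tolerance = 1e-8)
    expect_equal(mine$ci_high, min(ci[3], 1), tolerance = 1e-8)
  })
  # interleaved toy data: DeLong SE within 20% of a 10,000-rep bootstrap
  controls <- c(1, 3, 5, 7); cases <- c(2, 4, 6, 8)
  mine <- auc_inference(controls, cases)
  expect_equal(mine$auc, 0.625)
  boot_se <- withr::with_seed(21L,
    auc_inference(controls, cases, method = "bootstrap", n_boot = 10000L)$se)
  expect_equal(mine$se, boot_se, tolerance = 0.2)
})

test_that("degenerate and null AUC inference behave as contracted", {
  sep <- auc_inference(1:5, 11:15)
  expect_true(sep$degenerate)
  expect_equal(c(sep$ci_low, sep$ci_high), c(1, 1))
  expect_equal(sep$p_one_tailed, 1 / choose(10, 5))
  # permuted labels give AUC near 0.5 and one-tailed p near 0.5
  withr::with_seed(9L, {
    pooled <- rnorm(200)
    null_inf <- auc_inference(pooled[1:100], pooled[101:200])
    expect_equal(null_inf$auc, 0.5, tolerance = 0.1)
    expect_equal(null_inf$p_one_tailed, 0.5, tolerance = 0.35)
  })
})

test_that("fixed-specificity and fixed-sensitivity operating points enumerate correctly", {
  # perfect separation
  expect_equal(sensitivity_at_specificity(1:5, 11:15, 0.998)$sensitivity, 1)
  expect_equal(specificity_at_sensitivity(1:5, 11:15, 0.95)$specificity, 1)
  # hand enumeration: controls 1..10, cases 6..15, target specificity 1
  op <- sensitivity_at_specificity(1:10, 6:15, 1.0)
  expect_equal(op$sensitivity, 0.5)
  expect_gt(op$threshold, 10)
  # with 20 controls, 0.998 is as stringent as 1.0 (granularity 1/20)
  withr::with_seed(14L, {
    controls <- rnorm(20); cases <- rnorm(10, 1)
    expect_equal(sensitivity_at_specificity(controls, cases, 0.998),
                 sensitivity_at_specificity(controls, cases, 1.0))
  })
  # reversed marker: specificity collapses to 0
  expect_equal(specificity_at_sensitivity(6:15, 1:10, 0.95)$specificity, 0)
  # symmetry of the two fixed-point operations on label-swapped, negated data
  withr::with_seed(15L, {
    controls <- rnorm(20); cases <- rnorm(10, 2)
    a <- sensitivity_at_specificity(controls, cases, 0.9)
    b <- specificity_at_sensitivity(-cases, -controls, 0.9)
    expect_equal(a$sensitivity, b$specificity)
  })
  # sensitivity is non-increasing in the specificity target
  withr::with_seed(16L, {
    controls <- rnorm(50); cases <- rnorm(30, 1)
    sens <- vapply(c(0.5, 0.7, 0.9, 0.95, 1.0), function(t)
      sensitivity_at_specificity(controls, cases, t)$sensitivity, numeric(1))
    expect_true(all(diff(sens) <= 0))
  })
})

test_that("youden point maximizes J and matches the binormal closed form", {
  expect_equal(youden(1:5, 11:15)$youden_j, 1)
  withr::with_seed(17L, {
    pooled <- rnorm(400)
    expect_equal(youden(pooled[1:200], pooled[201:400])$youden_j, 0,
                 tolerance = 0.15)
  })
  res <- withr::with_seed(18L, youden(rnorm(5000), rnorm(5000, 2)))
  expect_equal(res$youden_j, 2 * pnorm(1) - 1, tolerance = 0.03)
  expect_equal(res$youden_j, res$sensitivity + res$specificity - 1)
  # J at the chosen threshold dominates J at every other threshold
  withr::with_seed(19L, {
    controls <- rnorm(40); cases <- rnorm(30, 1)
    best <- youden(controls, cases)
    for (t in c(controls, cases)) {
      j_t <- mean(cases >= t) + mean(controls < t) - 1
      expect_gte(best$youden_j, j_t)
    }
  })
})
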