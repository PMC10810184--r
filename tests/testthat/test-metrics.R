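test_that("ROC curve handles separation, ties and mixed labels", {
  r <- compute_roc(c("DNA", "NONE"), c(0.9, 0.1))
  expect_equal(r$points$fpr, c(0, 0, 1))
  expect_equal(r$points$tpr, c(0, 1, 1))

  ## full tie collapses to a single interior point
  r2 <- compute_roc(c("DNA", "NONE"), c(0.5, 0.5))
  expect_equal(nrow(r2$points), 2)
  expect_equal(r2$points$fpr, c(0, 1))
  expect_equal(r2$points$tpr, c(0, 1))

  r3 <- compute_roc(c("DNA", "NONE", "DNA", "OTHER"), c(0.8, 0.7, 0.6, 0.2))
  expect_equal(roc_auc(r3), 0.75)  # 3 of 4 concordant pairs

  expect_error(compute_roc(c("DNA", "DNA"), c(1, 2)), "no negative")
  expect_error(compute_roc(c("NONE", "OTHER"), c(1, 2)), "no DNA")
})

test_that("trapezoidal AUC equals brute-force pair counting on random instances", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    labels <- sample(c("DNA", "OTHER", "NONE"), n, replace = TRUE)
    if (!any(labels == "DNA")) labels[1] <- "DNA"
    if (all(labels == "DNA")) labels[2] <- "NONE"
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(compute_roc(labels, scores)), brute_auc(labels, scores))
  }
})

test_that("AULC restricts the curve and recovers the full AUC at bound 1", {
  ## perfect predictor: TPR = 1 across the whole low-FPR region
  labels <- c(rep("DNA", 5), rep("NONE", 20))
  scores <- c(seq(2, 3, length.out = 5), seq(0, 1, length.out = 20))
  r <- compute_roc(labels, scores)
  expect_equal(aulc(r, fpr_bound = 0.1)$area, 0.1)
  expect_equal(aulc(r, fpr_bound = 1)$area, roc_auc(r))

  ## random scores: area near the diagonal's b^2/2
  set.seed(5)
  labels2 <- sample(c("DNA", "NONE"), 40000, replace = TRUE, prob = c(0.1, 0.9))
  scores2 <- runif(40000)
  r2 <- compute_roc(labels2, scores2)
  expect_equal(aulc(r2, fpr_bound = 0.2)$area, 0.02, tolerance = 0.15)

  expect_error(aulc(r, fpr_bound = 0), "fpr_bound")
})

test_that("count-matched AULC bound sits where predicted positives equal P", {
  set.seed(7)
  labels <- sample(c("DNA", "OTHER", "NONE"), 500, replace = TRUE,
                   prob = c(0.1, 0.1, 0.8))
  scores <- rnorm(500) + (labels == "DNA")
  r <- compute_roc(labels, scores)
  res <- aulc(r, mode = "count_matched")
  ## explicit threshold scan oracle: FPR at the P-th highest score
  P <- sum(labels == "DNA")
  thr <- sort(scores, decreasing = TRUE)[P]
  fp <- sum(scores >= thr & labels != "DNA")
  expect_equal(res$bound, fp / sum(labels != "DNA"), tolerance = 1e-12)
  expect_lt(res$area, res$bound)  # area below the achievable square
})

test_that("AULC ratio matches the analytic diagonal baseline", {
  ## perfect predictor at bound 0.1: 0.1 / 0.005 = 20
  labels <- c(rep("DNA", 5), rep("NONE", 20))
  scores <- c(seq(2, 3, length.out = 5), seq(0, 1, length.out = 20))
  r <- compute_roc(labels, scores)
  expect_equal(aulc_ratio(aulc(r, fpr_bound = 0.1)), 20)
  expect_equal(aulc_ratio(0.01, 0.1), 2)
})

test_that("threshold calibration interpolates linearly between curve points", {
  r <- compute_roc(c("DNA", "DNA", "NONE", "NONE"), c(0.9, 0.8, 0.7, 0.1))
  ## between (fpr 0, tpr 1) and (fpr 0.5, tpr 1): any low fpr keeps tpr 1
  op <- threshold_at(r, fpr = 0.25)
  expect_equal(op$tpr, 1)
  expect_gt(op$threshold, 0.1)

  ## hand-built interpolation case: target between two curve points
  labels <- c(rep("DNA", 5), rep("NONE", 5))
  scores <- c(5, 4, 3, 2, 1, 3.5, 2.5, 1.5, 0.5, 0.2)
  r2 <- compute_roc(labels, scores)
  ## curve passes (0.2, 0.6) and (0.4, 0.8); at fpr 0.3 expect tpr 0.7
  op2 <- threshold_at(r2, fpr = 0.3)
  expect_equal(op2$tpr, 0.7)

  ## degenerate curve: calibration impossible
  rd <- compute_roc(c("DNA", "NONE", "NONE"), c(1, 1, 1))
  expect_error(threshold_at(rd, fpr = 0.1), "degenerate")

  ## tpr-target side
  op3 <- threshold_at(r2, tpr = 0.7)
  expect_equal(op3$fpr, 0.3)
})

test_that("binary counts partition false positives by negative sub-class", {
  bc <- binary_counts(c("DNA", "OTHER", "NONE"), c(1, 1, 0))
  expect_equal(bc$tp, 1)
  expect_equal(bc$fp, 1)
  expect_equal(bc$fp_other, 1)
  expect_equal(bc$fp_none, 0)
  expect_equal(bc$tn, 1)
  expect_equal(bc$fp, bc$fp_other + bc$fp_none)

  bc0 <- binary_counts(c("DNA", "DNA", "NONE"), c(0, 0, 0))
  expect_equal(bc0$fp, 0)
  expect_equal(bc0$fn, bc0$n_pos)

  ## weighted identity: fpr == (cpr * n_other + opr * n_none) / N
  bc2 <- binary_counts(c("DNA", "OTHER", "OTHER", "NONE", "NONE"),
                       c(0, 1, 0, 0, 0))
  rates <- cpr_opr(bc2)
  fpr <- bc2$fp / bc2$n_neg
  expect_equal(fpr, 0.25)
  expect_equal((rates$cpr * bc2$n_other + rates$opr * bc2$n_none) / bc2$n_neg, fpr)
})

test_that("sensitivity/specificity F1 follows the harmonic-mean formula", {
  expect_equal(f1_sens_spec(1, 0), 1)
  expect_equal(f1_sens_spec(0.5, 0.1), 2 * 0.5 * 0.9 / (0.5 + 0.9))
  expect_equal(f1_sens_spec(0, 1), 0)  # degenerate: both terms zero
})

test_that("maxF1 is an exhaustive maximum over curve points", {
  labels <- c(rep("DNA", 5), rep("NONE", 5))
  scores <- c(5, 4, 3, 2, 1, 3.5, 2.5, 1.5, 0.5, 0.2)
  r <- compute_roc(labels, scores)
  oracle <- max(mapply(f1_sens_spec, r$points$tpr, r$points$fpr))
  expect_equal(max_f1(r), oracle)
  ## maximum dominates any calibrated operating point
  op <- threshold_at(r, fpr = 0.1)
  expect_gte(max_f1(r), f1_sens_spec(op$tpr, 0.1))

  rp <- compute_roc(c("DNA", "NONE"), c(1, 0))
  expect_equal(max_f1(rp), 1)
})

test_that("CPR/OPR rates and ratios behave at the boundaries", {
  bc <- binary_counts(c("DNA", "OTHER", "OTHER", "NONE"), c(0, 1, 0, 0))
  expect_equal(cpr_opr(bc)$cpr, 0.5)
  expect_equal(cpr_opr(bc)$opr, 0)

  ## empty denominator flags NA, not 0
  bc2 <- binary_counts(c("DNA", "NONE"), c(1, 0))
  expect_true(is.na(cpr_opr(bc2)$cpr))

  rr <- cpr_opr_ratios(0.05, 0, 0.1)
  expect_equal(rr$cpr_ratio, 2)
  expect_identical(rr$opr_ratio, Inf)
  expect_equal(cpr_opr_ratios(0.1, 0.1, 0.1)$cpr_ratio, 1)
})

test_that("cross-/over-prediction curves hit the analytic extremes", {
  ## perfect ligand-specific predictor: all DNA above all others
  labels <- c(rep("DNA", 4), rep("OTHER", 4), rep("NONE", 8))
  scores <- c(8:5, 4:1, seq(0.9, 0.2, length.out = 8))
  co <- cross_over_curves(labels, scores)
  expect_equal(co$aucpc, 0)
  expect_equal(co$auopc, 0)

  ## anti-perfect: all OTHER above all DNA -> CPR reaches 1 before any TPR gain
  scores2 <- c(4:1, 8:5, seq(0.9, 0.2, length.out = 8))
  expect_equal(cross_over_curves(labels, scores2)$aucpc, 1)

  ## random scores: both areas near 0.5
  set.seed(3)
  labels3 <- sample(c("DNA", "OTHER", "NONE"), 30000, replace = TRUE,
                    prob = c(0.05, 0.1, 0.85))
  co3 <- cross_over_curves(labels3, runif(30000))
  expect_equal(co3$aucpc, 0.5, tolerance = 0.05)
  expect_equal(co3$auopc, 0.5, tolerance = 0.05)

  ## missing class: the corresponding curve is undefined
  co4 <- cross_over_curves(c("DNA", "NONE", "NONE"), c(3, 2, 1))
  expect_null(co4$cpc)
  expect_true(is.na(co4$aucpc))
  expect_false(is.na(co4$auopc))
})

test_that("FPR decomposes into CPR and OPR at every threshold", {
  set.seed(21)
  labels <- sample(c("DNA", "OTHER", "NONE"), 300, replace = TRUE,
                   prob = c(0.1, 0.2, 0.7))
  scores <- rnorm(300) + 0.8 * (labels == "DNA")
  r <- compute_roc(labels, scores)
  cpr <- r$fp_other / r$n_other
  opr <- r$fp_none / r$n_none
  expect_equal((cpr * r$n_other + opr * r$n_none) / r$n_neg, r$points$fpr)
})

test_that("all metrics are invariant under strictly monotone score transforms", {
  set.seed(13)
  labels <- sample(c("DNA", "OTHER", "NONE"), 400, replace = TRUE,
                   prob = c(0.1, 0.15, 0.75))
  scores <- rnorm(400) + (labels == "DNA")
  m1 <- metric_report(labels, scores)
  m2 <- metric_report(labels, exp(2 * scores) + 5)
  for (nm in setdiff(names(m1), "calibration_fpr")) {
    expect_equal(m1[[nm]], m2[[nm]], tolerance = 1e-9, label = nm)
  }
})

test_that("implementation AUC agrees with an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(8)
  labels <- sample(c("DNA", "OTHER", "NONE"), 600, replace = TRUE,
                   prob = c(0.1, 0.1, 0.8))
  scores <- rnorm(600) + 0.9 * (labels == "DNA")
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(labels == "DNA", scores, quiet = TRUE)))
  )
  expect_equal(roc_auc(compute_roc(labels, scores)), ref, tolerance = 1e-10)
})
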