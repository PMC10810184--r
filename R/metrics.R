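#' Compute a ROC curve over pooled per-residue labels and scores
#'
#' Positives are residues labelled `"DNA"`; negatives are everything else
#' (`"OTHER"` residues that bind non-DNA ligands and `"NONE"` non-binding
#' residues). Tied scores are collapsed into a single curve point, so the
#' trapezoidal area equals the tie-corrected Mann-Whitney statistic. The
#' curve keeps the decomposition of false positives into the two negative
#' sub-classes, which is what the cross-/over-prediction machinery consumes.
#'
#' @param labels Character vector of residue labels (`"DNA"`, `"OTHER"`,
#'   `"NONE"`), pooled over a protein set.
#' @param scores Numeric vector of predictor propensities, same length.
#' @return An object of class `dbr_roc`: list with `points` (data.frame of
#'   `fpr`, `tpr`, `threshold` from strictest to loosest, starting at (0,0)),
#'   `fp_other`/`fp_none` cumulative counts aligned with `points`, and class
#'   totals `n_pos`, `n_neg`, `n_other`, `n_none`.
#' @export
compute_roc <- function(labels, scores) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores))
  if (any(!is.finite(scores))) stop("scores must be finite")
  bad <- setdiff(unique(labels), DBR_LABELS)
  if (length(bad)) stop(sprintf("unknown label token(s): %s", paste(bad, collapse = ", ")))
  pos <- labels == "DNA"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L) stop("ROC undefined: no DNA-labelled (positive) residues")
  if (n_neg == 0L) stop("ROC undefined: no negative residues")
  n_other <- sum(labels == "OTHER"); n_none <- sum(labels == "NONE")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  ## indices of the last element of each tie group (distinct thresholds)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l == "DNA")[last]
  fpo <- cumsum(l == "OTHER")[last]
  fpn <- cumsum(l == "NONE")[last]
  fp <- fpo + fpn
  points <- data.frame(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    threshold = c(Inf, s[last])
  )
  structure(
    list(points = points,
         fp_other = c(0L, fpo), fp_none = c(0L, fpn),
         n_pos = n_pos, n_neg = n_neg, n_other = n_other, n_none = n_none),
    class = "dbr_roc"
  )
}

#' @export
print.dbr_roc <- function(x, ...) {
  cat(sprintf("<dbr_roc> %d points; P = %d, N = %d (%d other-ligand, %d non-binding); AUC = %.4f\n",
              nrow(x$points), x$n_pos, x$n_neg, x$n_other, x$n_none, roc_auc(x)))
  invisible(x)
}

## trapezoid rule over an (x, y) polyline
trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Area under a ROC curve
#'
#' Trapezoidal area of a [compute_roc] curve; with tied scores collapsed this
#' equals the tie-corrected Mann-Whitney statistic (ties count 1/2).
#'
#' @param curve A `dbr_roc` object.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "dbr_roc"))
  trapezoid(curve$points$fpr, curve$points$tpr)
}

#' Area under the low-FPR part of the ROC curve (AULC)
#'
#' Restricts the ROC curve to the low false-positive-rate region, where
#' predictions are practically useful given that DNA-binding residues are a
#' small minority class. Two bounds are supported: a fixed FPR bound
#' (default 0.1), or a count-matched bound placed at the threshold where the
#' number of predicted positives equals the number of actual positives.
#'
#' @param curve A `dbr_roc` object.
#' @param mode `"fixed_fpr"` (default) or `"count_matched"`.
#' @param fpr_bound FPR bound for `"fixed_fpr"` mode, in (0, 1\].
#' @return List with `area` (trapezoidal area over FPR in \[0, bound\], with
#'   linear interpolation at the bound) and `bound` (the FPR bound used).
#' @export
aulc <- function(curve, mode = c("fixed_fpr", "count_matched"), fpr_bound = 0.1) {
  stopifnot(inherits(curve, "dbr_roc"))
  mode <- match.arg(mode)
  pts <- curve$points
  if (mode == "count_matched") {
    ## predicted positives at each distinct threshold
    npred <- round(pts$tpr * curve$n_pos + pts$fpr * curve$n_neg)
    P <- curve$n_pos
    if (max(npred) < P) stop("count-matched bound unattainable")
    i <- which(npred >= P)[1L]
    if (i == 1L || npred[i] == P) {
      fpr_bound <- pts$fpr[i]
    } else {
      ## interpolate FPR linearly in the predicted-positive count
      w <- (P - npred[i - 1L]) / (npred[i] - npred[i - 1L])
      fpr_bound <- pts$fpr[i - 1L] + w * (pts$fpr[i] - pts$fpr[i - 1L])
    }
    if (fpr_bound <= 0) stop("count-matched bound is zero: no curve support")
  }
  if (fpr_bound <= 0 || fpr_bound > 1) stop("fpr_bound must be in (0, 1]")
  ## integrate along the swept polyline over FPR <= bound; vertical segments
  ## at the bound contribute zero area, and a segment crossing the bound is
  ## cut by linear interpolation
  keep <- pts$fpr <= fpr_bound
  x <- pts$fpr[keep]; y <- pts$tpr[keep]
  if (any(!keep)) {
    i <- which(!keep)[1L]
    if (pts$fpr[i - 1L] < fpr_bound) {
      w <- (fpr_bound - pts$fpr[i - 1L]) / (pts$fpr[i] - pts$fpr[i - 1L])
      x <- c(x, fpr_bound)
      y <- c(y, pts$tpr[i - 1L] + w * (pts$tpr[i] - pts$tpr[i - 1L]))
    }
  }
  list(area = trapezoid(x, y), bound = fpr_bound)
}

#' AULC ratio against the analytic random baseline
#'
#' Divides an AULC value by the AULC of a random predictor over the same FPR
#' region. The random baseline is the diagonal ROC, whose area over
#' \[0, bound\] is `bound^2 / 2` in closed form. A ratio of 1 is
#' random-equivalent; 2 means twice better than random.
#'
#' @param aulc_value AULC area, or the list returned by [aulc].
#' @param fpr_bound The FPR bound the area was computed over (ignored when
#'   `aulc_value` is an [aulc] result, which carries its own bound).
#' @return The ratio, a non-negative number.
#' @export
aulc_ratio <- function(aulc_value, fpr_bound = 0.1) {
  if (is.list(aulc_value)) {
    fpr_bound <- aulc_value$bound
    aulc_value <- aulc_value$area
  }
  if (fpr_bound <= 0) stop("fpr_bound must be positive")
  aulc_value / (fpr_bound^2 / 2)
}

#' Calibrate a decision threshold at a target FPR or TPR
#'
#' Operating points are standardized across predictors by picking, for each
#' one, the threshold that achieves a common FPR (or TPR) on the pooled
#' residues. Between adjacent ROC points the curve is interpolated linearly,
#' and the reported sensitivity/specificity are the interpolated values at
#' exactly the target.
#'
#' @param curve A `dbr_roc` object.
#' @param fpr Target false positive rate in (0, 1), or `NULL`.
#' @param tpr Target true positive rate in (0, 1), or `NULL` (exactly one of
#'   `fpr`/`tpr` must be given).
#' @return List with `threshold`, `fpr` and `tpr` at the operating point.
#' @export
threshold_at <- function(curve, fpr = NULL, tpr = NULL) {
  stopifnot(inherits(curve, "dbr_roc"))
  if (is.null(fpr) == is.null(tpr)) stop("give exactly one of 'fpr' or 'tpr'")
  pts <- curve$points
  if (nrow(pts) < 3L) {
    stop("calibration impossible: degenerate curve (all scores equal)")
  }
  thr <- pts$threshold
  thr[1L] <- thr[2L]  # finite stand-in for +Inf; any value above the top score
  if (!is.null(fpr)) {
    stopifnot(fpr > 0, fpr < 1)
    achieved_tpr <- stats::approx(pts$fpr, pts$tpr, xout = fpr, ties = max)$y
    threshold <- stats::approx(pts$fpr, thr, xout = fpr, ties = min)$y
    list(threshold = threshold, fpr = fpr, tpr = achieved_tpr)
  } else {
    stopifnot(tpr > 0, tpr < 1)
    achieved_fpr <- stats::approx(pts$tpr, pts$fpr, xout = tpr, ties = min)$y
    threshold <- stats::approx(pts$tpr, thr, xout = tpr, ties = max)$y
    list(threshold = threshold, fpr = achieved_fpr, tpr = tpr)
  }
}

#' Confusion counts with the false positives split by negative sub-class
#'
#' Beyond the usual TP/TN/FP/FN, false positives are partitioned into
#' cross-predictions (`fp_other`: residues binding a non-DNA ligand called
#' positive) and over-predictions (`fp_none`: non-binding residues called
#' positive).
#'
#' @param labels Character vector of residue labels.
#' @param calls Logical or 0/1 vector of binary predictions, same length.
#' @return An object of class `dbr_counts`: list with `tp`, `tn`, `fp`, `fn`,
#'   `fp_other`, `fp_none`, `n_other`, `n_none`, `n_pos`, `n_neg`.
#' @export
binary_counts <- function(labels, calls) {
  labels <- as.character(labels)
  calls <- as.logical(calls)
  stopifnot(length(labels) == length(calls), !anyNA(calls))
  pos <- labels == "DNA"
  structure(
    list(tp = sum(pos & calls), fn = sum(pos & !calls),
         fp = sum(!pos & calls), tn = sum(!pos & !calls),
         fp_other = sum(labels == "OTHER" & calls),
         fp_none = sum(labels == "NONE" & calls),
         n_other = sum(labels == "OTHER"), n_none = sum(labels == "NONE"),
         n_pos = sum(pos), n_neg = sum(!pos)),
    class = "dbr_counts"
  )
}

#' Harmonic mean of sensitivity and specificity
#'
#' The F1-style summary used for the calibrated operating points:
#' `2 * TPR * (1 - FPR) / (TPR + (1 - FPR))`, i.e. the harmonic mean of
#' sensitivity and specificity (not the precision-recall F1; see
#' [f1_precision_recall] for that). Returns 0 when both terms are 0.
#'
#' @param tpr Sensitivity in \[0, 1\].
#' @param fpr False positive rate in \[0, 1\].
#' @return The harmonic mean, in \[0, 1\].
#' @export
f1_sens_spec <- function(tpr, fpr) {
  stopifnot(all(tpr >= 0 & tpr <= 1), all(fpr >= 0 & fpr <= 1))
  spec <- 1 - fpr
  den <- tpr + spec
  ifelse(den == 0, 0, 2 * tpr * spec / den)
}

#' Conventional precision-recall F1
#'
#' @param counts A `dbr_counts` object.
#' @return `2 * precision * recall / (precision + recall)`; 0 when no
#'   positive calls or no positives.
#' @export
f1_precision_recall <- function(counts) {
  stopifnot(inherits(counts, "dbr_counts"))
  if (counts$tp == 0L) return(0)
  prec <- counts$tp / (counts$tp + counts$fp)
  rec <- counts$tp / (counts$tp + counts$fn)
  2 * prec * rec / (prec + rec)
}

#' Maximum of the sensitivity/specificity F1 over all thresholds
#'
#' @param curve A `dbr_roc` object.
#' @return The maximum of [f1_sens_spec] over all distinct curve points.
#' @export
max_f1 <- function(curve) {
  stopifnot(inherits(curve, "dbr_roc"))
  max(f1_sens_spec(curve$points$tpr, curve$points$fpr))
}

#' Cross-prediction and over-prediction rates
#'
#' CPR is the fraction of residues that bind non-DNA ligands predicted as
#' DNA-binding; OPR is the fraction of non-binding residues predicted as
#' DNA-binding. An empty denominator makes the corresponding rate `NA`
#' (undefined, not zero).
#'
#' @param counts A `dbr_counts` object.
#' @return List with `cpr` and `opr`.
#' @export
cpr_opr <- function(counts) {
  stopifnot(inherits(counts, "dbr_counts"))
  list(cpr = if (counts$n_other > 0L) counts$fp_other / counts$n_other else NA_real_,
       opr = if (counts$n_none > 0L) counts$fp_none / counts$n_none else NA_real_)
}

#' CPR and OPR ratios against the random baseline
#'
#' A random predictor calibrated to a given overall FPR calls negatives
#' positive independently of their sub-class, so its CPR and OPR both equal
#' that FPR. The ratios divide the random rates by the method's rates, so
#' higher is better; 1 is random-equivalent. A method rate of 0 yields
#' `Inf`.
#'
#' @param cpr,opr Rates from [cpr_opr] (NA passes through).
#' @param calibration_fpr The FPR the binary calls were calibrated to, in
#'   (0, 1).
#' @return List with `cpr_ratio` and `opr_ratio`.
#' @export
cpr_opr_ratios <- function(cpr, opr, calibration_fpr) {
  stopifnot(calibration_fpr > 0, calibration_fpr < 1)
  ratio <- function(rate) {
    if (is.na(rate)) NA_real_ else if (rate == 0) Inf else calibration_fpr / rate
  }
  list(cpr_ratio = ratio(cpr), opr_ratio = ratio(opr))
}

#' Cross-prediction and over-prediction curves and their areas
#'
#' Sweeps all thresholds and records (TPR, CPR) and (TPR, OPR) pairs; the
#' areas under these curves (AUCPC, AUOPC; trapezoid over TPR in \[0, 1\])
#' summarize how much cross- and over-prediction a method incurs while
#' gaining sensitivity. Random scores give areas near 0.5; lower is better;
#' a perfect ligand-specific predictor reaches 0.
#'
#' @param labels Character vector of residue labels (all three classes must
#'   be present for both curves; a missing class makes that curve `NULL` and
#'   its area `NA`).
#' @param scores Numeric vector of propensities.
#' @return List with `cpc` and `opc` (data.frames of `tpr` and the rate,
#'   threshold-ordered), and areas `aucpc`, `auopc`.
#' @export
cross_over_curves <- function(labels, scores) {
  curve <- compute_roc(labels, scores)
  tpr <- curve$points$tpr
  out <- list(cpc = NULL, opc = NULL, aucpc = NA_real_, auopc = NA_real_)
  if (curve$n_other > 0L) {
    cpr <- curve$fp_other / curve$n_other
    out$cpc <- data.frame(tpr = tpr, cpr = cpr)
    out$aucpc <- trapezoid(tpr, cpr)
  }
  if (curve$n_none > 0L) {
    opr <- curve$fp_none / curve$n_none
    out$opc <- data.frame(tpr = tpr, opr = opr)
    out$auopc <- trapezoid(tpr, opr)
  }
  out
}

#' Full metric report for one method on one protein set
#'
#' Computes, from pooled per-residue labels and propensities: AUC, AULC and
#' AULCratio, sensitivities at calibrated low FPR points, specificities at
#' calibrated sensitivity points, maxF1, CPR/OPR and their random-baseline
#' ratios at the calibration FPR, and AUCPC/AUOPC.
#'
#' @param labels Character vector of residue labels, pooled over the set.
#' @param scores Numeric vector of propensities.
#' @param fpr_points FPR operating points for calibrated sensitivity
#'   (default `c(0.1, 0.2)`).
#' @param tpr_points TPR operating points for calibrated specificity
#'   (default `c(0.5, 0.7)`).
#' @param aulc_mode,aulc_bound AULC mode and fixed bound (see [aulc]).
#' @param calibration_fpr FPR at which CPR/OPR (and their ratios) are taken
#'   (default 0.1).
#' @return An object of class `dbr_metric_report`: a named list of scalar
#'   metrics plus `calibration_fpr`.
#' @export
metric_report <- function(labels, scores,
                          fpr_points = c(0.1, 0.2), tpr_points = c(0.5, 0.7),
                          aulc_mode = "fixed_fpr", aulc_bound = 0.1,
                          calibration_fpr = 0.1) {
  curve <- compute_roc(labels, scores)
  a <- aulc(curve, mode = aulc_mode, fpr_bound = aulc_bound)
  rep <- list(
    auc = roc_auc(curve),
    aulc = a$area,
    aulc_bound = a$bound,
    aulc_ratio = aulc_ratio(a)
  )
  for (f in fpr_points) {
    rep[[sprintf("sensitivity_at_fpr%g", f)]] <- threshold_at(curve, fpr = f)$tpr
  }
  for (t in tpr_points) {
    rep[[sprintf("specificity_at_tpr%g", t)]] <- 1 - threshold_at(curve, tpr = t)$fpr
  }
  rep$max_f1 <- max_f1(curve)
  ## CPR/OPR at the calibrated FPR: the cumulative FP decomposition changes
  ## only when FPR moves, so each rate is a single-valued piecewise-linear
  ## function of FPR and interpolates cleanly.
  pts <- curve$points
  cpr <- opr <- NA_real_
  if (curve$n_other > 0L) {
    cpr <- stats::approx(pts$fpr, curve$fp_other / curve$n_other,
                         xout = calibration_fpr, ties = max)$y
  }
  if (curve$n_none > 0L) {
    opr <- stats::approx(pts$fpr, curve$fp_none / curve$n_none,
                         xout = calibration_fpr, ties = max)$y
  }
  rep$cpr <- cpr
  rep$opr <- opr
  ratios <- cpr_opr_ratios(cpr, opr, calibration_fpr)
  rep$cpr_ratio <- ratios$cpr_ratio
  rep$opr_ratio <- ratios$opr_ratio
  co <- cross_over_curves(labels, scores)
  rep$aucpc <- co$aucpc
  rep$auopc <- co$auopc
  rep$calibration_fpr <- calibration_fpr
  structure(rep, class = "dbr_metric_report")
}

#' @export
print.dbr_metric_report <- function(x, digits = 3, ...) {
  cat("<dbr_metric_report>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, format(round(x[[nm]], digits))))
  }
  invisible(x)
}
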