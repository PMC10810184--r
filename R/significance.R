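#' Design of the stratified subsampling protocol
#'
#' Method comparisons are run over repeated random subsets of the benchmark:
#' each draw selects a fixed number of DNA-binding and non-DNA-binding
#' proteins, with an equal split of structure- and disorder-annotated
#' proteins inside each group. Draws are made without replacement within a
#' draw and independently across draws (proteins recur between draws).
#'
#' @param n_draws Number of subsets (default 100).
#' @param n_dna DNA-binding proteins per draw (default 20).
#' @param n_other Non-DNA-binding proteins per draw (default 40).
#' @param balanced_source Split each group equally between STRUCTURE and
#'   DISORDER sources (default TRUE; requires even `n_dna` and `n_other`).
#' @param seed Integer RNG seed.
#' @return An object of class `subsample_design`.
#' @export
subsample_design <- function(n_draws = 100L, n_dna = 20L, n_other = 40L,
                             balanced_source = TRUE, seed = 1L) {
  stopifnot(n_draws >= 1L, n_dna >= 1L, n_other >= 1L)
  if (balanced_source && (n_dna %% 2L != 0L || n_other %% 2L != 0L)) {
    stop("balanced_source requires even n_dna and n_other")
  }
  structure(list(n_draws = as.integer(n_draws), n_dna = as.integer(n_dna),
                 n_other = as.integer(n_other),
                 balanced_source = isTRUE(balanced_source),
                 seed = as.integer(seed)),
            class = "subsample_design")
}

#' Draw stratified protein subsets
#'
#' @param dataset A [dbr_dataset].
#' @param design A [subsample_design].
#' @return List of length `n_draws`; each element is a character vector of
#'   protein ids. Reproducible from `design$seed`.
#' @export
draw_subsets <- function(dataset, design) {
  stopifnot(inherits(dataset, "dbr_dataset"), inherits(design, "subsample_design"))
  cls <- vapply(dataset$proteins, `[[`, character(1), "protein_class")
  src <- vapply(dataset$proteins, `[[`, character(1), "source")
  ids <- names(dataset$proteins)
  strata <- if (design$balanced_source) {
    list(dna_structure = list(pool = ids[cls == "DNA_BINDING" & src == "STRUCTURE"],
                              k = design$n_dna %/% 2L),
         dna_disorder = list(pool = ids[cls == "DNA_BINDING" & src == "DISORDER"],
                             k = design$n_dna %/% 2L),
         other_structure = list(pool = ids[cls == "OTHER_BINDING" & src == "STRUCTURE"],
                                k = design$n_other %/% 2L),
         other_disorder = list(pool = ids[cls == "OTHER_BINDING" & src == "DISORDER"],
                               k = design$n_other %/% 2L))
  } else {
    list(dna = list(pool = ids[cls == "DNA_BINDING"], k = design$n_dna),
         other = list(pool = ids[cls == "OTHER_BINDING"], k = design$n_other))
  }
  for (nm in names(strata)) {
    st <- strata[[nm]]
    if (length(st$pool) < st$k) {
      stop(sprintf("stratum '%s' has %d proteins, need %d", nm,
                   length(st$pool), st$k))
    }
  }
  rng <- local_rng(design$seed)
  on.exit(rng(), add = TRUE)
  lapply(seq_len(design$n_draws), function(i) {
    unlist(lapply(strata, function(st) sample(st$pool, st$k)), use.names = FALSE)
  })
}

## Save/restore the global RNG state and seed a fresh one; returns the
## restore function. Keeps user RNG streams untouched by package internals.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Metric values per subset and method
#'
#' Evaluates a metric for each method on the pooled residues of each subset.
#'
#' @param dataset A [dbr_dataset] whose `tracks` hold one entry per method.
#' @param subsets List of protein-id vectors (as from [draw_subsets]).
#' @param metric Name of a [metric_report] field (e.g. `"auc"`,
#'   `"aulc_ratio"`, `"aucpc"`), or a function `(labels, scores) -> scalar`.
#' @param methods Character vector of predictor ids (default: all tracks).
#' @param ... Passed to [metric_report] when `metric` is a field name.
#' @return An object of class `dbr_metric_matrix`: list with `values`
#'   (n_draws x n_methods numeric matrix), `metric_name`, and `summary`
#'   (per-method mean and sample standard deviation).
#' @export
metric_matrix <- function(dataset, subsets, metric = "auc",
                          methods = names(dataset$tracks), ...) {
  stopifnot(inherits(dataset, "dbr_dataset"), length(subsets) >= 1L)
  metric_name <- if (is.function(metric)) "custom" else as.character(metric)
  eval_one <- function(labels, scores) {
    if (is.function(metric)) {
      metric(labels, scores)
    } else {
      rep <- metric_report(labels, scores, ...)
      if (!metric %in% names(rep)) {
        stop(sprintf("unknown metric '%s'; available: %s", metric,
                     paste(names(rep), collapse = ", ")))
      }
      rep[[metric]]
    }
  }
  values <- matrix(NA_real_, nrow = length(subsets), ncol = length(methods),
                   dimnames = list(NULL, methods))
  for (i in seq_along(subsets)) {
    ids <- subsets[[i]]
    labels <- pooled_labels(dataset, ids)
    for (m in methods) {
      v <- eval_one(labels, pooled_scores(dataset, m, ids))
      if (is.na(v)) {
        stop(sprintf("metric '%s' undefined for method '%s' on subset %d",
                     metric_name, m, i))
      }
      values[i, m] <- v
    }
  }
  structure(list(values = values, metric_name = metric_name,
                 summary = data.frame(
                   method = methods,
                   mean = colMeans(values),
                   sd = apply(values, 2, stats::sd),
                   row.names = NULL)),
            class = "dbr_metric_matrix")
}

#' @export
print.dbr_metric_matrix <- function(x, ...) {
  cat(sprintf("<dbr_metric_matrix> metric '%s' over %d subsets\n",
              x$metric_name, nrow(x$values)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s %.3f +/- %.3f\n", s$method[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Paired significance comparison of two methods over subsets
#'
#' Each method's per-subset metric values are first checked for normality
#' with the Anderson-Darling test; if both pass, a Student's t-test on the
#' paired values is used, otherwise the Wilcoxon rank-sum test (the paired
#' signed-rank variant is available via `paired_wilcoxon = TRUE`). The
#' verdict direction comes from the column means; the difference is called
#' significant when the p-value is below `alpha_sig`.
#'
#' @param matrix A `dbr_metric_matrix` (or a plain numeric matrix with named
#'   columns).
#' @param method_a,method_b Column names to compare.
#' @param alpha_normality Significance level of the normality gate
#'   (default 0.05).
#' @param alpha_sig Significance level of the comparison (default 0.01).
#' @param paired_wilcoxon Use the Wilcoxon signed-rank test on paired
#'   differences instead of the rank-sum test (default FALSE).
#' @return List with `p_value`, `test_used` (`"t"` or `"wilcoxon"`), and
#'   `verdict` (`"a_better"`, `"b_better"` or `"no_difference"`).
#' @export
compare_methods <- function(matrix, method_a, method_b,
                            alpha_normality = 0.05, alpha_sig = 0.01,
                            paired_wilcoxon = FALSE) {
  values <- if (inherits(matrix, "dbr_metric_matrix")) matrix$values else matrix
  stopifnot(all(c(method_a, method_b) %in% colnames(values)))
  a <- values[, method_a]; b <- values[, method_b]
  if (length(a) < 2L) stop("need at least 2 draws to compare methods")
  if (isTRUE(all.equal(a, b))) {
    return(list(p_value = 1, test_used = "none", verdict = "no_difference"))
  }
  normal <- function(x) {
    ## ad.test needs n > 7 and non-constant data
    if (length(x) < 8L || stats::sd(x) == 0) return(FALSE)
    nortest::ad.test(x)$p.value > alpha_normality
  }
  if (normal(a) && normal(b)) {
    test_used <- "t"
    p <- stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    test_used <- "wilcoxon"
    p <- if (paired_wilcoxon) {
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
  }
  verdict <- if (p >= alpha_sig) {
    "no_difference"
  } else if (mean(a) > mean(b)) "a_better" else "b_better"
  list(p_value = p, test_used = test_used, verdict = verdict)
}
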