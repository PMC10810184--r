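#' Per-residue sequence distance to the nearest native DNA-binding residue
#'
#' Distances are computed within a single protein (no cross-protein
#' adjacency); DNA-labelled residues have distance 0.
#'
#' @param labels Character vector of residue labels for one protein; must
#'   contain at least one `"DNA"` residue.
#' @return Integer vector of distances.
#' @export
dbr_distances <- function(labels) {
  labels <- as.character(labels)
  L <- length(labels)
  if (!any(labels == "DNA")) stop("protein has no DNA-labelled residues; distances undefined")
  d <- rep.int(L, L)
  d[labels == "DNA"] <- 0L
  for (i in seq_len(L)[-1L]) d[i] <- min(d[i], d[i - 1L] + 1L)
  for (i in rev(seq_len(L))[-1L]) d[i] <- min(d[i], d[i + 1L] + 1L)
  as.integer(d)
}

## Pool distances and calls over the proteins that carry >= 1 native DBR;
## proteins without one are skipped (distance undefined there).
pool_proximity <- function(dataset, calls) {
  stopifnot(inherits(dataset, "dbr_dataset"), is.list(calls))
  ids <- names(dataset$proteins)
  keep <- ids[vapply(dataset$proteins, function(p) any(p$labels == "DNA"), logical(1))]
  if (!length(keep)) stop("no protein has DNA-labelled residues")
  skipped <- setdiff(ids, keep)
  if (length(skipped)) {
    message(sprintf("proximity analysis: skipping %d protein(s) without native DBRs",
                    length(skipped)))
  }
  dist <- integer(0); call <- logical(0)
  for (pid in keep) {
    p <- dataset$proteins[[pid]]
    v <- calls[[pid]]
    if (is.null(v) || length(v) != length(p$labels)) {
      stop(sprintf("calls missing or wrong length for protein '%s'", pid))
    }
    dist <- c(dist, dbr_distances(p$labels))
    call <- c(call, as.logical(v))
  }
  list(dist = dist, call = call, n_pos = sum(dist == 0L))
}

#' Tolerant true-positive rate as a function of distance to native DBRs
#'
#' Counts a predicted DNA-binding residue as correct when it lies within `x`
#' sequence positions of a native DBR: `TPR(x) = TP(x) / P` where `TP(x)` is
#' the number of positive calls at distance at most `x`, pooled over the
#' proteins with at least one native DBR, and `P` is the number of native
#' DBRs in those proteins. `TPR(0)` is the ordinary TPR. The value is not
#' capped at 1 and the denominator stays `P`, so it can exceed 1 for large
#' `x` when many near-miss predictions cluster around few native residues.
#'
#' @param dataset A [dbr_dataset].
#' @param calls Named list of logical (or 0/1) per-residue call vectors,
#'   keyed by protein id.
#' @param x_max Largest tolerance (default 5).
#' @return An object of class `dbr_proximity`: list with `x` (0..`x_max`),
#'   `tpr_at`, `positive_rate` (fraction of pooled residues called positive)
#'   and `n_pos`.
#' @export
tolerant_tpr_curve <- function(dataset, calls, x_max = 5L) {
  pooled <- pool_proximity(dataset, calls)
  x <- 0:x_max
  tpr_at <- vapply(x, function(k) sum(pooled$call & pooled$dist <= k) / pooled$n_pos,
                   numeric(1))
  structure(list(x = x, tpr_at = tpr_at,
                 positive_rate = mean(pooled$call), n_pos = pooled$n_pos),
            class = "dbr_proximity")
}

#' @export
print.dbr_proximity <- function(x, ...) {
  cat(sprintf("<dbr_proximity> P = %d, positive rate = %.4f\n",
              x$n_pos, x$positive_rate))
  df <- data.frame(x = x$x, tpr = round(x$tpr_at, 4))
  if (!is.null(x$baseline_at)) df$baseline <- round(x$baseline_at, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rate-matched random baseline for the tolerant-TPR curve
#'
#' Calls residues positive i.i.d. at the method's observed positive rate and
#' computes the tolerant TPR identically, averaged over `n_reps` seeded
#' replicates. The excess of a method's x = 0 to 1 increment over this
#' baseline's is the diagnostic for false positives clustering next to
#' native DBRs.
#'
#' @param dataset A [dbr_dataset].
#' @param positive_rate Probability of calling a residue positive, in
#'   (0, 1\].
#' @param x_max Largest tolerance (default 5).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer RNG seed.
#' @return Numeric vector of baseline TPR values for x = 0..`x_max`.
#' @export
random_baseline_curve <- function(dataset, positive_rate, x_max = 5L,
                                  n_reps = 100L, seed = 1L) {
  stopifnot(positive_rate > 0, positive_rate <= 1, n_reps >= 1L)
  ids <- names(dataset$proteins)
  keep <- ids[vapply(dataset$proteins, function(p) any(p$labels == "DNA"), logical(1))]
  if (!length(keep)) stop("no protein has DNA-labelled residues")
  dist <- unlist(lapply(dataset$proteins[keep],
                        function(p) dbr_distances(p$labels)), use.names = FALSE)
  n_pos <- sum(dist == 0L)
  n_le <- vapply(0:x_max, function(k) sum(dist <= k), integer(1))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  acc <- numeric(x_max + 1L)
  for (r in seq_len(n_reps)) {
    call <- stats::runif(length(dist)) < positive_rate
    dc <- dist[call]
    acc <- acc + vapply(0:x_max, function(k) sum(dc <= k), numeric(1)) / n_pos
  }
  acc / n_reps
}

#' Full proximity analysis for one set of binary predictions
#'
#' Combines [tolerant_tpr_curve] with its rate-matched [random_baseline_curve]
#' and the per-step relative increments
#' `(TPR(x + 1) - TPR(x)) / TPR(x)`.
#'
#' @inheritParams tolerant_tpr_curve
#' @param n_reps,seed Passed to [random_baseline_curve].
#' @return A `dbr_proximity` object with additional fields `baseline_at`,
#'   `rel_increase` and `baseline_rel_increase`.
#' @export
proximity_curve <- function(dataset, calls, x_max = 5L, n_reps = 100L, seed = 1L) {
  curve <- tolerant_tpr_curve(dataset, calls, x_max = x_max)
  curve$baseline_at <- random_baseline_curve(dataset, curve$positive_rate,
                                             x_max = x_max, n_reps = n_reps,
                                             seed = seed)
  curve$rel_increase <- relative_increase(curve$tpr_at)
  curve$baseline_rel_increase <- relative_increase(curve$baseline_at)
  curve
}

#' Relative step-to-step increase of a tolerant-TPR curve
#'
#' @param tpr Numeric vector of TPR values at consecutive tolerances.
#' @return `(tpr[k + 1] - tpr[k]) / tpr[k]` for each consecutive pair.
#' @export
relative_increase <- function(tpr) {
  diff(tpr) / utils::head(tpr, -1L)
}
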