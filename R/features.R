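AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Per-residue amino-acid scales (order: ACDEFGHIKLMNPQRSTVWY).
## polarizability: Charton & Charton; charge: side-chain charge at neutral pH
## (His partial); hydrophilicity: Hopp & Woods; disorder_propensity: TOP-IDP;
## hydrophobicity: Kyte & Doolittle.
AA_SCALES_RAW <- list(
  polarizability = c(0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186,
                     0.219, 0.186, 0.221, 0.134, 0.131, 0.180, 0.291, 0.062,
                     0.108, 0.140, 0.409, 0.298),
  charge = c(0, 0, -1, -1, 0, 0, 0.1, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
  hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                     -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
  disorder_propensity = c(0.060, 0.020, 0.192, 0.736, -0.697, 0.166, 0.303,
                          -0.486, 0.586, -0.326, -0.397, 0.007, 0.987, 0.318,
                          0.180, 0.341, 0.059, -0.121, -0.884, -0.510),
  hydrophobicity = c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                     1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
)

#' Amino-acid scale tables used by the feature builder
#'
#' Each scale is min-max normalized to \[0, 1\] over the 20-letter alphabet;
#' the unknown residue `X` maps to the alphabet mean of the normalized scale.
#'
#' @return Named list of numeric vectors of length 21 (20 amino acids plus
#'   `X`), values in \[0, 1\].
#' @export
aa_scales <- function() {
  lapply(AA_SCALES_RAW, function(v) {
    z <- (v - min(v)) / (max(v) - min(v))
    names(z) <- AA_ALPHABET
    c(z, X = mean(z))
  })
}

#' Per-residue values of the physicochemical scale features
#'
#' @param sequence Amino-acid string (normalized as by [read_fasta]; `X`
#'   allowed).
#' @param scales Character vector of scale names (subset of
#'   `names(aa_scales())`).
#' @return Numeric matrix, one row per residue, one column per scale.
#' @export
scale_features <- function(sequence, scales = names(AA_SCALES_RAW)) {
  tabs <- aa_scales()
  bad <- setdiff(scales, names(tabs))
  if (length(bad)) stop(sprintf("unknown scale name(s): %s", paste(bad, collapse = ", ")))
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% c(AA_ALPHABET, "X"))) {
    stop("sequence contains characters outside the normalized alphabet")
  }
  out <- vapply(scales, function(sc) unname(tabs[[sc]][res]), numeric(length(res)))
  matrix(out, nrow = length(res), dimnames = list(NULL, scales))
}

#' Aggregate disorder-segment features (group 3)
#'
#' Summarizes a per-residue disorder track over centered sequence segments of
#' several lengths, targeting the detection of intrinsically disordered
#' regions: for each segment length the windowed mean of the track and the
#' windowed fraction of values above 0.5 are computed, truncating segments at
#' the termini.
#'
#' @param track Numeric per-residue vector in \[0, 1\].
#' @param segments Odd segment lengths (default `seq(5, 41, by = 4)`, ten
#'   lengths).
#' @param stats Statistics per segment, subset of `c("mean", "frac_gt_half")`.
#' @return Numeric matrix, one row per residue, `length(segments) *
#'   length(stats)` columns (segment-major order).
#' @export
aggregate_disorder_features <- function(track, segments = seq(5L, 41L, by = 4L),
                                        stats = c("mean", "frac_gt_half")) {
  stopifnot(is.numeric(track), all(is.finite(track)))
  stats <- match.arg(stats, c("mean", "frac_gt_half"), several.ok = TRUE)
  if (any(segments %% 2L == 0L)) stop("segment lengths must be odd")
  L <- length(track)
  win_mean <- function(v, s) {
    h <- (s - 1L) %/% 2L
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(L) - h, 1L)
    hi <- pmin(seq_len(L) + h, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  cols <- list()
  for (s in segments) {
    for (st in stats) {
      nm <- sprintf("g3.s%d.%s", s, st)
      cols[[nm]] <- if (st == "mean") win_mean(track, s) else win_mean(as.numeric(track > 0.5), s)
    }
  }
  matrix(unlist(cols), nrow = L, dimnames = list(NULL, names(cols)))
}

#' Sliding-window expansion of per-residue features
#'
#' Concatenates, for every residue, the feature vectors of its neighbours at
#' offsets `-(w-1)/2 ... +(w-1)/2`. Positions beyond the termini contribute
#' zero vectors.
#'
#' @param mat Numeric matrix, one row per residue.
#' @param window Odd window width.
#' @return Matrix with `ncol(mat) * window` columns, ordered offset-major
#'   (offset `-h` block first), names `w<offset>.<feature>`.
#' @export
windowed_profile <- function(mat, window = 15L) {
  stopifnot(is.matrix(mat), window %% 2L == 1L, window >= 1L)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("f%d", seq_len(ncol(mat)))
  L <- nrow(mat); k <- ncol(mat); h <- (window - 1L) %/% 2L
  out <- matrix(0, nrow = L, ncol = k * window)
  nms <- character(k * window)
  for (j in seq_len(window)) {
    off <- j - 1L - h
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    cols <- (j - 1L) * k + seq_len(k)
    out[ok, cols] <- mat[src[ok], , drop = FALSE]
    nms[cols] <- sprintf("w%+d.%s", off, colnames(mat))
  }
  colnames(out) <- nms
  out
}

#' Configuration of the per-residue feature profile
#'
#' The profile has three groups: (1) the base predictors' propensity tracks;
#' (2) physicochemical scales plus two auxiliary predicted tracks (relative
#' solvent accessibility and disorder probability); groups 1+2 are expanded
#' with a sliding window. Group (3) holds aggregate disorder-segment
#' features computed from the disorder track. Under the defaults (3 tracks +
#' 5 scales + 2 aux = 10 windowed features, window 15, 10 segment lengths x 2
#' statistics = 20 aggregates) each residue maps to 150 + 20 = 170 values.
#'
#' @param window Odd sliding-window width (default 15).
#' @param group1_predictors Ordered predictor ids, or `NULL` to use all
#'   tracks present in the dataset (in their stored order).
#' @param group2_scales Scale names (see [aa_scales]).
#' @param aux_tracks Names of the auxiliary tracks used as features (default
#'   `c("rsa", "disorder")`). When a named track is absent from the dataset a
#'   scale-derived fallback is used: a smoothed disorder-propensity scale for
#'   `"disorder"` and a smoothed inverted hydrophobicity scale for `"rsa"`.
#' @param group3_track Name of the disorder track feeding group 3 (default
#'   `"disorder"`, same fallback).
#' @param group3_segments,group3_stats Segment lengths and statistics for
#'   [aggregate_disorder_features].
#' @param use_group3 Include group 3 (default TRUE; the ablation switch
#'   `no_group3` clears it).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(window = 15L, group1_predictors = NULL,
                           group2_scales = c("polarizability", "charge",
                                             "hydrophilicity",
                                             "disorder_propensity",
                                             "hydrophobicity"),
                           aux_tracks = c("rsa", "disorder"),
                           group3_track = "disorder",
                           group3_segments = seq(5L, 41L, by = 4L),
                           group3_stats = c("mean", "frac_gt_half"),
                           use_group3 = TRUE) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  structure(list(window = as.integer(window),
                 group1_predictors = group1_predictors,
                 group2_scales = group2_scales, aux_tracks = aux_tracks,
                 group3_track = group3_track,
                 group3_segments = as.integer(group3_segments),
                 group3_stats = group3_stats,
                 use_group3 = isTRUE(use_group3)),
            class = "feature_config")
}

## Smoothed-scale fallbacks for missing auxiliary tracks, so the feature
## builder works from sequence alone.
fallback_aux_track <- function(name, sequence) {
  base <- switch(name,
    disorder = scale_features(sequence, "disorder_propensity")[, 1L],
    rsa = 1 - scale_features(sequence, "hydrophobicity")[, 1L],
    stop(sprintf("no fallback defined for aux track '%s'", name))
  )
  as.numeric(aggregate_disorder_features(base, segments = 21L, stats = "mean"))
}

## Resolve one auxiliary per-residue track for one protein.
aux_track_for <- function(dataset, name, pid) {
  v <- dataset$aux_tracks[[name]][[pid]]
  if (is.null(v)) fallback_aux_track(name, dataset$proteins[[pid]]$sequence) else v
}

#' Build per-residue feature profiles for every protein in a dataset
#'
#' @param dataset A [dbr_dataset] carrying the group-1 prediction tracks and
#'   (optionally) the auxiliary tracks.
#' @param config A [feature_config].
#' @return Named list of numeric matrices (one per protein, rows =
#'   residues); all matrices share the same column names, also attached as
#'   `attr(, "column_names")` on the list. Column order is `[windowed
#'   groups 1+2 | group 3]` and deterministic given the configuration.
#' @export
build_profiles <- function(dataset, config = feature_config()) {
  stopifnot(inherits(dataset, "dbr_dataset"), inherits(config, "feature_config"))
  preds <- config$group1_predictors
  if (is.null(preds)) preds <- names(dataset$tracks)
  if (is.null(preds) || length(preds) == 0L) stop("no group-1 predictor tracks")
  missing_trk <- setdiff(preds, names(dataset$tracks))
  if (length(missing_trk)) {
    stop(sprintf("dataset lacks track(s): %s", paste(missing_trk, collapse = ", ")))
  }
  profiles <- lapply(names(dataset$proteins), function(pid) {
    p <- dataset$proteins[[pid]]
    L <- nchar(p$sequence)
    g1 <- vapply(preds, function(tr) {
      v <- dataset$tracks[[tr]][[pid]]
      if (is.null(v)) stop(sprintf("track '%s' missing for protein '%s'", tr, pid))
      v
    }, numeric(L))
    g1 <- matrix(g1, nrow = L, dimnames = list(NULL, preds))
    g2s <- scale_features(p$sequence, config$group2_scales)
    g2a <- vapply(config$aux_tracks, function(nm) aux_track_for(dataset, nm, pid),
                  numeric(L))
    g2a <- matrix(g2a, nrow = L, dimnames = list(NULL, paste0("aux.", config$aux_tracks)))
    win <- windowed_profile(cbind(g1, g2s, g2a), config$window)
    if (config$use_group3) {
      g3 <- aggregate_disorder_features(
        aux_track_for(dataset, config$group3_track, pid),
        segments = config$group3_segments, stats = config$group3_stats)
      cbind(win, g3)
    } else {
      win
    }
  })
  names(profiles) <- names(dataset$proteins)
  attr(profiles, "column_names") <- colnames(profiles[[1L]])
  profiles
}
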