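#' @keywords internal
"_PACKAGE"

## Residue label and annotation-source vocabularies used throughout the package.
DBR_LABELS <- c("DNA", "OTHER", "NONE")
DBR_SOURCES <- c("STRUCTURE", "DISORDER")

#' Construct a per-protein record of sequence and binding annotations
#'
#' A protein record holds an amino-acid sequence together with a ternary
#' per-residue binding annotation (`"DNA"`, `"OTHER"` for non-DNA ligands,
#' `"NONE"` for non-binding) and the annotation source of the protein:
#' `"STRUCTURE"` (binding sites mapped from solved protein-DNA complexes) or
#' `"DISORDER"` (binding regions annotated in intrinsically disordered
#' proteins). The protein class is derived: a protein is DNA-binding iff it
#' carries at least one DNA-labelled residue.
#'
#' @param id Unique protein identifier.
#' @param sequence Amino-acid string (20-letter alphabet; `X` allowed).
#' @param labels Character vector of per-residue labels, one of
#'   `"DNA"`, `"OTHER"`, `"NONE"`; length must equal `nchar(sequence)`.
#' @param source Annotation source, `"STRUCTURE"` or `"DISORDER"`.
#' @return An object of class `protein_record`: a list with elements `id`,
#'   `sequence`, `labels`, `source` and the derived `protein_class`
#'   (`"DNA_BINDING"` or `"OTHER_BINDING"`).
#' @export
protein_record <- function(id, sequence, labels, source) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  labels <- as.character(labels)
  if (length(labels) != nchar(sequence)) {
    stop(sprintf("protein '%s': %d labels for a sequence of length %d",
                 id, length(labels), nchar(sequence)))
  }
  bad <- setdiff(unique(labels), DBR_LABELS)
  if (length(bad)) {
    stop(sprintf("protein '%s': unknown label token(s): %s",
                 id, paste(bad, collapse = ", ")))
  }
  source <- match.arg(source, DBR_SOURCES)
  structure(
    list(id = id, sequence = sequence, labels = labels, source = source,
         protein_class = if (any(labels == "DNA")) "DNA_BINDING" else "OTHER_BINDING"),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s, %s): %d aa, %d DNA / %d OTHER / %d NONE\n",
              x$id, x$source, x$protein_class, nchar(x$sequence),
              sum(x$labels == "DNA"), sum(x$labels == "OTHER"),
              sum(x$labels == "NONE")))
  invisible(x)
}

#' Assemble proteins, prediction tracks and auxiliary tracks into a dataset
#'
#' A `dbr_dataset` bundles protein records with per-residue propensity tracks
#' from one or more base predictors and optional auxiliary tracks (e.g.
#' predicted disorder or relative solvent accessibility). All tracks are
#' checked for length consistency against the protein sequences.
#'
#' @param proteins List of [protein_record] objects (names are taken from the
#'   records' ids).
#' @param tracks Nested list `tracks[[predictor_id]][[protein_id]]` of numeric
#'   per-residue propensity vectors, or `NULL`.
#' @param aux_tracks Nested list `aux_tracks[[track_name]][[protein_id]]` of
#'   numeric per-residue vectors in any range, or `NULL`.
#' @return An object of class `dbr_dataset`.
#' @export
dbr_dataset <- function(proteins, tracks = NULL, aux_tracks = NULL) {
  stopifnot(is.list(proteins), length(proteins) > 0L)
  ok <- vapply(proteins, inherits, logical(1), "protein_record")
  if (!all(ok)) stop("all elements of 'proteins' must be protein_record objects")
  ids <- vapply(proteins, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate protein id: %s", ids[duplicated(ids)][1L]))
  }
  names(proteins) <- ids
  lens <- vapply(proteins, function(p) nchar(p$sequence), integer(1))
  check_tracks <- function(trk, what) {
    if (is.null(trk)) return(invisible(NULL))
    for (tn in names(trk)) {
      for (pid in names(trk[[tn]])) {
        if (!pid %in% ids) {
          stop(sprintf("%s '%s' refers to unknown protein '%s'", what, tn, pid))
        }
        v <- trk[[tn]][[pid]]
        if (!is.numeric(v) || length(v) != lens[[pid]]) {
          stop(sprintf("%s '%s' for protein '%s': length %d, expected %d",
                       what, tn, pid, length(v), lens[[pid]]))
        }
        if (any(!is.finite(v))) {
          stop(sprintf("%s '%s' for protein '%s' contains non-finite values",
                       what, tn, pid))
        }
      }
    }
  }
  check_tracks(tracks, "track")
  check_tracks(aux_tracks, "aux track")
  structure(list(proteins = proteins, tracks = tracks, aux_tracks = aux_tracks),
            class = "dbr_dataset")
}

#' @export
print.dbr_dataset <- function(x, ...) {
  lens <- vapply(x$proteins, function(p) nchar(p$sequence), integer(1))
  lab <- unlist(lapply(x$proteins, `[[`, "labels"), use.names = FALSE)
  src <- vapply(x$proteins, `[[`, character(1), "source")
  cls <- vapply(x$proteins, `[[`, character(1), "protein_class")
  cat(sprintf("<dbr_dataset> %d proteins (%d DNA-binding), %d residues\n",
              length(x$proteins), sum(cls == "DNA_BINDING"), sum(lens)))
  cat(sprintf("  sources: %d STRUCTURE / %d DISORDER\n",
              sum(src == "STRUCTURE"), sum(src == "DISORDER")))
  cat(sprintf("  residues: %.2f%% DNA, %.2f%% other-ligand, %.2f%% non-binding\n",
              100 * mean(lab == "DNA"), 100 * mean(lab == "OTHER"),
              100 * mean(lab == "NONE")))
  if (!is.null(x$tracks)) {
    cat(sprintf("  prediction tracks: %s\n", paste(names(x$tracks), collapse = ", ")))
  }
  if (!is.null(x$aux_tracks)) {
    cat(sprintf("  aux tracks: %s\n", paste(names(x$aux_tracks), collapse = ", ")))
  }
  invisible(x)
}

## Pooled per-residue labels for a set of proteins, in protein order.
pooled_labels <- function(dataset, ids = names(dataset$proteins)) {
  unlist(lapply(dataset$proteins[ids], `[[`, "labels"), use.names = FALSE)
}

#' Per-protein residue labels of a dataset
#'
#' Convenience accessor pairing with [build_profiles] when fitting or
#' evaluating models: returns the ternary label vectors keyed by protein id.
#'
#' @param dataset A [dbr_dataset].
#' @param ids Protein ids to include (default all).
#' @return Named list of character vectors.
#' @export
dataset_labels <- function(dataset, ids = names(dataset$proteins)) {
  stopifnot(inherits(dataset, "dbr_dataset"))
  lapply(dataset$proteins[ids], `[[`, "labels")
}

## Pooled per-residue scores of one predictor over a set of proteins.
pooled_scores <- function(dataset, predictor_id, ids = names(dataset$proteins)) {
  trk <- dataset$tracks[[predictor_id]]
  if (is.null(trk)) stop(sprintf("no track '%s' in dataset", predictor_id))
  missing <- setdiff(ids, names(trk))
  if (length(missing)) {
    stop(sprintf("track '%s' missing for protein(s): %s", predictor_id,
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  unlist(trk[ids], use.names = FALSE)
}
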