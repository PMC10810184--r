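#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and any character outside the 20-letter amino
#' acid alphabet is mapped to `X`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, names are record ids (the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(aa), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1L]))
  }
  seqs <- toupper(as.character(aa))
  seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read per-residue binding annotations
#'
#' The annotation file is a TSV with columns `protein_id`, `position`
#' (1-based), `label` (`DNA` or `OTHER`) and `source` (`STRUCTURE` or
#' `DISORDER`; constant within a protein). Positions not listed default to
#' `NONE` (non-binding). Every sequence in `sequences` yields one protein
#' record; proteins without rows get all-`NONE` labels and need a `source`
#' entry in `default_source`.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Named character vector of sequences (as from
#'   [read_fasta]).
#' @param default_source Either a single source used for proteins without
#'   annotation rows, or a named character vector keyed by protein id.
#' @return A list of [protein_record] objects.
#' @export
read_annotations <- function(path, sequences, default_source = "STRUCTURE") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label", "source")
  if (!all(need %in% names(df))) {
    stop(sprintf("annotation TSV must have columns: %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(df$label), c("DNA", "OTHER"))
  if (length(bad)) stop(sprintf("unknown label token(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(df$source), DBR_SOURCES)
  if (length(bad)) stop(sprintf("unknown source token(s): %s", paste(bad, collapse = ", ")))
  unknown <- setdiff(unique(df$protein_id), names(sequences))
  if (length(unknown)) {
    stop(sprintf("annotation rows for unknown protein(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  get_source <- function(pid) {
    if (length(default_source) == 1L && is.null(names(default_source))) {
      default_source
    } else if (pid %in% names(default_source)) {
      default_source[[pid]]
    } else {
      stop(sprintf("no source for unannotated protein '%s'", pid))
    }
  }
  rows_by_pid <- split(df, df$protein_id)
  lapply(names(sequences), function(pid) {
    len <- nchar(sequences[[pid]])
    labels <- rep("NONE", len)
    src <- NULL
    rows <- rows_by_pid[[pid]]
    if (!is.null(rows)) {
      if (any(rows$position < 1L | rows$position > len)) {
        bad_pos <- rows$position[rows$position < 1L | rows$position > len][1L]
        stop(sprintf("protein '%s': position %d outside sequence of length %d",
                     pid, bad_pos, len))
      }
      labels[rows$position] <- rows$label
      src <- unique(rows$source)
      if (length(src) != 1L) {
        stop(sprintf("protein '%s': inconsistent source annotations", pid))
      }
    } else {
      src <- get_source(pid)
    }
    protein_record(pid, sequences[[pid]], labels, src)
  })
}

#' Write per-residue binding annotations
#'
#' Inverse of [read_annotations]: emits one row per DNA- or OTHER-labelled
#' residue; `NONE` residues are implicit.
#'
#' @param proteins List of [protein_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(proteins, path) {
  rows <- lapply(proteins, function(p) {
    keep <- which(p$labels != "NONE")
    if (!length(keep)) return(NULL)
    data.frame(protein_id = p$id, position = keep, label = p$labels[keep],
               source = p$source, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(protein_id = character(), position = integer(),
                     label = character(), source = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue prediction tracks
#'
#' The prediction file is a TSV with columns `protein_id`, `position`
#' (1-based), `residue`, `propensity` and optionally `call` (0/1). The
#' residue column is validated against the protein sequence.
#'
#' @param path Path to the prediction TSV.
#' @param dataset A [dbr_dataset] providing the sequences.
#' @param predictor_id Identifier to attach to the returned tracks.
#' @return A list with elements `propensities` (named list of numeric vectors
#'   per protein), `calls` (named list of 0/1 integer vectors, or `NULL` when
#'   the file has no call column) and `predictor_id`.
#' @export
read_prediction_tsv <- function(path, dataset, predictor_id = "predictor") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "propensity")
  if (!all(need %in% names(df))) {
    stop(sprintf("prediction TSV must have columns: %s", paste(need, collapse = ", ")))
  }
  has_calls <- "call" %in% names(df)
  props <- list(); calls <- list()
  for (pid in unique(df$protein_id)) {
    p <- dataset$proteins[[pid]]
    if (is.null(p)) stop(sprintf("prediction rows for unknown protein '%s'", pid))
    rows <- df[df$protein_id == pid, , drop = FALSE]
    len <- nchar(p$sequence)
    if (nrow(rows) != len || !setequal(rows$position, seq_len(len))) {
      stop(sprintf("protein '%s': predictions must cover positions 1..%d exactly",
                   pid, len))
    }
    rows <- rows[order(rows$position), , drop = FALSE]
    seq_res <- strsplit(p$sequence, "")[[1]]
    mism <- which(rows$residue != seq_res)
    if (length(mism)) {
      stop(sprintf("protein '%s': residue mismatch at position %d ('%s' in file, '%s' in sequence)",
                   pid, mism[1L], rows$residue[mism[1L]], seq_res[mism[1L]]))
    }
    props[[pid]] <- rows$propensity
    if (has_calls) calls[[pid]] <- as.integer(rows$call)
  }
  list(predictor_id = predictor_id, propensities = props,
       calls = if (has_calls) calls else NULL)
}

#' Write per-residue prediction tracks
#'
#' Propensities are written with full double precision (17 significant
#' digits) so a write/read round trip is lossless. When `threshold` is given,
#' a binary `call` column (`propensity > threshold`) is added.
#'
#' @param propensities Named list of numeric per-residue vectors per protein.
#' @param dataset A [dbr_dataset] providing the sequences.
#' @param path Output path.
#' @param threshold Optional numeric threshold used to derive binary calls.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(propensities, dataset, path, threshold = NULL) {
  rows <- lapply(names(propensities), function(pid) {
    p <- dataset$proteins[[pid]]
    if (is.null(p)) stop(sprintf("unknown protein '%s'", pid))
    v <- propensities[[pid]]
    df <- data.frame(protein_id = pid, position = seq_along(v),
                     residue = strsplit(p$sequence, "")[[1]],
                     propensity = sprintf("%.17g", v),
                     stringsAsFactors = FALSE)
    if (!is.null(threshold)) df$call <- as.integer(v > threshold)
    df
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
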