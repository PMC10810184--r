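# Shared fixtures and independent oracles, built in code.

# Hand-sized labelled dataset with both sources and both protein classes.
tiny_dataset <- function() {
  p <- list(
    protein_record("d_s1", "MKVLNNACQW", c("NONE","DNA","DNA","NONE","NONE",
                                           "OTHER","NONE","NONE","NONE","NONE"),
                   "STRUCTURE"),
    protein_record("d_s2", "ACDEFGHIKL", c("DNA","NONE","NONE","NONE","OTHER",
                                           "OTHER","NONE","NONE","NONE","DNA"),
                   "STRUCTURE"),
    protein_record("d_d1", "PPPQQSSTTA", c("NONE","NONE","DNA","DNA","DNA",
                                           "NONE","NONE","NONE","OTHER","NONE"),
                   "DISORDER"),
    protein_record("d_d2", "GGHHIIKKLL", c("NONE","DNA","NONE","NONE","NONE",
                                           "NONE","OTHER","NONE","NONE","NONE"),
                   "DISORDER"),
    protein_record("o_s1", "MMNNPPQQRR", c("NONE","NONE","OTHER","OTHER","NONE",
                                           "NONE","NONE","NONE","NONE","NONE"),
                   "STRUCTURE"),
    protein_record("o_s2", "AACCEEGGII", c("OTHER","NONE","NONE","NONE","NONE",
                                           "NONE","NONE","OTHER","NONE","NONE"),
                   "STRUCTURE"),
    protein_record("o_d1", "LLMMNNPPSS", c("NONE","NONE","NONE","OTHER","NONE",
                                           "NONE","NONE","NONE","NONE","NONE"),
                   "DISORDER"),
    protein_record("o_d2", "TTVVWWYYAA", c("NONE","OTHER","NONE","NONE","NONE",
                                           "NONE","OTHER","NONE","NONE","NONE"),
                   "DISORDER")
  )
  dbr_dataset(p)
}

# Attach label-independent uniform-random tracks for the named methods.
with_random_tracks <- function(dataset, methods, seed) {
  set.seed(seed)
  tracks <- lapply(stats::setNames(methods, methods), function(m) {
    lapply(dataset$proteins, function(p) stats::runif(nchar(p$sequence)))
  })
  dbr_dataset(dataset$proteins, tracks = tracks,
              aux_tracks = dataset$aux_tracks)
}

# Brute-force AUC oracle: concordant-pair counting with ties scoring 1/2.
brute_auc <- function(labels, scores) {
  pos <- which(labels == "DNA")
  neg <- which(labels != "DNA")
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
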