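# Meta-predictor benchmark: complementary tracks informative on only one
# annotation source each, so no single track does well on the combined set.
benchmark_track_configs <- function() {
  list(
    struct_t = track_sim_config("structure_trained", d_struct = 1.6, d_dis = 0,
                                cross_shift = 0.3),
    diso_t = track_sim_config("disorder_trained", d_struct = 0, d_dis = 1.6,
                              cross_shift = 0.3),
    weak_t = track_sim_config("structure_trained", d_struct = 0.6, d_dis = 0.3,
                              cross_shift = 0.3)
  )
}

# Training configuration sized for the desk-scale benchmark (see the methods
# vignette): small batches and a raised learning rate so full-batch Adam
# converges within tens of epochs on a few thousand residues.
benchmark_model_config <- function(seed, ...) {
  model_config(lr = 3e-3, batch_size = 8, pos_weight = 6, max_epochs = 45,
               patience = 12, seed = seed, ...)
}

# Stratified protein split: 1/2 train, 1/4 validation, 1/4 test within each
# protein-class x source stratum.
benchmark_split <- function(dataset, seed) {
  cls <- vapply(dataset$proteins, `[[`, character(1), "protein_class")
  src <- vapply(dataset$proteins, `[[`, character(1), "source")
  set.seed(seed)
  split <- list(train = character(0), val = character(0), test = character(0))
  for (cl in unique(cls)) for (s in unique(src)) {
    ids <- sample(names(dataset$proteins)[cls == cl & src == s])
    n <- length(ids)
    n_tr <- ceiling(n / 2); n_va <- ceiling((n - n_tr) / 2)
    split$train <- c(split$train, ids[seq_len(n_tr)])
    split$val <- c(split$val, ids[n_tr + seq_len(n_va)])
    split$test <- c(split$test, ids[-seq_len(n_tr + n_va)])
  }
  split
}

make_meta_benchmark <- function(seed) {
  ds <- generate_dataset(sim_config(n_dna_proteins = 18, n_other_proteins = 42,
                                    dbr_fraction = 0.04,
                                    length_meanlog = log(150), length_sdlog = 0.3,
                                    seed = seed))
  ds <- simulate_tracks(ds, benchmark_track_configs(), seed = seed + 1000L)
  list(ds = ds, split = benchmark_split(ds, seed + 2000L),
       labs = dataset_labels(ds))
}

# Fit one configuration on a benchmark and return its test-set AUC.
benchmark_fit_auc <- function(bench, feature, model) {
  prof <- build_profiles(bench$ds, feature)
  m <- dbr_transformer(prof[bench$split$train], bench$labs[bench$split$train],
                       prof[bench$split$val], bench$labs[bench$split$val],
                       model)
  p <- predict(m, prof[bench$split$test])
  truth <- unlist(bench$labs[bench$split$test], use.names = FALSE) == "DNA"
  auc_fast(truth, unlist(p, use.names = FALSE))
}

auc_fast <- function(y, s) {
  nP <- sum(y); nN <- sum(!y)
  r <- rank(s)
  (sum(r[y]) - nP * (nP + 1) / 2) / (nP * nN)
}
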