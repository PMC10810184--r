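# Small learnable task: one group-1 track equals the label plus mild noise.
make_easy_task <- function(n_prot = 28, len = 60, seed = 1) {
  set.seed(seed)
  prots <- lapply(seq_len(n_prot), function(i) {
    lab <- rep("NONE", len)
    lab[sample(len, round(0.15 * len))] <- "DNA"
    protein_record(sprintf("p%02d", i),
                   paste(sample(c("A", "C", "D", "E"), len, TRUE), collapse = ""),
                   lab, if (i %% 3 == 0) "DISORDER" else "STRUCTURE")
  })
  names(prots) <- vapply(prots, `[[`, character(1), "id")
  tracks <- list(
    oracle = lapply(prots, function(p) 3 * (p$labels == "DNA") + rnorm(len, 0, 0.3)),
    noise = lapply(prots, function(p) rnorm(len))
  )
  ds <- dbr_dataset(prots, tracks = tracks)
  prof <- build_profiles(ds, feature_config(group1_predictors = names(tracks)))
  labs <- dataset_labels(ds)
  tr <- names(prots)[seq_len(round(0.7 * n_prot))]
  va <- setdiff(names(prots), tr)
  list(ds = ds, prof = prof, labs = labs, train = tr, val = va)
}

# training configuration sized for desk-scale fixtures
fast_config <- function(...) {
  model_config(lr = 3e-3, batch_size = 8, pos_weight = 6, ...)
}

test_that("parameter count matches the closed-form architecture formula", {
  for (cfg in list(model_config(),
                   model_config(n_blocks = 0L),
                   model_config(n_heads = 4L, ff_hidden = 32L),
                   model_config(d_model = 10L, head_dims = c(10L, 4L, 1L)))) {
    set.seed(1)
    p <- dbrmeta:::init_params(cfg, 170)
    expect_equal(n_parameters(cfg, 170), length(unlist(p)))
  }
  expect_error(model_config(d_model = 20, n_heads = 3), "divisible")
  expect_error(model_config(head_dims = c(10, 5, 1)), "head_dims")
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(n_blocks = 2L, ff_hidden = 8L, seed = 7)
  set.seed(7)
  params <- dbrmeta:::init_params(cfg, 12)
  X <- matrix(rnorm(9 * 12), 9, 12)
  y <- rbinom(9, 1, 0.3)
  for (loss in c("bce", "l1")) {
    cfg$loss <- loss
    lossfun <- function(pp) {
      fw <- dbrmeta:::forward_chunk(pp, X, cfg)
      dbrmeta:::chunk_loss_grad(fw$p, fw$logits, y, cfg)$loss
    }
    fw <- dbrmeta:::forward_chunk(params, X, cfg, keep_cache = TRUE)
    lg <- dbrmeta:::chunk_loss_grad(fw$p, fw$logits, y, cfg)
    g <- dbrmeta:::backward_chunk(params, fw$cache, lg$dlogit, cfg)
    set.seed(99)
    for (nm in sample(names(params), 8)) {
      i <- sample(length(params[[nm]]), 1)
      eps <- 1e-5
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-5,
                   label = sprintf("%s grad [%s]", loss, nm))
    }
  }
})

test_that("an untrained model sits at chance-level cross-entropy on balanced data", {
  cfg <- model_config(seed = 3)
  set.seed(3)
  params <- dbrmeta:::init_params(cfg, 30)
  X <- matrix(rnorm(200 * 30), 200, 30)
  y <- rep(c(0, 1), 100)
  fw <- dbrmeta:::forward_chunk(params, X, cfg)
  loss <- dbrmeta:::chunk_loss_grad(fw$p, fw$logits, y, cfg)$loss / 200
  expect_equal(loss, log(2), tolerance = 0.05)
})

test_that("training learns an easy signal, is seeded, and early-stops on the best epoch", {
  task <- make_easy_task()
  cfg <- fast_config(max_epochs = 20, patience = 20, seed = 5)
  m <- dbr_transformer(task$prof[task$train], task$labs[task$train],
                       task$prof[task$val], task$labs[task$val], cfg)
  ## training loss decreases over the first epochs
  expect_lt(m$training_log$train_loss[10], m$training_log$train_loss[1])
  ## held-out AUC on the easy task
  p <- predict(m, task$prof[task$val])
  truth <- unlist(task$labs[task$val], use.names = FALSE) == "DNA"
  expect_gt(dbrmeta:::auc_fast(truth, unlist(p, use.names = FALSE)), 0.95)
  ## the kept weights are the best-validation-epoch weights
  expect_equal(m$best_val_auc, max(m$training_log$val_auc))

  ## full reproducibility from the seed
  m2 <- dbr_transformer(task$prof[task$train], task$labs[task$train],
                        task$prof[task$val], task$labs[task$val], cfg)
  expect_identical(m$training_log, m2$training_log)
  expect_identical(coef(m), coef(m2))

  ## guard rails
  one_class <- lapply(task$labs[task$train], function(l) rep("NONE", length(l)))
  expect_error(dbr_transformer(task$prof[task$train], one_class,
                               task$prof[task$val], task$labs[task$val], cfg),
               "one class")
  expect_error(dbr_transformer(task$prof[task$train], task$labs[task$train],
                               task$prof[task$train[1]], task$labs[task$train[1]],
                               cfg),
               "disjoint")
})

test_that("prediction is stitched invisibly across chunks and thresholds calls", {
  task <- make_easy_task(n_prot = 10, len = 90, seed = 2)
  cfg <- fast_config(max_epochs = 3, patience = 3, chunk_len = 256, seed = 2)
  m <- dbr_transformer(task$prof[task$train], task$labs[task$train],
                       task$prof[task$val], task$labs[task$val], cfg)
  p <- predict(m, task$prof[1:3])
  expect_equal(lengths(p), lengths(task$labs[1:3]))
  expect_true(all(unlist(p) >= 0 & unlist(p) <= 1))
  ## proteins shorter than the chunk length: chunking cannot matter
  p128 <- predict(m, task$prof[1:3], chunk_len = 128)
  expect_identical(p, p128)
  ## calls derive from the calibrated threshold
  calls <- predict(m, task$prof[1:3], type = "call")
  expect_identical(calls[[1]], p[[1]] > m$calibrated_threshold)
  ## manifest mismatch is named
  bad <- task$prof[1:2]
  colnames(bad[[1]])[3] <- "bogus"
  colnames(bad[[2]])[3] <- "bogus"
  expect_error(predict(m, bad), "bogus")
})

test_that("threshold calibration lands at the target false positive rate", {
  task <- make_easy_task(n_prot = 16, len = 80, seed = 4)
  cfg <- fast_config(max_epochs = 8, patience = 8, seed = 4)
  m <- dbr_transformer(task$prof[task$train], task$labs[task$train],
                       task$prof[task$val], task$labs[task$val], cfg)
  thr <- calibrate_threshold(m, task$prof[task$val], task$labs[task$val],
                             target_fpr = 0.1)
  p <- unlist(predict(m, task$prof[task$val]), use.names = FALSE)
  truth <- unlist(task$labs[task$val], use.names = FALSE) == "DNA"
  fpr <- mean(p[!truth] > thr)
  expect_equal(fpr, 0.1, tolerance = 0.03)
  ## target 1: threshold below all scores
  expect_lt(calibrate_threshold(m, task$prof[task$val], task$labs[task$val],
                                target_fpr = 1), min(p))
})

test_that("ablation switches modify configurations idempotently", {
  fc <- feature_config(group1_predictors = c("a", "b", "c"))
  mc <- model_config()
  ab <- ablate(fc, mc, "no_window")
  expect_equal(ab$feature$window, 1L)
  expect_identical(ablate(ab$feature, ab$model, "no_window"), ab)

  expect_false(ablate(fc, mc, "no_group3")$feature$use_group3)
  expect_equal(ablate(fc, mc, "no_transformer")$model$n_blocks, 0L)
  expect_equal(ablate(fc, mc, "l1_loss")$model$loss, "l1")
  expect_equal(ablate(fc, mc, "drop_predictor:b")$feature$group1_predictors,
               c("a", "c"))
  expect_error(ablate(fc, mc, "warp_drive"), "unknown ablation")

  ## dimensional consequences: no_window -> 30 columns, drop -> 9 windowed features
  ds <- generate_dataset(sim_config(n_dna_proteins = 2, n_other_proteins = 2,
                                    length_meanlog = log(40), seed = 1))
  ds <- simulate_tracks(ds, seed = 1)
  fc2 <- feature_config(group1_predictors = names(ds$tracks))
  expect_equal(ncol(build_profiles(ds, ablate(fc2, mc, "no_window")$feature)[[1]]),
               30)
  dropped <- ablate(fc2, mc, paste0("drop_predictor:", names(ds$tracks)[1]))
  expect_equal(ncol(build_profiles(ds, dropped$feature)[[1]]), 9 * 15 + 20)
})
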