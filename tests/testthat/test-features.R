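test_that("scale features are normalized per residue and handle X", {
  m <- scale_features("AAA", "charge")
  expect_equal(unname(m[, 1]), rep(unname(m[1, 1]), 3))

  ## normalization endpoints: the most extreme residue maps to 1, least to 0
  tabs <- aa_scales()
  for (sc in names(tabs)) {
    vals <- tabs[[sc]][setdiff(names(tabs[[sc]]), "X")]
    expect_equal(max(vals), 1)
    expect_equal(min(vals), 0)
  }

  ## charge: lysine strictly above aspartate
  kd <- scale_features("KD", "charge")
  expect_gt(kd[1, 1], kd[2, 1])

  ## X maps to the alphabet mean
  x <- scale_features("X", "hydrophobicity")
  expect_equal(unname(x[1, 1]), mean(tabs$hydrophobicity[1:20]))

  expect_error(scale_features("AA", "nope"), "unknown scale")
})

test_that("aggregate disorder features compute truncated windowed statistics", {
  g <- aggregate_disorder_features(rep(0.8, 30))
  expect_equal(dim(g), c(30, 20))
  expect_equal(max(abs(g[, grep("mean", colnames(g))] - 0.8)), 0,
               tolerance = 1e-9)
  expect_true(all(g[, grep("frac", colnames(g))] == 1))

  g0 <- aggregate_disorder_features(rep(0, 10))
  expect_true(all(g0 == 0))

  ## hand-computed centered segment: positions 2..4 of [1,0,1,0,1]
  g3 <- aggregate_disorder_features(c(1, 0, 1, 0, 1), segments = 3L)
  expect_equal(unname(g3[3, "g3.s3.mean"]), 1 / 3)
  expect_equal(unname(g3[3, "g3.s3.frac_gt_half"]), 1 / 3)
  expect_equal(unname(g3[4, "g3.s3.mean"]), 2 / 3)
  ## terminus truncation: position 1 sees positions 1..2
  expect_equal(unname(g3[1, "g3.s3.mean"]), 1 / 2)

  expect_error(aggregate_disorder_features(rep(0.5, 5), segments = 4L), "odd")
})

test_that("windowed profiles pad termini with zeros and keep interior exact", {
  m <- matrix(seq_len(30) / 10, nrow = 3, ncol = 10)
  w <- windowed_profile(m, 15L)
  expect_equal(dim(w), c(3, 150))

  ## length-1 protein: 140 zeros around the 10 central values
  w1 <- windowed_profile(m[1, , drop = FALSE], 15L)
  expect_equal(sum(w1 != 0), 10)
  centre <- grep("^w\\+0\\.", colnames(w1))
  expect_equal(unname(w1[1, centre]), unname(m[1, ]))

  ## window 3 on position 2 of a length-3 protein: rows 1..3 concatenated
  w3 <- windowed_profile(m, 3L)
  expect_equal(unname(w3[2, ]), unname(c(m[1, ], m[2, ], m[3, ])))

  ## interior residue of a long protein has no zero padding
  long <- matrix(runif(100 * 10) + 0.1, 100, 10)
  wl <- windowed_profile(long, 15L)
  expect_true(all(wl[50, ] > 0))
})

test_that("profiles have 170 columns under defaults and are deterministic", {
  ds <- generate_dataset(sim_config(n_dna_proteins = 3, n_other_proteins = 6,
                                    length_meanlog = log(60), seed = 2))
  ds <- simulate_tracks(ds, seed = 3)
  prof <- build_profiles(ds)
  expect_equal(ncol(prof[[1]]), 170)
  expect_equal(nrow(prof[[1]]), nchar(ds$proteins[[1]]$sequence))
  expect_true(all(vapply(prof, function(m) all(is.finite(m)), logical(1))))

  ## window 1 shrinks rows to 10 + 20 = 30
  prof30 <- build_profiles(ds, feature_config(window = 1L))
  expect_equal(ncol(prof30[[1]]), 30)

  ## bit-identical across runs
  expect_identical(prof, build_profiles(ds))

  ## missing track is reported by name
  expect_error(build_profiles(ds, feature_config(group1_predictors = "zz")),
               "zz")
})

test_that("reversing a protein reverses its profile with mirrored offsets", {
  ds <- generate_dataset(sim_config(n_dna_proteins = 2, n_other_proteins = 2,
                                    length_meanlog = log(50), seed = 5))
  ds <- simulate_tracks(ds, seed = 6)
  cfg <- feature_config()
  prof <- build_profiles(ds, cfg)

  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  prots_r <- lapply(ds$proteins, function(p) {
    protein_record(p$id, rev_str(p$sequence), rev(p$labels), p$source)
  })
  ds_r <- dbr_dataset(prots_r,
                      tracks = lapply(ds$tracks, function(t) lapply(t, rev)),
                      aux_tracks = lapply(ds$aux_tracks, function(t) lapply(t, rev)))
  prof_r <- build_profiles(ds_r, cfg)

  cn <- colnames(prof[[1]])
  mirrored <- suppressWarnings(ifelse(grepl("^w", cn),
                     sprintf("w%+d.%s",
                             -as.integer(sub("^w([+-]?\\d+)\\..*$", "\\1", cn)),
                             sub("^w[+-]?\\d+\\.", "", cn)),
                     cn))
  for (pid in names(prof)) {
    expect_equal(unname(prof_r[[pid]][rev(seq_len(nrow(prof[[pid]]))), mirrored]),
                 unname(prof[[pid]]), tolerance = 1e-12)
  }
})

test_that("group-3 columns depend only on the disorder track", {
  ds <- generate_dataset(sim_config(n_dna_proteins = 2, n_other_proteins = 3,
                                    length_meanlog = log(50), seed = 8))
  ds <- simulate_tracks(ds, seed = 9)
  prof <- build_profiles(ds)
  ## permute the group-1 predictor order: only windowed blocks move
  perm <- rev(names(ds$tracks))
  prof_p <- build_profiles(ds, feature_config(group1_predictors = perm))
  g3_cols <- grep("^g3\\.", colnames(prof[[1]]), value = TRUE)
  for (pid in names(prof)) {
    expect_identical(prof[[pid]][, g3_cols], prof_p[[pid]][, g3_cols])
    ## permuted track columns carry the same values under permuted names
    for (tk in names(ds$tracks)) {
      expect_identical(prof[[pid]][, sprintf("w+0.%s", tk)],
                       prof_p[[pid]][, sprintf("w+0.%s", tk)])
    }
  }

  ## aux-track fallbacks keep the builder working without aux tracks
  ds_bare <- dbr_dataset(ds$proteins, tracks = ds$tracks)
  prof_b <- build_profiles(ds_bare)
  expect_equal(ncol(prof_b[[1]]), 170)
  expect_true(all(is.finite(prof_b[[1]])))
})
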