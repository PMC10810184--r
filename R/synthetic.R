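## Background amino-acid frequencies (SwissProt composition, order
## ACDEFGHIKLMNPQRSTVWY); sequences carry no label signal by default.
AA_BACKGROUND <- c(0.0825, 0.0138, 0.0546, 0.0672, 0.0386, 0.0708, 0.0227,
                   0.0591, 0.0580, 0.0965, 0.0241, 0.0406, 0.0474, 0.0393,
                   0.0553, 0.0664, 0.0535, 0.0686, 0.0110, 0.0292)

#' Configuration of the synthetic benchmark generator
#'
#' Defaults emulate the composition of a mixed structure-/disorder-annotated
#' benchmark of DNA-binding and other-ligand-binding proteins: 39 DNA-binding
#' and 396 non-DNA-binding proteins, a 2:1 structure-to-disorder annotation
#' ratio in both groups, about 1.5% DNA-binding residues and about 9.8%
#' other-ligand residues overall, and log-normal protein lengths with median
#' near 450 residues.
#'
#' @param n_dna_proteins,n_other_proteins Protein counts (defaults 39, 396).
#' @param structure_fraction Fraction of proteins with STRUCTURE annotation
#'   source in each group (default 2/3; applied deterministically by
#'   rounding).
#' @param dbr_fraction Target fraction of DNA-labelled residues among all
#'   residues (default 0.015).
#' @param other_fraction Target fraction of OTHER-labelled residues
#'   (default 0.098).
#' @param length_meanlog,length_sdlog Log-normal length law (defaults
#'   `log(450)` and 0.4; lengths are rounded and floored at 30).
#' @param run_mean Mean length of contiguous binding runs (geometric run
#'   lengths; default 4).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_dna_proteins = 39L, n_other_proteins = 396L,
                       structure_fraction = 2 / 3, dbr_fraction = 0.015,
                       other_fraction = 0.098, length_meanlog = log(450),
                       length_sdlog = 0.4, run_mean = 4, seed = 1L) {
  stopifnot(n_dna_proteins >= 0L, n_other_proteins >= 0L,
            structure_fraction > 0, structure_fraction < 1,
            dbr_fraction >= 0, other_fraction >= 0,
            dbr_fraction + other_fraction < 1, run_mean >= 1)
  structure(list(n_dna_proteins = as.integer(n_dna_proteins),
                 n_other_proteins = as.integer(n_other_proteins),
                 structure_fraction = structure_fraction,
                 dbr_fraction = dbr_fraction, other_fraction = other_fraction,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 run_mean = run_mean, seed = as.integer(seed)),
            class = "sim_config")
}

## Place `quota` labelled residues as contiguous geometric runs on positions
## still labelled NONE; returns the updated label vector.
place_runs <- function(labels, quota, label, run_mean) {
  if (quota <= 0L) return(labels)
  L <- length(labels)
  placed <- 0L
  attempts <- 0L
  p_geom <- 1 / run_mean
  while (placed < quota) {
    attempts <- attempts + 1L
    if (attempts > 200L * quota + 1000L) {
      stop(sprintf("cannot place %d '%s' residues in a protein of length %d",
                   quota, label, L))
    }
    r <- 1L + stats::rgeom(1L, p_geom)
    start <- sample.int(L, 1L)
    idx <- start:min(L, start + r - 1L)
    idx <- idx[labels[idx] == "NONE"]
    if (!length(idx)) next
    idx <- idx[seq_len(min(length(idx), quota - placed))]
    labels[idx] <- label
    placed <- placed + length(idx)
  }
  labels
}

#' Generate a synthetic labelled protein dataset
#'
#' Sequences are drawn i.i.d. from background amino-acid frequencies (no
#' label signal in residue identity); DNA-binding residues are placed as
#' contiguous runs inside the DNA-binding proteins and other-ligand residues
#' as runs in all proteins, hitting the configured class fractions exactly up
#' to rounding per protein.
#'
#' @param config A [sim_config].
#' @return A [dbr_dataset] with proteins and labels (no tracks).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  n_dna <- config$n_dna_proteins; n_oth <- config$n_other_proteins
  n <- n_dna + n_oth
  if (n == 0L) stop("no proteins requested")
  is_dna <- c(rep(TRUE, n_dna), rep(FALSE, n_oth))
  src_of <- function(k) {
    ns <- round(config$structure_fraction * k)
    c(rep("STRUCTURE", ns), rep("DISORDER", k - ns))
  }
  source <- c(src_of(n_dna), src_of(n_oth))
  lens <- pmax(30L, as.integer(round(stats::rlnorm(n, config$length_meanlog,
                                                   config$length_sdlog))))
  total <- sum(lens)
  dna_total <- sum(lens[is_dna])
  if (n_dna > 0L) {
    dbr_density <- config$dbr_fraction * total / dna_total
    if (dbr_density + config$other_fraction > 0.9) {
      stop(sprintf("infeasible fractions: DBR density %.2f within DNA-binding proteins",
                   dbr_density))
    }
  }
  proteins <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    seq_i <- paste(sample(AA_ALPHABET, L, replace = TRUE, prob = AA_BACKGROUND),
                   collapse = "")
    labels <- rep("NONE", L)
    if (is_dna[i]) {
      quota <- max(1L, as.integer(round(config$dbr_fraction * total * L / dna_total)))
      labels <- place_runs(labels, quota, "DNA", config$run_mean)
    }
    quota_other <- as.integer(round(config$other_fraction * L))
    labels <- place_runs(labels, quota_other, "OTHER", config$run_mean)
    proteins[[i]] <- protein_record(sprintf("sim%04d", i), seq_i, labels, source[i])
  }
  dbr_dataset(proteins)
}

#' Configuration of one simulated predictor track
#'
#' Scores follow a binormal model: residue score = N(0, sd) + `d` for DNA
#' residues + `cross_shift` for other-ligand residues, where `d` is
#' `d_struct` on STRUCTURE-source proteins and `d_dis` on DISORDER-source
#' proteins. The implied per-stratum AUC is `pnorm(d / sqrt(2))` in closed
#' form. `cross_shift` controls the cross-prediction tendency: 0 gives a
#' fully ligand-specific track, `cross_shift = d` a fully ligand-agnostic
#' one.
#'
#' @param role `"structure_trained"` or `"disorder_trained"`; sets the
#'   defaults `d_struct`/`d_dis` to (1.5, 0) or (0, 1.5) respectively.
#' @param d_struct,d_dis Binormal shifts applied to DNA residues by protein
#'   source.
#' @param cross_shift Shift applied to OTHER residues (all proteins).
#' @param noise_sd Score noise standard deviation (default 1).
#' @return An object of class `track_sim_config`.
#' @export
track_sim_config <- function(role = c("structure_trained", "disorder_trained"),
                             d_struct = NULL, d_dis = NULL, cross_shift = 0,
                             noise_sd = 1) {
  role <- match.arg(role)
  if (is.null(d_struct)) d_struct <- if (role == "structure_trained") 1.5 else 0
  if (is.null(d_dis)) d_dis <- if (role == "disorder_trained") 1.5 else 0
  stopifnot(is.finite(d_struct), is.finite(d_dis), is.finite(cross_shift),
            noise_sd > 0)
  structure(list(role = role, d_struct = d_struct, d_dis = d_dis,
                 cross_shift = cross_shift, noise_sd = noise_sd),
            class = "track_sim_config")
}

#' Default set of three simulated base-predictor tracks
#'
#' Emulates the characteristic asymmetry of published tools: two
#' structure-trained tracks that discriminate well on structure-annotated
#' proteins and poorly on disorder-annotated ones, and one disorder-trained
#' track with the complementary (weaker) profile. Shifts were chosen so the
#' per-stratum closed-form AUCs `pnorm(d / sqrt(2))` land in the ranges
#' typical for the respective tool families (0.75-0.81 in-domain for the
#' structure-trained tracks, near chance out of domain); the nonzero
#' `cross_shift` values reproduce moderate cross-prediction rates.
#'
#' @return Named list of [track_sim_config] objects (`structure_a`,
#'   `structure_b`, `disorder_a`).
#' @export
default_track_configs <- function() {
  list(
    structure_a = track_sim_config("structure_trained", d_struct = 1.24,
                                   d_dis = 0.12, cross_shift = 0.5),
    structure_b = track_sim_config("structure_trained", d_struct = 0.95,
                                   d_dis = 0.67, cross_shift = 0.35),
    disorder_a = track_sim_config("disorder_trained", d_struct = 0.44,
                                  d_dis = 0.48, cross_shift = 0.4)
  )
}

#' Simulate predictor tracks and auxiliary tracks for a labelled dataset
#'
#' Generates binormal propensity tracks per [track_sim_config], plus two
#' auxiliary per-residue tracks: a disorder probability track that is high
#' (mean 0.8) in the binding regions of DISORDER-source proteins, moderate
#' (mean 0.5) elsewhere in those proteins, and low (mean 0.2) throughout
#' STRUCTURE-source proteins; and a relative solvent accessibility track
#' mildly elevated at binding residues (mean 0.6 vs 0.45). Both are Beta
#' distributed in \[0, 1\].
#'
#' @param dataset A labelled [dbr_dataset].
#' @param track_configs Named list of [track_sim_config] objects (default
#'   [default_track_configs]).
#' @param seed Integer RNG seed.
#' @return A new [dbr_dataset] with the same proteins and the simulated
#'   `tracks` and `aux_tracks` attached.
#' @export
simulate_tracks <- function(dataset, track_configs = default_track_configs(),
                            seed = 1L) {
  stopifnot(inherits(dataset, "dbr_dataset"), length(track_configs) >= 1L)
  if (is.null(names(track_configs)) || any(!nzchar(names(track_configs)))) {
    stop("track_configs must be a named list")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  rbeta_mean <- function(n, mu, conc = 8) {
    stats::rbeta(n, shape1 = mu * conc, shape2 = (1 - mu) * conc)
  }
  tracks <- lapply(track_configs, function(tc) {
    stopifnot(inherits(tc, "track_sim_config"))
    lapply(dataset$proteins, function(p) {
      d <- if (p$source == "STRUCTURE") tc$d_struct else tc$d_dis
      stats::rnorm(length(p$labels), 0, tc$noise_sd) +
        d * (p$labels == "DNA") + tc$cross_shift * (p$labels == "OTHER")
    })
  })
  aux_disorder <- lapply(dataset$proteins, function(p) {
    L <- length(p$labels)
    if (p$source == "DISORDER") {
      mu <- ifelse(p$labels == "NONE", 0.5, 0.8)
      rbeta_mean(L, mu)
    } else {
      rbeta_mean(L, 0.2)
    }
  })
  aux_rsa <- lapply(dataset$proteins, function(p) {
    mu <- ifelse(p$labels == "NONE", 0.45, 0.6)
    rbeta_mean(length(p$labels), mu)
  })
  dbr_dataset(dataset$proteins, tracks = tracks,
              aux_tracks = list(disorder = aux_disorder, rsa = aux_rsa))
}
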