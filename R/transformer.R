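#' Configuration of the transformer meta-predictor
#'
#' The network maps each residue's feature vector into a `d_model`-wide
#' latent space with a learned linear projection, passes the per-chunk
#' sequence through `n_blocks` transformer modules (multi-head
#' self-attention, then a feed-forward layer, then a normalization layer,
#' with residual connections), and reduces the latent space through a fully
#' connected head (20 to 10 to 5 to 1 by default) ending in a logistic
#' output neuron that emits the DNA-binding propensity.
#'
#' @param d_model Latent width (default 20; must divide by `n_heads`).
#' @param n_blocks Number of transformer modules (default 3; 0 reduces the
#'   network to projection + head).
#' @param n_heads Attention heads (default 2).
#' @param ff_hidden Width of the feed-forward layer inside each block
#'   (default 64).
#' @param head_dims Widths of the reducing head; must start at `d_model` and
#'   end at 1 (default `c(20, 10, 5, 1)`).
#' @param loss `"bce"` (binary cross-entropy, default) or `"l1"` (mean
#'   absolute error).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Training chunks per optimizer step (default 128).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Epochs without validation-AUC improvement before stopping
#'   (default 10).
#' @param chunk_len Residues per training chunk (default 256); sequences are
#'   split into consecutive chunks so self-attention sees sequence context.
#' @param pos_weight Optional weight on the positive class in the BCE loss
#'   (default 1, i.e. no reweighting).
#' @param seed Integer RNG seed controlling initialization and shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_model = 20L, n_blocks = 3L, n_heads = 2L,
                         ff_hidden = 64L, head_dims = c(20L, 10L, 5L, 1L),
                         loss = c("bce", "l1"), lr = 1e-4, batch_size = 128L,
                         max_epochs = 100L, patience = 10L, chunk_len = 256L,
                         pos_weight = 1, seed = 1L) {
  loss <- match.arg(loss)
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  if (head_dims[1L] != d_model || utils::tail(head_dims, 1L) != 1L) {
    stop("head_dims must start at d_model and end at 1")
  }
  stopifnot(n_blocks >= 0L, ff_hidden >= 1L, lr > 0, batch_size >= 1L,
            max_epochs >= 1L, patience >= 1L, chunk_len >= 1L, pos_weight > 0)
  structure(list(d_model = as.integer(d_model), n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads), ff_hidden = as.integer(ff_hidden),
                 head_dims = as.integer(head_dims), loss = loss, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 chunk_len = as.integer(chunk_len), pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "model_config")
}

## ---- low-level tensor helpers (row-major sequences: L x d matrices) ----

addb <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)
mulb <- function(X, v) X * matrix(v, nrow(X), length(v), byrow = TRUE)

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Glorot-uniform weight matrix
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## Flat named parameter list; shapes are a deterministic function of config.
init_params <- function(config, n_features) {
  d <- config$d_model
  p <- list(in.W = glorot(n_features, d), in.b = numeric(d))
  for (i in seq_len(config$n_blocks)) {
    pre <- sprintf("b%d.", i)
    p[[paste0(pre, "Wq")]] <- glorot(d, d)
    p[[paste0(pre, "Wk")]] <- glorot(d, d)
    p[[paste0(pre, "Wv")]] <- glorot(d, d)
    p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- glorot(d, d)
    p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- glorot(d, config$ff_hidden)
    p[[paste0(pre, "b1")]] <- numeric(config$ff_hidden)
    p[[paste0(pre, "W2")]] <- glorot(config$ff_hidden, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "g")]] <- rep(1, d)
    p[[paste0(pre, "beta")]] <- numeric(d)
  }
  hd <- config$head_dims
  for (j in seq_len(length(hd) - 1L)) {
    p[[sprintf("h%d.W", j)]] <- glorot(hd[j], hd[j + 1L])
    p[[sprintf("h%d.b", j)]] <- numeric(hd[j + 1L])
  }
  p
}

#' Number of trainable parameters implied by a model configuration
#'
#' Closed-form count over the layers: input projection, the per-block
#' attention/feed-forward/normalization weights, and the reducing head.
#'
#' @param config A [model_config].
#' @param n_features Input feature dimensionality.
#' @return Integer parameter count.
#' @export
n_parameters <- function(config, n_features) {
  d <- config$d_model; ff <- config$ff_hidden
  per_block <- 4L * (d * d + d) +        # Wq, Wk, Wv, Wo with biases
    (d * ff + ff) + (ff * d + d) +       # feed-forward
    2L * d                               # layernorm gain and shift
  hd <- config$head_dims
  head <- sum(hd[-length(hd)] * hd[-1L] + hd[-1L])
  as.integer(n_features * d + d + config$n_blocks * per_block + head)
}

## Forward pass over one chunk (X: L x F). Returns propensities, logits and
## (optionally) the cache of intermediates needed for the backward pass.
forward_chunk <- function(params, X, config, keep_cache = FALSE) {
  d <- config$d_model; nh <- config$n_heads; dh <- d %/% nh
  H <- addb(X %*% params[["in.W"]], params[["in.b"]])
  cache <- if (keep_cache) list(X = X, H0 = H, blocks = vector("list", config$n_blocks))
  for (i in seq_len(config$n_blocks)) {
    pre <- sprintf("b%d.", i)
    Hin <- H
    Q <- addb(Hin %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    K <- addb(Hin %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    V <- addb(Hin %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    C <- matrix(0, nrow(Hin), d)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh))
      C[, cols] <- A %*% V[, cols, drop = FALSE]
      A_heads[[h]] <- A
    }
    O <- addb(C %*% params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
    A1 <- Hin + O
    Z1 <- addb(A1 %*% params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    R1 <- pmax(Z1, 0)
    F1 <- addb(R1 %*% params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    A2 <- A1 + F1
    mu <- rowMeans(A2)
    xc <- A2 - mu
    inv <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
    xhat <- xc * inv
    H <- addb(mulb(xhat, params[[paste0(pre, "g")]]), params[[paste0(pre, "beta")]])
    if (keep_cache) {
      cache$blocks[[i]] <- list(Hin = Hin, Q = Q, K = K, V = V, A = A_heads,
                                C = C, A1 = A1, Z1 = Z1, R1 = R1,
                                xhat = xhat, inv = inv)
    }
  }
  hd <- config$head_dims
  Zs <- if (keep_cache) vector("list", length(hd) - 1L)
  Z <- H
  for (j in seq_len(length(hd) - 1L)) {
    if (keep_cache) Zs[[j]] <- Z
    Z <- addb(Z %*% params[[sprintf("h%d.W", j)]], params[[sprintf("h%d.b", j)]])
    if (j < length(hd) - 1L) Z <- pmax(Z, 0)
  }
  logits <- as.numeric(Z)
  if (keep_cache) {
    cache$Htop <- H
    cache$head_in <- Zs
  }
  list(p = sigmoid(logits), logits = logits, cache = cache)
}

## Backward pass; dlogits is dLoss/dlogit per residue. Returns the gradient
## as a flat list matching the parameter shapes.
backward_chunk <- function(params, cache, dlogits, config) {
  d <- config$d_model; nh <- config$n_heads; dh <- d %/% nh
  g <- list()
  hd <- config$head_dims
  dZ <- matrix(dlogits, ncol = 1L)
  for (j in rev(seq_len(length(hd) - 1L))) {
    Zin <- cache$head_in[[j]]
    Wn <- sprintf("h%d.W", j)
    if (j < length(hd) - 1L) {
      ## dZ currently refers to post-ReLU output of layer j
      pre_act <- addb(Zin %*% params[[Wn]], params[[sprintf("h%d.b", j)]])
      dZ <- dZ * (pre_act > 0)
    }
    g[[Wn]] <- crossprod(Zin, dZ)
    g[[sprintf("h%d.b", j)]] <- colSums(dZ)
    dZ <- tcrossprod(dZ, params[[Wn]])
  }
  dH <- dZ
  for (i in rev(seq_len(config$n_blocks))) {
    pre <- sprintf("b%d.", i)
    bc <- cache$blocks[[i]]
    ## layernorm
    g[[paste0(pre, "g")]] <- colSums(dH * bc$xhat)
    g[[paste0(pre, "beta")]] <- colSums(dH)
    dxhat <- mulb(dH, params[[paste0(pre, "g")]])
    dA2 <- bc$inv * (dxhat - rowMeans(dxhat) -
                       bc$xhat * rowMeans(dxhat * bc$xhat))
    ## feed-forward with residual: A2 = A1 + relu(A1 W1 + b1) W2 + b2
    dF1 <- dA2
    dR1 <- tcrossprod(dF1, params[[paste0(pre, "W2")]])
    g[[paste0(pre, "W2")]] <- crossprod(bc$R1, dF1)
    g[[paste0(pre, "b2")]] <- colSums(dF1)
    dZ1 <- dR1 * (bc$Z1 > 0)
    g[[paste0(pre, "W1")]] <- crossprod(bc$A1, dZ1)
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    dA1 <- dA2 + tcrossprod(dZ1, params[[paste0(pre, "W1")]])
    ## attention with residual: A1 = Hin + (concat heads) Wo + bo
    dO <- dA1
    g[[paste0(pre, "Wo")]] <- crossprod(bc$C, dO)
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dC <- tcrossprod(dO, params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, nrow(dH), d); dK <- dQ; dV <- dQ
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- bc$A[[h]]
      dOh <- dC[, cols, drop = FALSE]
      Vh <- bc$V[, cols, drop = FALSE]
      dV[, cols] <- crossprod(A, dOh)
      dA <- tcrossprod(dOh, Vh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% bc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, bc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g[[paste0(pre, "Wq")]] <- crossprod(bc$Hin, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(bc$Hin, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(bc$Hin, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dH <- dA1 + tcrossprod(dQ, params[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, params[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, params[[paste0(pre, "Wv")]])
  }
  g[["in.W"]] <- crossprod(cache$X, dH)
  g[["in.b"]] <- colSums(dH)
  g
}

## Per-residue loss and dLoss/dlogit for a chunk (sums, not means; the
## caller normalizes by the residue count of the batch).
chunk_loss_grad <- function(p, logits, y, config) {
  eps <- 1e-12
  if (config$loss == "bce") {
    w <- ifelse(y > 0.5, config$pos_weight, 1)
    loss <- -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
    dlogit <- w * (p - y)
  } else {
    loss <- sum(abs(p - y))
    dlogit <- sign(p - y) * p * (1 - p)
  }
  if (!is.finite(loss)) stop("non-finite loss")
  list(loss = loss, dlogit = dlogit)
}

## Tie-corrected AUC from logical truth and numeric scores (midranks).
auc_fast <- function(y, s) {
  nP <- sum(y); nN <- sum(!y)
  if (nP == 0L || nN == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[y]) - nP * (nP + 1) / 2) / (nP * nN)
}

## Split 1..L into consecutive chunks of at most chunk_len.
chunk_indices <- function(L, chunk_len) {
  starts <- seq(1L, L, by = chunk_len)
  lapply(starts, function(s) s:min(L, s + chunk_len - 1L))
}

## Coerce per-protein labels (character ternary or 0/1) to numeric 0/1.
as_binary_labels <- function(labels) {
  lapply(labels, function(l) {
    if (is.character(l) || is.factor(l)) as.numeric(as.character(l) == "DNA")
    else as.numeric(as.logical(l))
  })
}

#' Fit the transformer meta-predictor
#'
#' Trains the network of [model_config] on per-residue feature profiles with
#' the Adam optimizer, chunking sequences to `chunk_len` residues, and
#' early-stops on validation AUC: the returned model carries the weights of
#' the best validation epoch. After training, the decision threshold is
#' calibrated on the pooled validation residues at `calibration_fpr`.
#'
#' @param x Named list of feature matrices, one per training protein (as
#'   from [build_profiles]).
#' @param y Named list of per-residue labels (ternary character vectors or
#'   0/1), aligned with `x`.
#' @param val_x,val_y Validation profiles and labels; required, and disjoint
#'   from the training proteins by name.
#' @param config A [model_config].
#' @param calibration_fpr Target FPR for the stored decision threshold
#'   (default 0.1).
#' @param verbose Print per-epoch progress (default FALSE).
#' @return An object of class `dbr_transformer` with elements `config`,
#'   `params`, `feature_manifest`, `calibrated_threshold`, `training_log`
#'   (per-epoch train/validation loss and validation AUC) and `best_epoch`.
#' @export
dbr_transformer <- function(x, y, val_x, val_y, config = model_config(),
                            calibration_fpr = 0.1, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"),
            is.list(x), is.list(y), is.list(val_x), is.list(val_y),
            length(x) == length(y), length(val_x) == length(val_y),
            length(val_x) > 0L)
  if (length(intersect(names(x), names(val_x)))) {
    stop("training and validation sets must be disjoint by protein")
  }
  y_bin <- as_binary_labels(y)[names(x)]
  val_bin <- as_binary_labels(val_y)[names(val_x)]
  y_all <- unlist(y_bin, use.names = FALSE)
  if (all(y_all == 0) || all(y_all == 1)) {
    stop("training labels are all one class")
  }
  val_all <- unlist(val_bin, use.names = FALSE)
  if (all(val_all == 0) || all(val_all == 1)) {
    stop("validation labels are all one class; early stopping by AUC impossible")
  }
  manifest <- colnames(x[[1L]])
  n_features <- ncol(x[[1L]])

  ## flatten proteins into (protein, chunk-index) pairs
  chunks <- list()
  for (pid in names(x)) {
    stopifnot(nrow(x[[pid]]) == length(y_bin[[pid]]))
    for (idx in chunk_indices(nrow(x[[pid]]), config$chunk_len)) {
      chunks[[length(chunks) + 1L]] <- list(pid = pid, idx = idx)
    }
  }
  n_chunks <- length(chunks)

  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  params <- init_params(config, n_features)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  adam_t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  predict_pooled <- function(prof_list) {
    unlist(lapply(prof_list, function(X) {
      out <- numeric(nrow(X))
      for (idx in chunk_indices(nrow(X), config$chunk_len)) {
        out[idx] <- forward_chunk(params, X[idx, , drop = FALSE], config)$p
      }
      out
    }), use.names = FALSE)
  }
  val_truth <- unlist(val_bin, use.names = FALSE) > 0.5

  log_rows <- vector("list", config$max_epochs)
  best <- list(auc = -Inf, epoch = 0L, params = NULL)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_chunks)
    train_loss <- 0; train_n <- 0L
    for (batch_start in seq(1L, n_chunks, by = config$batch_size)) {
      members <- ord[batch_start:min(n_chunks, batch_start + config$batch_size - 1L)]
      acc <- NULL; batch_n <- 0L
      for (ci in members) {
        ch <- chunks[[ci]]
        X <- x[[ch$pid]][ch$idx, , drop = FALSE]
        yv <- y_bin[[ch$pid]][ch$idx]
        fw <- forward_chunk(params, X, config, keep_cache = TRUE)
        lg <- chunk_loss_grad(fw$p, fw$logits, yv, config)
        grads <- backward_chunk(params, fw$cache, lg$dlogit, config)
        acc <- if (is.null(acc)) grads else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
          acc
        }
        train_loss <- train_loss + lg$loss
        batch_n <- batch_n + length(yv)
      }
      train_n <- train_n + batch_n
      adam_t <- adam_t + 1L
      for (nm in names(params)) {
        gr <- acc[[nm]] / batch_n
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gr
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
        mhat <- adam_m[[nm]] / (1 - beta1^adam_t)
        vhat <- adam_v[[nm]] / (1 - beta2^adam_t)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    val_p <- predict_pooled(val_x)
    val_loss <- chunk_loss_grad(val_p, stats::qlogis(pmin(pmax(val_p, 1e-12), 1 - 1e-12)),
                                as.numeric(val_truth), config)$loss / length(val_p)
    val_auc <- auc_fast(val_truth, val_p)
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = train_loss / train_n,
                                    val_loss = val_loss, val_auc = val_auc)
    if (verbose) {
      message(sprintf("epoch %3d: train %.4f  val %.4f  val AUC %.4f",
                      epoch, train_loss / train_n, val_loss, val_auc))
    }
    if (!is.na(val_auc) && val_auc > best$auc) {
      best <- list(auc = val_auc, epoch = epoch, params = params)
    }
    if (epoch - best$epoch >= config$patience) break
  }
  params <- best$params
  training_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])

  model <- structure(
    list(config = config, params = params, feature_manifest = manifest,
         n_features = n_features, calibrated_threshold = NA_real_,
         training_log = training_log, best_epoch = best$epoch,
         best_val_auc = best$auc),
    class = "dbr_transformer"
  )
  model$calibrated_threshold <- tryCatch(
    calibrate_threshold(model, val_x, val_y, target_fpr = calibration_fpr),
    error = function(e) NA_real_
  )
  model
}

#' Calibrate the decision threshold of a fitted meta-predictor
#'
#' Picks the propensity threshold achieving a target FPR on the pooled
#' validation residues, by linear interpolation on the validation ROC.
#'
#' @param model A fitted `dbr_transformer`.
#' @param val_x Named list of validation feature matrices.
#' @param val_y Named list of validation labels.
#' @param target_fpr Target false positive rate (default 0.1); 1 places the
#'   threshold below all scores.
#' @return The threshold, a number in (0, 1).
#' @export
calibrate_threshold <- function(model, val_x, val_y, target_fpr = 0.1) {
  stopifnot(inherits(model, "dbr_transformer"), target_fpr > 0, target_fpr <= 1)
  p <- unlist(predict(model, val_x), use.names = FALSE)
  truth <- unlist(as_binary_labels(val_y)[names(val_x)], use.names = FALSE) > 0.5
  if (all(truth) || !any(truth)) stop("validation set must contain both classes")
  if (target_fpr == 1) return(min(p) - 1e-9)
  labels <- ifelse(truth, "DNA", "NONE")
  threshold_at(compute_roc(labels, p), fpr = target_fpr)$threshold
}

#' Predict DNA-binding propensities with a fitted meta-predictor
#'
#' @param object A `dbr_transformer`.
#' @param x Named list of feature matrices whose columns must match the
#'   model's feature manifest.
#' @param type `"propensity"` (default) for per-residue values in \[0, 1\],
#'   or `"call"` for binary calls at the calibrated threshold.
#' @param chunk_len Inference chunk length (default: the training value);
#'   outputs are stitched so chunking is invisible.
#' @param ... Unused.
#' @return Named list of numeric (or logical) per-residue vectors.
#' @export
predict.dbr_transformer <- function(object, x, type = c("propensity", "call"),
                                    chunk_len = NULL, ...) {
  type <- match.arg(type)
  stopifnot(is.list(x), length(x) > 0L)
  if (is.null(chunk_len)) chunk_len <- object$config$chunk_len
  mism <- c(setdiff(object$feature_manifest, colnames(x[[1L]])),
            setdiff(colnames(x[[1L]]), object$feature_manifest))
  if (length(mism)) {
    stop(sprintf("feature manifest mismatch; differing column(s): %s",
                 paste(utils::head(mism, 8L), collapse = ", ")))
  }
  out <- lapply(x, function(X) {
    X <- X[, object$feature_manifest, drop = FALSE]
    p <- numeric(nrow(X))
    for (idx in chunk_indices(nrow(X), chunk_len)) {
      p[idx] <- forward_chunk(object$params, X[idx, , drop = FALSE],
                              object$config)$p
    }
    p
  })
  if (type == "call") {
    if (is.na(object$calibrated_threshold)) stop("model has no calibrated threshold")
    out <- lapply(out, function(p) p > object$calibrated_threshold)
  }
  out
}

#' @export
print.dbr_transformer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dbr_transformer> %d features -> %d-d latent, %d transformer block(s) (%d heads), head %s\n",
              x$n_features, cfg$d_model, cfg$n_blocks, cfg$n_heads,
              paste(cfg$head_dims, collapse = "-")))
  cat(sprintf("  %d parameters; loss %s; trained %d epoch(s), best epoch %d (val AUC %.4f)\n",
              n_parameters(cfg, x$n_features), cfg$loss, nrow(x$training_log),
              x$best_epoch, x$best_val_auc))
  cat(sprintf("  calibrated threshold: %s\n", format(x$calibrated_threshold, digits = 4)))
  invisible(x)
}

#' @export
summary.dbr_transformer <- function(object, ...) {
  print(object)
  cat("\nTraining log (last epochs):\n")
  print(utils::tail(object$training_log, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.dbr_transformer <- function(object, ...) {
  unlist(object$params)
}

#' @export
plot.dbr_transformer <- function(x, ...) {
  log <- x$training_log
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(log$epoch, log$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Training / validation loss", ...)
  graphics::lines(log$epoch, log$val_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "validation"), lty = 1:2,
                   bty = "n")
  graphics::plot(log$epoch, log$val_auc, type = "l", xlab = "epoch",
                 ylab = "validation AUC", main = "Validation AUC", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Apply an ablation switch to a feature/model configuration pair
#'
#' Each switch removes one design element: `"no_group3"` drops the 20
#' aggregate disorder columns, `"no_window"` sets the sliding window to 1,
#' `"no_transformer"` removes the transformer blocks (projection + head
#' remain), `"l1_loss"` swaps binary cross-entropy for mean absolute error,
#' and `"drop_predictor:<id>"` removes one base-predictor track. Switches
#' are idempotent.
#'
#' @param feature A [feature_config].
#' @param model A [model_config].
#' @param switch One of `"no_group3"`, `"no_window"`, `"no_transformer"`,
#'   `"l1_loss"`, or `"drop_predictor:<id>"`.
#' @return List with modified `feature` and `model` configurations.
#' @export
ablate <- function(feature, model, switch) {
  stopifnot(inherits(feature, "feature_config"), inherits(model, "model_config"))
  if (startsWith(switch, "drop_predictor:")) {
    id <- sub("^drop_predictor:", "", switch)
    if (is.null(feature$group1_predictors)) {
      stop("drop_predictor requires feature$group1_predictors to be set explicitly")
    }
    feature$group1_predictors <- setdiff(feature$group1_predictors, id)
    if (!length(feature$group1_predictors)) stop("cannot drop the last predictor track")
  } else {
    switch(switch,
      no_group3 = { feature$use_group3 <- FALSE },
      no_window = { feature$window <- 1L },
      no_transformer = { model$n_blocks <- 0L },
      l1_loss = { model$loss <- "l1" },
      stop(sprintf("unknown ablation switch '%s'", switch))
    )
  }
  list(feature = feature, model = model)
}
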