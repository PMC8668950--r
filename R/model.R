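#' Model configuration
#'
#' Hyperparameters of the two-layer convolutional sequence labeller. The
#' defaults are the settings the predictor was developed with: a first
#' convolution mapping the `L x 1024` embedding to `L x 128` feature
#' channels (kernel 5), an ELU non-linearity and 70% dropout, a second
#' convolution (kernel 5) to `L x 3` per-class logits, per-channel sigmoid
#' outputs, a class-weighted binary cross-entropy loss with positive-class
#' weights 8.9 / 7.7 / 4.4 for metal / nucleic / small (countering the ~8%
#' binding vs. 92% non-binding imbalance), the Adamax optimizer at learning
#' rate 0.01, batches of up to 406 proteins, and early stopping on the
#' validation loss.
#'
#' @param input_dim Embedding width per residue.
#' @param hidden_channels Feature channels of the first convolution.
#' @param kernel_size Convolution window (odd; same-padding keeps length L).
#' @param dropout_rate Dropout rate between the two layers, in `[0, 1)`.
#' @param n_classes Output channels (one per ligand class).
#' @param class_weights Positive-class loss weights per channel
#'   (METAL, NUCLEIC, SMALL).
#' @param learning_rate Adamax learning rate.
#' @param batch_size Maximum proteins per batch.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early stopping patience (epochs without validation
#'   improvement before stopping; best checkpoint is restored).
#' @param val_fraction Fraction of proteins held out for validation when no
#'   explicit validation set is supplied to [train_model()].
#' @param decision_threshold Probability threshold for binary calls, in (0,1).
#' @param seed Integer seed for parameter initialization, dropout and
#'   batch assignment.
#' @return Object of class `"model_config"` (a validated list).
#' @export
#' @examples
#' model_config(seed = 1)
model_config <- function(input_dim = 1024L, hidden_channels = 128L,
                         kernel_size = 5L, dropout_rate = 0.70, n_classes = 3L,
                         class_weights = c(METAL = 8.9, NUCLEIC = 7.7, SMALL = 4.4),
                         learning_rate = 0.01, batch_size = 406L,
                         max_epochs = 60L, patience = 10L, val_fraction = 0.2,
                         decision_threshold = 0.5, seed = 42L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden_channels = as.integer(hidden_channels),
              kernel_size = as.integer(kernel_size),
              dropout_rate = dropout_rate,
              n_classes = as.integer(n_classes),
              class_weights = unname(class_weights),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              val_fraction = val_fraction,
              decision_threshold = decision_threshold,
              seed = as.integer(seed))
  if (cfg$input_dim < 1L || cfg$hidden_channels < 1L || cfg$n_classes < 1L)
    stop("input_dim, hidden_channels and n_classes must be positive")
  if (cfg$kernel_size < 1L || cfg$kernel_size %% 2L == 0L)
    stop("kernel_size must be odd (same-padding convolution)")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (length(cfg$class_weights) != cfg$n_classes || any(cfg$class_weights <= 0))
    stop("class_weights must be ", cfg$n_classes, " positive values")
  if (cfg$decision_threshold <= 0 || cfg$decision_threshold >= 1)
    stop("decision_threshold must be in (0, 1)")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  if (cfg$patience < 0L) stop("patience must be >= 0")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  class(cfg) <- "model_config"
  cfg
}

#' Build an (untrained) two-layer convolutional model
#'
#' Architecture: same-padding convolution `kernel x input_dim -> hidden`,
#' ELU, dropout, same-padding convolution `kernel x hidden -> n_classes`,
#' per-channel sigmoid. Weights are He-initialized from `config$seed`
#' (two builds with the same seed are identical); biases start at zero so
#' the initial output probability is exactly 0.5 everywhere.
#'
#' @param config A [model_config()].
#' @return Object of class `"plm_model"` with elements `config`, `params`
#'   (weight matrices `W1`, `b1`, `W2`, `b2` in im2col layout), `history`
#'   (`NULL` until trained) and `trained`.
#' @export
build_model <- function(config = model_config()) {
  if (!inherits(config, "model_config")) stop("config must be a model_config")
  k <- config$kernel_size
  fan1 <- k * config$input_dim
  fan2 <- k * config$hidden_channels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  # He init for the hidden layer; a small output-layer init keeps the
  # initial probabilities at ~0.5 (maximal uncertainty, per-channel loss
  # ~ln 2 under unit weights) while still breaking symmetry
  params <- list(
    W1 = matrix(rnorm(fan1 * config$hidden_channels, sd = sqrt(2 / fan1)),
                nrow = fan1, ncol = config$hidden_channels),
    b1 = numeric(config$hidden_channels),
    W2 = matrix(rnorm(fan2 * config$n_classes, sd = 0.01),
                nrow = fan2, ncol = config$n_classes),
    b2 = numeric(config$n_classes))
  structure(list(config = config, params = params, history = NULL,
                 trained = FALSE),
            class = "plm_model")
}

#' @export
print.plm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<plm_model> conv(%d x %d -> %d) | ELU | dropout %.2f | conv(%d x %d -> %d) | sigmoid%s\n",
              cfg$kernel_size, cfg$input_dim, cfg$hidden_channels, cfg$dropout_rate,
              cfg$kernel_size, cfg$hidden_channels, cfg$n_classes,
              if (isTRUE(x$trained)) sprintf(" | trained (%d epochs)", nrow(x$history)) else " | untrained"))
  invisible(x)
}

# ---- internal forward machinery (stacked-batch im2col representation) ----

# save/restore the global RNG so seeded internals do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Tap index matrix for a stack of sequences: row r of the output indexes the
# k input rows feeding output residue r; index n_total+1 is the virtual
# zero row standing in for the out-of-sequence positions of same-padding.
conv_tap_index <- function(lengths, k) {
  pad <- (k - 1L) %/% 2L
  n_total <- sum(lengths)
  offsets <- c(0L, cumsum(lengths))
  idx <- matrix(n_total + 1L, nrow = n_total, ncol = k)
  for (p in seq_along(lengths)) {
    L <- lengths[p]
    rows <- offsets[p] + seq_len(L)
    for (j in seq_len(k)) {
      src <- seq_len(L) + (j - 1L) - pad
      ok <- src >= 1L & src <= L
      idx[rows[ok], j] <- offsets[p] + src[ok]
    }
  }
  idx
}

# im2col gather: A is n x C, idx is n x k (with n+1 = zero row);
# returns n x (k*C) design matrix
im2col_gather <- function(A, idx) {
  Az <- rbind(A, 0)
  do.call(cbind, lapply(seq_len(ncol(idx)), function(j) Az[idx[, j], , drop = FALSE]))
}

elu <- function(z) {
  a <- z
  neg <- z < 0
  a[neg] <- expm1(z[neg])
  a
}

# derivative of ELU given pre-activation z and activation a = elu(z)
elu_grad <- function(z, a) {
  g <- matrix(1, nrow(z), ncol(z))
  neg <- z < 0
  g[neg] <- a[neg] + 1
  g
}

# Forward pass over a stack of concatenated proteins.
# X: sum(L) x input_dim; lengths: per-protein L. Returns intermediates for
# training when keep = TRUE. dropout_mask NULL => inference (no dropout).
forward_stack <- function(params, X, lengths, k, dropout_mask = NULL,
                          keep = FALSE, U1 = NULL, idx = NULL) {
  if (is.null(idx)) idx <- conv_tap_index(lengths, k)
  if (is.null(U1)) U1 <- im2col_gather(X, idx)
  Z1 <- U1 %*% params$W1
  Z1 <- sweep(Z1, 2L, params$b1, "+")
  H <- elu(Z1)
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  U2 <- im2col_gather(Hd, idx)
  Z2 <- U2 %*% params$W2
  Z2 <- sweep(Z2, 2L, params$b2, "+")
  P <- plogis(Z2)
  if (keep)
    list(P = P, Z2 = Z2, U2 = U2, H = H, Z1 = Z1, U1 = U1, idx = idx)
  else list(P = P, Z2 = Z2)
}

# Class-weighted binary cross-entropy on logits; returns overall mean over
# (residues x channels) and per-channel means. mask: logical per residue
# (FALSE rows contribute nothing; used for the explicit-padding property).
weighted_bce <- function(Z, Y, class_weights, mask = NULL) {
  logp <- plogis(Z, log.p = TRUE)       # log sigmoid(z)
  log1mp <- plogis(-Z, log.p = TRUE)    # log (1 - sigmoid(z))
  W <- matrix(class_weights, nrow(Z), ncol(Z), byrow = TRUE)
  ll <- -(W * Y * logp + (1 - Y) * log1mp)
  if (!is.null(mask)) ll <- ll[mask, , drop = FALSE]
  per_channel <- colMeans(ll)
  list(loss = mean(per_channel), per_channel = per_channel)
}

#' Masked training loss of a model on one protein
#'
#' Computes the class-weighted binary cross-entropy the trainer minimizes,
#' in inference mode (no dropout). Residues outside `mask` are treated as
#' padding: their rows are zeroed at the input and between the two
#' convolution layers and they are excluded from the loss, so appending
#' padding rows to a sequence can never change the masked loss.
#'
#' @param model A `"plm_model"`.
#' @param emb Numeric `L x input_dim` embedding matrix.
#' @param labels Logical/numeric `L x n_classes` label matrix.
#' @param mask Optional logical vector over residues; `NULL` means all.
#' @return List with `loss` (scalar) and `per_channel` (length-`n_classes`).
#' @export
model_loss <- function(model, emb, labels, mask = NULL) {
  cfg <- model$config
  if (ncol(emb) != cfg$input_dim)
    stop("embedding width ", ncol(emb), " does not match input_dim ", cfg$input_dim)
  if (nrow(emb) != nrow(labels))
    stop("embedding and label row counts differ")
  L <- nrow(emb)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == L)
    emb[!mask, ] <- 0
  }
  idx <- conv_tap_index(L, cfg$kernel_size)
  U1 <- im2col_gather(emb, idx)
  Z1 <- sweep(U1 %*% model$params$W1, 2L, model$params$b1, "+")
  H <- elu(Z1)
  if (!is.null(mask)) H[!mask, ] <- 0  # padding rows carry no activation
  U2 <- im2col_gather(H, idx)
  Z2 <- sweep(U2 %*% model$params$W2, 2L, model$params$b2, "+")
  weighted_bce(Z2, matrix(as.numeric(labels), nrow(labels), ncol(labels)),
               cfg$class_weights, mask = mask)
}

#' Predict binding probabilities
#'
#' Applies a trained (or untrained) model to one embedding matrix or a list
#' of them. Inference is deterministic: dropout is disabled, and a protein's
#' probabilities are identical whether it is predicted alone or inside a
#' batch (the convolution never crosses protein boundaries).
#'
#' @param object A `"plm_model"`.
#' @param embeddings One numeric `L x input_dim` matrix, or a named list.
#' @param ... Unused.
#' @return An `L x n_classes` probability matrix, or a named list of them.
#' @export
predict.plm_model <- function(object, embeddings, ...) {
  cfg <- object$config
  single <- is.matrix(embeddings)
  embs <- if (single) list(embeddings) else embeddings
  # each protein runs through its own forward pass: batch composition can
  # then never change a protein's probabilities, not even in the last ulp
  out <- lapply(seq_along(embs), function(i) {
    emb <- embs[[i]]
    if (!is.matrix(emb) || ncol(emb) != cfg$input_dim)
      stop("embedding ", if (!single) names(embs)[i] else "", " has width ",
           ncol(emb), ", expected ", cfg$input_dim)
    P <- forward_stack(object$params, emb, nrow(emb), cfg$kernel_size)$P
    colnames(P) <- ligand_classes()[seq_len(cfg$n_classes)]
    P
  })
  if (single) return(out[[1L]])
  names(out) <- names(embs)
  out
}

#' Full prediction objects for a set of proteins
#'
#' Runs the model, binarizes at the decision threshold and attaches
#' reliability indices, returning one [binding_prediction()] per protein.
#'
#' @param model A trained `"plm_model"`.
#' @param embeddings Named list of `L x input_dim` matrices.
#' @param threshold Decision threshold (default: the model config's).
#' @return Named list of [binding_prediction()] objects (source `"DL"`).
#' @export
predict_binding <- function(model, embeddings, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$decision_threshold
  probs <- predict(model, embeddings)
  out <- lapply(names(probs), function(pid)
    binding_prediction(pid, probs[[pid]], threshold = threshold, source = "DL"))
  names(out) <- names(probs)
  out
}

#' Binarize a probability matrix
#'
#' A residue is called binding for a class when its probability reaches the
#' threshold; it is non-binding overall only when all class probabilities
#' are below the threshold. Calls are multi-label: one residue can be called
#' for several ligand classes.
#'
#' @param prob Numeric `L x 3` probability matrix.
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return List with `calls` (logical `L x 3`) and `any` (logical `L`).
#' @export
#' @examples
#' binarize(rbind(c(0.6, 0.2, 0.7), c(0.49, 0.49, 0.49)))
binarize <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  stopifnot(is.matrix(prob))
  calls <- prob >= threshold
  colnames(calls) <- ligand_classes()[seq_len(ncol(calls))]
  list(calls = calls, any = rowSums(calls) > 0L)
}

#' Reliability index of a prediction probability
#'
#' Maps a probability to a single-digit integer confidence: 0 at p = 0.5
#' (maximally uncertain) rising to 9 at p = 1 (confident binding) and
#' equally at p = 0 (confident non-binding). The raw index is
#' `|p - 0.5| * 9 / 0.5`; it is floored to an integer and clamped to
#' `[0, 9]`, which keeps the endpoints exact and the mapping monotone in
#' `|p - 0.5|` and symmetric (`RI(p) == RI(1 - p)`).
#'
#' @param p Probabilities in `[0, 1]` (vector, matrix or array; shape kept).
#' @return Integer reliability indices in `[0, 9]`, same shape as `p`.
#' @export
#' @examples
#' reliability_index(c(0.5, 0.75, 1, 0))
reliability_index <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  ri <- pmin(9L, as.integer(floor(abs(p - 0.5) * 18)))
  attributes(ri) <- attributes(p)
  if (is.matrix(ri)) colnames(ri) <- ligand_classes()[seq_len(ncol(ri))]
  storage.mode(ri) <- "integer"
  ri
}

#' Save a model checkpoint
#'
#' Serializes configuration, parameters and training history into a single
#' versioned checkpoint file (RDS).
#'
#' @param model A `"plm_model"`.
#' @param path Checkpoint path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "plm_model"))
  saveRDS(list(format = "plmbind-checkpoint", version = 1L,
               config = unclass(model$config), params = model$params,
               history = model$history, trained = model$trained),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_model()].
#' @return A `"plm_model"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "plmbind-checkpoint"))
    stop("not a plmbind checkpoint: ", path)
  cfg <- x$config
  class(cfg) <- "model_config"
  structure(list(config = cfg, params = x$params, history = x$history,
                 trained = x$trained),
            class = "plm_model")
}
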