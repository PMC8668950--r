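# Training of the two-layer convolutional sequence labeller.
#
# Proteins are concatenated into stacked design matrices (one per batch,
# assembled once and cached): the convolution taps of each residue are
# gathered through an index matrix whose out-of-sequence entries point at a
# single virtual zero row, which realizes zero same-padding without ever
# letting the kernel cross a protein boundary. Gradients follow by plain
# matrix calculus on the im2col representation.

adamax_step <- function(param, grad, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$u <- pmax(beta2 * state$u, abs(grad))
  list(param = param - (lr / (1 - beta1^t)) * state$m / (state$u + eps),
       state = state)
}

# backward pass for one stacked batch; returns gradients for all parameters
backward_stack <- function(params, fw, Y, class_weights, dropout_mask, idx) {
  n <- nrow(fw$P)
  C <- ncol(fw$P)
  W <- matrix(class_weights, n, C, byrow = TRUE)
  dZ2 <- ((1 - Y) * fw$P - W * Y * (1 - fw$P)) / (n * C)
  gW2 <- crossprod(fw$U2, dZ2)
  gb2 <- colSums(dZ2)
  dU2 <- dZ2 %*% t(params$W2)
  # col2im scatter-add back onto the (dropped-out) hidden activations;
  # for a fixed tap the output->input row map is injective, so indexed
  # addition accumulates correctly
  h <- ncol(fw$H)
  dHd <- matrix(0, n, h)
  for (j in seq_len(ncol(idx))) {
    rows <- idx[, j]
    keep <- rows <= n
    if (any(keep))
      dHd[rows[keep], ] <- dHd[rows[keep], , drop = FALSE] +
        dU2[keep, ((j - 1L) * h + 1L):(j * h), drop = FALSE]
  }
  dH <- if (is.null(dropout_mask)) dHd else dHd * dropout_mask
  dZ1 <- dH * elu_grad(fw$Z1, fw$H)
  gW1 <- crossprod(fw$U1, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

stack_set <- function(embeddings, annotations, ids, k) {
  embs <- embeddings[ids]
  lengths <- vapply(embs, nrow, integer(1))
  Y <- do.call(rbind, lapply(ids, function(pid)
    matrix(as.numeric(annotations[[pid]]), nrow(annotations[[pid]]), 3L)))
  idx <- conv_tap_index(lengths, k)
  list(X = do.call(rbind, embs), Y = Y, lengths = lengths, idx = idx)
}

#' Train the convolutional binding-residue model
#'
#' Minimizes the class-weighted per-channel binary cross-entropy over all
#' residues of the training proteins with the Adamax optimizer. Proteins are
#' grouped into batches of at most `config$batch_size` (one seeded shuffle
#' fixes batch membership). Training stops early when the validation loss
#' has not improved for `config$patience` epochs and the parameters of the
#' best validation epoch are restored. When no validation set is supplied,
#' a seeded fraction `config$val_fraction` of the training proteins is held
#' out; with too few proteins to split, the training loss is monitored.
#'
#' @param model A `"plm_model"` from [build_model()].
#' @param embeddings Named list of `L x input_dim` training matrices.
#' @param annotations Named list of [residue_annotations()], same names.
#' @param val_embeddings,val_annotations Optional explicit validation set.
#' @param max_epochs Override of `config$max_epochs`.
#' @param verbose Print per-epoch losses.
#' @return The trained `"plm_model"`; `$history` holds per-epoch training
#'   and validation losses plus the selected best epoch as an attribute.
#' @export
train_model <- function(model, embeddings, annotations,
                        val_embeddings = NULL, val_annotations = NULL,
                        max_epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "plm_model"))
  cfg <- model$config
  if (length(embeddings) == 0L) stop("empty training set")
  ids <- names(embeddings)
  if (is.null(ids) || !all(ids %in% names(annotations)))
    stop("every training protein needs annotations with a matching name")
  for (pid in ids)
    check_length_match(annotations[[pid]], nrow(embeddings[[pid]]),
                       "annotations", pid)
  if (is.null(max_epochs)) max_epochs <- cfg$max_epochs

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  if (is.null(val_embeddings)) {
    n_val <- floor(length(ids) * cfg$val_fraction)
    if (n_val >= 1L && length(ids) - n_val >= 1L) {
      val_ids <- sample(ids, n_val)
      train_ids <- setdiff(ids, val_ids)
      val_embeddings <- embeddings[val_ids]
      val_annotations <- annotations[val_ids]
    } else {
      # too few proteins to hold any out: monitor the training loss
      train_ids <- ids
      val_embeddings <- embeddings
      val_annotations <- annotations
    }
  } else {
    train_ids <- ids
    for (pid in names(val_embeddings))
      check_length_match(val_annotations[[pid]], nrow(val_embeddings[[pid]]),
                         "annotations", pid)
  }

  # fixed seeded batch assignment, cached design matrices
  train_ids <- sample(train_ids)
  batches_ids <- split(train_ids, ceiling(seq_along(train_ids) / cfg$batch_size))
  batches <- lapply(batches_ids, function(b) {
    s <- stack_set(embeddings, annotations, b, cfg$kernel_size)
    s$U1 <- im2col_gather(s$X, s$idx)
    s$X <- NULL
    s
  })
  val <- stack_set(val_embeddings, val_annotations, names(val_embeddings),
                   cfg$kernel_size)

  params <- model$params
  states <- lapply(params, function(p)
    list(m = p * 0, u = p * 0))
  t_step <- 0L
  keep_prob <- 1 - cfg$dropout_rate
  n_hidden <- cfg$hidden_channels

  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(max_epochs)) {
    epoch_loss <- 0
    epoch_n <- 0L
    for (b in batches) {
      n <- sum(b$lengths)
      mask <- if (keep_prob < 1)
        matrix((runif(n * n_hidden) < keep_prob) / keep_prob, n, n_hidden)
      else NULL
      fw <- forward_stack(params, NULL, b$lengths, cfg$kernel_size,
                          dropout_mask = mask, keep = TRUE,
                          U1 = b$U1, idx = b$idx)
      loss <- weighted_bce(fw$Z2, b$Y, cfg$class_weights)
      grads <- backward_stack(params, fw, b$Y, cfg$class_weights, mask, b$idx)
      t_step <- t_step + 1L
      for (nm in names(params)) {
        upd <- adamax_step(params[[nm]], grads[[nm]], states[[nm]],
                           cfg$learning_rate, t_step)
        params[[nm]] <- upd$param
        states[[nm]] <- upd$state
      }
      epoch_loss <- epoch_loss + loss$loss * n
      epoch_n <- epoch_n + n
    }
    train_loss <- epoch_loss / epoch_n

    vfw <- forward_stack(params, val$X, val$lengths, cfg$kernel_size, idx = val$idx)
    val_loss <- weighted_bce(vfw$Z2, val$Y, cfg$class_weights)$loss
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, train_loss, val_loss))

    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss
      best_params <- params
      best_epoch <- epoch
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > cfg$patience) break
    }
  }

  attr(history, "best_epoch") <- best_epoch
  structure(list(config = cfg, params = best_params, history = history,
                 trained = TRUE),
            class = "plm_model")
}
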