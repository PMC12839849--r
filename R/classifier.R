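
#' Configuration for the subtype classifier
#'
#' A fully connected network mapping functional spectra to subtype
#' probabilities. The default architecture is input -> 128 -> 32 -> 10 ->
#' classes with rectified-linear activations; the width of the last hidden
#' layer (10) is the number of deep features exposed downstream.
#'
#' @param hidden_layer_widths Integer widths of the hidden layers; the last
#'   one (>= 2) is the deep-feature dimension K.
#' @param activation Hidden activation; only `"relu"` is implemented.
#' @param max_epochs Training epoch cap.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param validation_fraction Fraction of labelled samples held out for
#'   validation / early stopping (stratified by class).
#' @param patience Early-stop patience (epochs without validation-loss
#'   improvement); best-epoch weights are restored.
#' @param class_weights `"none"` (default) or `"inverse_frequency"` to
#'   up-weight rare subtypes in the loss.
#' @param seed Seed driving initialization, the validation split and batch
#'   shuffling.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden_layer_widths = c(128L, 32L, 10L),
                              activation = "relu",
                              max_epochs = 200L,
                              batch_size = 32L,
                              learning_rate = 1e-3,
                              validation_fraction = 0.2,
                              patience = 20L,
                              class_weights = c("none", "inverse_frequency"),
                              seed = 1L) {
  widths <- vapply(hidden_layer_widths, check_count, integer(1L), name = "hidden width")
  if (length(widths) < 1L || widths[length(widths)] < 2L) {
    abort("Last hidden width (deep-feature dimension K) must be >= 2.")
  }
  if (!identical(activation, "relu")) abort("Only the 'relu' activation is implemented.")
  structure(list(
    hidden_layer_widths = widths,
    activation = activation,
    max_epochs = check_count(max_epochs, "max_epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = check_scalar_number(learning_rate, "learning_rate"),
    validation_fraction = check_scalar_number(validation_fraction,
                                              "validation_fraction", 0, 0.9),
    patience = check_count(patience, "patience"),
    class_weights = match.arg(class_weights),
    seed = check_count(seed, "seed")
  ), class = "classifier_config")
}

relu <- function(x) pmax(x, 0)

mlp_init <- function(widths) {
  # He-normal initialization; hidden biases slightly positive so rectified
  # units start active (keeps the deep-feature layer from going dark)
  n_layer <- length(widths) - 1L
  lapply(seq_len(n_layer), function(l) {
    list(
      W = matrix(rnorm(widths[l] * widths[l + 1L], sd = sqrt(2 / widths[l])),
                 nrow = widths[l]),
      b = rep(if (l < n_layer) 0.01 else 0, widths[l + 1L])
    )
  })
}

mlp_forward <- function(layers, X) {
  # returns activations per layer; last entry holds class probabilities
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(layers)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < length(layers)) relu(Z) else softmax_rows(Z)
  }
  acts
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

weighted_ce <- function(P, y_idx, w_obs) {
  -sum(w_obs * log(pmax(P[cbind(seq_along(y_idx), y_idx)], 1e-12))) / sum(w_obs)
}

mlp_backward <- function(layers, acts, y_idx, w_obs) {
  grads <- vector("list", length(layers))
  n_eff <- sum(w_obs)
  # softmax + cross-entropy: dL/dZ_out = w * (P - Y) / sum(w)
  delta <- acts[[length(acts)]]
  delta[cbind(seq_along(y_idx), y_idx)] <-
    delta[cbind(seq_along(y_idx), y_idx)] - 1
  delta <- delta * (w_obs / n_eff)
  for (l in rev(seq_along(layers))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0
  ))
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(layers)) {
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[l]]$W
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[l]]$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[l]]$b
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[l]]$b^2
    mW_hat <- st$mW / (1 - beta1^t); vW_hat <- st$vW / (1 - beta2^t)
    mb_hat <- st$mb / (1 - beta1^t); vb_hat <- st$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

#' Train the subtype classifier on functional spectra
#'
#' Cross-entropy training with the Adam first-order stochastic optimizer,
#' mini-batches, a seeded validation split, and early stopping on validation
#' loss with best-weights restore. Unlabelled (`NOLBL` / `NA`) samples are
#' excluded from both splits; they can still be embedded afterwards.
#' Deterministic given `config$seed`.
#'
#' @param spectra A `functional_spectra` matrix (samples x sets).
#' @param labels Character vector of subtype labels aligned with the spectra
#'   rows (CMS1..CMS4, `NOLBL` or `NA` for unlabelled).
#' @param config A [classifier_config()].
#' @return A `subtype_classifier` with layer weights, the feature contract
#'   (`set_names`), class labels, input standardization parameters, training
#'   history and held-out accuracy.
#' @export
train_classifier <- function(spectra, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (nrow(spectra) != length(labels)) {
    abort("`labels` must align with the rows of `spectra`.")
  }
  labelled <- !is.na(labels) & labels != "NOLBL"
  y_all <- labels[labelled]
  classes <- sort(unique(y_all))
  if (length(classes) < 2L) abort("Need at least 2 distinct subtype labels to train.")
  X_all <- unclass(spectra)[labelled, , drop = FALSE]

  # z-score the input features with training statistics (stored in the model)
  mu <- colMeans(X_all)
  sdv <- apply(X_all, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X_all, 2L, mu), 2L, sdv, `/`)
  y_idx <- match(y_all, classes)

  cw <- if (config$class_weights == "inverse_frequency") {
    tab <- tabulate(y_idx, nbins = length(classes))
    w <- length(y_idx) / (length(classes) * tab)
    w / mean(w)
  } else {
    rep(1, length(classes))
  }

  widths <- c(ncol(Xs), config$hidden_layer_widths, length(classes))
  n <- nrow(Xs)

  fit <- with_seed(config$seed, {
    # stratified validation split: the held-out class mix matches the
    # cohort's, so validation metrics are comparable across seeds even with
    # skewed subtype priors
    val_idx <- unlist(lapply(seq_along(classes), function(k) {
      members <- which(y_idx == k)
      n_k <- max(1L, round(config$validation_fraction * length(members)))
      sample(members, min(n_k, length(members)))
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)
    layers <- mlp_init(widths)
    # start the output head at the prior-predicting point: zero weights and
    # log-prior biases, so a no-signal fit degrades gracefully to the
    # marginal class distribution instead of chasing noise
    tab0 <- tabulate(y_idx[tr_idx], nbins = length(classes))
    layers[[length(layers)]]$W[] <- 0
    layers[[length(layers)]]$b <- log(pmax(tab0, 0.5) / sum(tab0))
    state <- adam_state(layers)
    P0 <- mlp_forward(layers, Xs[val_idx, , drop = FALSE])[[length(layers) + 1L]]
    best <- list(loss = weighted_ce(P0, y_idx[val_idx], cw[y_idx[val_idx]]),
                 layers = layers, epoch = 0L)
    history <- vector("list", config$max_epochs)
    t_step <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acts <- mlp_forward(layers, Xs[batch, , drop = FALSE])
        grads <- mlp_backward(layers, acts, y_idx[batch], cw[y_idx[batch]])
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, config$learning_rate, t_step)
        layers <- upd$layers
        state <- upd$state
      }
      P_tr <- mlp_forward(layers, Xs[tr_idx, , drop = FALSE])[[length(layers) + 1L]]
      P_val <- mlp_forward(layers, Xs[val_idx, , drop = FALSE])[[length(layers) + 1L]]
      tr_loss <- weighted_ce(P_tr, y_idx[tr_idx], cw[y_idx[tr_idx]])
      val_loss <- weighted_ce(P_val, y_idx[val_idx], cw[y_idx[val_idx]])
      val_acc <- mean(max.col(P_val) == y_idx[val_idx])
      history[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss,
                                 val_loss = val_loss, val_accuracy = val_acc)
      if (val_loss < best$loss - 1e-4) {
        best <- list(loss = val_loss, layers = layers, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
    P_val <- mlp_forward(best$layers, Xs[val_idx, , drop = FALSE])[[length(widths)]]
    list(
      layers = best$layers,
      history = dplyr::bind_rows(history),
      heldout_accuracy = mean(max.col(P_val) == y_idx[val_idx]),
      val_idx = val_idx
    )
  })

  structure(list(
    layers = fit$layers,
    set_names = colnames(spectra),
    classes = classes,
    input_center = mu,
    input_scale = sdv,
    class_weights = cw,
    config = config,
    history = fit$history,
    heldout_accuracy = fit$heldout_accuracy,
    validation_samples = rownames(spectra)[labelled][fit$val_idx]
  ), class = "subtype_classifier")
}

align_spectra <- function(model, spectra) {
  missing <- setdiff(model$set_names, colnames(spectra))
  if (length(missing) > 0L) {
    abort(glue(
      "Spectra lack gene set(s) of the model's feature contract: ",
      "{paste(head(missing, 5L), collapse = ', ')}."
    ))
  }
  X <- unclass(spectra)[, model$set_names, drop = FALSE]
  sweep(sweep(X, 2L, model$input_center), 2L, model$input_scale, `/`)
}

#' Predict subtype probabilities and labels
#'
#' @param model A trained `subtype_classifier`.
#' @param spectra Functional spectra whose columns cover the model's feature
#'   contract (aligned by set name).
#' @return Tibble with `sample_id`, `.pred_class`, and one probability column
#'   per class (rows sum to 1).
#' @export
predict_subtype <- function(model, spectra) {
  stopifnot(inherits(model, "subtype_classifier"))
  X <- align_spectra(model, spectra)
  P <- mlp_forward(model$layers, X)[[length(model$layers) + 1L]]
  colnames(P) <- model$classes
  dplyr::bind_cols(
    tibble(
      sample_id = rownames(spectra),
      .pred_class = model$classes[max.col(P, ties.method = "first")]
    ),
    as_tibble(P, .name_repair = "minimal")
  )
}

#' Extract deep features (last hidden layer)
#'
#' The K-dimensional feature vector of the model's last hidden layer for
#' each sample: a learned low-dimensional embedding of subtype biology, used
#' downstream for signature distillation. The pre-rectification values of
#' the layer are returned — the continuous linear embedding rather than its
#' half-rectified transform — so every latent coordinate remains informative
#' for the Pearson-correlation distillation step. Pure function of
#' (model, spectra).
#'
#' @inheritParams predict_subtype
#' @return Samples x K numeric matrix (columns `DF1..DFK`).
#' @export
extract_deep_features <- function(model, spectra) {
  stopifnot(inherits(model, "subtype_classifier"))
  X <- align_spectra(model, spectra)
  acts <- mlp_forward(model$layers, X)
  l_last <- length(model$layers) - 1L  # index of the last hidden layer
  prev <- acts[[l_last]]
  deep <- sweep(prev %*% model$layers[[l_last]]$W, 2L,
                model$layers[[l_last]]$b, `+`)
  colnames(deep) <- sprintf("DF%d", seq_len(ncol(deep)))
  rownames(deep) <- rownames(spectra)
  deep
}

#' @export
print.subtype_classifier <- function(x, ...) {
  widths <- c(length(x$set_names), x$config$hidden_layer_widths, length(x$classes))
  cat("<subtype_classifier>\n")
  cat("  architecture:", paste(widths, collapse = " -> "), "\n")
  cat(glue("  held-out accuracy: {round(x$heldout_accuracy, 3)}"), "\n")
  invisible(x)
}
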