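#' Feed-forward network configuration
#'
#' The classifier is a small fully-connected network, 401-200-75-10-3 by
#' default, with sigmoid activations on every hidden and output layer and
#' three independent sigmoid outputs (one per class; no softmax) trained with
#' binary cross-entropy and Adam. The input layer is sized to the feature
#' length (401: 300 anterior + RPE pixel + 100 posterior).
#'
#' @param layer_sizes Integer vector of layer widths, input first; the final
#'   layer must have size 3.
#' @param learning_rate Adam step size (default 0.001).
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decay rates and
#'   stabilizer (defaults 0.9, 0.999, 1e-8).
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (default 10).
#' @param seed Seed for weight initialization and epoch shuffling.
#' @return An object of class `network_config`.
#' @export
network_config <- function(layer_sizes = c(401, 200, 75, 10, 3),
                           learning_rate = 0.001,
                           adam_beta1 = 0.9, adam_beta2 = 0.999,
                           adam_epsilon = 1e-8,
                           batch_size = 128, max_epochs = 200, patience = 10,
                           seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1))
    abort_validation("layer_sizes must be >= 2 positive integers")
  if (layer_sizes[length(layer_sizes)] != 3)
    abort_validation("the output layer must have size 3 (PED, RD, NEITHER)")
  if (learning_rate <= 0) abort_validation("learning_rate must be > 0")
  if (!is_count(batch_size) || !is_count(max_epochs) || !is_count(patience))
    abort_validation("batch_size, max_epochs, patience must be positive integers")
  structure(list(layer_sizes = layer_sizes, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_epsilon = adam_epsilon, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Per-class sampling budget
#'
#' During training, equal numbers of feature vectors are drawn from each
#' class so that class imbalance (RD A-scans vastly outnumber PED) does not
#' bias the classifier. The default quota of 14,000 per class matches the
#' study design.
#'
#' @param per_class_quota Maximum samples retained per class (default 14000).
#' @return An object of class `training_budget`.
#' @export
training_budget <- function(per_class_quota = 14000) {
  if (!is_count(per_class_quota)) abort_validation("per_class_quota must be >= 1")
  structure(list(per_class_quota = as.integer(per_class_quota)),
            class = "training_budget")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a network
#'
#' Weights are drawn uniformly from `[-a, a]` with `a = sqrt(3 / fan_in)`
#' (unit-variance-preserving, fan-in scaled); biases start at zero, as do the
#' Adam moment accumulators. Fully determined by `config$seed`.
#'
#' @param config A [network_config()].
#' @return An object of class `mlp_model` with fields `weights`, `biases`,
#'   `config`, `opt` (Adam state), `history`.
#' @export
init_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  sizes <- config$layer_sizes
  n_layers <- length(sizes) - 1
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  with_seed(config$seed, {
    for (l in seq_len(n_layers)) {
      a <- sqrt(3 / sizes[l])
      weights[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -a, a),
                             sizes[l], sizes[l + 1])
      biases[[l]] <- numeric(sizes[l + 1])
    }
  })
  structure(
    list(weights = weights, biases = biases, config = config,
         opt = list(mW = lapply(weights, function(w) w * 0),
                    vW = lapply(weights, function(w) w * 0),
                    mb = lapply(biases, function(b) b * 0),
                    vb = lapply(biases, function(b) b * 0),
                    step = 0L),
         history = data.frame(epoch = integer(0), train_loss = numeric(0),
                              val_loss = numeric(0))),
    class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s, sigmoid activations, %d training epoch(s) recorded\n",
              paste(x$config$layer_sizes, collapse = "-"), nrow(x$history)))
  invisible(x)
}

# Forward pass keeping all layer activations (input first) for backprop.
forward_all <- function(model, x) {
  acts <- vector("list", length(model$weights) + 1)
  acts[[1]] <- x
  for (l in seq_along(model$weights)) {
    z <- acts[[l]] %*% model$weights[[l]]
    z <- sweep(z, 2, model$biases[[l]], "+")
    acts[[l + 1]] <- sigmoid(z)
  }
  acts
}

#' Forward pass
#'
#' Propagates a batch through every layer (`sigmoid(W'x + b)` at each) and
#' returns the three per-class sigmoid outputs in `(0, 1)`.
#'
#' @param model An [init_network()] model.
#' @param batch Numeric matrix (samples x input size).
#' @return Matrix (samples x 3), columns ordered as [signature_classes()].
#' @export
forward <- function(model, batch) {
  stopifnot(inherits(model, "mlp_model"))
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1)
  if (ncol(batch) != model$config$layer_sizes[1])
    abort_validation("batch width (%d) does not match input layer (%d)",
                     ncol(batch), model$config$layer_sizes[1])
  out <- forward_all(model, batch)[[length(model$weights) + 1]]
  colnames(out) <- signature_classes()
  out
}

#' Binary cross-entropy loss
#'
#' Mean over samples and the three output units of
#' `-(t log p + (1 - t) log(1 - p))`, with predictions clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param predictions Matrix of probabilities in `(0, 1)`.
#' @param targets One-hot matrix of the same shape.
#' @return Scalar loss.
#' @export
bce_loss <- function(predictions, targets) {
  if (!identical(dim(predictions), dim(targets)))
    abort_validation("predictions and targets must have identical shapes")
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

#' One-hot encode class labels
#'
#' @param labels Factor or character over [signature_classes()].
#' @return Matrix (n x 3) of 0/1, columns in class order.
#' @export
one_hot <- function(labels) {
  f <- factor(as.character(labels), levels = signature_classes())
  if (anyNA(f)) abort_validation("labels must be PED, RD, or NEITHER")
  out <- matrix(0, length(f), 3, dimnames = list(NULL, signature_classes()))
  out[cbind(seq_along(f), as.integer(f))] <- 1
  out
}

# Backpropagation: gradients of mean BCE w.r.t. every weight and bias.
# Sigmoid output + BCE gives dL/dz_out = (p - t) / (n * 3).
mlp_gradients <- function(model, x, targets) {
  acts <- forward_all(model, x)
  L <- length(model$weights)
  n <- nrow(x)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (acts[[L + 1]] - targets) / (n * ncol(targets))
  for (l in L:1) {
    gW[[l]] <- unname(crossprod(acts[[l]], delta))
    gb[[l]] <- unname(colSums(delta))
    if (l > 1) {
      a <- acts[[l]]
      delta <- (delta %*% t(model$weights[[l]])) * a * (1 - a)
    }
  }
  list(gW = gW, gb = gb)
}

adam_update <- function(model, grads) {
  cfg <- model$config
  model$opt$step <- model$opt$step + 1L
  t <- model$opt$step
  c1 <- 1 - cfg$adam_beta1^t
  c2 <- 1 - cfg$adam_beta2^t
  for (l in seq_along(model$weights)) {
    model$opt$mW[[l]] <- cfg$adam_beta1 * model$opt$mW[[l]] + (1 - cfg$adam_beta1) * grads$gW[[l]]
    model$opt$vW[[l]] <- cfg$adam_beta2 * model$opt$vW[[l]] + (1 - cfg$adam_beta2) * grads$gW[[l]]^2
    model$weights[[l]] <- model$weights[[l]] -
      cfg$learning_rate * (model$opt$mW[[l]] / c1) / (sqrt(model$opt$vW[[l]] / c2) + cfg$adam_epsilon)
    model$opt$mb[[l]] <- cfg$adam_beta1 * model$opt$mb[[l]] + (1 - cfg$adam_beta1) * grads$gb[[l]]
    model$opt$vb[[l]] <- cfg$adam_beta2 * model$opt$vb[[l]] + (1 - cfg$adam_beta2) * grads$gb[[l]]^2
    model$biases[[l]] <- model$biases[[l]] -
      cfg$learning_rate * (model$opt$mb[[l]] / c1) / (sqrt(model$opt$vb[[l]] / c2) + cfg$adam_epsilon)
  }
  model
}

#' Train a network by mini-batch backpropagation with Adam
#'
#' Shuffles samples each epoch (seeded), updates parameters per mini-batch
#' with bias-corrected Adam, records the per-epoch training and validation
#' loss, and stops once the validation loss has not improved for
#' `config$patience` epochs (or at `max_epochs`), restoring the
#' best-validation parameters. Without a validation set, the training loss
#' drives early stopping.
#'
#' @param model An [init_network()] model.
#' @param x,y Training features (normalized) and one-hot targets.
#' @param x_val,y_val Optional validation features and targets.
#' @return The trained `mlp_model` with populated `history`.
#' @export
train_mlp <- function(model, x, y, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  if (nrow(x) == 0) abort_validation("training set is empty")
  if (!identical(dim(y), c(nrow(x), 3L)) && !identical(dim(y), c(nrow(x), 3)))
    abort_validation("y must be a one-hot matrix with 3 columns")
  cfg <- model$config
  n <- nrow(x)
  best <- list(loss = Inf, weights = model$weights, biases = model$biases)
  stall <- 0
  hist <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- with_seed(derive_seed(cfg$seed, epoch), sample.int(n))
    for (ofs in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[ofs:min(ofs + cfg$batch_size - 1, n)]
      grads <- mlp_gradients(model, x[idx, , drop = FALSE], y[idx, , drop = FALSE])
      model <- adam_update(model, grads)
    }
    train_loss <- bce_loss(forward(model, x), y)
    val_loss <- if (is.null(x_val)) train_loss else bce_loss(forward(model, x_val), y_val)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, weights = model$weights, biases = model$biases)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= cfg$patience) break
    }
  }
  model$weights <- best$weights
  model$biases <- best$biases
  model$history <- do.call(rbind, Filter(Negate(is.null), hist))
  model
}

#' Predict class probabilities and labels
#'
#' `predict_proba` returns the three independent sigmoid outputs;
#' `predict_label` takes the per-sample argmax, with ties resolved by class
#' priority PED > RD > NEITHER.
#'
#' @param model A trained `mlp_model`.
#' @param features Numeric matrix (samples x input size), normalized.
#' @return `predict_proba`: matrix (n x 3); `predict_label`: factor over
#'   [signature_classes()].
#' @export
predict_proba <- function(model, features) forward(model, features)

#' @rdname predict_proba
#' @export
predict_label <- function(model, features) {
  p <- forward(model, features)
  factor(signature_classes()[max.col(p, ties.method = "first")],
         levels = signature_classes())
}

#' Class-balanced subsampling
#'
#' Uniform random sampling without replacement of at most
#' `budget$per_class_quota` samples per class; classes below quota are kept
#' whole. Every class must be present.
#'
#' @param dataset A [labeled_feature_set()].
#' @param budget A [training_budget()].
#' @param seed Sampling seed.
#' @return A [labeled_feature_set()] with balanced class counts.
#' @export
balanced_sample <- function(dataset, budget = training_budget(), seed = 1L) {
  stopifnot(inherits(dataset, "labeled_feature_set"),
            inherits(budget, "training_budget"))
  keep <- with_seed(seed, {
    unlist(lapply(signature_classes(), function(k) {
      idx <- which(dataset$labels == k)
      if (!length(idx))
        abort_validation("class %s is absent from the dataset", k)
      if (length(idx) <= budget$per_class_quota) idx
      else sort(sample(idx, budget$per_class_quota))
    }))
  })
  subset_feature_set(dataset, keep)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the configuration, training
#' history, and full-precision parameters.
#'
#' @param model An `mlp_model`.
#' @param path Checkpoint path.
#' @return `load_model` returns the restored `mlp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  jsonlite::write_json(
    list(config = unclass(model$config),
         weights = lapply(model$weights, function(w) list(dim = dim(w), data = as.vector(w))),
         biases = model$biases,
         history = model$history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, j$config[c("layer_sizes", "learning_rate",
                                            "adam_beta1", "adam_beta2", "adam_epsilon",
                                            "batch_size", "max_epochs", "patience", "seed")])
  model <- init_network(cfg)
  model$weights <- lapply(seq_along(model$weights), function(l)
    matrix(j$weights$data[[l]], j$weights$dim[[l]][1], j$weights$dim[[l]][2]))
  model$biases <- lapply(seq_along(model$biases), function(l) as.numeric(j$biases[[l]]))
  model$history <- as.data.frame(j$history)
  model
}
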