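# Multilayer perceptron classifier: dense 64-sigmoid / 32-relu / 32-relu
# hidden stack with a dropout layer after each hidden layer, softmax or
# sigmoid head, trained with Nadam (Nesterov-accelerated Adam) on
# categorical / binary cross-entropy. Implemented directly in matrix code
# so training is fully seeded and single-threaded-reproducible.

#' MLP configuration
#'
#' Defaults follow the reference training regimes: hidden widths 64/32/32
#' with sigmoid then ReLU activations, Nadam with learning rate 0.002,
#' per-iteration decay 0.004, beta1 = 0.9, beta2 = 0.999; 200 epochs at
#' batch size 6 for the 3-class task, 100 epochs at batch size 32 for the
#' binary task. Dropout rates are tunable (the reference architecture
#' places a dropout layer after each hidden layer without printing the
#' rates; 0.3/0.2/0.2 here).
#'
#' @param input_dim number of input features (2G).
#' @param mode `"multiclass"` (3-way softmax head, categorical
#'   cross-entropy) or `"binary"` (single sigmoid, binary cross-entropy).
#' @param hidden_widths positive integer vector.
#' @param hidden_activations `"sigmoid"`/`"relu"` per hidden layer.
#' @param dropout_rates rate in `[0, 1)` per hidden layer.
#' @param learning_rate,decay,beta1,beta2 Nadam hyperparameters; the
#'   effective rate at iteration t is `learning_rate / (1 + decay * t)`.
#' @param epochs training epochs (default 200 multiclass / 100 binary).
#' @param batch_size minibatch size (default 6 multiclass / 32 binary).
#' @param seed seed for weight init, shuffling and dropout masks.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(input_dim,
                       mode = c("multiclass", "binary"),
                       hidden_widths = c(64L, 32L, 32L),
                       hidden_activations = c("sigmoid", "relu", "relu"),
                       dropout_rates = c(0.3, 0.2, 0.2),
                       learning_rate = 0.002,
                       decay = 0.004,
                       beta1 = 0.9,
                       beta2 = 0.999,
                       epochs = NULL,
                       batch_size = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  input_dim <- stopifnot_count(input_dim, "input_dim")
  if (length(hidden_widths) != length(hidden_activations) ||
      length(hidden_widths) != length(dropout_rates)) {
    stop("hidden_widths, hidden_activations and dropout_rates must have equal length",
         call. = FALSE)
  }
  if (any(hidden_widths < 1)) stop("hidden widths must be positive",
                                   call. = FALSE)
  if (!all(hidden_activations %in% c("sigmoid", "relu"))) {
    stop("hidden activations must be 'sigmoid' or 'relu'", call. = FALSE)
  }
  if (any(dropout_rates < 0 | dropout_rates >= 1)) {
    stop("dropout rates must be in [0, 1)", call. = FALSE)
  }
  if (is.null(epochs)) epochs <- if (mode == "multiclass") 200L else 100L
  if (is.null(batch_size)) batch_size <- if (mode == "multiclass") 6L else 32L
  epochs <- stopifnot_count(epochs, "epochs", min = 0L)
  batch_size <- stopifnot_count(batch_size, "batch_size")
  seed <- stopifnot_count(seed, "seed", min = 0L)

  structure(list(
    input_dim = input_dim, mode = mode,
    hidden_widths = as.integer(hidden_widths),
    hidden_activations = hidden_activations,
    dropout_rates = as.numeric(dropout_rates),
    output_dim = if (mode == "multiclass") 3L else 1L,
    loss = if (mode == "multiclass") "categorical_crossentropy"
           else "binary_crossentropy",
    learning_rate = learning_rate, decay = decay,
    beta1 = beta1, beta2 = beta2,
    epochs = epochs, batch_size = batch_size, seed = seed),
    class = "mlp_config")
}

#' Build an untrained MLP
#'
#' Dense layers with Glorot-uniform weight initialization (seeded) and zero
#' biases, in the sequence input -> hidden stack -> output head.
#'
#' @param config an [mlp_config()].
#' @return an object of class `mlp_model` with elements `config`, `W`
#'   (list of weight matrices, fan_in x fan_out) and `b` (list of bias
#'   vectors).
#' @export
build_mlp <- function(config) {
  stopifnot(inherits(config, "mlp_config"))
  dims <- c(config$input_dim, config$hidden_widths, config$output_dim)
  with_seed(config$seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      limit <- sqrt(6 / (dims[l] + dims[l + 1L]))
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -limit, limit),
                       nrow = dims[l], ncol = dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    structure(list(config = config, W = W, b = b), class = "mlp_model")
  })
}

#' Trainable parameter count of an MLP
#'
#' Equals the closed-form sum of `(fan_in + 1) * fan_out` over the dense
#' layers.
#'
#' @param model an [mlp_model][build_mlp()].
#' @return integer parameter count.
#' @export
mlp_n_params <- function(model) {
  stopifnot(inherits(model, "mlp_model"))
  sum(vapply(seq_along(model$W),
             function(l) length(model$W[[l]]) + length(model$b[[l]]),
             numeric(1)))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

# forward pass; when training, draws inverted-dropout masks from the
# current RNG stream and returns everything backprop needs.
.mlp_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  L <- length(cfg$hidden_widths)
  a <- X
  zs <- vector("list", L + 1L)
  as <- vector("list", L + 1L)  # post-activation, post-dropout
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], `+`)
    h <- if (cfg$hidden_activations[l] == "sigmoid") .sigmoid(z)
         else pmax(z, 0)
    if (training && cfg$dropout_rates[l] > 0) {
      p <- cfg$dropout_rates[l]
      mask <- matrix(stats::rbinom(length(h), 1L, 1 - p) / (1 - p),
                     nrow = nrow(h))
      h <- h * mask
      masks[[l]] <- mask
    }
    zs[[l]] <- z
    as[[l]] <- h
    a <- h
  }
  z_out <- sweep(a %*% model$W[[L + 1L]], 2L, model$b[[L + 1L]], `+`)
  out <- if (cfg$mode == "multiclass") .softmax(z_out) else .sigmoid(z_out)
  list(out = out, zs = zs, as = as, masks = masks, X = X)
}

# mean cross-entropy of predictions vs target matrix Y (one-hot or 0/1)
.mlp_loss <- function(out, Y, mode) {
  eps <- 1e-12
  if (mode == "multiclass") {
    -mean(rowSums(Y * log(pmax(out, eps))))
  } else {
    -mean(Y * log(pmax(out, eps)) + (1 - Y) * log(pmax(1 - out, eps)))
  }
}

.one_hot <- function(labels, K) {
  Y <- matrix(0, nrow = length(labels), ncol = K)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

.labels_to_Y <- function(labels, cfg) {
  if (cfg$mode == "multiclass") .one_hot(labels, cfg$output_dim)
  else matrix(labels, ncol = 1L)
}

#' Train an MLP on a dataset split
#'
#' Runs exactly `config$epochs` epochs of shuffled minibatch Nadam on the
#' training partition; the validation partition is used for monitoring
#' only (no early stopping — the epoch count is fixed). Per-epoch train and
#' validation loss/accuracy are recorded with dropout disabled. The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param model an untrained (or further-trainable) [build_mlp()] model.
#' @param split a [split_dataset()]/[build_st_dataset()] split whose
#'   feature width matches `config$input_dim` and whose labels match the
#'   head (`0..2` multiclass, `0/1` binary).
#' @param verbose print a line every 10 epochs.
#' @return list with `model` (trained) and `history` (data.frame with
#'   columns `epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_mlp <- function(model, split, verbose = FALSE) {
  stopifnot(inherits(model, "mlp_model"), inherits(split, "dataset_split"))
  cfg <- model$config
  X <- split$train$features
  labels <- as.integer(split$train$meta$label)
  if (ncol(X) != cfg$input_dim) {
    stop(sprintf("configuration error: features have %d columns, model expects %d",
                 ncol(X), cfg$input_dim), call. = FALSE)
  }
  if (any(labels < 0L) || any(labels >= max(cfg$output_dim, 2L))) {
    stop("configuration error: labels do not match the output head",
         call. = FALSE)
  }
  Y <- .labels_to_Y(labels, cfg)
  Xv <- split$validation$features
  Yv <- .labels_to_Y(as.integer(split$validation$meta$label), cfg)

  if (cfg$epochs == 0L) {
    return(list(model = model,
                history = data.frame(epoch = integer(0), loss = numeric(0),
                                     accuracy = numeric(0),
                                     val_loss = numeric(0),
                                     val_accuracy = numeric(0))))
  }

  n <- nrow(X)
  L <- length(cfg$hidden_widths)
  n_tensors <- 2L * (L + 1L)
  m_state <- lapply(c(model$W, model$b), function(w) w * 0)
  v_state <- m_state
  step <- 0L
  eps <- 1e-7
  history <- vector("list", cfg$epochs)

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fwd <- .mlp_forward(model, Xb, training = TRUE)

        # backprop: softmax+CE and sigmoid+BCE share delta = (p - y) / B
        grads_W <- vector("list", L + 1L)
        grads_b <- vector("list", L + 1L)
        delta <- (fwd$out - Yb) / nrow(Xb)
        for (l in seq(L + 1L, 1L)) {
          a_prev <- if (l == 1L) fwd$X else fwd$as[[l - 1L]]
          grads_W[[l]] <- crossprod(a_prev, delta)
          grads_b[[l]] <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(model$W[[l]])
            if (!is.null(fwd$masks[[l - 1L]])) {
              delta <- delta * fwd$masks[[l - 1L]]
            }
            if (cfg$hidden_activations[l - 1L] == "sigmoid") {
              # note: derivative uses the pre-dropout activation
              s <- .sigmoid(fwd$zs[[l - 1L]])
              delta <- delta * s * (1 - s)
            } else {
              delta <- delta * (fwd$zs[[l - 1L]] > 0)
            }
          }
        }

        # Nadam update (Dozat): Nesterov lookahead on bias-corrected moments
        step <- step + 1L
        lr_t <- cfg$learning_rate / (1 + cfg$decay * (step - 1L))
        grads <- c(grads_W, grads_b)
        params <- c(model$W, model$b)
        for (j in seq_len(n_tensors)) {
          g <- grads[[j]]
          m_state[[j]] <- cfg$beta1 * m_state[[j]] + (1 - cfg$beta1) * g
          v_state[[j]] <- cfg$beta2 * v_state[[j]] + (1 - cfg$beta2) * g^2
          m_hat <- cfg$beta1 * m_state[[j]] / (1 - cfg$beta1^(step + 1L)) +
            (1 - cfg$beta1) * g / (1 - cfg$beta1^step)
          v_hat <- v_state[[j]] / (1 - cfg$beta2^step)
          params[[j]] <- params[[j]] - lr_t * m_hat / (sqrt(v_hat) + eps)
        }
        model$W <- params[seq_len(L + 1L)]
        model$b <- params[L + 1L + seq_len(L + 1L)]
      }

      tr <- .mlp_forward(model, X, training = FALSE)$out
      va <- .mlp_forward(model, Xv, training = FALSE)$out
      history[[epoch]] <- data.frame(
        epoch = epoch,
        loss = .mlp_loss(tr, Y, cfg$mode),
        accuracy = .pred_accuracy(tr, labels, cfg$mode),
        val_loss = .mlp_loss(va, Yv, cfg$mode),
        val_accuracy = .pred_accuracy(va,
                                      as.integer(split$validation$meta$label),
                                      cfg$mode))
      if (verbose && epoch %% 10L == 0L) {
        h <- history[[epoch]]
        message(sprintf("epoch %3d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                        epoch, h$loss, h$accuracy, h$val_loss,
                        h$val_accuracy))
      }
    }
  })
  list(model = model, history = do.call(rbind, history))
}

.pred_classes <- function(out, mode) {
  if (mode == "multiclass") max.col(out, ties.method = "first") - 1L
  else as.integer(out[, 1L] > 0.5)
}

.pred_accuracy <- function(out, labels, mode) {
  mean(.pred_classes(out, mode) == labels)
}

#' Predict with a trained MLP
#'
#' @param model a trained [mlp_model][build_mlp()].
#' @param features numeric matrix, `n x input_dim`.
#' @param type `"prob"` (class probabilities / sigmoid score) or `"class"`
#'   (argmax for multiclass, score > 0.5 for binary).
#' @return a matrix of probabilities or an integer vector of class labels.
#' @export
predict_mlp <- function(model, features, type = c("prob", "class")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "mlp_model"))
  if (ncol(features) != model$config$input_dim) {
    stop("configuration error: feature width does not match input_dim",
         call. = FALSE)
  }
  out <- .mlp_forward(model, features, training = FALSE)$out
  if (type == "prob") out else .pred_classes(out, model$config$mode)
}

#' Save/load an MLP as a single portable JSON file
#'
#' The configuration is embedded alongside the weights.
#'
#' @param model a [mlp_model][build_mlp()].
#' @param path JSON file path.
#' @return `path` invisibly (save); the restored model (load).
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  jsonlite::write_json(
    list(config = unclass(model$config),
         W = lapply(model$W, function(w) list(dim = dim(w),
                                              data = as.numeric(w))),
         b = model$b),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mlp_config, obj$config[c(
    "input_dim", "mode", "hidden_widths", "hidden_activations",
    "dropout_rates", "learning_rate", "decay", "beta1", "beta2",
    "epochs", "batch_size", "seed")])
  W <- lapply(seq_len(nrow(obj$W)), function(i) {
    matrix(obj$W$data[[i]], nrow = obj$W$dim[[i]][1],
           ncol = obj$W$dim[[i]][2])
  })
  b <- if (is.list(obj$b)) obj$b else list(obj$b)
  structure(list(config = cfg, W = W, b = b), class = "mlp_model")
}
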