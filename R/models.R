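#' Classifier configuration
#'
#' Settings of the per-shape scoring classifiers. The default "small"
#' preset is a compact single-hidden-layer feed-forward network applied to
#' block-downsampled crops: enough capacity to recover the
#' contrast-to-noise structure that drives phantom-shape visibility while
#' training in seconds on a CPU. Multi-class heads end in a softmax over
#' the three visibility scores; binary heads in a single sigmoid unit.
#'
#' @param architecture preset name (currently "small").
#' @param input_side side of the downsampled model input, pixels.
#' @param hidden number of hidden units.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param dropout hidden-layer dropout rate in [0, 1).
#' @param augment logical; apply flip augmentation to the training crops.
#' @param class_weights `NULL` (none) or "balanced" (inverse-frequency
#'   sample weights in the loss).
#' @param use_pretrained logical; reserved flag for externally initialised
#'   weights (off by default, and no weights ship with the package).
#' @param seed integer seed for weight initialisation, shuffling and
#'   dropout.
#' @return A list of class `dps_config`.
#' @export
dps_config <- function(architecture = "small", input_side = 14, hidden = 32,
                       epochs = 30, batch_size = 32, learning_rate = 0.005,
                       dropout = 0, augment = TRUE, class_weights = NULL,
                       use_pretrained = FALSE, seed = 1) {
  abort_if(epochs < 1, "epochs must be at least 1")
  abort_if(dropout < 0 || dropout >= 1, "dropout must lie in [0, 1)")
  structure(list(architecture = architecture,
                 input_side = as.integer(input_side),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 augment = isTRUE(augment), class_weights = class_weights,
                 use_pretrained = isTRUE(use_pretrained),
                 seed = as.integer(seed)),
            class = "dps_config")
}

# Downsample crop pixels to the model input resolution and scale to [0, 1].
crop_features <- function(crops, input_side) {
  feats <- vapply(crops, function(cr) {
    p <- cr$pixels / 65535
    n <- nrow(p)
    if (n == input_side) {
      as.vector(p)
    } else if (n %% input_side == 0) {
      f <- n %/% input_side
      dim(p) <- c(f, input_side, f, input_side)
      as.vector(apply(p, c(2, 4), mean))
    } else {
      as.vector(EBImage::imageData(EBImage::resize(
        EBImage::Image(p), w = input_side, h = input_side)))
    }
  }, numeric(input_side^2))
  t(feats)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

crop_labels <- function(crops, head_type) {
  scores <- vapply(crops, `[[`, 0, "truth_score")
  abort_if(anyNA(scores), "all crops must carry a truth score for training")
  abort_if(!all(scores %in% SCORE_LEVELS), "scores must be 0, 0.5 or 1")
  if (head_type == "BCC") as.numeric(scores > 0)
  else match(scores, SCORE_LEVELS)  # 1, 2, 3 for scores 0, 0.5, 1
}

#' Train a phantom-shape scoring classifier
#'
#' Fits one classifier head for one shape kind: `head_type = "MCC"` trains
#' the three-class scorer over visibility scores {0, 0.5, 1} (softmax
#' output, cross-entropy loss); `head_type = "BCC"` trains the binary
#' visible-vs-invisible scorer that pools scores 0.5 and 1 into one class
#' (sigmoid output, binary cross-entropy). Flip augmentation is applied to
#' the training crops only. Training is deterministic given the config
#' seed and records a per-epoch history of training and validation loss
#' and accuracy.
#'
#' @param head_type "MCC" or "BCC".
#' @param crops labelled training crops, all of one kind.
#' @param val_crops optional validation crops (never augmented).
#' @param config a [dps_config()].
#' @return An object of class `dps_model` with elements `weights`,
#'   `head_type`, `kind`, `config`, `feature_stats` and `history`
#'   (data.frame with `epochs` rows).
#' @export
train_dps <- function(head_type = c("MCC", "BCC"), crops, val_crops = NULL,
                      config = dps_config()) {
  head_type <- match.arg(head_type)
  abort_if(length(crops) == 0, "no training crops")
  kinds <- unique(vapply(crops, `[[`, "", "kind"))
  abort_if(length(kinds) != 1, "training crops must all be of one kind")
  if (!is.null(val_crops)) {
    vk <- unique(vapply(val_crops, `[[`, "", "kind"))
    abort_if(!identical(vk, kinds), "validation crops are of a different kind")
  }

  if (config$augment) crops <- unlist(lapply(crops, augment), recursive = FALSE)
  y <- crop_labels(crops, head_type)
  abort_if(length(unique(y)) < 2,
           "degenerate labels: training data contains a single class")

  X <- crop_features(crops, config$input_side)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  Xv <- NULL; yv <- NULL
  if (!is.null(val_crops) && length(val_crops) > 0) {
    Xv <- crop_features(val_crops, config$input_side)
    Xv <- sweep(sweep(Xv, 2, mu), 2, sdv, `/`)
    yv <- crop_labels(val_crops, head_type)
  }

  k <- if (head_type == "MCC") 3L else 1L
  d <- ncol(X); h <- config$hidden; n <- nrow(X)

  w_sample <- rep(1, n)
  if (identical(config$class_weights, "balanced")) {
    tab <- table(y)
    w_sample <- as.numeric(length(y) / (length(tab) * tab[as.character(y)]))
  }

  set.seed(stage_seed(config$seed, "train_init"))
  W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
  b1 <- rep(0, h)
  W2 <- matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k)
  b2 <- rep(0, k)

  adam <- list(m = list(W1 * 0, b1 * 0, W2 * 0, b2 * 0),
               v = list(W1 * 0, b1 * 0, W2 * 0, b2 * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  lr <- config$learning_rate

  Ymat <- if (k > 1) {
    m <- matrix(0, n, k); m[cbind(seq_len(n), y)] <- 1; m
  } else matrix(y, n, 1)

  forward <- function(X, train_drop = FALSE) {
    A1 <- pmax(X %*% W1 + matrix(b1, nrow(X), h, byrow = TRUE), 0)
    if (train_drop && config$dropout > 0) {
      mask <- matrix(stats::rbinom(length(A1), 1, 1 - config$dropout),
                     nrow(A1), ncol(A1)) / (1 - config$dropout)
      A1 <- A1 * mask
    }
    Z2 <- A1 %*% W2 + matrix(b2, nrow(X), k, byrow = TRUE)
    P <- if (k > 1) softmax_rows(Z2) else 1 / (1 + exp(-Z2))
    list(A1 = A1, P = P)
  }

  eval_set <- function(Xs, ys) {
    P <- forward(Xs)$P
    if (k > 1) {
      loss <- -mean(log(pmax(P[cbind(seq_len(nrow(Xs)), ys)], 1e-12)))
      acc <- mean(max.col(P, ties.method = "first") == ys)
    } else {
      p <- as.vector(P)
      loss <- -mean(ys * log(pmax(p, 1e-12)) +
                      (1 - ys) * log(pmax(1 - p, 1e-12)))
      acc <- mean((p >= 0.5) == (ys == 1))
    }
    c(loss = loss, acc = acc)
  }

  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_, val_loss = NA_real_,
                        val_accuracy = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]
      Yb <- Ymat[b, , drop = FALSE]
      wb <- w_sample[b]
      fw <- forward(Xb, train_drop = TRUE)
      dZ2 <- (fw$P - Yb) * wb / length(b)
      gW2 <- t(fw$A1) %*% dZ2
      gb2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(W2)
      dA1[fw$A1 <= 0] <- 0
      gW1 <- t(Xb) %*% dA1
      gb1 <- colSums(dA1)
      grads <- list(gW1, gb1, gW2, gb2)
      t_step <- t_step + 1
      params <- list(W1, b1, W2, b2)
      for (j in seq_along(params)) {
        adam$m[[j]] <- beta1 * adam$m[[j]] + (1 - beta1) * grads[[j]]
        adam$v[[j]] <- beta2 * adam$v[[j]] + (1 - beta2) * grads[[j]]^2
        mhat <- adam$m[[j]] / (1 - beta1^t_step)
        vhat <- adam$v[[j]] / (1 - beta2^t_step)
        params[[j]] <- params[[j]] - lr * mhat / (sqrt(vhat) + eps)
      }
      W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]; b2 <- params[[4]]
    }
    tr <- eval_set(X, y)
    history$loss[ep] <- tr["loss"]
    history$accuracy[ep] <- tr["acc"]
    if (!is.null(Xv)) {
      va <- eval_set(Xv, yv)
      history$val_loss[ep] <- va["loss"]
      history$val_accuracy[ep] <- va["acc"]
    }
  }

  structure(list(weights = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
                 head_type = head_type, kind = kinds,
                 config = config,
                 feature_stats = list(mean = mu, sd = sdv),
                 history = history),
            class = "dps_model")
}

#' @export
print.dps_model <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("dps_model %s/%s: %d epochs, final train acc %.3f%s\n",
              x$head_type, x$kind, n, x$history$accuracy[n],
              if (!is.na(x$history$val_accuracy[n]))
                sprintf(", val acc %.3f", x$history$val_accuracy[n]) else ""))
  invisible(x)
}

#' Apply a scoring classifier to crops
#'
#' Deterministic forward pass. For an MCC model returns a matrix of class
#' probabilities with columns `p0`, `p0.5`, `p1` (rows sum to 1); for a BCC
#' model returns the vector of probabilities of the merged visible class
#' {0.5, 1}.
#'
#' @param model a [train_dps()] model.
#' @param crops a single [shape_crop()] or a list of them.
#' @return Probability matrix (MCC) or vector (BCC).
#' @export
predict_dps <- function(model, crops) {
  abort_if(!inherits(model, "dps_model"), "model must be a dps_model")
  if (inherits(crops, "shape_crop")) crops <- list(crops)
  kinds <- unique(vapply(crops, `[[`, "", "kind"))
  abort_if(!identical(kinds, model$kind),
           sprintf("crop kind (%s) does not match model kind (%s)",
                   paste(kinds, collapse = ","), model$kind))
  X <- crop_features(crops, model$config$input_side)
  X <- sweep(sweep(X, 2, model$feature_stats$mean), 2,
             model$feature_stats$sd, `/`)
  w <- model$weights
  A1 <- pmax(X %*% w$W1 + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE), 0)
  Z2 <- A1 %*% w$W2 + matrix(w$b2, nrow(X), ncol(w$W2), byrow = TRUE)
  if (model$head_type == "MCC") {
    P <- softmax_rows(Z2)
    colnames(P) <- c("p0", "p0.5", "p1")
    P
  } else {
    as.vector(1 / (1 + exp(-Z2)))
  }
}

#' Predicted score of the three-class head
#'
#' The class with the highest probability is the prediction; no threshold
#' is involved. Ties resolve to the lower score.
#'
#' @param probs MCC probability matrix (columns p0, p0.5, p1) or 3-vector.
#' @return Numeric vector of scores in {0, 0.5, 1}.
#' @export
mcc_predicted_score <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  SCORE_LEVELS[max.col(probs, ties.method = "first")]
}

#' Threshold the binary head
#'
#' Assigns the merged visible class when the probability clears the
#' threshold (>= convention, so a probability exactly at the threshold is
#' classified visible).
#'
#' @param bcc_prob probability (vector) of the class {0.5, 1}.
#' @param threshold decision threshold, default 0.5.
#' @return Factor with levels "0" and "0.5|1".
#' @export
classify_bcc <- function(bcc_prob, threshold = 0.5) {
  check_prob(bcc_prob, "bcc_prob")
  check_prob(threshold, "threshold")
  factor(ifelse(bcc_prob >= threshold, "0.5|1", "0"),
         levels = c("0", "0.5|1"))
}

#' Save / load a trained scoring classifier
#'
#' Models are stored as a single JSON file embedding the head type, kind,
#' configuration, training history and full-precision weights, so that a
#' save/load round trip reproduces predictions exactly to numerical
#' precision.
#'
#' @param model a `dps_model`.
#' @param path file path.
#' @return `save_dps` returns `path` invisibly; `load_dps` the model.
#' @export
save_dps <- function(model, path) {
  abort_if(!inherits(model, "dps_model"), "model must be a dps_model")
  obj <- list(
    head_type = model$head_type, kind = model$kind,
    config = unclass(model$config),
    history = model$history,
    feature_stats = model$feature_stats,
    dims = lapply(model$weights, function(w) dim(w) %||% length(w)),
    weights = lapply(model$weights, as.vector)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dps
#' @export
load_dps <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  for (nm in c("W1", "W2"))
    w[[nm]] <- matrix(w[[nm]], obj$dims[[nm]][1], obj$dims[[nm]][2])
  cfg <- obj$config
  config <- dps_config(architecture = cfg$architecture,
                       input_side = cfg$input_side, hidden = cfg$hidden,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       learning_rate = cfg$learning_rate,
                       dropout = cfg$dropout, augment = cfg$augment,
                       class_weights = cfg$class_weights,
                       use_pretrained = cfg$use_pretrained, seed = cfg$seed)
  structure(list(weights = w, head_type = obj$head_type, kind = obj$kind,
                 config = config,
                 feature_stats = list(mean = obj$feature_stats$mean,
                                      sd = obj$feature_stats$sd),
                 history = as.data.frame(obj$history)),
            class = "dps_model")
}

#' Score all 16 targets of phantom images with a model pair per kind
#'
#' Convenience wrapper: applies each kind's BCC and MCC models to the
#' corresponding crops and assembles the probability table consumed by the
#' filtering algorithm.
#'
#' @param models named list with elements `fiber`, `speck_group`, `mass`,
#'   each a list with `bcc` and `mcc` [train_dps()] models.
#' @param crops list of [shape_crop()] objects (any kinds, any images).
#' @return A data.frame with columns `image_id`, `kind`, `rank`,
#'   `truth_score`, `bcc_prob`, `p0`, `p0.5`, `p1`.
#' @export
score_crops <- function(models, crops) {
  abort_if(!all(TARGET_KINDS %in% names(models)),
           "models must be named fiber/speck_group/mass")
  kind <- vapply(crops, `[[`, "", "kind")
  out <- data.frame(
    image_id = vapply(crops, `[[`, "", "image_id"),
    kind = kind,
    rank = vapply(crops, `[[`, 0L, "rank"),
    truth_score = vapply(crops, `[[`, 0, "truth_score"),
    bcc_prob = NA_real_, p0 = NA_real_, p0.5 = NA_real_, p1 = NA_real_,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (k in TARGET_KINDS) {
    sel <- which(kind == k)
    if (length(sel) == 0) next
    out$bcc_prob[sel] <- predict_dps(models[[k]]$bcc, crops[sel])
    P <- predict_dps(models[[k]]$mcc, crops[sel])
    out[sel, c("p0", "p0.5", "p1")] <- P
  }
  out
}
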