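# The pluggable probabilistic-classifier contract and the query-by-committee
# construction: the same model trained on the same labeled seed under
# several learning rates, then run forward-only over the unlabeled pool.

#' Training configuration for committee members
#'
#' Defaults mirror the fine-tuning hyperparameters used throughout the
#' framework: 30 epochs, mini-batches of 16, SGD momentum 0.8, L2 penalty
#' 1e-4.
#'
#' @param learning_rate positive step size.
#' @param max_epochs positive integer, passes over the training data.
#' @param batch_size positive integer mini-batch size.
#' @param momentum SGD momentum in \[0, 1).
#' @param l2_penalty non-negative L2 regularization strength.
#' @param seed integer RNG seed controlling initialization and shuffling.
#' @return a list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, max_epochs = 30L,
                            batch_size = 16L, momentum = 0.8,
                            l2_penalty = 1e-4, seed = 1L) {
  check_fraction(learning_rate, "learning_rate", lo = 0, hi = Inf, lo_open = TRUE)
  if (!is_scalar_number(max_epochs) || max_epochs < 1) {
    stopf("`max_epochs` must be a positive integer")
  }
  if (!is_scalar_number(batch_size) || batch_size < 1) {
    stopf("`batch_size` must be a positive integer")
  }
  check_fraction(momentum, "momentum", lo = 0, hi = 1, hi_open = TRUE)
  check_fraction(l2_penalty, "l2_penalty", lo = 0, hi = Inf)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 momentum = momentum, l2_penalty = l2_penalty,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Read a training configuration from a YAML file
#'
#' Recognized keys are the arguments of [training_config()]; unknown keys
#' are rejected so a typo cannot silently fall back to a default.
#'
#' @param path YAML file path.
#' @return a `training_config`.
#' @export
read_training_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(training_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(training_config, vals)
}

#' Fit a trainable probabilistic classifier
#'
#' Generic for the classifier contract: `fit()` trains on a labeled slice
#' dataset under a [training_config()]; [predict_proba()] returns one class
#' distribution per sample and never reads labels. Fitting is reproducible
#' given identical data, config and seed.
#'
#' @param object a classifier (e.g. from [reference_classifier()]).
#' @param data a `slice_dataset` with labels.
#' @param config a [training_config()].
#' @param validation optional `slice_dataset` used for checkpoint
#'   selection: when supplied, the parameters from the epoch with the
#'   highest validation AUC are kept; otherwise training runs to
#'   `max_epochs`.
#' @param ... passed to methods.
#' @return the fitted classifier.
#' @export
fit <- function(object, data, config, validation = NULL, ...) {
  UseMethod("fit")
}

#' Class-probability predictions
#'
#' @param object a fitted classifier.
#' @param data a `slice_dataset` (labels, if present, are ignored).
#' @param ... passed to methods.
#' @return numeric `N x C` matrix; each row a valid distribution. Column
#'   names are the class labels seen at fit time.
#' @export
predict_proba <- function(object, data, ...) {
  UseMethod("predict_proba")
}

#' Reference committee member: seeded SGD multinomial logistic model
#'
#' A desk-scale probabilistic classifier over flattened,
#' channel-concatenated pixels: multinomial logistic regression trained by
#' mini-batch stochastic gradient descent with momentum and L2 penalty,
#' exactly as parameterized by [training_config()]. Deterministic given the
#' config seed (Gaussian initialization and epoch shuffling both draw from
#' it). It exercises every part of the committee/scoring/selection pipeline
#' without GPU-scale training; any deep model exposing the same `fit()` /
#' [predict_proba()] contract can be substituted.
#'
#' @return an unfitted classifier of class `sgd_logit`.
#' @export
reference_classifier <- function() {
  structure(list(fitted = FALSE, W = NULL, b = NULL, classes = NULL,
                 n_features = NULL, config = NULL),
            class = c("sgd_logit", "probabilistic_classifier"))
}

# Flatten an N x S x S x 3 image array to an N x D design matrix.
# matrix() unrolls column-major, so row n holds sample n's pixels in a
# fixed (x, y, channel) order.
flatten_images <- function(data) {
  imgs <- data$images
  matrix(imgs, nrow = dim(imgs)[1L])
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' @rdname fit
#' @export
fit.sgd_logit <- function(object, data, config, validation = NULL, ...) {
  stopifnot(inherits(config, "training_config"))
  X <- flatten_images(data)
  y <- dataset_manifest(data)$label
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stopf("training subset contains a single class (%s); probabilistic training is degenerate",
          classes[1L])
  }
  n <- nrow(X)
  d <- ncol(X)
  k <- length(classes)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), match(y, classes))] <- 1

  val_X <- NULL
  val_y <- NULL
  if (!is.null(validation)) {
    val_X <- flatten_images(validation)
    val_y <- dataset_manifest(validation)$label
    if (length(unique(val_y)) < 2L) {
      stopf("validation set contains a single class; AUC checkpointing needs both")
    }
  }

  lr <- config$learning_rate
  mom <- config$momentum
  l2 <- config$l2_penalty
  bs <- min(config$batch_size, n)

  withr::with_seed(config$seed, {
    W <- matrix(stats::rnorm(d * k, sd = 0.01), d, k)
    b <- rep(0, k)
    vW <- matrix(0, d, k)
    vb <- rep(0, k)
    best <- list(auc = -Inf, W = W, b = b)
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      for (s in starts) {
        idx <- perm[s:min(s + bs - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        P <- softmax_rows(Xb %*% W + matrix(b, length(idx), k, byrow = TRUE))
        G <- P - Y[idx, , drop = FALSE]
        gW <- crossprod(Xb, G) / length(idx) + l2 * W
        gb <- colMeans(G)
        vW <- mom * vW - lr * gW
        vb <- mom * vb - lr * gb
        W <- W + vW
        b <- b + vb
      }
      if (!is.null(val_X)) {
        P <- softmax_rows(val_X %*% W + matrix(b, nrow(val_X), k, byrow = TRUE))
        auc <- roc_auc(as.integer(val_y == classes[k]), P[, k])
        if (auc > best$auc) best <- list(auc = auc, W = W, b = b)
      }
    }
    if (!is.null(val_X)) {
      W <- best$W
      b <- best$b
    }
  })

  object$fitted <- TRUE
  object$W <- W
  object$b <- b
  object$classes <- classes
  object$n_features <- d
  object$config <- config
  object
}

#' @rdname predict_proba
#' @export
predict_proba.sgd_logit <- function(object, data, ...) {
  if (!isTRUE(object$fitted)) {
    stopf("classifier has not been fitted; call fit() first")
  }
  X <- flatten_images(data)
  if (ncol(X) != object$n_features) {
    stopf("input has %d features per sample but the model was fitted on %d",
          ncol(X), object$n_features)
  }
  k <- length(object$classes)
  P <- softmax_rows(X %*% object$W + matrix(object$b, nrow(X), k, byrow = TRUE))
  colnames(P) <- as.character(object$classes)
  P
}

#' Build an M-member committee by varying the learning rate
#'
#' Trains one copy of the base classifier per learning rate, all on the
#' same labeled seed subset and otherwise identical configuration. The
#' canonical committee uses learning rates 0.001, 0.0005 and 0.0001
#' (M = 3). By default member m trains with seed `config$seed + m - 1`, so
#' members also differ in initialization/shuffling; with
#' `vary_seeds = FALSE` all members share `config$seed`, which together
#' with equal learning rates yields identical members (and zero downstream
#' KL disagreement).
#'
#' @param labeled_subset `slice_dataset` with both classes present.
#' @param base_classifier zero-argument factory returning an unfitted
#'   classifier; defaults to [reference_classifier].
#' @param learning_rates numeric vector of length >= 2.
#' @param config shared [training_config()] (its `learning_rate` is
#'   overridden per member).
#' @param validation optional validation `slice_dataset` for checkpoint
#'   selection, passed to every member's `fit()`.
#' @param vary_seeds logical; see above.
#' @return a list of class `committee` with fields `members`, `configs`.
#' @export
build_committee <- function(labeled_subset,
                            base_classifier = reference_classifier,
                            learning_rates = c(0.001, 0.0005, 0.0001),
                            config = training_config(),
                            validation = NULL,
                            vary_seeds = TRUE) {
  if (length(learning_rates) < 2L) {
    stopf("a committee needs >= 2 learning rates (got %d); pairwise disagreement is undefined for M < 2",
          length(learning_rates))
  }
  if (any(learning_rates <= 0)) stopf("learning rates must be positive")
  labels <- dataset_manifest(labeled_subset)$label
  if (length(unique(labels)) < 2L) {
    stopf("labeled subset contains a single class; committee training is degenerate")
  }
  members <- vector("list", length(learning_rates))
  configs <- vector("list", length(learning_rates))
  for (m in seq_along(learning_rates)) {
    cfg <- config
    cfg$learning_rate <- learning_rates[m]
    cfg$seed <- config$seed + if (vary_seeds) m - 1L else 0L
    clf <- base_classifier()
    members[[m]] <- fit(clf, labeled_subset, cfg, validation = validation)
    configs[[m]] <- cfg
  }
  structure(list(members = members, configs = configs), class = "committee")
}

#' @export
print.committee <- function(x, ...) {
  lrs <- vapply(x$configs, function(cfg) cfg$learning_rate, numeric(1))
  cat(sprintf("<committee> M = %d members, learning rates: %s\n",
              length(x$members), paste(signif(lrs, 4), collapse = ", ")))
  invisible(x)
}

#' Forward-only committee predictions over a sample pool
#'
#' Runs every committee member's [predict_proba()] over the pool and
#' bundles the results as [committee_profiles]. Only images are read: pool
#' labels are never touched, so the pool may be entirely unlabeled.
#'
#' @param committee a `committee` from [build_committee()].
#' @param pool non-empty `slice_dataset`.
#' @return a [committee_profiles] object (member order preserved).
#' @export
predict_profiles <- function(committee, pool) {
  stopifnot(inherits(committee, "committee"))
  man <- dataset_manifest(pool)
  if (nrow(man) == 0L) stopf("pool is empty")
  m <- length(committee$members)
  preds <- lapply(committee$members, predict_proba, data = pool)
  k <- ncol(preds[[1L]])
  probs <- array(NA_real_, dim = c(m, nrow(man), k))
  for (i in seq_len(m)) probs[i, , ] <- preds[[i]]
  committee_profiles(man$sample_id, probs)
}

#' Serialize / restore a fitted reference classifier
#'
#' Writes the weight matrix, bias vector, class labels and an echo of the
#' training configuration as JSON (plain text, full double precision).
#'
#' @param object a fitted `sgd_logit`.
#' @param path file path.
#' @return `read_classifier` returns the restored classifier.
#' @export
write_classifier <- function(object, path) {
  if (!isTRUE(object$fitted)) stopf("cannot serialize an unfitted classifier")
  payload <- list(
    type = "sgd_logit",
    classes = object$classes,
    n_features = object$n_features,
    W = as.vector(object$W),
    b = object$b,
    config = unclass(object$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) stopf("classifier file not found: '%s'", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$type, "sgd_logit")) {
    stopf("unsupported classifier type '%s'", payload$type)
  }
  obj <- reference_classifier()
  obj$fitted <- TRUE
  obj$classes <- payload$classes
  obj$n_features <- payload$n_features
  obj$W <- matrix(payload$W, nrow = payload$n_features)
  obj$b <- payload$b
  obj$config <- do.call(training_config, as.list(payload$config))
  obj
}
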