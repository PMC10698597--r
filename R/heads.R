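#' Specification of a frozen-feature classification head
#'
#' The audit evaluates three head capacities on top of a frozen feature
#' extractor: a single fully connected layer (`linear`, 0 hidden layers) and
#' multilayer perceptrons with three (`mlp3`) and five (`mlp5`) hidden layers.
#' All heads produce independent per-label probabilities via sigmoid outputs.
#'
#' @param name One of `"linear"`, `"mlp3"`, `"mlp5"`.
#' @param n_labels Number of output labels.
#' @param hidden_width Width of each hidden layer (rectifier nonlinearity);
#'   ignored for the linear head. Default 256.
#' @return An object of class `head_spec`.
#' @export
head_spec <- function(name = c("linear", "mlp3", "mlp5"), n_labels,
                      hidden_width = 256L) {
  name <- match.arg(name)
  if (n_labels < 1) abort("`n_labels` must be positive.")
  if (hidden_width < 1) abort("`hidden_width` must be positive.")
  hidden_layers <- c(linear = 0L, mlp3 = 3L, mlp5 = 5L)[[name]]
  structure(list(name = name, hidden_layers = hidden_layers,
                 hidden_width = as.integer(hidden_width),
                 n_labels = as.integer(n_labels)),
            class = "head_spec")
}

# ---- internal multilabel MLP (full-batch Adam, BCE-with-logits) -------------

mlp_init <- function(d_in, spec) {
  dims <- c(d_in, rep(spec$hidden_width, spec$hidden_layers), spec$n_labels)
  w <- b <- vector("list", length(dims) - 1)
  for (l in seq_along(w)) {
    # He initialization for rectifier layers
    w[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(w = w, b = b)
}

mlp_forward <- function(params, x) {
  L <- length(params$w)
  acts <- vector("list", L + 1)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% params$w[[l]], 2, params$b[[l]], "+")
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  acts
}

# numerically stable mean binary cross-entropy from logits
bce_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

mlp_gradients <- function(params, acts, y) {
  L <- length(params$w)
  n <- nrow(y)
  gw <- gb <- vector("list", L)
  delta <- (plogis(acts[[L + 1]]) - y) / (n * ncol(y))
  for (l in rev(seq_len(L))) {
    gw[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$w[[l]])) * (acts[[l]] > 0)
    }
  }
  list(w = gw, b = gb)
}

#' Train a classification head on frozen embeddings
#'
#' Fits a multilabel head (independent per-label binary cross-entropy,
#' sigmoid outputs) on frozen feature vectors with full-batch Adam, using the
#' validation set for model selection: the parameter state achieving the best
#' mean validation AUC over non-degenerate labels is returned. The embedding
#' inputs are never modified (the frozen-backbone contract); internally the
#' head standardizes its inputs by the training-set mean and SD.
#'
#' Labels that are constant in the training data trigger a warning and are
#' excluded from the selection metric (they remain in the loss, where they
#' only shift the bias).
#'
#' @param train_features,val_features Numeric matrices (rows = scans).
#' @param train_labels,val_labels Binary matrices/data frames, one column per
#'   label, row-aligned to the features.
#' @param spec A [head_spec()].
#' @param seed Integer seed; training is deterministic given it.
#' @param epochs Full-batch epochs (default 200).
#' @param learning_rate Adam step size (default 0.05; training is
#'   full-batch, so larger steps than the minibatch habit are appropriate).
#' @param eval_every Validation evaluation period in epochs (default 5).
#' @return An object of class `embed_head` with the selected parameters, the
#'   `selection_metric` (best mean validation AUC), and a training `history`
#'   tibble (`epoch`, `train_loss`, `val_auc`).
#' @examples
#' x <- matrix(rnorm(600), 300, 2)
#' y <- cbind(sick = as.integer(x[, 1] + rnorm(300, sd = .5) > 0))
#' fit <- train_head(x[1:200, ], y[1:200, , drop = FALSE],
#'                   x[201:300, ], y[201:300, , drop = FALSE],
#'                   head_spec("linear", n_labels = 1), seed = 1, epochs = 50)
#' glance(fit)
#' @export
train_head <- function(train_features, train_labels, val_features, val_labels,
                       spec, seed = 1L, epochs = 200L, learning_rate = 0.05,
                       eval_every = 5L) {
  if (!inherits(spec, "head_spec")) abort("`spec` must be a head_spec().")
  x <- as.matrix(train_features)
  y <- as.matrix(train_labels)
  xv <- as.matrix(val_features)
  yv <- as.matrix(val_labels)
  if (nrow(x) != nrow(y)) abort("training features/labels row counts differ.")
  if (nrow(xv) != nrow(yv)) abort("validation features/labels row counts differ.")
  if (ncol(y) != spec$n_labels) {
    abort(sprintf("spec expects %d labels but %d columns given.", spec$n_labels, ncol(y)))
  }
  if (!all(y %in% c(0, 1)) || !all(yv %in% c(0, 1))) abort("labels must be binary 0/1.")
  label_names <- colnames(y) %||% paste0("label", seq_len(ncol(y)))

  degenerate <- apply(y, 2, function(col) all(col == 0) || all(col == 1))
  if (any(degenerate)) {
    warn(paste0("label(s) constant in training, excluded from model selection: ",
                paste(label_names[degenerate], collapse = ", ")))
  }
  keep <- which(!degenerate)

  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  xvs <- sweep(sweep(xv, 2, center), 2, scale_, "/")

  selection_auc <- function(probs) {
    if (length(keep) == 0) return(NA_real_)
    mean(vapply(keep, function(j) auc_rank(probs[, j], yv[, j]), numeric(1)),
         na.rm = TRUE)
  }

  local_seed(seed, 707L, {
    params <- mlp_init(ncol(xs), spec)
    m <- v <- lapply(c(params$w, params$b), function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    best <- list(metric = -Inf, params = params, epoch = 0L)
    hist_epoch <- integer(0); hist_loss <- numeric(0); hist_auc <- numeric(0)

    for (epoch in seq_len(epochs)) {
      acts <- mlp_forward(params, xs)
      loss <- bce_logits(acts[[length(acts)]], y)
      grads <- mlp_gradients(params, acts, y)
      flat_g <- c(grads$w, grads$b)
      flat_p <- c(params$w, params$b)
      t <- t + 1L
      for (i in seq_along(flat_p)) {
        m[[i]] <- beta1 * m[[i]] + (1 - beta1) * flat_g[[i]]
        v[[i]] <- beta2 * v[[i]] + (1 - beta2) * flat_g[[i]]^2
        mhat <- m[[i]] / (1 - beta1^t)
        vhat <- v[[i]] / (1 - beta2^t)
        flat_p[[i]] <- flat_p[[i]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
      L <- length(params$w)
      params$w <- flat_p[seq_len(L)]
      params$b <- flat_p[L + seq_len(L)]

      if (epoch %% eval_every == 0 || epoch == epochs) {
        val_logits <- mlp_forward(params, xvs)[[L + 1]]
        metric <- selection_auc(plogis(val_logits))
        # fall back to training loss when every label is degenerate
        score <- if (is.na(metric)) -loss else metric
        hist_epoch <- c(hist_epoch, epoch)
        hist_loss <- c(hist_loss, loss)
        hist_auc <- c(hist_auc, metric)
        if (score > best$metric) {
          best <- list(metric = score, params = params, epoch = epoch)
        }
      }
    }

    structure(list(
      spec = spec,
      params = best$params,
      center = center,
      scale = scale_,
      label_names = label_names,
      degenerate_labels = label_names[degenerate],
      selection_metric = best$metric,
      best_epoch = best$epoch,
      history = tibble::tibble(epoch = hist_epoch, train_loss = hist_loss,
                               val_auc = hist_auc),
      seed = as.integer(seed)
    ), class = "embed_head")
  })
}

#' Predict per-label probabilities from a trained head
#'
#' @param object An `embed_head` from [train_head()].
#' @param features Numeric matrix with the training feature dimension.
#' @param ... Unused.
#' @return Matrix of probabilities in \[0, 1\], rows aligned to `features`,
#'   columns named by label.
#' @export
predict.embed_head <- function(object, features, ...) {
  x <- as.matrix(features)
  if (ncol(x) != length(object$center)) {
    abort(sprintf("feature dimension %d does not match training dimension %d.",
                  ncol(x), length(object$center)))
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  logits <- mlp_forward(object$params, xs)[[length(object$params$w) + 1]]
  probs <- plogis(logits)
  colnames(probs) <- object$label_names
  probs
}

#' @export
print.embed_head <- function(x, ...) {
  cat(sprintf("<embed_head> %s (%d hidden layers x %d), %d labels\n",
              x$spec$name, x$spec$hidden_layers, x$spec$hidden_width,
              x$spec$n_labels))
  cat(sprintf("  best validation AUC %.4f at epoch %d\n",
              x$selection_metric, x$best_epoch))
  invisible(x)
}

#' Tidiers for trained heads
#'
#' `tidy()` returns the training history (epoch, training loss, validation
#' AUC); `glance()` a one-row summary of the architecture and selection
#' outcome.
#'
#' @param x An `embed_head` object.
#' @param ... Unused.
#' @method tidy embed_head
#' @export
tidy.embed_head <- function(x, ...) x$history

#' @rdname tidy.embed_head
#' @method glance embed_head
#' @export
glance.embed_head <- function(x, ...) {
  n_par <- sum(vapply(c(x$params$w, x$params$b), length, numeric(1)))
  tibble::tibble(
    name = x$spec$name,
    hidden_layers = x$spec$hidden_layers,
    hidden_width = x$spec$hidden_width,
    n_labels = x$spec$n_labels,
    n_parameters = n_par,
    selection_metric = x$selection_metric,
    best_epoch = x$best_epoch
  )
}
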