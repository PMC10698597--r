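#' Principal component projection of an embedding matrix
#'
#' Projects scan embeddings onto their leading principal modes. The
#' decomposition is computed by singular value decomposition of the centered
#' (never scaled) matrix; the sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are deterministic. Either a
#' fixed number of modes or a cumulative explained-variance target can be
#' requested; with a target, the minimal number of leading modes whose
#' cumulative explained-variance ratio meets it is retained.
#'
#' @param embeddings Numeric matrix, one row per scan, finite entries.
#' @param n_modes Number of leading modes to retain, or `NULL`.
#' @param var_target Cumulative explained-variance fraction in (0, 1] to
#'   retain, or `NULL`. Exactly one of `n_modes`/`var_target` may be given;
#'   with neither, all modes are kept.
#' @return An object of class `embed_pca` with elements `rotation`
#'   (`embed_dim` x `n_modes` orthonormal loadings), `ev_ratio` (retained
#'   explained-variance ratios), `ev_ratio_all` (all modes), `coordinates`
#'   (`n_scans` x `n_modes` scores), `center` and `var_target`.
#' @examples
#' x <- matrix(rnorm(400), 100, 4)
#' p <- fit_pca(x, n_modes = 2)
#' tidy(p)
#' @export
fit_pca <- function(embeddings, n_modes = NULL, var_target = NULL) {
  if (!is.matrix(embeddings)) embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2) abort("PCA needs at least 2 rows.")
  if (any(!is.finite(embeddings))) abort("embeddings contain non-finite values.")
  if (!is.null(n_modes) && !is.null(var_target)) {
    abort("give either `n_modes` or `var_target`, not both.")
  }
  max_modes <- min(nrow(embeddings) - 1L, ncol(embeddings))
  if (!is.null(n_modes)) {
    if (n_modes < 1) abort("`n_modes` must be >= 1.")
    if (n_modes > max_modes) {
      abort(sprintf("requested %d modes but only %d are available (%d rows, %d columns).",
                    n_modes, max_modes, nrow(embeddings), ncol(embeddings)))
    }
  }
  if (!is.null(var_target) && (var_target <= 0 || var_target > 1)) {
    abort("`var_target` must lie in (0, 1].")
  }

  center <- colMeans(embeddings)
  xc <- sweep(embeddings, 2, center)
  total_var <- sum(xc^2)
  if (total_var < .Machine$double.eps * nrow(embeddings)) {
    abort("embeddings are constant: zero variance, PCA undefined.")
  }
  sv <- svd(xc, nu = 0)
  ev_all <- sv$d^2 / total_var

  k <- if (!is.null(n_modes)) {
    as.integer(n_modes)
  } else if (!is.null(var_target)) {
    which(cumsum(ev_all) >= var_target - 1e-12)[1]
  } else {
    max_modes
  }
  rotation <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    peak <- which.max(abs(rotation[, j]))
    if (rotation[peak, j] < 0) rotation[, j] <- -rotation[, j]
  }
  colnames(rotation) <- paste0("mode", seq_len(k))
  coords <- xc %*% rotation
  structure(list(
    rotation = rotation,
    ev_ratio = ev_all[seq_len(k)],
    ev_ratio_all = ev_all,
    coordinates = coords,
    center = center,
    var_target = var_target,
    n_modes = k
  ), class = "embed_pca")
}

#' Project new embeddings onto a fitted principal basis
#'
#' @param object An `embed_pca` fit.
#' @param embeddings Numeric matrix with the same column dimension.
#' @return Score matrix (`n_rows` x `n_modes`).
#' @export
project_embeddings <- function(object, embeddings) {
  if (!inherits(object, "embed_pca")) abort("`object` must be an embed_pca fit.")
  if (ncol(embeddings) != length(object$center)) {
    abort("embedding dimension does not match the PCA fit.")
  }
  sweep(embeddings, 2, object$center) %*% object$rotation
}

#' @export
print.embed_pca <- function(x, ...) {
  cat(sprintf("<embed_pca> %d modes over %d scans (dim %d)\n",
              x$n_modes, nrow(x$coordinates), length(x$center)))
  cat(sprintf("  cumulative explained variance: %.1f%%\n",
              100 * sum(x$ev_ratio)))
  invisible(x)
}

#' @describeIn fit_pca One row per retained mode: `mode`, `ev_ratio`,
#'   `cumulative`.
#' @param x,object An `embed_pca` object.
#' @param ... Unused.
#' @method tidy embed_pca
#' @export
tidy.embed_pca <- function(x, ...) {
  tibble::tibble(
    mode = seq_len(x$n_modes),
    ev_ratio = x$ev_ratio,
    cumulative = cumsum(x$ev_ratio)
  )
}

#' @describeIn fit_pca One-row summary of the fit.
#' @method glance embed_pca
#' @export
glance.embed_pca <- function(x, ...) {
  tibble::tibble(
    n_scans = nrow(x$coordinates),
    embed_dim = length(x$center),
    n_modes = x$n_modes,
    var_explained = sum(x$ev_ratio)
  )
}

#' @describeIn fit_pca Scree plot of explained-variance ratios.
#' @method autoplot embed_pca
#' @export
autoplot.embed_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$ev_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::labs(x = "PCA mode", y = "Explained variance ratio",
                  title = "Scree plot (line: cumulative)") +
    ggplot2::theme_minimal()
}
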