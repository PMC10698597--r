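#' Two-dimensional t-SNE view of a principal projection
#'
#' Runs t-SNE on PCA coordinates retained to a cumulative explained-variance
#' target (99% by default), giving a qualitative two-dimensional view of the
#' overall similarity structure of the feature space. No statistics are
#' computed on these coordinates — the shift tests operate on PCA modes only;
#' the t-SNE view feeds marginal-density panels.
#'
#' @param projection An `embed_pca` fit built with a `var_target` (see
#'   [fit_pca()]); at least 2 retained modes are required.
#' @param config An [audit_config()]; supplies the seed and is checked against
#'   the projection's retention target.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically for
#'   small samples).
#' @param max_iter Iteration budget (default 1000).
#' @return A tibble with columns `tsne_1`, `tsne_2`, one row per scan.
#'   Deterministic given the config seed.
#' @export
tsne_view <- function(projection, config = audit_config(), perplexity = 30,
                      max_iter = 1000) {
  if (!inherits(projection, "embed_pca")) {
    abort("`projection` must be an embed_pca fit.")
  }
  if (is.null(projection$var_target)) {
    abort("`projection` must be fitted with a variance-retention target (var_target).")
  }
  if (projection$var_target < config$tsne_variance - 1e-12) {
    abort(sprintf("projection retains %.3f of variance; config requires %.3f.",
                  projection$var_target, config$tsne_variance))
  }
  if (projection$n_modes < 2) abort("need at least 2 retained modes for t-SNE.")
  n <- nrow(projection$coordinates)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 1) abort("too few scans for t-SNE.")
  out <- local_seed(config$seed, 404L, {
    Rtsne::Rtsne(projection$coordinates, dims = 2, perplexity = perplexity,
                 max_iter = max_iter, pca = FALSE, check_duplicates = FALSE,
                 verbose = FALSE, num_threads = 1)
  })
  tibble::tibble(tsne_1 = out$Y[, 1], tsne_2 = out$Y[, 2])
}
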