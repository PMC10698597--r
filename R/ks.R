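#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sample KS statistic
#' \eqn{D = \sup_x |\hat F_a(x) - \hat F_b(x)|}, evaluated over the pooled
#' sample points with the standard right-continuous ECDF convention (ties are
#' handled by counting values \eqn{\le x}), and a two-sided p-value from the
#' asymptotic Kolmogorov distribution at effective sample size
#' \eqn{n_a n_b / (n_a + n_b)}. The asymptotic form is accurate at the
#' per-group subsample sizes the audit uses (hundreds to thousands).
#'
#' @param a,b Non-empty numeric vectors.
#' @return A one-row tibble: `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @examples
#' ks_two_sample(rnorm(100), rnorm(100, mean = 1))
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty.")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("samples must be finite.")
  n_a <- length(a)
  n_b <- length(b)
  z <- sort(c(a, b))
  fa <- findInterval(z, sort(a)) / n_a
  fb <- findInterval(z, sort(b)) / n_b
  d <- max(abs(fa - fb))
  ne <- n_a * n_b / (n_a + n_b)
  p <- kolmogorov_sf(sqrt(ne) * d)
  tibble::tibble(statistic = d, p_value = p, n_a = n_a, n_b = n_b)
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2), clamped to (0, 1].
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0.05) return(1)
  k <- seq_len(200)
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(q, .Machine$double.xmin))
}

#' Benjamini-Yekutieli adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence:
#' with order statistics \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \deqn{\tilde p_{(i)} = \min\Big(1,\ \min_{j \ge i} p_{(j)}\, m\, c(m) / j\Big),
#'   \qquad c(m) = \sum_{k=1}^m 1/k.}
#' Adjusted values are returned in input order; they always dominate both the
#' raw p-values and the Benjamini-Hochberg adjustment.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @examples
#' adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_benjamini_yekutieli <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  m <- length(p)
  c_m <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(ps * m * c_m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}
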