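# Hypergeometric overlap between regulated gene sets and promoter-bound
# genes: the probability of drawing at least k bound genes when n regulated
# genes are sampled without replacement from a universe of N genes of which
# M are bound.

#' Exact hypergeometric tail probability of a gene-set overlap
#'
#' Computes `P = 1 - sum_{i=0}^{k-1} C(M,i) C(N-M, n-i) / C(N,n)`, the
#' upper-tail probability of observing at least `k` marked genes in `n`
#' draws without replacement from `N` genes of which `M` are marked. The
#' sum is evaluated in log space over the upper-tail terms
#' (`i = k .. min(n, M)`), which is algebraically identical to the
#' one-minus form but numerically exact for very small tails.
#'
#' @param N Universe size (genes probed).
#' @param M Number of marked genes (promoter-bound).
#' @param n Regulated-set size.
#' @param k Number of regulated genes that are marked.
#' @return An `overlap_test` object (one-row tibble subclass with `N`,
#'   `M`, `n`, `k`, `p_value`).
#' @export
#' @examples
#' hypergeometric_overlap(5046, 570, 22, 13)$p_value # 8.1e-8
hypergeometric_overlap <- function(N, M, n, k) {
  N <- check_count(N, "N", 0L); M <- check_count(M, "M", 0L)
  n <- check_count(n, "n", 0L); k <- check_count(k, "k", 0L)
  if (M > N || n > N) abort("M and n must not exceed N")
  if (k > min(n, M)) abort("k must not exceed min(n, M)")
  if (n - k > N - M) abort("n - k cannot exceed N - M")
  if (k == 0) {
    p <- 1
  } else {
    i <- k:min(n, M)
    i <- i[n - i <= N - M]
    logterms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
    mx <- max(logterms)
    p <- exp(mx) * sum(exp(logterms - mx))
    p <- min(p, 1)
  }
  structure(tibble(N = N, M = M, n = n, k = k, p_value = p),
            class = c("overlap_test", class(tibble())))
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "hypergeometric overlap: %d of %d regulated genes bound (universe %d, bound %d)\np = %.2g\n",
    x$k, x$n, x$N, x$M, x$p_value
  ))
  invisible(x)
}

#' @rdname hypergeometric_overlap
#' @param x,object An `overlap_test` object.
#' @param ... Unused.
#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) as_tibble(unclass(x))

#' @rdname hypergeometric_overlap
#' @method glance overlap_test
#' @export
glance.overlap_test <- function(x, ...) as_tibble(unclass(x))

#' Build overlap-test parameters from gene-id sets
#'
#' @param regulated Character vector of regulated gene ids (subset of
#'   `universe`).
#' @param bound Character vector of promoter-bound gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all genes probed.
#' @return Tibble: `N`, `M`, `n`, `k`.
#' @export
build_overlap_params <- function(regulated, bound, universe) {
  regulated <- unique(regulated); bound <- unique(bound)
  universe <- unique(universe)
  if (!all(regulated %in% universe)) abort("regulated genes not all in universe")
  if (!all(bound %in% universe)) abort("bound genes not all in universe")
  tibble(
    N = length(universe), M = length(bound), n = length(regulated),
    k = length(intersect(regulated, bound))
  )
}

#' Overlap test straight from gene-id sets
#'
#' Convenience wrapper: [build_overlap_params()] then
#' [hypergeometric_overlap()].
#'
#' @inheritParams build_overlap_params
#' @return An `overlap_test` object.
#' @export
overlap_test <- function(regulated, bound, universe) {
  p <- build_overlap_params(regulated, bound, universe)
  hypergeometric_overlap(p$N, p$M, p$n, p$k)
}
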