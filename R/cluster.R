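# k-means clustering of expression profiles with best-of-restarts selection
# and an elbow scan of the within-cluster sum of squares.

#' Cluster expression profiles with k-means
#'
#' Euclidean k-means on the ORF-by-time-point profile matrix, taking the
#' best of `n_restarts` random starts by total within-cluster sum of
#' squares (WCSS). When `k` is `NULL` it is chosen by the elbow rule: the
#' k in the interior of `k_range` with the largest second difference of the
#' WCSS curve. Deterministic for a fixed `seed`.
#'
#' @param profiles Long profile tibble (`orf_id`, `time_point`, `value`),
#'   complete over time points.
#' @param k Number of clusters, or `NULL` to use the elbow rule.
#' @param n_restarts Random restarts per k (default 100).
#' @param seed Integer seed (default 0).
#' @param k_range Candidate k values scanned for the WCSS curve.
#' @return A `profile_clusters` object: list with `assignments` (tibble
#'   `orf_id`, `cluster`), `centers` (tibble, one row per cluster per time
#'   point), `wcss` (tibble `k`, `wcss`), chosen `k`, and the profile data.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
kmeans_profiles <- function(profiles, k = NULL, n_restarts = 100, seed = 0,
                            k_range = 1:8) {
  stopifnot(all(c("orf_id", "time_point", "value") %in% names(profiles)))
  wide <- profiles |>
    tidyr::pivot_wider(id_cols = "orf_id", names_from = "time_point",
                       values_from = "value")
  if (anyNA(wide)) abort("profiles are incomplete over time points")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$orf_id
  n_distinct_rows <- nrow(unique(mat))
  if (!is.null(k) && k > nrow(mat)) abort("k exceeds the number of profiles")

  ks <- sort(unique(pmin(k_range, n_distinct_rows)))
  fits <- with_seed(seed, {
    lapply(ks, function(kk) {
      suppressWarnings(kmeans(mat, centers = kk, nstart = n_restarts,
                              iter.max = 50))
    })
  })
  wcss <- tibble(k = ks, wcss = vapply(fits, function(f) f$tot.withinss, 0))

  if (is.null(k)) {
    if (length(ks) < 3) {
      k <- ks[length(ks)]
    } else {
      d2 <- diff(wcss$wcss, differences = 2) # indexed by interior ks
      k <- ks[which.max(d2) + 1L]
    }
  }
  fit <- if (k %in% ks) fits[[match(k, ks)]] else {
    with_seed(seed, suppressWarnings(
      kmeans(mat, centers = k, nstart = n_restarts, iter.max = 50)
    ))
  }

  centers <- as_tibble(fit$centers) |>
    mutate(cluster = seq_len(nrow(fit$centers))) |>
    tidyr::pivot_longer(-"cluster", names_to = "time_point",
                        values_to = "value") |>
    mutate(time_point = as.numeric(.data$time_point))

  structure(
    list(
      assignments = tibble(orf_id = wide$orf_id,
                           cluster = unname(fit$cluster)),
      centers = centers,
      wcss = wcss,
      k = k,
      seed = seed,
      profiles = profiles
    ),
    class = "profile_clusters"
  )
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("k-means profile clustering: %d profiles, k = %d (WCSS %.3f)\n",
              nrow(x$assignments), x$k,
              x$wcss$wcss[match(x$k, x$wcss$k)]))
  invisible(x)
}

#' @rdname kmeans_profiles
#' @param x A `profile_clusters` object.
#' @param ... Unused.
#' @method tidy profile_clusters
#' @export
tidy.profile_clusters <- function(x, ...) x$assignments

#' @rdname kmeans_profiles
#' @method glance profile_clusters
#' @export
glance.profile_clusters <- function(x, ...) {
  tibble(k = x$k, n_profiles = nrow(x$assignments),
         wcss = x$wcss$wcss[match(x$k, x$wcss$k)])
}

#' @rdname kmeans_profiles
#' @param object A `profile_clusters` object.
#' @method autoplot profile_clusters
#' @export
autoplot.profile_clusters <- function(object, ...) {
  dat <- object$profiles |>
    left_join(object$assignments, by = "orf_id")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_point, .data$value,
                                    group = .data$orf_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::geom_line(
      data = object$centers,
      ggplot2::aes(group = NULL), colour = "firebrick", linewidth = 1
    ) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "minutes post-starvation", y = "log2 fold change",
                  title = sprintf("expression profile clusters (k = %d)",
                                  object$k))
}
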