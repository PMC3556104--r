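# Two-color normalization: within-array lowess correction of the
# intensity-dependent dye bias, then across-array quantile normalization.

#' Lowess-correct the dye bias of one two-color hybridization
#'
#' Computes per-probe log ratios `M = log2(cy3/cy5)` and average intensities
#' `A = 0.5 * log2(cy3 * cy5)` (both channels floored at 1 to avoid taking
#' logs of background-subtracted zeros), fits `M` on `A` with locally
#' weighted regression, and returns `M` minus the fit — removing any
#' intensity-dependent dye bias while leaving biological signal, which does
#' not track `A`, intact.
#'
#' @param array Tibble of one hybridization with `cy3` and `cy5` columns
#'   (and typically `probe_id`/`orf_id`).
#' @param span Lowess span as a fraction of the data (default 0.3, a common
#'   two-color choice).
#' @return The input tibble with columns `a` (average intensity) and `m`
#'   (corrected log2 ratio) appended.
#' @export
lowess_normalize <- function(array, span = 0.3) {
  stopifnot(all(c("cy3", "cy5") %in% names(array)))
  if (nrow(array) < 10) abort("lowess fit needs at least 10 probes")
  cy3 <- pmax(array$cy3, 1)
  cy5 <- pmax(array$cy5, 1)
  m <- log2(cy3 / cy5)
  a <- 0.5 * log2(cy3 * cy5)
  fit <- lowess(a, m, f = span)
  trend <- approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
  array |> mutate(a = a, m = m - trend)
}

#' Lowess-correct every hybridization in a long intensity table
#'
#' Convenience wrapper applying [lowess_normalize()] per `sample_id`.
#'
#' @inheritParams lowess_normalize
#' @param arrays Long tibble with `sample_id`, `cy3`, `cy5`.
#' @return The input with `a` and `m` columns appended.
#' @export
lowess_normalize_all <- function(arrays, span = 0.3) {
  arrays |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map_dfr(lowess_normalize, span = span)
}

#' Quantile-normalize corrected ratios across hybridizations
#'
#' Forces every array onto the identical value distribution: after
#' normalization each array's sorted values equal the per-rank cross-array
#' mean, while the rank order within each array is preserved.
#'
#' @param arrays Long tibble with `sample_id`, `probe_id` and the value
#'   column named by `value`.
#' @param value Name of the column to normalize (default `"m"`).
#' @return The input tibble with the value column replaced by its
#'   quantile-normalized version.
#' @export
quantile_normalize <- function(arrays, value = "m") {
  stopifnot(all(c("sample_id", "probe_id", value) %in% names(arrays)))
  wide <- arrays |>
    select("sample_id", "probe_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(value))
  if (anyNA(wide)) abort("arrays have mismatched probe sets")
  mat <- as.matrix(wide[-1])
  qn <- limma::normalizeQuantiles(mat, ties = TRUE)
  long <- wide |>
    mutate(across(-"probe_id", ~ NULL)) |>
    dplyr::bind_cols(as_tibble(qn)) |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = ".qn_value")
  arrays |>
    left_join(long, by = c("sample_id", "probe_id")) |>
    mutate(!!value := .data$.qn_value) |>
    select(-".qn_value")
}
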