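# Time-course analysis: probe averaging, pooled-reference ratios normalized
# to t = 0, genome-wide induction thresholds and rapid/slow classification.

#' Average the two probes per ORF into single data points
#'
#' @param x Long tibble with `orf_id`, `sample_id` and a value column;
#'   any additional metadata columns constant within (`orf_id`,
#'   `sample_id`) groups are carried through.
#' @param value Name of the value column (default `"m"`).
#' @return Tibble with one row per ORF per sample; the value column holds
#'   the arithmetic mean of that ORF's probes. ORFs with a probe count
#'   other than two are averaged over the probes present, with a warning.
#' @export
average_probes <- function(x, value = "m") {
  stopifnot(all(c("orf_id", "sample_id", value) %in% names(x)))
  counts <- x |> dplyr::count(.data$orf_id, .data$sample_id)
  odd <- unique(counts$orf_id[counts$n != 2L])
  if (length(odd)) {
    warn(sprintf(
      "%d ORF(s) do not have exactly two probes; averaging available probes",
      length(odd)
    ))
  }
  meta <- setdiff(names(x), c("probe_id", "a", "cy3", "cy5", value))
  x |>
    group_by(across(dplyr::all_of(meta))) |>
    summarise(!!value := mean(.data[[value]]), .groups = "drop")
}

#' Pooled-reference time-course expression profiles
#'
#' For each ORF and time point `x`, computes
#' `log2(Cy3_t=x / Cy5_pool) - log2(Cy3_t=0 / Cy5_pool)` — the log ratio
#' against the pooled reference, re-referenced to the pre-starvation sample
#' so every profile starts at exactly 0. The gene-specific reference level
#' cancels in the difference, as does any rescaling of a single array's two
#' channels by a common factor.
#'
#' @param arrays Per-ORF (after [average_probes()]) or per-probe long tibble
#'   with `orf_id`, `sample_id`, `time_point` (minutes) and the log-ratio
#'   column `value`. Per-probe input is probe-averaged first.
#' @param value Name of the log-ratio column (default `"m"`).
#' @return Long profile tibble: `orf_id`, `time_point`, `value` (log2 fold
#'   change relative to t = 0).
#' @export
timecourse_ratios <- function(arrays, value = "m") {
  stopifnot(all(c("orf_id", "time_point", value) %in% names(arrays)))
  if ("probe_id" %in% names(arrays)) arrays <- average_probes(arrays, value)
  if (!any(arrays$time_point == 0)) abort("no t = 0 sample in the design")
  base <- arrays |>
    filter(.data$time_point == 0) |>
    select("orf_id", m0 = dplyr::all_of(value))
  arrays |>
    left_join(base, by = "orf_id") |>
    mutate(value = .data[[value]] - .data$m0) |>
    select("orf_id", "time_point", "value") |>
    arrange(.data$orf_id, .data$time_point)
}

#' Genome-wide induction threshold at one time point
#'
#' The induction threshold is `median + 2 * sigma` of the log2 fold changes
#' of all ORFs at that time point, with `sigma` the sample standard
#' deviation (n - 1 denominator). It is translation- and (for the spread
#' part) scale-equivariant: `threshold(a*v + b) = a*threshold(v) + b` for
#' `a > 0`.
#'
#' @param values Numeric vector of log2 fold changes (all ORFs, one time
#'   point); at least 3 finite values required.
#' @param time_point Optional label stored in the output.
#' @return One-row tibble: `time_point`, `median`, `sigma`, `value`
#'   (= median + 2 * sigma).
#' @export
#' @examples
#' compute_induction_threshold(c(-1, 0, 1)) # value = 2
compute_induction_threshold <- function(values, time_point = NA_real_) {
  values <- values[is.finite(values)]
  if (length(values) < 3) abort("need at least 3 finite values")
  med <- median(values)
  sig <- sd(values)
  tibble(time_point = time_point, median = med, sigma = sig,
         value = med + 2 * sig)
}

#' Classify temporal response as rapid, slow, or unresponsive
#'
#' Genes at or above threshold at both 120 and 240 minutes post-starvation
#' form the rapid (fast) response; genes above only the 240-minute
#' threshold form the slow response; everything else — including genes
#' above only the 120-minute threshold — is classified `none`.
#'
#' @param profiles Long profile tibble from [timecourse_ratios()] with
#'   values at 120 and 240 minutes.
#' @param thr120,thr240 Thresholds from [compute_induction_threshold()]
#'   (one-row tibbles) or plain numbers.
#' @return Tibble: `orf_id`, `v120`, `v240`, `class`
#'   (`fast`/`slow`/`none`).
#' @export
classify_temporal_response <- function(profiles, thr120, thr240) {
  t120 <- if (is.data.frame(thr120)) thr120$value else thr120
  t240 <- if (is.data.frame(thr240)) thr240$value else thr240
  wide <- profiles |>
    filter(.data$time_point %in% c(120, 240)) |>
    tidyr::pivot_wider(id_cols = "orf_id", names_from = "time_point",
                       values_from = "value", names_prefix = "v")
  if (!all(c("v120", "v240") %in% names(wide)) || anyNA(wide)) {
    abort("profiles must contain 120- and 240-minute values for every ORF")
  }
  wide |>
    mutate(class = dplyr::case_when(
      .data$v120 >= t120 & .data$v240 >= t240 ~ "fast",
      .data$v240 >= t240 ~ "slow",
      TRUE ~ "none"
    ))
}
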