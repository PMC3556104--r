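# Flow-cytometry event simulator for the promoter-reporter assay: scatter
# values straddle the analysis gate, YFP is Gaussian floored at zero.

#' Simulate FACS events for a YFP promoter reporter
#'
#' @param n_events Number of events.
#' @param scatter_range Bounds of the uniform forward/side-scatter draw;
#'   chosen to straddle the 50,000-150,000 analysis gate by default.
#' @param yfp_mean,yfp_sd Mean and sd of the YFP intensity (Gaussian,
#'   floored at 0).
#' @param autofluor_mean Mean autofluorescence of untagged cells; stored so
#'   gating can threshold on it.
#' @param seed Integer seed.
#' @param condition Optional condition label column.
#' @return Tibble: `condition`, `fsc`, `ssc`, `yfp`; attribute
#'   `autofluor_mean`.
#' @export
simulate_facs_events <- function(n_events, scatter_range = c(0, 2e5),
                                 yfp_mean = 1000, yfp_sd = 250,
                                 autofluor_mean = 100, seed = 1,
                                 condition = "sample") {
  n_events <- check_count(n_events, "n_events")
  stopifnot(length(scatter_range) == 2, scatter_range[1] < scatter_range[2],
            yfp_sd >= 0)
  with_seed(seed, {
    out <- tibble(
      condition = condition,
      fsc = runif(n_events, scatter_range[1], scatter_range[2]),
      ssc = runif(n_events, scatter_range[1], scatter_range[2]),
      yfp = pmax(0, rnorm(n_events, yfp_mean, yfp_sd))
    )
    attr(out, "autofluor_mean") <- autofluor_mean
    out
  })
}

#' Gate FACS events and summarize reporter intensity
#'
#' Retains events with forward- and side-scatter inside
#' `[scatter_low, scatter_high]` and YFP at or above the mean
#' autofluorescence of untagged cells, then reports the mean YFP of the
#' gated population — the proxy for promoter activity. The ratio of
#' `mean_yfp` between two summaries is the reporter fold change.
#'
#' @param events Event tibble (`fsc`, `ssc`, `yfp`, optional `condition`).
#' @param scatter_low,scatter_high Scatter gate bounds (inclusive).
#' @param autofluor_mean YFP gate; defaults to the value recorded by
#'   [simulate_facs_events()].
#' @return Tibble with one row per condition: `condition`, `n_total`,
#'   `n_gated`, `mean_yfp` (`NA` with a warning when nothing passes).
#' @export
facs_gate_and_summarize <- function(events, scatter_low = 50000,
                                    scatter_high = 150000,
                                    autofluor_mean = NULL) {
  if (nrow(events) == 0) abort("no events supplied")
  autofluor_mean <- autofluor_mean %||% attr(events, "autofluor_mean")
  if (is.null(autofluor_mean)) {
    abort("`autofluor_mean` not given and not recorded on `events`")
  }
  if (!"condition" %in% names(events)) events$condition <- "sample"
  out <- events |>
    group_by(.data$condition) |>
    summarise(
      n_total = n(),
      n_gated = sum(.data$fsc >= scatter_low & .data$fsc <= scatter_high &
                      .data$ssc >= scatter_low & .data$ssc <= scatter_high &
                      .data$yfp >= autofluor_mean),
      mean_yfp = mean(.data$yfp[.data$fsc >= scatter_low &
                                  .data$fsc <= scatter_high &
                                  .data$ssc >= scatter_low &
                                  .data$ssc <= scatter_high &
                                  .data$yfp >= autofluor_mean])
    ) |>
    ungroup()
  if (any(out$n_gated == 0)) {
    warn("no events passed the gate for some conditions; mean_yfp is NA")
    out$mean_yfp[out$n_gated == 0] <- NA_real_
  }
  out
}
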