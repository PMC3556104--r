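# Genotype/condition differential calls: one-tailed pooled-variance t-test
# with joint fold-change and p-value thresholds, plus the per-design
# fold-change threshold rules used across the stress panels.

#' One-tailed differential expression call per ORF
#'
#' Tests whether group A exceeds group B with a two-sample pooled-variance
#' Student t-test, one-tailed in the A-over-B direction
#' (`df = nA + nB - 2`). A gene passes when both `log2fc >= fc_threshold`
#' and `p_value <= p_threshold`. With two replicates per group the test has
#' 2 degrees of freedom; no multiple-testing correction is applied.
#'
#' When the pooled variance is exactly zero the p-value is 0 if the means
#' differ in the tested direction and 1 otherwise.
#'
#' @param group_a,group_b Long tibbles with `orf_id` and a `value` column,
#'   one row per replicate measurement; at least 2 replicates per group.
#' @param fc_threshold Log2 fold-change threshold (default 1.8).
#' @param p_threshold p-value threshold (default 0.10).
#' @param contrast Label stored in the output.
#' @param value Name of the value column (default `"m"`).
#' @return Tibble: `orf_id`, `log2fc` (= mean(A) - mean(B)), `p_value`,
#'   `passes`, `contrast`.
#' @export
differential_call <- function(group_a, group_b, fc_threshold = 1.8,
                              p_threshold = 0.10, contrast = "A_over_B",
                              value = "m") {
  sums <- function(g, nm) {
    if (!all(c("orf_id", value) %in% names(g))) {
      abort(sprintf("`%s` needs `orf_id` and `%s` columns", nm, value))
    }
    s <- g |>
      group_by(.data$orf_id) |>
      summarise(n = n(), mean = mean(.data[[value]]),
                var = stats::var(.data[[value]]))
    if (any(s$n < 2)) abort(sprintf("`%s` needs >= 2 replicates per ORF", nm))
    s
  }
  a <- sums(group_a, "group_a")
  b <- sums(group_b, "group_b")
  d <- inner_join(a, b, by = "orf_id", suffix = c("_a", "_b"))
  if (nrow(d) != nrow(a) || nrow(d) != nrow(b)) {
    abort("groups cover different ORF sets")
  }
  df <- d$n_a + d$n_b - 2
  sp2 <- ((d$n_a - 1) * d$var_a + (d$n_b - 1) * d$var_b) / df
  fc <- d$mean_a - d$mean_b
  se <- sqrt(sp2 * (1 / d$n_a + 1 / d$n_b))
  p <- ifelse(se > 0, pt(fc / se, df, lower.tail = FALSE),
              ifelse(fc > 0, 0, 1))
  tibble(
    orf_id = d$orf_id, log2fc = fc, p_value = p,
    passes = fc >= fc_threshold & p <= p_threshold,
    contrast = contrast
  )
}

#' Fold-change threshold for a given array design
#'
#' Encodes the per-design threshold rules: genotype contrasts
#' (labels of the form `"..._vs_..."`) use 1.8 log2; the copper-starvation
#' (`"-Cu/+Cu"`) and carbon-switch (`"GE/G"`) arrays, where far more genes
#' respond, use the adaptive `median + 2 * sigma` of all ORF log2 changes;
#' every other stress contrast (slash-separated label, e.g. `"-Fe/+Fe"`)
#' uses log2(1.5).
#'
#' @param design Contrast label.
#' @param values All-ORF log2 changes; required for the adaptive designs.
#' @return Log2 fold-change threshold (scalar).
#' @export
#' @examples
#' select_stress_threshold("-Fe/+Fe")            # log2(1.5)
#' select_stress_threshold("-Cu/+Cu", c(-1, 0, 1)) # median + 2 sd = 2
select_stress_threshold <- function(design, values = NULL) {
  stopifnot(is.character(design), length(design) == 1L)
  if (design %in% c("-Cu/+Cu", "GE/G")) {
    if (is.null(values)) {
      abort(sprintf("design \"%s\" uses an adaptive threshold; supply `values`",
                    design))
    }
    return(compute_induction_threshold(values)$value)
  }
  if (grepl("_vs_", design, fixed = TRUE)) return(1.8)
  if (grepl("/", design, fixed = TRUE)) return(log2(1.5))
  abort(sprintf("unknown design label \"%s\"", design))
}
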