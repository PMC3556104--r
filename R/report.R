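# Regulon report: joins temporal classes, differential calls and
# promoter-binding status into per-gene and per-contrast summaries, with
# overlap significance for each regulated set.

#' Assemble the regulon report
#'
#' Produces (i) a per-gene table with temporal class, per-contrast log2
#' fold change / p-value / pass flags, bound status, and an optional
#' epistasis flag; (ii) overlap tests for each regulated set against the
#' bound set; (iii) a per-contrast summary of how many responsive genes are
#' bound.
#'
#' The epistasis flag marks genes induced in the *csk1* deletion background
#' but not in the *pho7 csk1* double deletion — the pattern placing Pho7
#' downstream of Csk1.
#'
#' @param classes Tibble from [classify_temporal_response()] (`orf_id`,
#'   `class`); may be `NULL`.
#' @param calls Tibble of [differential_call()] rows across contrasts.
#' @param bound Character vector of bound gene ids (e.g.
#'   `unique(assign_peaks_to_promoters(...)$gene_id)`).
#' @param universe Character vector of all gene ids probed.
#' @param regulated_sets Named list of regulated gene-id sets to test
#'   against the bound set; defaults to the temporal responders
#'   (fast + slow) and the passing genes of every contrast.
#' @param epistasis Optional named character vector
#'   `c(single = <contrast>, double = <contrast>)` defining the epistasis
#'   pattern from the calls table.
#' @return A `regulon_report` object: list with `gene_table`,
#'   `overlap_tests`, `contrast_summary`.
#' @export
regulon_report <- function(classes, calls, bound, universe,
                           regulated_sets = NULL, epistasis = NULL) {
  bound <- unique(bound)
  known <- unique(c(
    if (!is.null(classes)) classes$orf_id,
    if (!is.null(calls)) calls$orf_id, bound
  ))
  stray <- setdiff(known, universe)
  if (length(stray)) {
    abort(paste0("gene ids absent from the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }

  gene_table <- tibble(gene_id = universe)
  if (!is.null(classes)) {
    gene_table <- gene_table |>
      left_join(classes |> select(gene_id = "orf_id", "class"),
                by = "gene_id") |>
      mutate(class = dplyr::coalesce(.data$class, "none"))
  }
  if (!is.null(calls) && nrow(calls) > 0) {
    wide <- calls |>
      select(gene_id = "orf_id", "contrast", "log2fc", "p_value", "passes") |>
      tidyr::pivot_wider(names_from = "contrast",
                         values_from = c("log2fc", "p_value", "passes"))
    gene_table <- gene_table |> left_join(wide, by = "gene_id")
  }
  gene_table <- gene_table |> mutate(bound = .data$gene_id %in% bound)

  if (!is.null(epistasis)) {
    need <- paste0("passes_", unname(epistasis[c("single", "double")]))
    if (!all(need %in% names(gene_table))) {
      abort("epistasis contrasts not found in the calls table")
    }
    gene_table <- gene_table |>
      mutate(epistasis = dplyr::coalesce(.data[[need[1]]], FALSE) &
               !dplyr::coalesce(.data[[need[2]]], FALSE))
  }

  if (is.null(regulated_sets)) {
    regulated_sets <- list()
    if (!is.null(classes)) {
      regulated_sets$pi_regulated <-
        classes$orf_id[classes$class %in% c("fast", "slow")]
    }
    if (!is.null(calls) && nrow(calls) > 0) {
      by_con <- split(calls$orf_id[calls$passes], calls$contrast[calls$passes])
      regulated_sets <- c(regulated_sets, by_con)
    }
  }
  overlap_tests <- purrr::imap_dfr(regulated_sets, function(set, nm) {
    tidy(overlap_test(set, bound, universe)) |>
      mutate(regulated_set = nm, .before = 1)
  })

  contrast_summary <- if (!is.null(calls) && nrow(calls) > 0) {
    calls |>
      group_by(.data$contrast) |>
      summarise(
        n_tested = n(),
        n_passing = sum(.data$passes),
        n_passing_bound = sum(.data$passes & .data$orf_id %in% bound),
        .groups = "drop"
      ) |>
      mutate(frac_passing_bound = ifelse(.data$n_passing > 0,
                                         .data$n_passing_bound / .data$n_passing,
                                         NA_real_))
  } else {
    tibble(contrast = character(), n_tested = integer(),
           n_passing = integer(), n_passing_bound = integer(),
           frac_passing_bound = numeric())
  }

  structure(
    list(gene_table = gene_table, overlap_tests = overlap_tests,
         contrast_summary = contrast_summary),
    class = "regulon_report"
  )
}

#' @export
print.regulon_report <- function(x, ...) {
  cat(sprintf("regulon report: %d genes, %d bound, %d overlap test(s)\n",
              nrow(x$gene_table), sum(x$gene_table$bound),
              nrow(x$overlap_tests)))
  if (nrow(x$overlap_tests)) {
    print(x$overlap_tests |>
            mutate(p_value = signif(.data$p_value, 2)))
  }
  invisible(x)
}

#' @rdname regulon_report
#' @param x A `regulon_report`.
#' @param ... Unused.
#' @method tidy regulon_report
#' @export
tidy.regulon_report <- function(x, ...) x$gene_table

#' @rdname regulon_report
#' @method glance regulon_report
#' @export
glance.regulon_report <- function(x, ...) {
  tibble(
    n_genes = nrow(x$gene_table),
    n_bound = sum(x$gene_table$bound),
    n_overlap_tests = nrow(x$overlap_tests),
    min_overlap_p = if (nrow(x$overlap_tests)) min(x$overlap_tests$p_value)
                    else NA_real_
  )
}
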