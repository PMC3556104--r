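# Promoter windows and peak-to-promoter assignment. The promoter is the
# 800 bp upstream of the translation start in gene orientation.

#' Promoter windows for a set of gene models
#'
#' For a `+` strand gene with 0-based start-codon coordinate `atg` the
#' window is `[atg - 800, atg)`; for a `-` strand gene, upstream lies at
#' higher genomic coordinates and the window is `[atg + 1, atg + 801)`.
#' Windows are clipped at chromosome ends when `genome` is supplied.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `atg`).
#' @param window Window width in bases (default 800).
#' @param genome Optional genome tibble for end clipping.
#' @return Tibble: `gene_id`, `chrom`, `strand`, `win_start`, `win_end`
#'   (0-based half-open).
#' @export
promoter_windows <- function(genes, window = 800L, genome = NULL) {
  out <- genes |>
    mutate(
      win_start = ifelse(.data$strand == "+", .data$atg - window,
                         .data$atg + 1L),
      win_end = ifelse(.data$strand == "+", .data$atg,
                       .data$atg + 1L + window)
    ) |>
    mutate(win_start = pmax(.data$win_start, 0L))
  if (!is.null(genome)) {
    out <- out |>
      left_join(genome |> select("chrom", chrom_length = "length"),
                by = "chrom") |>
      mutate(win_end = pmin(.data$win_end, .data$chrom_length)) |>
      select(-"chrom_length")
  }
  out |> select("gene_id", "chrom", "strand", "win_start", "win_end")
}

#' Assign retained peaks to gene promoters
#'
#' A gene is bound when at least one retained peak overlaps its promoter
#' window by at least one base. The result is idempotent and independent of
#' input order.
#'
#' @param peaks Scored peak tibble; only rows with `retained == TRUE` are
#'   used when the column is present.
#' @param genes Gene tibble.
#' @param window Promoter width (default 800).
#' @param genome Optional genome tibble for window clipping.
#' @return Tibble: `gene_id`, `peak_id`, one row per (gene, overlapping
#'   peak) pair. Bound genes are `unique(result$gene_id)`.
#' @export
assign_peaks_to_promoters <- function(peaks, genes, window = 800L,
                                      genome = NULL) {
  if ("retained" %in% names(peaks)) peaks <- peaks |> filter(.data$retained)
  if (nrow(peaks) > 0 && nrow(genes) > 0 &&
      !all(peaks$chrom %in% genes$chrom | peaks$chrom %in% (genome$chrom %||% genes$chrom))) {
    abort("peaks reference chromosomes absent from the gene annotation")
  }
  win <- promoter_windows(genes, window, genome)
  if (nrow(peaks) == 0 || nrow(win) == 0) {
    return(tibble(gene_id = character(), peak_id = character()))
  }
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks)))
  }
  win |>
    inner_join(peaks |> select("peak_id", "chrom", "start", "end"),
               by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$win_end, .data$end > .data$win_start) |>
    dplyr::distinct(.data$gene_id, .data$peak_id) |>
    arrange(.data$gene_id, .data$peak_id)
}
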