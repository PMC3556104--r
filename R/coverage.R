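# Per-base coverage tracks from extended read starts, per-chromosome
# normalization, and the genome-average depth that anchors peak discovery.

new_coverage_track <- function(values, genome, n_reads, normalized,
                               sample_id = NA_character_, extension = NA_integer_) {
  structure(values,
            genome = genome, n_reads = n_reads, normalized = normalized,
            sample_id = sample_id, extension = extension,
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  g <- attr(x, "genome")
  cat(sprintf(
    "coverage_track (%s): %d chromosome(s), %d bases, %s reads%s\n",
    if (isTRUE(attr(x, "normalized"))) "normalized" else "raw",
    nrow(g), sum(g$length), format(attr(x, "n_reads"), big.mark = ","),
    if (is.na(attr(x, "extension"))) "" else
      sprintf(", %d-bp extension", attr(x, "extension"))
  ))
  invisible(x)
}

#' Build raw coverage by extending read starts
#'
#' Each read contributes +1 over an interval of `extension` bases beginning
#' at its 5' start and running in read orientation: a `+` read at 0-based
#' position p covers `[p, p + extension)`, a `-` read covers
#' `(p - extension, p]`, i.e. `[p - extension + 1, p + 1)` — the extension
#' runs 3'-ward toward the far end of the sequenced fragment. Intervals are
#' truncated at chromosome ends, so total coverage mass equals
#' `extension * n_reads` minus end-truncation losses, exactly.
#'
#' @param reads Read tibble (`chrom`, `start` 0-based 5' position,
#'   `strand`), e.g. from [simulate_chipseq()] or [read_reads_bed()].
#' @param genome Genome tibble (`chrom`, `length`).
#' @param extension Extension length in bases (default 80, the average
#'   library insert beyond the read).
#' @return A `coverage_track`: named list of per-base numeric vectors, one
#'   per chromosome.
#' @export
extend_reads <- function(reads, genome, extension = 80L) {
  if (extension <= 0) abort("`extension` must be positive")
  if (!all(reads$chrom %in% genome$chrom)) {
    abort("reads reference chromosomes absent from the genome")
  }
  lens <- setNames(as.integer(genome$length), genome$chrom)
  if (any(reads$start < 0 | reads$start >= lens[reads$chrom])) {
    abort("read 5' starts must lie within chromosome bounds")
  }
  values <- lapply(genome$chrom, function(ch) {
    len <- lens[[ch]]
    r <- reads[reads$chrom == ch, ]
    if (nrow(r) == 0) return(numeric(len))
    s0 <- ifelse(r$strand == "+", r$start, pmax(r$start - extension + 1L, 0L))
    e0 <- ifelse(r$strand == "+", pmin(r$start + extension, len), r$start + 1L)
    delta <- numeric(len + 1L)
    add <- tabulate(s0 + 1L, nbins = len + 1L)
    sub <- tabulate(e0 + 1L, nbins = len + 1L)
    cumsum(add - sub)[seq_len(len)]
  })
  names(values) <- genome$chrom
  new_coverage_track(values, genome, nrow(reads), normalized = FALSE,
                     sample_id = if ("sample_id" %in% names(reads))
                       reads$sample_id[1] else NA_character_,
                     extension = as.integer(extension))
}

#' Normalize coverage to total counts per chromosome
#'
#' Scales each chromosome's per-base values so the chromosome total equals
#' 1e6, making chromosome-wise totals comparable across samples of
#' different sequencing depth. The constant is arbitrary; all downstream
#' quantities are ratios.
#'
#' @param track Raw `coverage_track` from [extend_reads()].
#' @return Normalized `coverage_track`. Chromosomes with zero coverage are
#'   left at zero with a warning.
#' @export
normalize_coverage <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  totals <- vapply(track, sum, 0)
  if (any(totals == 0)) {
    warn(paste0("no coverage on: ",
                paste(names(track)[totals == 0], collapse = ", ")))
  }
  values <- lapply(seq_along(track), function(i) {
    if (totals[i] == 0) track[[i]] else track[[i]] * (1e6 / totals[i])
  })
  names(values) <- names(track)
  new_coverage_track(values, attr(track, "genome"), attr(track, "n_reads"),
                     normalized = TRUE, sample_id = attr(track, "sample_id"),
                     extension = attr(track, "extension"))
}

#' Genome-average per-base depth of a coverage track
#'
#' @param track A `coverage_track`.
#' @return Total coverage mass divided by total genome length.
#' @export
genome_average <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  total_len <- sum(vapply(track, length, 0L))
  if (total_len == 0) abort("zero-length genome")
  sum(vapply(track, sum, 0)) / total_len
}

#' Coverage track as a run-length (bedGraph-style) tibble
#'
#' @param x A `coverage_track`.
#' @param ... Unused.
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `depth`.
#' @method as_tibble coverage_track
#' @export
as_tibble.coverage_track <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(v, ch) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    tibble(chrom = ch, start = c(0L, head(ends, -1)), end = ends,
           depth = r$values)
  })
}

#' @rdname as_tibble.coverage_track
#' @param object A `coverage_track`.
#' @param peaks Optional peak tibble to overlay as shaded intervals.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, peaks = NULL, ...) {
  dat <- as_tibble(object)
  p <- ggplot2::ggplot(dat) +
    ggplot2::geom_step(ggplot2::aes(.data$start, .data$depth)) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = if (isTRUE(attr(object, "normalized")))
                    "normalized depth" else "read depth")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.2
    )
  }
  p
}
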