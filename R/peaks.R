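# Iterative multi-threshold peak discovery and mock-comparison scoring.
#
# Discovery sweeps 380 evenly spaced thresholds from the sample maximum down
# to one increment above the genome-average depth. At each level, candidate
# regions are maximal runs of bases at or above the level after closing gaps
# narrower than 20 nt; regions wider than 100 nt qualify. Each locus is
# compiled once, at the highest level at which it qualifies, and compiled
# peaks closer than 150 nt edge-to-edge are merged (or dropped).

# Close sub-`min_sep` gaps in a logical run structure and return qualifying
# runs as a two-column matrix of 1-based [start, end] positions.
qualifying_runs <- function(mask, min_width, min_sep) {
  r <- rle(mask)
  nr <- length(r$values)
  if (nr > 2) {
    interior <- which(!r$values & r$lengths < min_sep &
                        seq_len(nr) > 1L & seq_len(nr) < nr)
    if (length(interior)) {
      r$values[interior] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths > min_width
  cbind(start = ends[keep] - r$lengths[keep] + 1L, end = ends[keep])
}

# Sweep one chromosome's values over a fixed descending level ladder.
# Consecutive levels with no coverage value between them produce identical
# masks; each distinct mask is processed once, at the highest of its levels
# (exact, since region geometry and hence qualification are mask functions).
sweep_chromosome <- function(v, levels, min_width, min_sep) {
  uv <- sort(unique(v))
  mask_id <- vapply(levels, function(t) length(uv) - findInterval(t, uv) +
                      sum(uv == t), 0) # = count of unique values >= t
  first <- !duplicated(mask_id)
  occupied <- logical(length(v))
  out <- list()
  for (j in which(first)) {
    t <- levels[j]
    mask <- v >= t
    if (!any(mask)) next
    runs <- qualifying_runs(mask, min_width, min_sep)
    if (nrow(runs) == 0) next
    for (i in seq_len(nrow(runs))) {
      s <- unname(runs[i, 1]); e <- unname(runs[i, 2])
      if (any(occupied[s:e])) next
      occupied[s:e] <- TRUE
      out[[length(out) + 1L]] <- c(start = s - 1L, end = e,
                                   compile_threshold = t)
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(),
                  compile_threshold = numeric()))
  }
  as_tibble(do.call(rbind, out)) |> arrange(.data$start)
}

# Apply the neighbor rule to one chromosome's compiled peaks.
apply_neighbor_rule <- function(pk, v, min_neighbor, policy) {
  if (nrow(pk) < 2 || min_neighbor <= 0) return(pk)
  pk <- pk |> arrange(.data$start)
  if (policy == "drop") {
    gap_prev <- c(Inf, pk$start[-1] - pk$end[-nrow(pk)])
    gap_next <- c(pk$start[-1] - pk$end[-nrow(pk)], Inf)
    return(pk[gap_prev >= min_neighbor & gap_next >= min_neighbor, ])
  }
  repeat {
    gaps <- pk$start[-1] - pk$end[-nrow(pk)]
    i <- which(gaps < min_neighbor)
    if (!length(gaps) || !length(i)) break
    i <- i[1]
    pk$end[i] <- pk$end[i + 1]
    pk$compile_threshold[i] <- max(pk$compile_threshold[i],
                                   pk$compile_threshold[i + 1])
    pk <- pk[-(i + 1), ]
  }
  pk
}

#' Discover peaks by an iterative multi-threshold sweep
#'
#' Runs the 380-increment threshold sweep over a normalized coverage track.
#' The level ladder is shared across chromosomes: the top level is the
#' highest observed normalized depth in the sample, the bottom level one
#' increment above `lower` (the genome-average depth). At each level,
#' candidate regions are runs of bases at or above the level after closing
#' gaps narrower than `min_separation`; regions wider than `min_width`
#' qualify and are compiled at the highest level at which they qualify.
#' Compiled peaks closer than `min_neighbor` edge-to-edge are merged
#' (`neighbor_policy = "merge"`, the default, which preserves signal mass)
#' or discarded (`"drop"`).
#'
#' @param track Normalized `coverage_track` (see [normalize_coverage()]).
#' @param lower Lower sweep bound; defaults to [genome_average()] of the
#'   track.
#' @param n_increments Number of sweep levels (default 380).
#' @param min_width Minimum peak width, exclusive (default 100 nt).
#' @param min_separation Gaps narrower than this are closed (default 20 nt).
#' @param min_neighbor Minimum edge-to-edge distance between retained
#'   neighbors (default 150 nt).
#' @param neighbor_policy `"merge"` or `"drop"`.
#' @return Unscored peak tibble: `chrom`, `start`, `end` (0-based
#'   half-open), `compile_threshold`, `max_height`. A flat track (maximum
#'   not above `lower`) yields zero rows with a warning.
#' @export
multithreshold_peak_discovery <- function(track, lower = genome_average(track),
                                          n_increments = 380L,
                                          min_width = 100L,
                                          min_separation = 20L,
                                          min_neighbor = 150L,
                                          neighbor_policy = c("merge", "drop")) {
  stopifnot(inherits(track, "coverage_track"))
  neighbor_policy <- match.arg(neighbor_policy)
  stopifnot(n_increments >= 1, min_width > 0, min_separation > 0)
  upper <- max(vapply(track, max, 0))
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  compile_threshold = numeric(), max_height = numeric())
  if (upper <= lower) {
    warn("track maximum does not exceed the lower threshold; no peaks")
    return(empty)
  }
  step <- (upper - lower) / n_increments
  levels <- upper - step * (seq_len(n_increments) - 1L) # descending to lower+step

  purrr::imap_dfr(unclass(track), function(v, ch) {
    pk <- sweep_chromosome(v, levels, min_width, min_separation)
    pk <- apply_neighbor_rule(pk, v, min_neighbor, neighbor_policy)
    if (nrow(pk) == 0) return(NULL)
    pk$max_height <- mapply(function(s, e) max(v[(s + 1):e]),
                            pk$start, pk$end)
    pk$chrom <- ch
    pk |> select("chrom", "start", "end", "compile_threshold", "max_height")
  })
}

#' Score peaks against the mock sample and the genome average
#'
#' Fold enrichment is the peak's maximum normalized height over the
#' genome-average normalized depth of the IP sample. Significance against
#' the mock IP is an upper-tail Poisson probability of the raw IP read mass
#' in the peak footprint (extended-coverage mass divided by the extension
#' length, i.e. read equivalents), with expectation the depth-scaled mock
#' mass in the footprint, floored at the footprint length times the
#' genome-average raw IP depth. Peaks are retained when
#' `fold_enrichment >= fold_min` and `p_mock <= p_max`.
#'
#' @param peaks Unscored peak tibble from
#'   [multithreshold_peak_discovery()].
#' @param ip_norm,mock_norm Normalized `coverage_track`s for IP and mock.
#' @param ip_raw,mock_raw Raw `coverage_track`s for IP and mock.
#' @param fold_min Minimum fold enrichment (default 2).
#' @param p_max Maximum mock-comparison p-value (default 0.005).
#' @return The peak tibble with `fold_enrichment`, `p_mock` and `retained`
#'   appended, plus a `peak_id` column.
#' @export
score_peaks <- function(peaks, ip_norm, mock_norm, ip_raw, mock_raw,
                        fold_min = 2, p_max = 0.005) {
  stopifnot(inherits(ip_norm, "coverage_track"),
            inherits(mock_raw, "coverage_track"))
  ip_depth <- attr(ip_raw, "n_reads")
  mock_depth <- attr(mock_raw, "n_reads")
  if (is.null(mock_depth) || mock_depth == 0) {
    abort("mock sample has no reads genome-wide")
  }
  ext <- attr(ip_raw, "extension")
  if (is.na(ext)) ext <- 80L
  if (nrow(peaks) == 0) {
    return(peaks |> mutate(fold_enrichment = numeric(), p_mock = numeric(),
                           retained = logical(), peak_id = character()))
  }
  avg_norm <- genome_average(ip_norm)
  avg_raw <- genome_average(ip_raw)

  mass <- function(track, chrom, start, end) {
    vapply(seq_along(chrom),
           function(i) sum(track[[chrom[i]]][(start[i] + 1):end[i]]), 0)
  }
  ip_mass <- mass(ip_raw, peaks$chrom, peaks$start, peaks$end) / ext
  mock_mass <- mass(mock_raw, peaks$chrom, peaks$start, peaks$end) / ext
  width <- peaks$end - peaks$start
  lambda <- pmax(mock_mass * ip_depth / mock_depth, width * avg_raw / ext)

  peaks |>
    mutate(
      fold_enrichment = .data$max_height / avg_norm,
      p_mock = ppois(ceiling(ip_mass) - 1, lambda, lower.tail = FALSE),
      retained = .data$fold_enrichment >= fold_min & .data$p_mock <= p_max,
      peak_id = sprintf("peak_%04d", row_number())
    )
}

#' Call peaks end-to-end from IP and mock read sets
#'
#' Convenience wrapper chaining [extend_reads()], [normalize_coverage()],
#' [multithreshold_peak_discovery()] and [score_peaks()].
#'
#' @param ip_reads,mock_reads Read tibbles (`chrom`, `start`, `strand`).
#' @param genome Genome tibble (`chrom`, `length`).
#' @param extension Read extension in bases (default 80).
#' @param ... Passed to [multithreshold_peak_discovery()] and, for
#'   `fold_min`/`p_max`, to [score_peaks()].
#' @param fold_min,p_max Retention thresholds (defaults 2 and 0.005).
#' @return Scored peak tibble (see [score_peaks()]).
#' @export
call_peaks <- function(ip_reads, mock_reads, genome, extension = 80L,
                       fold_min = 2, p_max = 0.005, ...) {
  ip_raw <- extend_reads(ip_reads, genome, extension)
  mock_raw <- extend_reads(mock_reads, genome, extension)
  ip_norm <- normalize_coverage(ip_raw)
  mock_norm <- normalize_coverage(mock_raw)
  peaks <- multithreshold_peak_discovery(ip_norm, ...)
  score_peaks(peaks, ip_norm, mock_norm, ip_raw, mock_raw,
              fold_min = fold_min, p_max = p_max)
}
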