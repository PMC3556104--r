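# Shared fixtures and independent oracles.

# Build a coverage_track directly from per-base vectors (named list).
make_track <- function(values, normalized = TRUE, n_reads = NA_integer_,
                       extension = 80L) {
  genome <- tibble::tibble(
    chrom = names(values),
    length = vapply(values, length, 0L)
  )
  phoregulon:::new_coverage_track(values, genome, n_reads,
                                  normalized = normalized,
                                  extension = extension)
}

# Brute-force multi-threshold sweep oracle built on IRanges: enumerates all
# levels explicitly, applies the gap-closing, width, uniqueness and
# neighbor rules by direct interval arithmetic. Shares no run-finding code
# with the package implementation.
oracle_sweep_vector <- function(v, levels, min_width = 100L,
                                min_separation = 20L, min_neighbor = 150L,
                                policy = c("merge", "drop")) {
  policy <- match.arg(policy)
  compiled <- IRanges::IRanges()
  thr <- numeric()
  for (t in sort(levels, decreasing = TRUE)) {
    pos <- which(v >= t)
    if (!length(pos)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = pos, width = 1L),
                          min.gapwidth = min_separation)
    ir <- ir[IRanges::width(ir) > min_width]
    if (!length(ir)) next
    new <- ir[IRanges::countOverlaps(ir, compiled) == 0]
    if (length(new)) {
      compiled <- c(compiled, new)
      thr <- c(thr, rep(t, length(new)))
    }
  }
  o <- order(IRanges::start(compiled))
  compiled <- compiled[o]; thr <- thr[o]

  if (length(compiled) >= 2) {
    if (policy == "merge") {
      repeat {
        gaps <- IRanges::start(compiled)[-1] - IRanges::end(compiled)[-length(compiled)] - 1L
        i <- which(gaps < min_neighbor)
        if (!length(i)) break
        i <- i[1]
        merged <- IRanges::IRanges(
          start = IRanges::start(compiled)[i],
          end = IRanges::end(compiled)[i + 1]
        )
        thr[i] <- max(thr[i], thr[i + 1])
        compiled <- c(head(compiled, i - 1), merged,
                      tail(compiled, length(compiled) - i - 1))
        thr <- thr[-(i + 1)]
      }
    } else {
      gaps <- IRanges::start(compiled)[-1] - IRanges::end(compiled)[-length(compiled)] - 1L
      ok <- c(Inf, gaps) >= min_neighbor & c(gaps, Inf) >= min_neighbor
      compiled <- compiled[ok]; thr <- thr[ok]
    }
  }

  tibble::tibble(
    start = IRanges::start(compiled) - 1L, # back to 0-based half-open
    end = IRanges::end(compiled),
    compile_threshold = thr,
    max_height = vapply(seq_along(compiled), function(i) {
      max(v[IRanges::start(compiled)[i]:IRanges::end(compiled)[i]])
    }, 0)
  )
}

# Full oracle over a coverage_track, mirroring the exported discovery
# interface (shared sample-wide level ladder).
oracle_discovery <- function(track, lower = genome_average(track),
                             n_increments = 380L, min_width = 100L,
                             min_separation = 20L, min_neighbor = 150L,
                             policy = "merge") {
  upper <- max(vapply(track, max, 0))
  step <- (upper - lower) / n_increments
  levels <- upper - step * (seq_len(n_increments) - 1L)
  purrr::imap_dfr(unclass(track), function(v, ch) {
    out <- oracle_sweep_vector(v, levels, min_width, min_separation,
                               min_neighbor, policy)
    if (nrow(out)) dplyr::mutate(out, chrom = ch, .before = 1) else NULL
  })
}

# Random piecewise-constant tracks: integer baseline with random
# rectangular bumps, the shape extended-read coverage takes.
random_track <- function(len, seed, n_bumps = 8, base_rate = 25) {
  set.seed(seed)
  v <- as.numeric(rpois(len, base_rate))
  for (b in seq_len(n_bumps)) {
    w <- sample(30:600, 1)
    s <- sample(len - w, 1)
    v[s:(s + w - 1)] <- v[s:(s + w - 1)] + sample(c(0, 20, 50, 120), 1)
  }
  v
}

# Planted signal span of a simulated binding site: site reads derive from
# fragments overlapping the center, so coverage extends at most one maximum
# fragment length to either side.
site_windows <- function(sites, frag_max = 600) {
  tibble::tibble(
    chrom = sites$chrom,
    start = sites$center - frag_max,
    end = sites$center + frag_max
  )
}

overlaps_any <- function(chrom, start, end, win) {
  vapply(seq_along(chrom), function(i) {
    any(win$chrom == chrom[i] & win$start < end[i] & win$end > start[i])
  }, TRUE)
}
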