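# Multi-threshold peak discovery (with brute-force oracle) and
# mock-comparison scoring.

rect_track <- function(len = 3000, bg = 1, rects = list()) {
  v <- rep(bg, len)
  for (r in rects) v[(r$start + 1):r$end] <- r$h
  make_track(list(chrI = v))
}

test_that("rectangle geometries follow the width, gap and neighbor rules", {
  # single qualifying rectangle: one peak, exact footprint, compiled at the
  # highest sweep level at or below its height
  tr <- rect_track(rects = list(list(start = 1000, end = 1200, h = 10)))
  pk <- multithreshold_peak_discovery(tr, lower = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 1000)
  expect_equal(pk$end, 1200)
  levels <- 10 - (10 - 1) / 380 * (0:379)
  expect_equal(pk$compile_threshold, max(levels[levels <= 10]))
  expect_equal(pk$max_height, 10)

  # too narrow: nothing
  tr <- rect_track(rects = list(list(start = 1000, end = 1080, h = 10)))
  expect_equal(nrow(multithreshold_peak_discovery(tr, lower = 1)), 0)

  # 10-base gap between two blocks is closed into one region
  tr <- rect_track(rects = list(list(start = 1000, end = 1090, h = 10),
                                list(start = 1100, end = 1190, h = 10)))
  pk <- multithreshold_peak_discovery(tr, lower = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(1000, 1190))

  # two qualifying rectangles 120 bases apart are merged by the 150-nt rule
  tr <- rect_track(rects = list(list(start = 1000, end = 1150, h = 10),
                                list(start = 1270, end = 1420, h = 8)))
  pk <- multithreshold_peak_discovery(tr, lower = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(1000, 1420))
  # ... and dropped under the drop policy
  pk_drop <- multithreshold_peak_discovery(tr, lower = 1,
                                           neighbor_policy = "drop")
  expect_equal(nrow(pk_drop), 0)

  # flat track: warning and empty result
  expect_warning(out <- multithreshold_peak_discovery(rect_track(), lower = 1),
                 "no peaks")
  expect_equal(nrow(out), 0)
})

test_that("sweep matches the brute-force per-level oracle on random tracks", {
  for (s in 1:30) {
    v <- random_track(len = 5000, seed = s)
    tr <- make_track(list(chrI = v))
    got <- multithreshold_peak_discovery(tr)
    want <- oracle_discovery(tr)
    expect_equal(nrow(got), nrow(want), info = paste("seed", s))
    if (nrow(got)) {
      expect_equal(got$start, want$start, info = paste("seed", s))
      expect_equal(got$end, want$end, info = paste("seed", s))
      expect_equal(got$compile_threshold, want$compile_threshold,
                   tolerance = 1e-12, info = paste("seed", s))
      expect_equal(got$max_height, want$max_height, info = paste("seed", s))
    }
  }
})

test_that("scoring applies the fold rule and the exact Poisson tail", {
  len <- 10000L
  fp <- list(start = 0L, end = 100L)
  ip_v <- rep(0.1, len); ip_v[1:100] <- 80     # mass 8000/80 = 100 reads
  mock_v <- rep(0.1, len); mock_v[1:100] <- 8  # mass 800/80 = 10 reads
  ip_raw <- make_track(list(chrI = ip_v), normalized = FALSE, n_reads = 1000L)
  mock_raw <- make_track(list(chrI = mock_v), normalized = FALSE,
                         n_reads = 1000L)
  ip_norm <- normalize_coverage(ip_raw)
  mock_norm <- normalize_coverage(mock_raw)
  avg <- genome_average(ip_norm)

  peaks <- tibble::tibble(chrom = "chrI", start = fp$start, end = fp$end,
                          compile_threshold = avg * 3, max_height = avg * 3)
  sc <- score_peaks(peaks, ip_norm, mock_norm, ip_raw, mock_raw)
  expect_equal(sc$p_mock, ppois(99, 10, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(sc$p_mock, 1e-10)
  expect_true(sc$retained)

  # fold rule dominates regardless of p
  weak <- dplyr::mutate(peaks, max_height = avg * 1.5)
  expect_false(score_peaks(weak, ip_norm, mock_norm, ip_raw, mock_raw)$retained)

  # IP identical to scaled mock: never significant
  set.seed(13)
  v <- rpois(len, 5) + 0.0
  same_raw <- make_track(list(chrI = v), normalized = FALSE, n_reads = 500L)
  same_norm <- normalize_coverage(same_raw)
  rand_peaks <- tibble::tibble(
    chrom = "chrI",
    start = seq(0, 9000, by = 200),
    end = seq(150, 9150, by = 200)
  ) |>
    dplyr::mutate(compile_threshold = 1, max_height = 10 * genome_average(same_norm))
  null_sc <- score_peaks(rand_peaks, same_norm, same_norm, same_raw, same_raw)
  expect_true(all(null_sc$p_mock > 0.005))
  expect_false(any(null_sc$retained))
})

test_that("tightening thresholds never grows the retained set", {
  gn <- generate_genome(1, 5e4, 0, seed = 21)
  sites <- binding_sites(gn$genome, 3, enrichment_no_pi = 6, seed = 21)
  ip <- simulate_chipseq(gn$genome, sites, 3e4, "no_pi", seed = 22)
  mock <- simulate_chipseq(gn$genome, sites, 3e4, "mock", seed = 23)
  loose <- call_peaks(ip, mock, gn$genome, fold_min = 1.5, p_max = 0.05)
  tight <- call_peaks(ip, mock, gn$genome, fold_min = 3, p_max = 0.001)
  id <- function(p) paste(p$chrom, p$start, p$end)[p$retained]
  expect_true(all(id(tight) %in% id(loose)))
})
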