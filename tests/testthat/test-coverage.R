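# Read extension, per-chromosome normalization, genome average.

one_chrom <- tibble::tibble(chrom = "chrI", length = 1000L)

test_that("read extension follows orientation and truncates at ends", {
  plus <- tibble::tibble(chrom = "chrI", start = 100L, strand = "+")
  tr <- extend_reads(plus, one_chrom, 80L)
  expect_equal(which(tr$chrI == 1), 101:180) # 0-based [100, 180)
  expect_equal(sum(tr$chrI), 80)

  minus <- tibble::tibble(chrom = "chrI", start = 100L, strand = "-")
  tr <- extend_reads(minus, one_chrom, 80L)
  expect_equal(which(tr$chrI == 1), 22:101) # 0-based [21, 101)

  both <- tibble::tibble(chrom = "chrI", start = c(100L, 140L),
                         strand = c("+", "+"))
  tr <- extend_reads(both, one_chrom, 80L)
  expect_equal(which(tr$chrI == 2), 141:180)

  # truncation at the right end, mass conservation otherwise
  edge <- tibble::tibble(chrom = "chrI", start = c(990L, 5L),
                         strand = c("+", "-"))
  tr <- extend_reads(edge, one_chrom, 80L)
  expect_equal(sum(tr$chrI), (1000 - 990) + (5 + 1))

  expect_error(extend_reads(plus, one_chrom, 0), "positive")
  expect_error(
    extend_reads(tibble::tibble(chrom = "chrI", start = 1000L, strand = "+"),
                 one_chrom),
    "bounds"
  )
})

test_that("coverage mass is conserved exactly for interior reads", {
  set.seed(10)
  g <- tibble::tibble(chrom = c("a", "b"), length = c(5000L, 3000L))
  reads <- tibble::tibble(
    chrom = sample(c("a", "b"), 200, replace = TRUE),
    strand = sample(c("+", "-"), 200, replace = TRUE)
  ) |>
    dplyr::mutate(start = ifelse(chrom == "a",
                                 sample(100:4800, 200, replace = TRUE),
                                 sample(100:2800, 200, replace = TRUE)))
  tr <- extend_reads(reads, g, 80L)
  expect_equal(sum(tr$a) + sum(tr$b), 200 * 80)
})

test_that("normalization scales each chromosome to 1e6 and is scale-free", {
  set.seed(11)
  g <- tibble::tibble(chrom = c("a", "b"), length = c(2000L, 2000L))
  v <- list(a = rpois(2000, 5) + 0.0, b = rpois(2000, 2) + 0.0)
  tr <- phoregulon:::new_coverage_track(v, g, 100L, normalized = FALSE)
  nm <- normalize_coverage(tr)
  expect_equal(sum(nm$a), 1e6, tolerance = 1e-9)
  expect_equal(sum(nm$b), 1e6, tolerance = 1e-9)

  tr3 <- phoregulon:::new_coverage_track(lapply(v, `*`, 3), g, 100L,
                                         normalized = FALSE)
  expect_equal(unclass(normalize_coverage(tr3))[1:2], unclass(nm)[1:2],
               tolerance = 1e-12)

  v0 <- list(a = v$a, b = numeric(2000))
  tr0 <- phoregulon:::new_coverage_track(v0, g, 50L, normalized = FALSE)
  expect_warning(n0 <- normalize_coverage(tr0), "no coverage")
  expect_true(all(n0$b == 0))
})

test_that("genome average is the mass-per-base mean over chromosomes", {
  g <- tibble::tibble(chrom = c("a", "b"), length = c(100L, 100L))
  tr <- phoregulon:::new_coverage_track(
    list(a = rep(2, 100), b = rep(0, 100)), g, 10L, normalized = TRUE
  )
  expect_equal(genome_average(tr), 1)
  tr_swap <- phoregulon:::new_coverage_track(
    list(b = rep(0, 100), a = rep(2, 100)), g[2:1, ], 10L, normalized = TRUE
  )
  expect_equal(genome_average(tr_swap), 1)
  uni <- phoregulon:::new_coverage_track(
    list(a = rep(3.5, 100)), g[1, ], 10L, normalized = TRUE
  )
  expect_equal(genome_average(uni), 3.5)
})
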