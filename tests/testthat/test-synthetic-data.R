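# Generators: determinism, placement constraints, planted-truth geometry.

test_that("genome generation is deterministic and respects spacing", {
  a <- generate_genome(3, 1e5, 60, seed = 1)
  b <- generate_genome(3, 1e5, 60, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$genes), 60)
  expect_true(all(a$genes$strand %in% c("+", "-")))
  expect_gt(length(unique(a$genes$strand)), 1)

  # gene footprints within bounds, gaps wide enough for promoters
  by_chr <- split(a$genes, a$genes$chrom)
  for (g in by_chr) {
    g <- g[order(g$start), ]
    expect_true(all(g$start >= 0))
    expect_true(all(g$end <= a$genome$length[match(g$chrom[1], a$genome$chrom)]))
    if (nrow(g) > 1) expect_true(all(g$start[-1] - g$end[-nrow(g)] >= 1000))
  }

  # all 60 promoter windows pairwise disjoint
  pw <- promoter_windows(a$genes) |> dplyr::arrange(chrom, win_start)
  by_chr <- split(pw, pw$chrom)
  for (w in by_chr) {
    if (nrow(w) > 1) {
      expect_true(all(w$win_start[-1] >= w$win_end[-nrow(w)]))
    }
  }
})

test_that("genome generation handles empty and infeasible cases", {
  g <- generate_genome(1, 10000, 0, seed = 1)
  expect_equal(nrow(g$genes), 0)
  expect_named(g$genes, c("gene_id", "chrom", "strand", "atg", "length",
                          "start", "end"))
  expect_error(generate_genome(1, 5000, 50, seed = 1), "capacity")
})

test_that("expression simulator is deterministic and exact at zero noise", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:50))
  plan <- tibble::tibble(
    gene_id = "g001", class = "fast", pho7_dependent = FALSE,
    csk1_repressed = FALSE, log2_effect = 2.0
  )
  design <- tibble::tibble(sample_id = paste0("t", c(0, 30, 60, 120, 240)),
                           time_point = c(0, 30, 60, 120, 240))
  a <- simulate_expression(genes, plan, design, noise_sd = 0, seed = 5)
  b <- simulate_expression(genes, plan, design, noise_sd = 0, seed = 5)
  expect_identical(a, b)

  a$m <- log2(a$cy3 / a$cy5)
  prof <- timecourse_ratios(a)
  v <- prof$value[prof$orf_id == "g001"]
  expect_equal(v[prof$time_point[prof$orf_id == "g001"] == 120], 2.0,
               tolerance = 1e-12)
  expect_error(
    simulate_expression(genes, dplyr::mutate(plan, gene_id = "nope"), design),
    "unknown gene"
  )
})

test_that("null expression simulation has near-zero genome-wide median", {
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:5000))
  plan <- regulation_plan(genes, n_fast = 0, n_slow = 0,
                          n_pho7_dependent = 0, n_csk1_repressed = 0)
  design <- tibble::tibble(sample_id = c("t0", "t120"),
                           time_point = c(0, 120))
  arr <- simulate_expression(genes, plan, design, noise_sd = 0.2, seed = 9)
  arr$m <- log2(arr$cy3 / arr$cy5)
  prof <- timecourse_ratios(arr)
  expect_lt(abs(median(prof$value[prof$time_point == 120])), 0.05)
})

test_that("chip-seq background is uniform and site reads enrich the IP", {
  gn <- generate_genome(3, 1e5, 0, seed = 2)
  empty_sites <- binding_sites(gn$genome, 0, seed = 1)
  rs <- simulate_chipseq(gn$genome, empty_sites, 1e5, "no_pi", seed = 3)
  expect_identical(rs, simulate_chipseq(gn$genome, empty_sites, 1e5, "no_pi",
                                        seed = 3))
  counts <- table(factor(rs$chrom, levels = gn$genome$chrom))
  p <- gn$genome$length / sum(gn$genome$length)
  for (i in seq_len(3)) {
    expected <- nrow(rs) * p[i]
    sigma <- sqrt(nrow(rs) * p[i] * (1 - p[i]))
    expect_lt(abs(counts[i] - expected), 3 * sigma)
  }
  expect_true(all(rs$start >= 0))
  expect_true(all(rs$start < gn$genome$length[match(rs$chrom, gn$genome$chrom)]))

  one <- tibble::tibble(site_id = "s1", chrom = "chrI", center = 50000L,
                        footprint = 20L, enrichment_high_pi = 1,
                        enrichment_no_pi = 10)
  ip <- simulate_chipseq(gn$genome, one, 1e5, "no_pi", seed = 4)
  mock <- simulate_chipseq(gn$genome, one, 1e5, "mock", seed = 5)
  cov_at <- function(reads) {
    tr <- extend_reads(reads, gn$genome)
    tr$chrI[50000]
  }
  expect_gt(cov_at(ip), cov_at(mock))
  expect_error(
    simulate_chipseq(gn$genome, dplyr::mutate(one, center = 10^7), 100,
                     "no_pi", seed = 1),
    "outside"
  )
})

test_that("mock coverage at planted sites is background-like", {
  # dispersion of mock read starts in site windows should match the uniform
  # background (chi-square dispersion test against the uniform expectation)
  gn <- generate_genome(2, 1e5, 0, seed = 6)
  sites <- binding_sites(gn$genome, 8, seed = 6)
  pass <- vapply(1:10, function(s) {
    mock <- simulate_chipseq(gn$genome, sites, 5e4, "mock", seed = 100 + s)
    win <- 500L
    n_in <- vapply(seq_len(nrow(sites)), function(i) {
      sum(mock$chrom == sites$chrom[i] &
            abs(mock$start - sites$center[i]) <= win)
    }, 0)
    lambda <- nrow(mock) * (2 * win + 1) / sum(gn$genome$length)
    stat <- sum((n_in - lambda)^2 / lambda)
    p <- stats::pchisq(stat, df = nrow(sites), lower.tail = FALSE)
    p > 0.01
  }, TRUE)
  expect_gte(sum(pass), 9)
})

test_that("facs simulator straddles the gate and is exact at zero sd", {
  ev <- simulate_facs_events(50000, scatter_range = c(0, 2e5),
                             yfp_mean = 500, yfp_sd = 100,
                             autofluor_mean = 50, seed = 1)
  expect_identical(ev, simulate_facs_events(50000, scatter_range = c(0, 2e5),
                                            yfp_mean = 500, yfp_sd = 100,
                                            autofluor_mean = 50, seed = 1))
  in_gate <- mean(ev$fsc >= 5e4 & ev$fsc <= 15e4 &
                    ev$ssc >= 5e4 & ev$ssc <= 15e4)
  expect_lt(abs(in_gate - 0.25), 0.02) # 0.5 x 0.5 for two scatters

  ev0 <- simulate_facs_events(1000, yfp_mean = 700, yfp_sd = 0,
                              autofluor_mean = 50, seed = 2)
  s <- facs_gate_and_summarize(ev0)
  expect_equal(s$mean_yfp, 700)
})
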