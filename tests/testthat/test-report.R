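# Regulon report assembly on zero-noise fixtures with known planted truth.

make_zero_noise_calls <- function(genes, plan, genotypes, conditions,
                                  contrasts) {
  design <- tidyr::expand_grid(genotype = genotypes, condition = conditions,
                               replicate = 1:2) |>
    dplyr::mutate(sample_id = paste(genotype, condition, replicate, sep = "."))
  arr <- simulate_expression(genes, plan, design, noise_sd = 0, seed = 31)
  arr$m <- log2(arr$cy3 / arr$cy5)
  av <- average_probes(arr)
  purrr::imap_dfr(contrasts, function(ct, nm) {
    ga <- dplyr::filter(av, genotype == ct$a[1], condition == ct$a[2])
    gb <- dplyr::filter(av, genotype == ct$b[1], condition == ct$b[2])
    differential_call(ga, gb, contrast = nm)
  })
}

test_that("triple intersection of fast, dependent and bound genes is exact", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:100))
  # 5 fast genes, all pho7-dependent; 3 slow independent ones
  plan <- tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::mutate(
      class = dplyr::case_when(gene_id %in% sprintf("g%03d", 1:5) ~ "fast",
                               gene_id %in% sprintf("g%03d", 6:8) ~ "slow",
                               TRUE ~ "none"),
      pho7_dependent = gene_id %in% sprintf("g%03d", 1:5),
      csk1_repressed = FALSE,
      log2_effect = ifelse(class == "none", 0, 2.5)
    )

  tc_design <- tibble::tibble(sample_id = paste0("t", c(0, 120, 240)),
                              time_point = c(0, 120, 240))
  arr <- simulate_expression(genes, plan, tc_design, noise_sd = 0, seed = 30)
  arr$m <- log2(arr$cy3 / arr$cy5)
  prof <- timecourse_ratios(arr)
  cls <- classify_temporal_response(
    prof,
    compute_induction_threshold(prof$value[prof$time_point == 120], 120),
    compute_induction_threshold(prof$value[prof$time_point == 240], 240)
  )

  calls <- make_zero_noise_calls(
    genes, plan, c("wt", "pho7D"), "no_pi",
    list(wt_vs_pho7D_noPi = list(a = c("wt", "no_pi"),
                                 b = c("pho7D", "no_pi")))
  )
  bound <- c(sprintf("g%03d", 1:5), "g050", "g060") # the 5 plus two extras

  rep <- regulon_report(cls, calls, bound, genes$gene_id)
  triple <- tidy(rep) |>
    dplyr::filter(class == "fast", passes_wt_vs_pho7D_noPi, bound)
  expect_setequal(triple$gene_id, sprintf("g%03d", 1:5))

  ot <- rep$overlap_tests
  expect_true(all(c("pi_regulated", "wt_vs_pho7D_noPi") %in% ot$regulated_set))
  expect_equal(ot$k[ot$regulated_set == "wt_vs_pho7D_noPi"], 5)
  # hand-check one overlap p against the closed form
  expect_equal(
    ot$p_value[ot$regulated_set == "wt_vs_pho7D_noPi"],
    hypergeometric_overlap(100, 7, 5, 5)$p_value
  )

  cs <- rep$contrast_summary
  expect_equal(cs$n_passing, 5)
  expect_equal(cs$frac_passing_bound, 1)

  # no bound genes: every overlap p-value is 1
  rep0 <- regulon_report(cls, calls, character(0), genes$gene_id)
  expect_true(all(rep0$overlap_tests$p_value == 1))

  expect_error(regulon_report(cls, calls, "not_a_gene", genes$gene_id),
               "universe")
})

test_that("csk1-repressed genes carry the epistasis flag at zero noise", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:60))
  plan <- tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::mutate(
      class = ifelse(gene_id %in% sprintf("g%03d", 1:8), "fast", "none"),
      pho7_dependent = gene_id %in% sprintf("g%03d", 1:6),
      csk1_repressed = gene_id %in% sprintf("g%03d", 1:4),
      log2_effect = ifelse(class == "none", 0, 2.5)
    )
  calls <- make_zero_noise_calls(
    genes, plan, c("wt", "csk1D", "pho7D_csk1D"), c("high_pi", "no_pi"),
    list(
      csk1D_vs_wt_highPi = list(a = c("csk1D", "high_pi"),
                                b = c("wt", "high_pi")),
      dblD_noPi_vs_highPi = list(a = c("pho7D_csk1D", "no_pi"),
                                 b = c("pho7D_csk1D", "high_pi"))
    )
  )
  rep <- regulon_report(NULL, calls, character(0), genes$gene_id,
                        epistasis = c(single = "csk1D_vs_wt_highPi",
                                      double = "dblD_noPi_vs_highPi"))
  flagged <- tidy(rep) |> dplyr::filter(epistasis)
  expect_setequal(flagged$gene_id, sprintf("g%03d", 1:4))
})
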