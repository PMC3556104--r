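# Two-color expression-array simulator with planted temporal and
# genotype-dependent regulation, mirroring a 5-point starvation time course
# hybridized against a pooled reference and replicated genotype/condition
# contrasts.

PHO_TIME_POINTS <- c(0, 30, 60, 120, 240)

# shape of the induction profile across the time course, as a multiplier of
# the planted plateau effect; the "fast" class is fully induced by 120 min,
# the "slow" class only at 240 min (with a small sub-threshold shoulder)
fast_shape <- c(`0` = 0, `30` = 0.4, `60` = 0.8, `120` = 1, `240` = 1)
slow_shape <- c(`0` = 0, `30` = 0, `60` = 0, `120` = 0.1, `240` = 1)

#' Construct a planted-regulation plan
#'
#' Assigns temporal classes and genotype dependencies to a random subset of
#' genes. `fast` genes reach their full planted effect by 120 minutes of
#' phosphate starvation, `slow` genes only at 240 minutes; `pho7_dependent`
#' genes lose their induction when *pho7* is deleted, and `csk1_repressed`
#' genes are constitutively induced in a *csk1* deletion but uninducible in
#' the *pho7 csk1* double deletion (the epistasis pattern). Because that
#' pattern requires Pho7, `csk1_repressed` genes are drawn from the
#' `pho7_dependent` set.
#'
#' @param genes Tibble with a `gene_id` column.
#' @param n_fast,n_slow Numbers of rapidly and slowly induced genes.
#' @param n_pho7_dependent Number of induced genes whose induction requires
#'   *pho7* (must not exceed `n_fast + n_slow`).
#' @param n_csk1_repressed Number of *pho7*-dependent genes under Csk1
#'   repression (must not exceed `n_pho7_dependent`).
#' @param log2_effect Planted plateau effect in log2 units.
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `class` (`fast`/`slow`/`none`),
#'   `pho7_dependent`, `csk1_repressed`, `log2_effect`. One row per gene in
#'   `genes`; unregulated genes have class `none` and effect 0.
#' @export
regulation_plan <- function(genes, n_fast = 20, n_slow = 15,
                            n_pho7_dependent = 16, n_csk1_repressed = 5,
                            log2_effect = 2.5, seed = 1) {
  n_fast <- check_count(n_fast, "n_fast", 0L)
  n_slow <- check_count(n_slow, "n_slow", 0L)
  n_ind <- n_fast + n_slow
  if (n_ind > nrow(genes)) abort("more planted genes than genes available")
  if (n_pho7_dependent > n_ind) {
    abort("`n_pho7_dependent` cannot exceed the number of induced genes")
  }
  if (n_csk1_repressed > n_pho7_dependent) {
    abort("`n_csk1_repressed` cannot exceed `n_pho7_dependent`")
  }
  with_seed(seed, {
    ids <- sample(genes$gene_id, n_ind)
    fast <- ids[seq_len(n_fast)]
    slow <- setdiff(ids, fast)
    dep <- sample(ids, n_pho7_dependent)
    csk <- sample(dep, n_csk1_repressed)
    tibble(gene_id = genes$gene_id) |>
      mutate(
        class = dplyr::case_when(
          .data$gene_id %in% fast ~ "fast",
          .data$gene_id %in% slow ~ "slow",
          TRUE ~ "none"
        ),
        pho7_dependent = .data$gene_id %in% dep,
        csk1_repressed = .data$gene_id %in% csk,
        log2_effect = ifelse(.data$class == "none", 0, log2_effect)
      )
  })
}

#' Planted log2 signal for each gene in each sample
#'
#' Expands a regulation plan over a sample design into the true (noise-free)
#' log2 expression offset of every gene in every sample. Time-course designs
#' (a `time_point` column, minutes) follow the class shape profiles;
#' genotype/condition designs (`genotype` and `condition` columns) apply the
#' dependence rules: induction in `no_pi`, abolished by *pho7* deletion for
#' `pho7_dependent` genes, constitutive in `csk1D` and absent in
#' `pho7D_csk1D` for `csk1_repressed` genes.
#'
#' @param plan A [regulation_plan()] tibble.
#' @param design Sample sheet tibble with `sample_id` and either
#'   `time_point` or `genotype` + `condition` columns.
#' @return Tibble: `gene_id`, `sample_id`, `log2_signal`.
#' @export
planted_signal <- function(plan, design) {
  stopifnot(is.data.frame(plan), is.data.frame(design))
  grid <- tidyr::expand_grid(
    plan |> select("gene_id", "class", "pho7_dependent",
                   "csk1_repressed", "log2_effect"),
    design
  )
  if ("time_point" %in% names(design)) {
    tp <- as.character(grid$time_point)
    mult <- ifelse(
      grid$class == "fast", fast_shape[tp],
      ifelse(grid$class == "slow", slow_shape[tp], 0)
    )
    if (anyNA(mult)) abort("time points must be among 0, 30, 60, 120, 240")
    grid$log2_signal <- grid$log2_effect * mult
  } else if (all(c("genotype", "condition") %in% names(design))) {
    pho7_del <- grepl("pho7", grid$genotype)
    csk1_del <- grepl("csk1", grid$genotype)
    starved <- grid$condition == "no_pi"
    inducible <- grid$log2_effect > 0 & !(grid$pho7_dependent & pho7_del)
    constitutive <- grid$csk1_repressed & csk1_del & !pho7_del
    grid$log2_signal <- grid$log2_effect * as.numeric(
      inducible & (starved | constitutive)
    )
  } else {
    abort("design needs a `time_point` column or `genotype`+`condition` columns")
  }
  grid |> select("gene_id", "sample_id", "log2_signal")
}

#' Simulate two-color expression arrays with planted regulation
#'
#' Generates per-probe Cy3/Cy5 intensity tables for every sample in the
#' design. Each gene is probed twice (two probes per ORF, as on the 8x15K
#' platform the pipeline targets). The Cy3 channel carries the sample of
#' interest; the Cy5 channel carries a pooled reference built as an equal
#' mix of all sample states in the design, so time-course ratios against the
#' pool recover planted effects after differencing against t = 0.
#'
#' Intensities follow `2^(baseline + probe_offset + signal + dye_bias +
#' noise)` with gene baselines `N(10, 1)`, probe offsets `N(0, 0.3)` and
#' i.i.d. Gaussian noise of `noise_sd` log2 units per channel.
#'
#' @param genes Tibble with a `gene_id` column.
#' @param plan A [regulation_plan()] tibble; every `gene_id` it names must
#'   exist in `genes`.
#' @param design Sample sheet (see [planted_signal()]); may carry a
#'   `replicate` column.
#' @param noise_sd Per-channel Gaussian noise, log2 units.
#' @param dye_bias Constant Cy3-over-Cy5 bias, log2 units.
#' @param seed Integer seed; fixed seed gives identical tables.
#' @return Tibble: `sample_id`, `probe_id`, `orf_id`, `cy3`, `cy5` plus the
#'   design metadata columns, one row per probe per sample.
#' @export
simulate_expression <- function(genes, plan, design, noise_sd = 0.2,
                                dye_bias = 0, seed = 1) {
  if (!all(plan$gene_id %in% genes$gene_id)) {
    bad <- setdiff(plan$gene_id, genes$gene_id)
    abort(paste0("plan references unknown genes: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  noise_sd <- check_number(noise_sd, "noise_sd", 0)
  full_plan <- tibble(gene_id = genes$gene_id) |>
    left_join(plan, by = "gene_id") |>
    mutate(
      class = dplyr::coalesce(.data$class, "none"),
      pho7_dependent = dplyr::coalesce(.data$pho7_dependent, FALSE),
      csk1_repressed = dplyr::coalesce(.data$csk1_repressed, FALSE),
      log2_effect = dplyr::coalesce(.data$log2_effect, 0)
    )
  sig <- planted_signal(full_plan, design)

  with_seed(seed, {
    ng <- nrow(genes)
    base <- tibble(
      gene_id = rep(genes$gene_id, each = 2L),
      probe_id = paste0(rep(genes$gene_id, each = 2L), "_p", rep(1:2, ng)),
      baseline = rep(rnorm(ng, 10, 1), each = 2L),
      probe_off = rnorm(2L * ng, 0, 0.3)
    )
    # pooled reference: equal mix of the design's sample states
    ref <- sig |>
      group_by(.data$gene_id) |>
      summarise(ref_signal = log2(mean(2^.data$log2_signal)))

    out <- tidyr::expand_grid(sample_id = design$sample_id, base) |>
      left_join(sig, by = c("gene_id", "sample_id")) |>
      left_join(ref, by = "gene_id")
    n <- nrow(out)
    eps3 <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    eps5 <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    out |>
      mutate(
        cy3 = 2^(.data$baseline + .data$probe_off + .data$log2_signal +
                   dye_bias + eps3),
        cy5 = 2^(.data$baseline + .data$probe_off + .data$ref_signal + eps5),
        orf_id = .data$gene_id
      ) |>
      select("sample_id", "probe_id", "orf_id", "cy3", "cy5") |>
      left_join(design, by = "sample_id")
  })
}
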