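# ChIP-Seq read simulator: uniform background plus fragment-sampled reads at
# planted binding sites. Reads are 50-bp single-end 5' start positions with
# strand, the form in which uniquely-aligned reads enter the peak caller.

#' Construct a planted binding-site table
#'
#' Places `n_sites` binding sites at gene-free or arbitrary positions on a
#' toy genome, well separated so each site yields a distinct peak.
#'
#' @param genome Genome tibble (`chrom`, `length`).
#' @param n_sites Number of sites.
#' @param enrichment_no_pi,enrichment_high_pi Fold enrichment of site
#'   coverage over the background average in starvation and replete
#'   conditions (>= 1; 1 means no binding).
#' @param footprint Site footprint in bases.
#' @param min_separation Minimum distance between site centers (and from
#'   chromosome ends).
#' @param seed Integer seed.
#' @return Tibble: `site_id`, `chrom`, `center`, `footprint`,
#'   `enrichment_high_pi`, `enrichment_no_pi`.
#' @export
binding_sites <- function(genome, n_sites, enrichment_no_pi = 10,
                          enrichment_high_pi = 3, footprint = 20,
                          min_separation = 5000, seed = 1) {
  n_sites <- check_count(n_sites, "n_sites", 0L)
  stopifnot(enrichment_no_pi >= 1, enrichment_high_pi >= 1, footprint >= 1)
  with_seed(seed, {
    # one candidate grid per chromosome, spaced >= min_separation
    cand <- purrr::pmap_dfr(genome, function(chrom, length) {
      pos <- seq(min_separation, length - min_separation, by = min_separation)
      if (!length(pos)) return(tibble(chrom = character(), center = integer()))
      tibble(chrom = chrom, center = as.integer(pos))
    })
    if (nrow(cand) < n_sites) abort("genome too small for that many sites")
    picked <- cand[sort(sample.int(nrow(cand), n_sites)), , drop = FALSE]
    picked |>
      mutate(
        site_id = sprintf("site_%03d", row_number()),
        footprint = as.integer(footprint),
        enrichment_high_pi = enrichment_high_pi,
        enrichment_no_pi = enrichment_no_pi
      ) |>
      select("site_id", "chrom", "center", "footprint",
             "enrichment_high_pi", "enrichment_no_pi")
  })
}

# truncated-normal fragment lengths via inverse CDF
rfraglen <- function(n, mean = 450, sd = 75, range = c(300, 600)) {
  lo <- pnorm(range[1], mean, sd)
  hi <- pnorm(range[2], mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate a ChIP-Seq read set over a toy genome
#'
#' Background reads are uniform over the genome. Site reads are generated by
#' drawing a chromatin fragment of length `~ Normal(450, 75)` truncated to
#' 300-600 bp that overlaps the site center, then emitting a 50-bp read from
#' one fragment end on the matching strand. The expected number of site
#' reads is `(enrichment - 1) * depth * mean_fragment / genome_length`, so
#' the expected coverage at a site center is about `enrichment` times the
#' background average. Mock samples carry background only.
#'
#' @param genome Genome tibble (`chrom`, `length`).
#' @param sites [binding_sites()] tibble (may be empty).
#' @param depth Total number of reads.
#' @param condition One of `"high_pi"`, `"no_pi"`, `"mock"`; selects which
#'   enrichment column drives site read mass (mock ignores sites).
#' @param seed Integer seed.
#' @param sample_id Label stored in the output (defaults to the condition).
#' @param read_length Read length in bases (fixed at 50 by the platform).
#' @return Tibble: `sample_id`, `chrom`, `start` (0-based 5' position),
#'   `strand`; attribute `read_length`.
#' @export
simulate_chipseq <- function(genome, sites, depth, condition, seed,
                             sample_id = condition, read_length = 50L) {
  depth <- check_count(depth, "depth")
  condition <- match.arg(condition, c("high_pi", "no_pi", "mock"))
  if (nrow(sites) > 0) {
    bad <- !sites$chrom %in% genome$chrom |
      sites$center >= genome$length[match(sites$chrom, genome$chrom)] |
      sites$center < 0
    if (any(bad, na.rm = TRUE)) abort("binding site outside the genome")
  }
  L <- genome_length(genome)

  with_seed(seed, {
    enr <- if (condition == "mock" || nrow(sites) == 0) {
      rep(1, nrow(sites))
    } else if (condition == "no_pi") sites$enrichment_no_pi
    else sites$enrichment_high_pi
    n_site <- if (nrow(sites)) rpois(nrow(sites), (enr - 1) * depth * 450 / L)
              else integer(0)
    if (sum(n_site) >= depth) abort("site read mass exceeds total depth")
    n_bg <- depth - sum(n_site)

    # background: chromosome proportional to length, position uniform
    ci <- sample.int(nrow(genome), n_bg, replace = TRUE,
                     prob = genome$length / L)
    strand_bg <- sample(c("+", "-"), n_bg, replace = TRUE)
    len_ci <- genome$length[ci]
    pos_bg <- ifelse(
      strand_bg == "+",
      floor(runif(n_bg, 0, len_ci - read_length + 1)),
      floor(runif(n_bg, read_length - 1, len_ci))
    )
    bg <- tibble(chrom = genome$chrom[ci], start = as.integer(pos_bg),
                 strand = strand_bg)

    site_reads <- purrr::map_dfr(which(n_site > 0), function(i) {
      n <- n_site[i]
      fl <- round(rfraglen(n))
      a <- sites$center[i] - floor(runif(n) * fl) # fragment [a, a + fl)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      pos <- ifelse(strand == "+", a, a + fl - 1)
      clen <- genome$length[match(sites$chrom[i], genome$chrom)]
      ok <- ifelse(strand == "+", pos >= 0 & pos + read_length <= clen,
                   pos - read_length + 1 >= 0 & pos < clen)
      tibble(chrom = sites$chrom[i], start = as.integer(pos[ok]),
             strand = strand[ok])
    })

    out <- bind_rows(bg, site_reads) |>
      mutate(sample_id = sample_id) |>
      select("sample_id", "chrom", "start", "strand")
    attr(out, "read_length") <- as.integer(read_length)
    out
  })
}
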