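# Toy genomes and gene annotations with known placement, used as the ground
# truth surface for the ChIP-Seq and promoter-assignment stages.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy multi-chromosome genome with non-overlapping gene models
#'
#' Builds a small stand-in genome for desk-scale simulation: chromosome
#' lengths are drawn within +/-10% of `mean_length`, and `n_genes` gene
#' models are placed on random strands with wide intergenic spacing so that
#' every 800-bp promoter window (see [promoter_windows()]) is unambiguous
#' and disjoint from its neighbours.
#'
#' Coordinates are 0-based half-open throughout the package; `atg` is the
#' coordinate of the first base of the start codon, so a `+` strand gene
#' occupies `[atg, atg + length)` and a `-` strand gene `[atg + 1 - length,
#' atg + 1)`.
#'
#' @param n_chroms Number of chromosomes.
#' @param mean_length Mean chromosome length in bases.
#' @param n_genes Total number of gene models to place (0 allowed).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param gene_length Mean gene length in bases; individual lengths vary
#'   uniformly within +/-30%.
#' @param min_intergenic Minimum gap between adjacent gene footprints. The
#'   default (1700 bp) exceeds twice the promoter window plus one base, so
#'   even divergent gene pairs have disjoint promoters.
#'
#' @return A list with elements `genome` (tibble: `chrom`, `length`) and
#'   `genes` (tibble: `gene_id`, `chrom`, `strand`, `atg`, `length`,
#'   `start`, `end`), plus the `seed` used.
#' @export
#' @examples
#' gn <- generate_genome(3, 1e5, 60, seed = 1)
#' gn$genome
#' head(gn$genes)
generate_genome <- function(n_chroms, mean_length, n_genes, seed,
                            gene_length = 1500, min_intergenic = 1700) {
  n_chroms <- check_count(n_chroms, "n_chroms")
  mean_length <- check_number(mean_length, "mean_length", min = 1)
  n_genes <- check_count(n_genes, "n_genes", min = 0L)
  seed <- check_count(seed, "seed", min = 0L)

  with_seed(seed, {
    lens <- round(mean_length * runif(n_chroms, 0.9, 1.1))
    genome <- tibble(
      chrom = paste0("chr", as.character(utils::as.roman(seq_len(n_chroms)))),
      length = as.integer(lens)
    )

    margin <- 900L # keeps promoter windows inside chromosome bounds
    max_len <- ceiling(1.3 * gene_length)
    cap <- pmax(0, floor((genome$length - 2 * margin + min_intergenic) /
                           (max_len + min_intergenic)))
    if (sum(cap) < n_genes) {
      abort(sprintf(
        "cannot place %d genes: capacity is %d under the spacing constraints",
        n_genes, sum(cap)
      ))
    }

    # largest-remainder apportionment of genes to chromosomes, capped
    k <- integer(n_chroms)
    if (n_genes > 0) {
      share <- cap / sum(cap) * n_genes
      k <- pmin(cap, floor(share))
      while (sum(k) < n_genes) {
        room <- which(k < cap)
        i <- room[which.max((share - k)[room])]
        k[i] <- k[i] + 1L
      }
    }

    genes <- purrr::map2_dfr(seq_len(n_chroms), k, function(ci, kk) {
      if (kk == 0L) {
        return(tibble(
          chrom = character(), strand = character(),
          start = integer(), end = integer()
        ))
      }
      len_g <- round(runif(kk, 0.7, 1.3) * gene_length)
      avail <- genome$length[ci] - 2L * margin
      slack <- avail - sum(len_g) - (kk - 1L) * min_intergenic
      extra <- as.vector(stats::rmultinom(1, slack, rep(1, kk + 1L)))
      starts <- margin + cumsum(c(0L, len_g[-kk] + min_intergenic)) +
        cumsum(extra[seq_len(kk)])
      tibble(
        chrom = genome$chrom[ci],
        strand = sample(c("+", "-"), kk, replace = TRUE),
        start = as.integer(starts),
        end = as.integer(starts + len_g)
      )
    })

    if (nrow(genes) > 0) {
      genes <- genes |>
        mutate(
          gene_id = sprintf("gene_%04d", row_number()),
          atg = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
          length = .data$end - .data$start
        ) |>
        select("gene_id", "chrom", "strand", "atg", "length", "start", "end")
    } else {
      genes <- tibble(
        gene_id = character(), chrom = character(), strand = character(),
        atg = integer(), length = integer(), start = integer(), end = integer()
      )
    }

    list(genome = genome, genes = genes, seed = seed)
  })
}

#' Total genome length in bases
#' @param genome Tibble with `chrom` and `length` columns.
#' @return Total length (numeric scalar).
#' @export
genome_length <- function(genome) {
  sum(as.numeric(genome$length))
}
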