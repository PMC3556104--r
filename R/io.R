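# File-format boundaries. Interval coordinates are 0-based half-open inside
# the package; BED/bedGraph are native, GFF3 (1-based inclusive) is
# converted at this boundary by rtracklayer.

#' Write and read gene models as GFF3
#'
#' Gene footprints are written as `gene` features (1-based inclusive, per
#' the GFF3 standard) with the gene identifier in `ID`. On reading, the
#' 0-based `atg` coordinate is reconstructed from the strand: the first
#' base of the start codon is the leftmost footprint base for `+` genes and
#' the rightmost for `-` genes.
#'
#' @param genes Gene tibble (see [generate_genome()]).
#' @param path Output/input file path.
#' @return `write_genes_gff3()` returns `path` invisibly;
#'   `read_genes_gff3()` returns a gene tibble.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    atg = as.integer(ifelse(strand == "+", start0, end0 - 1L)),
    length = as.integer(end0 - start0),
    start = as.integer(start0),
    end = as.integer(end0)
  ) |> arrange(.data$chrom, .data$start)
}

#' Write and read 50-bp read sets as 4-column BED-like files
#'
#' Columns are `chrom`, 0-based `start`, `end` of the read interval, and
#' `strand`; the 5' start position is the left end for `+` reads and
#' `end - 1` for `-` reads.
#'
#' @param reads Read tibble (`chrom`, `start` = 0-based 5' position,
#'   `strand`).
#' @param path File path.
#' @param read_length Read length (default 50).
#' @param sample_id Sample label attached on reading.
#' @return `write_reads_bed()` returns `path` invisibly;
#'   `read_reads_bed()` returns a read tibble.
#' @export
write_reads_bed <- function(reads, path, read_length = attr(reads, "read_length") %||% 50L) {
  out <- tibble(
    chrom = reads$chrom,
    start = ifelse(reads$strand == "+", reads$start,
                   reads$start - read_length + 1L),
    end = ifelse(reads$strand == "+", reads$start + read_length,
                 reads$start + 1L),
    strand = reads$strand
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path, sample_id = NA_character_, read_length = 50L) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "strand"),
                       col_types = "ciic", progress = FALSE)
  out <- tibble(
    sample_id = sample_id,
    chrom = x$chrom,
    start = as.integer(ifelse(x$strand == "+", x$start, x$end - 1L)),
    strand = x$strand
  )
  attr(out, "read_length") <- as.integer(read_length)
  out
}

#' Write retained and candidate peaks as BED6
#'
#' The BED score is `fold_enrichment * 100`, clamped to the 0-1000 integer
#' range; the name column carries the peak id.
#'
#' @param peaks Scored peak tibble from [score_peaks()].
#' @param path File path.
#' @param retained_only Write only retained peaks (default TRUE).
#' @return `write_peaks()` returns `path` invisibly; `read_peaks()` a
#'   tibble (`chrom`, `start`, `end`, `peak_id`, `score`, `strand`).
#' @export
write_peaks <- function(peaks, path, retained_only = TRUE) {
  if (retained_only && "retained" %in% names(peaks)) {
    peaks <- peaks |> filter(.data$retained)
  }
  if (nrow(peaks) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = "*"
  )
  gr$name <- peaks$peak_id %||% sprintf("peak_%04d", seq_len(nrow(peaks)))
  score <- peaks$fold_enrichment %||% rep(0, nrow(peaks))
  gr$score <- pmin(pmax(as.integer(round(score * 100)), 0L), 1000L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  peak_id = character(), score = integer()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.integer(gr$score) else NA_integer_
  )
}

#' Write and read coverage as bedGraph
#'
#' Runs of equal depth are written as 0-based half-open intervals; zero
#' runs are included so the track reconstructs exactly.
#'
#' @param track A `coverage_track`.
#' @param path File path.
#' @param genome Genome tibble used to rebuild per-base vectors on reading.
#' @return `write_coverage()` returns `path` invisibly; `read_coverage()` a
#'   `coverage_track`.
#' @export
write_coverage <- function(track, path) {
  dat <- as_tibble(track)
  gr <- GenomicRanges::GRanges(
    seqnames = dat$chrom,
    ranges = IRanges::IRanges(start = dat$start + 1L, end = dat$end),
    score = dat$depth
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(seq_len(nrow(genome)), function(i) {
    v <- numeric(genome$length[i])
    sel <- as.character(GenomicRanges::seqnames(gr)) == genome$chrom[i]
    g <- gr[sel]
    for (j in seq_along(g)) {
      v[GenomicRanges::start(g)[j]:GenomicRanges::end(g)[j]] <- g$score[j]
    }
    v
  })
  names(values) <- genome$chrom
  new_coverage_track(values, genome, NA_integer_, normalized = NA)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Serializes a simulated study — genome, gene models, expression arrays,
#' read sets, FACS events — together with a JSON manifest recording the
#' planted truth (regulation plan, binding sites), the seeds, and the MD5
#' checksum of every written file, so a re-run with the same configuration
#' is byte-checkable.
#'
#' @param dir Output directory (created if needed).
#' @param genome,genes From [generate_genome()].
#' @param arrays Optional array tibble from [simulate_expression()].
#' @param reads Optional named list of read tibbles (name = sample id).
#' @param facs Optional FACS event tibble.
#' @param plan,sites Optional planted truth tibbles.
#' @param seeds Named list/vector of seeds used, recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_fixture_bundle <- function(dir, genome, genes, arrays = NULL,
                                 reads = list(), facs = NULL, plan = NULL,
                                 sites = NULL, seeds = list()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(sprintf("cannot create '%s'", dir))
  }
  paths <- character()
  wr <- function(name, fun) {
    p <- file.path(dir, name)
    tryCatch(fun(p), error = function(e) {
      abort(sprintf("failed writing '%s': %s", p, conditionMessage(e)))
    })
    paths[[name]] <<- p
  }
  wr("genome.tsv", function(p) readr::write_tsv(genome, p))
  wr("genes.gff3", function(p) write_genes_gff3(genes, p))
  if (!is.null(arrays)) {
    wr("arrays.tsv", function(p) readr::write_tsv(arrays, p))
  }
  for (nm in names(reads)) {
    wr(paste0("reads_", nm, ".bed"), function(p) write_reads_bed(reads[[nm]], p))
  }
  if (!is.null(facs)) wr("facs.tsv", function(p) readr::write_tsv(facs, p))

  manifest <- list(
    seeds = seeds,
    files = lapply(paths, function(p) unname(tools::md5sum(p))),
    planted = list(
      regulation = if (!is.null(plan)) plan else NULL,
      sites = if (!is.null(sites)) sites else NULL
    )
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(mpath)
}
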