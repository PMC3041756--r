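# genome and annotation I/O helpers

# Coerce FASTA path / DNAStringSet / DNAString / character into one plain
# uppercase sequence string (single-replicon genomes).
as_genome_string <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (length(genome) != 1L) abort("expected a single-sequence genome.")
    return(toupper(as.character(genome[[1L]])))
  }
  if (inherits(genome, "DNAString")) return(toupper(as.character(genome)))
  if (is.character(genome) && length(genome) == 1L) {
    if (nchar(genome) < 1024 && file.exists(genome)) {
      seqs <- Biostrings::readDNAStringSet(genome)
      return(as_genome_string(seqs))
    }
    return(toupper(genome))
  }
  abort("`genome` must be a FASTA path, DNAString(Set), or sequence string.")
}

genome_name <- function(genome, default = "chr") {
  if (inherits(genome, "DNAStringSet") && !is.null(names(genome))) {
    return(sub("\\s.*$", "", names(genome)[1L]))
  }
  if (is.character(genome) && length(genome) == 1L &&
      nchar(genome) < 1024 && file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    return(genome_name(seqs, default))
  }
  default
}

#' G/C and A/T site counts of a sequence
#'
#' @param genome FASTA path, `DNAString(Set)` or sequence string.
#' @param start,end Optional 1-based sub-region bounds.
#' @return A one-row tibble with `n_gc`, `n_at` and `length_nt`.
#' @export
genome_composition <- function(genome, start = NULL, end = NULL) {
  s <- as_genome_string(genome)
  if (!is.null(start)) s <- substr(s, start, end)
  bases <- strsplit(s, "", fixed = TRUE)[[1L]]
  n_gc <- sum(bases %in% c("G", "C"))
  n_at <- sum(bases %in% c("A", "T"))
  tibble(n_gc = n_gc, n_at = n_at, length_nt = nchar(s))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Read or write a gene table
#'
#' Gene tables are tab-separated text with columns `gene_id`, `start`, `end`,
#' `strand`, `length_nt`, `n_gc`, `n_at` (1-based inclusive coordinates).
#'
#' @param path File path.
#' @return `read_gene_table()`: a tibble. `write_gene_table()`: `path`,
#'   invisibly.
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_gene_table
#' @param genes Gene tibble to write.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

#' Read CDS annotation from a GFF3 file
#'
#' Extracts CDS (or gene) features into the tibble layout used throughout the
#' pipeline.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (default `"CDS"`).
#' @return A tibble with `gene_id`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path, feature_type = "CDS") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  tibble(
    gene_id = sub("^cds-", "", ids),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
}

#' Write genome FASTA and GFF3 annotation
#'
#' @param genome Sequence (string or `DNAString(Set)`).
#' @param genes Gene tibble with `gene_id`, `start`, `end`, `strand`.
#' @param dir Output directory (created if needed).
#' @param name Sequence/replicon name.
#' @return Named character vector of written paths (`fasta`, `gff3`,
#'   `gene_table`).
#' @export
write_genome_files <- function(genome, genes, dir, name = "chr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- as_genome_string(genome)
  fasta <- file.path(dir, "genome.fa")
  seqs <- Biostrings::DNAStringSet(s)
  names(seqs) <- name
  Biostrings::writeXStringSet(seqs, fasta)
  tab <- file.path(dir, "genes.tsv")
  write_gene_table(genes, tab)
  gff <- file.path(dir, "genes.gff3")
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = name,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand,
      type = "CDS", ID = genes$gene_id, phase = 0L
    )
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    gff <- NA_character_
  }
  c(fasta = fasta, gff3 = gff, gene_table = tab)
}

# ensure a gene table carries n_gc/n_at composition columns
ensure_composition <- function(genes, genome) {
  if (all(c("n_gc", "n_at") %in% names(genes)) && !anyNA(genes$n_gc)) {
    return(genes)
  }
  s <- as_genome_string(genome)
  comp <- purrr::map2(genes$start, genes$end, function(a, b) {
    seg <- substr(s, a, b)
    bases <- strsplit(seg, "", fixed = TRUE)[[1L]]
    c(sum(bases %in% c("G", "C")), sum(bases %in% c("A", "T")))
  })
  genes$n_gc <- vapply(comp, `[`, numeric(1), 1L)
  genes$n_at <- vapply(comp, `[`, numeric(1), 2L)
  genes$length_nt <- genes$end - genes$start + 1L
  genes
}
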