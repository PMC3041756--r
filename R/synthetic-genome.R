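#' Generate a toy annotated genome
#'
#' Builds a random single-replicon genome of non-overlapping CDS (start
#' codon, in-frame body free of stop codons, stop codon; length divisible by
#' 3) separated by intergenic spacers, at a controlled GC fraction. Some
#' genes are placed on the reverse strand. Deterministic given `seed`. The
#' result is a self-contained stand-in for a small annotated bacterial
#' genome, used to exercise every pipeline stage without downloads.
#'
#' @param n_genes Number of CDS features.
#' @param mean_gene_length Mean CDS length in nt (drawn per gene, always a
#'   multiple of 3, minimum 60).
#' @param gc_fraction Target genome GC fraction.
#' @param intergenic_fraction Fraction of the genome outside CDS.
#' @param minus_fraction Probability a gene lies on the reverse strand.
#' @param seed Optional integer seed.
#' @return A `toy_genome` object: list with `sequence` (string), `name`, and
#'   `genes` (tibble with `gene_id`, `start`, `end`, `strand`, `length_nt`,
#'   `n_gc`, `n_at`).
#' @export
#' @examples
#' tg <- make_toy_genome(n_genes = 10, seed = 1)
#' tg$genes
make_toy_genome <- function(n_genes = 40L, mean_gene_length = 900L,
                            gc_fraction = 0.5, intergenic_fraction = 0.15,
                            minus_fraction = 0.4, seed = NULL) {
  n_genes <- assert_count(n_genes, "n_genes", lower = 1L)
  assert_scalar_number(mean_gene_length, "mean_gene_length", lower = 60)
  assert_scalar_number(gc_fraction, "gc_fraction", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(intergenic_fraction, "intergenic_fraction",
                       lower = 0, upper = 1, strict_upper = TRUE)
  with_seed_or_stream(seed, {
    n_codons <- pmax(20L, round(stats::rnorm(n_genes, mean_gene_length / 3,
                                             mean_gene_length / 12)))
    cds <- vapply(n_codons, random_cds, character(1),
                  gc_fraction = gc_fraction)
    strand <- ifelse(runif(n_genes) < minus_fraction, "-", "+")
    segment <- ifelse(strand == "-", revcomp(cds), cds)

    gene_total <- sum(nchar(segment))
    inter_total <- round(gene_total * intergenic_fraction /
                           (1 - intergenic_fraction))
    spacer_len <- as.vector(rmultinom(1L, inter_total,
                                      rep(1, n_genes + 1L)))
    spacers <- vapply(spacer_len, random_seq, character(1),
                      gc_fraction = gc_fraction)

    pieces <- character(2L * n_genes + 1L)
    pieces[seq(1L, 2L * n_genes + 1L, by = 2L)] <- spacers
    pieces[seq(2L, 2L * n_genes, by = 2L)] <- segment
    genome <- paste(pieces, collapse = "")

    starts <- cumsum(c(1L, nchar(pieces)))[seq(2L, 2L * n_genes, by = 2L)]
    ends <- starts + nchar(segment) - 1L
    comp <- t(vapply(segment, function(x) {
      b <- strsplit(x, "", fixed = TRUE)[[1L]]
      c(sum(b %in% c("G", "C")), sum(b %in% c("A", "T")))
    }, numeric(2), USE.NAMES = FALSE))
    genes <- tibble(
      gene_id = sprintf("gene%03d", seq_len(n_genes)),
      start = starts, end = ends, strand = strand,
      length_nt = nchar(segment),
      n_gc = as.integer(comp[, 1L]), n_at = as.integer(comp[, 2L])
    )
    structure(
      list(sequence = genome, name = "toy_chr", genes = genes),
      class = "toy_genome"
    )
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %d nt, %d genes\n", nchar(x$sequence),
              nrow(x$genes)))
  invisible(x)
}

# random sequence at a target GC fraction
random_seq <- function(n, gc_fraction) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                        gc_fraction / 2, (1 - gc_fraction) / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# one CDS of n_codons codons: ATG + stop-free body + stop. In-frame stop
# codons drawn in the body are replaced by a random non-stop permutation of
# the same three letters, so the base composition (and GC content) is
# unchanged by the fix-up.
random_cds <- function(n_codons, gc_fraction) {
  n_body <- n_codons - 2L
  bases <- matrix(
    sample(c("A", "C", "G", "T"), 3L * n_body, replace = TRUE,
           prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                    gc_fraction / 2, (1 - gc_fraction) / 2)),
    nrow = 3L
  )
  codons <- apply(bases, 2L, paste, collapse = "")
  stops <- which(codons %in% STOP_CODONS)
  for (i in stops) {
    letters3 <- strsplit(codons[i], "", fixed = TRUE)[[1L]]
    perms <- unique(apply(permutations3(), 1L,
                          function(p) paste(letters3[p], collapse = "")))
    ok <- setdiff(perms, STOP_CODONS)
    codons[i] <- sample(ok, 1L)
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

permutations3 <- function() {
  matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
         ncol = 3L, byrow = TRUE)
}
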