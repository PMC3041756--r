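# programmatic fixtures: no files ship with the package

write_plain_vcf <- function(path, rows,
                            chrom = "toy", contig_length = 1000L) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, contig_length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- vapply(rows, function(r) {
    sprintf("%s\t%d\t.\t%s\t%s\t99\tPASS\tDP=%d;AF=%s",
            chrom, r$pos, r$ref, r$alt, r$dp %||% 30L, r$af)
  }, character(1))
  writeLines(c(header, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-gene genome with known codon layout:
#   1-5    AATTA            intergenic
#   6-14   ATGCTGTAA        gene_fwd (+): ATG CTG TAA
#   15-19  GGGGG            intergenic
#   20-28  TTAGGCCAT        gene_rev (-): CDS = revcomp = ATG GCC TAA
#   29-33  CCAAT            intergenic
codon_fixture <- function() {
  list(
    genome = paste0("AATTA", "ATGCTGTAA", "GGGGG", "TTAGGCCAT", "CCAAT"),
    genes = tibble::tibble(
      gene_id = c("gene_fwd", "gene_rev"),
      start = c(6L, 20L),
      end = c(14L, 28L),
      strand = c("+", "-")
    )
  )
}

snp_record <- function(position, ref, alt, library_id = "lib1",
                       lane_id = "lane1", af = 0.33) {
  tibble::tibble(
    chrom = "toy", position = position, ref = ref, alt = alt,
    allele_frequency = af, depth = 30, library_id = library_id,
    lane_id = lane_id
  )
}
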