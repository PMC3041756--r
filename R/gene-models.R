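#' Build a gene model table
#'
#' A gene model records one gene's identity, coordinates, length, base
#' composition and per-strain expected mutation count (its "effective size").
#' The per-strain rate is the GC-bias-weighted expected number of mutations,
#' `n_gc * mu_gc + n_at * mu_at`; with equal rates it reduces to
#' `length_nt * mu` per strain.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param length_nt Integer vector of gene lengths in nucleotides.
#' @param n_gc,n_at Counts of G/C and A/T sites per gene. Must satisfy
#'   `n_gc + n_at == length_nt`. Default splits the length evenly.
#' @param mu_gc,mu_at Per-base mutation rates at G/C and A/T sites
#'   (mutations per base per strain).
#' @param is_target Logical vector flagging phenotype target genes.
#' @param start,end,strand Optional 1-based genomic coordinates.
#'
#' @return A tibble with one row per gene and columns `gene_id`, `length_nt`,
#'   `n_gc`, `n_at`, `lambda` (expected mutations per strain) and `is_target`.
#' @export
#' @examples
#' gene_models(c("a", "b"), length_nt = c(900, 1500), mu_gc = 1e-5, mu_at = 1e-5)
gene_models <- function(gene_id, length_nt, n_gc = NULL, n_at = NULL,
                        mu_gc, mu_at, is_target = FALSE,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_) {
  if (is.null(n_gc) && is.null(n_at)) {
    n_gc <- round(length_nt / 2)
    n_at <- length_nt - n_gc
  }
  if (any(n_gc + n_at != length_nt)) {
    abort("`n_gc + n_at` must equal `length_nt` for every gene.")
  }
  if (any(c(n_gc, n_at, length_nt) < 0)) abort("composition counts must be >= 0.")
  tibble(
    gene_id = as.character(gene_id),
    start = start, end = end, strand = strand,
    length_nt = as.integer(length_nt),
    n_gc = as.integer(n_gc), n_at = as.integer(n_at),
    lambda = effective_gene_size(n_gc, n_at, mu_gc, mu_at),
    is_target = rep_len(is_target, length(gene_id))
  )
}

#' Uniform-size gene table
#'
#' Convenience constructor for the uniform-size model: `n_genes` genes of equal
#' effective size `mu_per_gene`, the first `n_targets` flagged as targets.
#'
#' @param n_genes Total number of genes.
#' @param mu_per_gene Expected mutations per gene per strain.
#' @param n_targets Number of target genes.
#' @param length_nt Nominal gene length in nt (used only for sequencing-error
#'   bookkeeping).
#' @return A gene model tibble (see [gene_models()]).
#' @export
uniform_genes <- function(n_genes, mu_per_gene, n_targets = 0L,
                          length_nt = 1000L) {
  n_genes <- assert_count(n_genes, "n_genes", lower = 1L)
  mu <- mu_per_gene / length_nt
  gene_models(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    length_nt = rep(length_nt, n_genes),
    mu_gc = mu, mu_at = mu,
    is_target = seq_len(n_genes) <= n_targets
  )
}

#' Effective gene size under GC-biased mutability
#'
#' The expected number of mutations per strain in a region with `n_gc` G/C
#' sites and `n_at` A/T sites, given per-base mutation probabilities measured
#' genome-wide. Chemical mutagens such as NTG are strongly GC-biased
#' (observed GC/AT rate ratios around 36), so a gene's mutability depends on
#' its composition, not just its length.
#'
#' @param n_gc,n_at Site counts (vectors recycle).
#' @param mu_gc,mu_at Per-base mutation rates.
#' @return Numeric vector `n_gc * mu_gc + n_at * mu_at`.
#' @export
#' @examples
#' effective_gene_size(500, 500, mu_gc = 36e-6, mu_at = 1e-6)
effective_gene_size <- function(n_gc, n_at, mu_gc, mu_at) {
  if (any(c(n_gc, n_at, mu_gc, mu_at) < 0)) {
    abort("all arguments to effective_gene_size() must be >= 0.")
  }
  n_gc * mu_gc + n_at * mu_at
}

#' Bin genes into size classes
#'
#' Sorts genes ascending by effective size and assigns each consecutive group
#' of `floor(n()/n_bins)` genes to a bin; remainder genes join the last
#' (largest-size) bin. Each bin is summarised by the arithmetic mean effective
#' size of its members. Ten bins approximate the full gene-size
#' distribution closely while keeping the non-target sampler cheap.
#'
#' @param genes Gene model tibble with a `lambda` column.
#' @param n_bins Number of size classes (>= 1).
#' @return A tibble with columns `bin`, `mean_lambda`, `n_genes` and
#'   `mean_length` (NA if lengths are absent).
#' @export
bin_genes_by_size <- function(genes, n_bins) {
  n_bins <- assert_count(n_bins, "n_bins", lower = 1L)
  if (nrow(genes) == 0L) abort("`genes` must be non-empty.")
  if (n_bins > nrow(genes)) abort("`n_bins` exceeds the number of genes.")
  ord <- genes[order(genes$lambda), , drop = FALSE]
  per <- nrow(ord) %/% n_bins
  idx <- pmin(((seq_len(nrow(ord)) - 1L) %/% per) + 1L, n_bins)
  ord$bin <- idx
  out <- ord |>
    group_by(.data$bin) |>
    summarise(
      mean_lambda = mean(.data$lambda),
      n_genes = dplyr::n(),
      mean_length = if ("length_nt" %in% names(ord)) mean(.data$length_nt) else NA_real_,
      .groups = "drop"
    )
  out
}
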