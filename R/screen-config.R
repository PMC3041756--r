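#' Screen simulation configuration
#'
#' Bundles the parameters of a phenotype screen: the number of independent
#' mutant strains sequenced (S), the mutation density, the number of target
#' genes (T, genes where a mutation can cause the phenotype), the total gene
#' count (G) and the false discovery rate used for yield computation.
#'
#' The mutation density can be given in three equivalent ways:
#' * `mu_per_gene`: expected mutations per gene per strain;
#' * `mut_per_genome`: expected (phenotypically relevant, e.g. non-synonymous)
#'   mutations per genome per strain, converted as `mut_per_genome / n_genes`;
#' * `total_mut_per_genome`: total mutations per genome; by random chance only
#'   about 2/3 of point mutations are non-synonymous, so the relevant density
#'   is taken as `2/3 * total_mut_per_genome / n_genes`.
#'
#' @param n_strains Number of mutant strains sequenced (S).
#' @param mu_per_gene Mutations per gene per strain.
#' @param mut_per_genome Relevant mutations per genome per strain.
#' @param total_mut_per_genome Total mutations per genome per strain.
#' @param n_targets Number of target genes (T).
#' @param n_genes Total genes in the genome (G); default 4244, the E. coli
#'   K-12 annotated gene count.
#' @param fdr False discovery rate for yield computation; default 0.67 ("out
#'   of every three genes reported, at least one must be a true target").
#' @param tail_mass_cutoff Truncation threshold for Poisson supports.
#' @param replicates Default replicate count for averaged simulations.
#'
#' @return An object of class `screen_config` (a named list).
#' @export
#' @examples
#' screen_config(n_strains = 10, mut_per_genome = 50, n_targets = 5)
screen_config <- function(n_strains, mu_per_gene = NULL, mut_per_genome = NULL,
                          total_mut_per_genome = NULL, n_targets,
                          n_genes = 4244L, fdr = 0.67,
                          tail_mass_cutoff = 1e-10, replicates = 1000L) {
  n_strains <- assert_count(n_strains, "n_strains", lower = 0L)
  n_targets <- assert_count(n_targets, "n_targets", lower = 1L)
  n_genes <- assert_count(n_genes, "n_genes", lower = 2L)
  if (n_targets >= n_genes) abort("`n_targets` must be smaller than `n_genes`.")
  assert_scalar_number(fdr, "fdr", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  given <- !c(is.null(mu_per_gene), is.null(mut_per_genome),
              is.null(total_mut_per_genome))
  if (sum(given) != 1L) {
    abort("supply exactly one of `mu_per_gene`, `mut_per_genome`, `total_mut_per_genome`.")
  }
  mu <- if (!is.null(mu_per_gene)) {
    mu_per_gene
  } else if (!is.null(mut_per_genome)) {
    mut_per_genome / n_genes
  } else {
    (2 / 3) * total_mut_per_genome / n_genes
  }
  assert_scalar_number(mu, "mu_per_gene", lower = 0)
  structure(
    list(
      n_strains = n_strains, mu_per_gene = mu, n_targets = n_targets,
      n_genes = n_genes, fdr = fdr, tail_mass_cutoff = tail_mass_cutoff,
      replicates = assert_count(replicates, "replicates", lower = 1L)
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  strains (S):        %d\n", x$n_strains))
  cat(sprintf("  targets (T):        %d of %d genes\n", x$n_targets, x$n_genes))
  cat(sprintf("  mutations/gene/strain: %.5g (%.3g per genome)\n",
              x$mu_per_gene, x$mu_per_gene * x$n_genes))
  cat(sprintf("  FDR:                %.2f\n", x$fdr))
  invisible(x)
}
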