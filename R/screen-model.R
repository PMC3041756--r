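#' Screen-conditioned distribution of target-region mutation counts
#'
#' A strain that passes the phenotype screen must carry at least one mutation
#' in the target region (the union of all target genes). If mutations arrive
#' as a Poisson process with mean `lambda_target` mutations per strain in the
#' target region, the per-strain count conditioned on passing the screen is a
#' zero-truncated Poisson. The support is truncated at the smallest count
#' whose remaining tail mass falls below `tail_mass_cutoff` and renormalized.
#'
#' @param lambda_target Expected target-region mutations per strain (> 0).
#' @param tail_mass_cutoff Tail mass at which the support is truncated.
#' @return A tibble with columns `m` (mutation count, from 1) and `prob`.
#' @export
#' @examples
#' conditional_target_distribution(0.25)
conditional_target_distribution <- function(lambda_target,
                                            tail_mass_cutoff = 1e-10) {
  if (!is.numeric(lambda_target) || length(lambda_target) != 1L ||
      is.na(lambda_target) || lambda_target <= 0) {
    abort(paste0(
      "`lambda_target` must be > 0: a screen with zero causal-mutation rate ",
      "cannot be conditioned on success."
    ))
  }
  truncated_poisson(lambda_target, m_min = 1L, cutoff = tail_mass_cutoff)
}

#' Sample per-target-gene mutation counts
#'
#' Draws the total number of target-region mutations K across `n_strains`
#' screened strains as a single multinomial draw of S counts over the
#' truncated screen-conditioned support (so K = sum over m of m * count(m),
#' and K >= S since every strain contributes at least one mutation), then
#' allocates K mutations across target genes by a multinomial with
#' probabilities `target_probs` (uniform for equal-size genes, proportional to
#' effective size otherwise).
#'
#' @param config A [screen_config()].
#' @param target_probs Probability vector over target genes (sums to 1).
#' @param replicates Number of independent experiments to draw.
#' @param lambda_target Target-region mutation rate per strain; defaults to
#'   `n_targets * mu_per_gene`.
#' @param seed Optional integer seed (isolated from the session RNG).
#' @return An integer matrix with one row per target gene and one column per
#'   replicate, with the drawn totals attached as attribute `"K"`.
#' @export
sample_target_counts <- function(config, target_probs, replicates = 1L,
                                 lambda_target = NULL, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  replicates <- assert_count(replicates, "replicates", lower = 1L)
  if (abs(sum(target_probs) - 1) > 1e-8) {
    abort("`target_probs` must sum to 1.")
  }
  n_t <- length(target_probs)
  if (config$n_strains == 0L) {
    out <- matrix(0L, nrow = n_t, ncol = replicates)
    attr(out, "K") <- rep(0L, replicates)
    return(out)
  }
  lambda_target <- lambda_target %||% (config$n_targets * config$mu_per_gene)
  cond <- conditional_target_distribution(lambda_target, config$tail_mass_cutoff)
  with_seed_or_stream(seed, {
    strain_counts <- rmultinom(replicates, config$n_strains, cond$prob)
    K <- as.integer(colSums(cond$m * strain_counts))
    out <- vapply(
      seq_len(replicates),
      function(r) rmultinom(1L, K[r], target_probs)[, 1L],
      integer(n_t)
    )
    out <- matrix(as.integer(out), nrow = n_t, ncol = replicates)
    attr(out, "K") <- K
    out
  })
}

#' Sample the non-target mutation-count histogram
#'
#' Non-target genes accumulate mutations freely: over S independent strains a
#' gene of per-strain effective size lambda carries Poisson(S * lambda) total
#' mutations. Genes are grouped into size bins (see [bin_genes_by_size()]);
#' for each bin a truncated Poisson probability vector is built and the bin's
#' gene count is allocated over mutation counts by one multinomial draw.
#' Histograms are summed across bins.
#'
#' @param config A [screen_config()].
#' @param bins Tibble with columns `mean_lambda` and `n_genes` (one row per
#'   size bin); gene counts must sum to `n_genes - n_targets`.
#' @param replicates Number of independent experiments.
#' @param seed Optional integer seed.
#' @param check_total If `TRUE` (default), require bin gene counts to sum to
#'   `n_genes - n_targets`.
#' @return An integer matrix of gene counts whose rows are mutation counts
#'   m = 0, 1, 2, ... (rownames give m) and columns are replicates.
#' @export
sample_nontarget_histogram <- function(config, bins, replicates = 1L,
                                       seed = NULL, check_total = TRUE) {
  stopifnot(inherits(config, "screen_config"))
  replicates <- assert_count(replicates, "replicates", lower = 1L)
  if (is.null(bins) || nrow(bins) == 0L) abort("`bins` must be non-empty.")
  if (!all(c("mean_lambda", "n_genes") %in% names(bins))) {
    abort("`bins` needs columns `mean_lambda` and `n_genes`.")
  }
  expected_total <- config$n_genes - config$n_targets
  if (check_total && sum(bins$n_genes) != expected_total) {
    abort(sprintf("bin gene counts must sum to G - T = %d.", expected_total))
  }
  with_seed_or_stream(seed, {
    per_bin <- lapply(seq_len(nrow(bins)), function(b) {
      lam <- config$n_strains * bins$mean_lambda[b]
      tp <- truncated_poisson(lam, m_min = 0L, cutoff = config$tail_mass_cutoff)
      rmultinom(replicates, bins$n_genes[b], tp$prob) # (mmax+1) x R
    })
    m_max <- max(vapply(per_bin, nrow, integer(1))) - 1L
    hist <- matrix(0L, nrow = m_max + 1L, ncol = replicates)
    for (h in per_bin) {
      hist[seq_len(nrow(h)), ] <- hist[seq_len(nrow(h)), , drop = FALSE] + h
    }
    rownames(hist) <- 0:m_max
    hist
  })
}

#' Simulate replicated phenotype-sequencing experiments
#'
#' One experiment draws per-target-gene mutation counts conditioned on every
#' strain passing the screen ([sample_target_counts()]) and a non-target
#' mutation-count histogram ([sample_nontarget_histogram()]). When a
#' [seq_design()] is supplied, sequencing effects are injected (see
#' [apply_sequencing_effects()]): real mutations are lost with the detection
#' failure rate and false-positive calls accrue in every gene.
#'
#' @param config A [screen_config()].
#' @param genes Optional gene model tibble ([gene_models()]) covering all G
#'   genes with T rows flagged `is_target`; `NULL` selects the uniform-size
#'   model implied by `config`.
#' @param design Optional [seq_design()] describing coverage, pooling, error
#'   rate and call threshold.
#' @param replicates Number of independent experiments.
#' @param n_bins Number of size bins for the non-target genes (variable-size
#'   model only).
#' @param seed Optional integer seed; fixing it makes the sample reproducible.
#' @return A `screen_sim` object: list with `target_counts` (T x replicates
#'   integer matrix), `nontarget_histogram` (mutation-count by replicate
#'   matrix), `K` (total target-region mutations per replicate), and the
#'   generating `config`/`design`.
#' @export
#' @examples
#' cfg <- screen_config(n_strains = 10, mut_per_genome = 50, n_targets = 5)
#' sim <- simulate_screen(cfg, replicates = 100, seed = 1)
#' mean(screen_yields(sim))
simulate_screen <- function(config, genes = NULL, design = NULL,
                            replicates = 1L, n_bins = 10L, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  replicates <- assert_count(replicates, "replicates", lower = 1L)
  glen <- if (!is.null(design)) design$genome_length / config$n_genes else 1000
  par <- screen_parameters(config, genes, n_bins, gene_length = glen)
  adj <- apply_sequencing_effects(par, design, config)

  with_seed_or_stream(seed, {
    base <- sample_target_counts(
      config, adj$alloc_probs, replicates,
      lambda_target = par$lambda_target
    )
    K <- attr(base, "K")
    # drop the detection-failure category (last row) if present
    target_counts <- base[seq_len(par$n_targets), , drop = FALSE]
    if (any(adj$target_fp_mean > 0)) {
      fp <- matrix(
        rpois(par$n_targets * replicates, adj$target_fp_mean),
        nrow = par$n_targets, ncol = replicates
      )
      target_counts <- target_counts + fp
    }
    nontarget <- sample_nontarget_histogram(config, adj$bins, replicates)
    structure(
      list(
        target_counts = target_counts, nontarget_histogram = nontarget,
        K = K, config = config, design = design,
        replicates = replicates
      ),
      class = "screen_sim"
    )
  })
}

# Resolve uniform/variable gene parameterization into sampler inputs.
screen_parameters <- function(config, genes = NULL, n_bins = 10L,
                              gene_length = 1000) {
  if (is.null(genes)) {
    mu <- config$mu_per_gene
    list(
      n_targets = config$n_targets,
      lambda_target = config$n_targets * mu,
      target_probs = rep(1 / config$n_targets, config$n_targets),
      target_length = rep(gene_length, config$n_targets),
      bins = tibble(
        mean_lambda = mu,
        n_genes = config$n_genes - config$n_targets,
        mean_length = gene_length
      )
    )
  } else {
    targets <- genes[genes$is_target, , drop = FALSE]
    nontargets <- genes[!genes$is_target, , drop = FALSE]
    if (nrow(targets) != config$n_targets || nrow(genes) != config$n_genes) {
      abort("`genes` must contain exactly n_genes rows with n_targets targets.")
    }
    lam_t <- sum(targets$lambda)
    if (lam_t <= 0) abort("target genes have zero total mutability.")
    list(
      n_targets = nrow(targets),
      lambda_target = lam_t,
      target_probs = targets$lambda / lam_t,
      target_length = targets$length_nt,
      bins = bin_genes_by_size(nontargets, min(n_bins, nrow(nontargets)))
    )
  }
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(
    "<screen_sim> %d replicate(s), %d target genes, %d strains\n",
    x$replicates, nrow(x$target_counts), x$config$n_strains
  ))
  invisible(x)
}

#' Yield of every replicate in a simulated screen
#'
#' Applies the count-threshold yield rule ([yield_from_counts()]) to each
#' replicate of a `screen_sim`.
#'
#' @param sim A `screen_sim` from [simulate_screen()].
#' @param fdr False discovery rate; defaults to the config's.
#' @return Integer vector of yields, one per replicate.
#' @export
screen_yields <- function(sim, fdr = NULL) {
  stopifnot(inherits(sim, "screen_sim"))
  fdr <- fdr %||% sim$config$fdr
  vapply(
    seq_len(sim$replicates),
    function(r) {
      yield_one(
        sim$target_counts[, r], sim$nontarget_histogram[, r], fdr
      )
    },
    integer(1)
  )
}

#' @describeIn screen_yields Tidy per-replicate summary: one row per
#'   replicate with total target-region mutations `K` and `yield`.
#' @param x A `screen_sim`.
#' @param ... Unused.
#' @export
tidy.screen_sim <- function(x, ...) {
  tibble(
    replicate = seq_len(x$replicates),
    K = x$K,
    max_target_hits = apply(x$target_counts, 2, max),
    yield = screen_yields(x)
  )
}

#' @describeIn screen_yields One-row summary with mean yield and its
#'   standard error.
#' @export
glance.screen_sim <- function(x, ...) {
  y <- screen_yields(x)
  tibble(
    replicates = x$replicates,
    mean_yield = mean(y),
    se_yield = se_mean(y),
    fdr = x$config$fdr,
    n_strains = x$config$n_strains,
    n_targets = x$config$n_targets
  )
}
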