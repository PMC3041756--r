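#' Poisson upper-tail p-value for a gene's mutation count
#'
#' Under the null hypothesis that a gene is not a target, its total mutation
#' count over all sequenced strains is Poisson with mean equal to the gene's
#' expected count (S times its per-strain effective size). The p-value is the
#' upper tail P(X >= m). A gene with zero observed mutations has p = 1
#' exactly.
#'
#' @param hit_count Observed mutation count(s) m (vectorised).
#' @param expected Null mean(s).
#' @return Upper-tail probabilities in (0, 1].
#' @export
#' @examples
#' gene_pvalue(0, 0.5) # exactly 1
#' gene_pvalue(1, 0.5) # 1 - exp(-0.5)
gene_pvalue <- function(hit_count, expected) {
  if (any(hit_count < 0) || any(expected < 0)) {
    abort("`hit_count` and `expected` must be >= 0.")
  }
  if (any(hit_count != round(hit_count))) {
    abort("`hit_count` must be integer-valued.")
  }
  ppois(hit_count - 1, expected, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies a p-value by the number of tests, capping at 1.
#'
#' @param p_raw Raw p-value(s).
#' @param n_tests Number of hypotheses tested (>= 1). In a phenotype-
#'   sequencing experiment this is conventionally the number of genes observed
#'   mutated at least once (see [score_genes()]'s `bonferroni` argument).
#' @return Corrected p-value(s).
#' @export
bonferroni_correct <- function(p_raw, n_tests) {
  n_tests <- assert_count(n_tests, "n_tests", lower = 1L)
  pmin(1, p_raw * n_tests)
}

# Core count-threshold yield rule on one sample.
# tc: per-target counts; hist: non-target gene counts indexed by m = 0,1,...
yield_one <- function(tc, hist, fdr, detail = FALSE) {
  none <- if (detail) {
    list(yield = 0L, m_star = NA_integer_, n_target_reported = 0L,
         n_nontarget_reported = 0L)
  } else {
    0L
  }
  m_top <- max(length(hist) - 1L, tc, 0L)
  if (m_top < 1L) return(none)
  nt_exact <- numeric(m_top)
  upto <- min(length(hist) - 1L, m_top)
  if (upto >= 1L) nt_exact[seq_len(upto)] <- hist[1L + seq_len(upto)]
  nt_ge <- rev(cumsum(rev(nt_exact)))                  # non-targets with >= h
  tg_ge <- rev(cumsum(rev(tabulate(tc, nbins = m_top)))) # targets with >= h
  tot <- nt_ge + tg_ge
  ok <- tot == 0 | (nt_ge / pmax(tot, 1)) < fdr
  valid <- rev(cumprod(rev(ok))) == 1 # h such that ok holds for all m >= h
  if (!any(valid)) return(none)
  h_star <- which(valid)[1L]
  if (!detail) return(as.integer(tg_ge[h_star]))
  list(
    yield = as.integer(tg_ge[h_star]), m_star = h_star,
    n_target_reported = as.integer(tg_ge[h_star]),
    n_nontarget_reported = as.integer(nt_ge[h_star])
  )
}

#' Target-gene yield from mutation counts at a false discovery rate
#'
#' Finds the smallest count threshold m* such that, for every m >= m*, the
#' fraction of non-target genes among all genes with at least m mutations
#' stays (strictly) below the FDR; the yield is the number of target genes
#' with at least m* mutations. With FDR 0.67, at least one out of every three
#' reported genes is a true target. Returns 0 when no threshold qualifies.
#'
#' @param target_counts Integer vector of per-target-gene mutation counts.
#' @param nontarget_histogram The non-target count histogram: a tibble with
#'   columns `m` and `n_genes`, or a named numeric vector mapping count to
#'   number of genes.
#' @param fdr False discovery rate in (0, 1).
#' @param detail Return a one-row tibble with the chosen threshold `m_star`
#'   and the reported-set composition instead of the bare yield.
#' @return Integer yield, or a detail tibble when `detail = TRUE`.
#' @export
#' @examples
#' yield_from_counts(c(5, 3, 1), c(`1` = 50, `2` = 1), fdr = 0.67)
yield_from_counts <- function(target_counts, nontarget_histogram, fdr,
                              detail = FALSE) {
  assert_scalar_number(fdr, "fdr", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (is.data.frame(nontarget_histogram)) {
    m <- nontarget_histogram$m
    n <- nontarget_histogram$n_genes
  } else {
    m <- if (is.null(names(nontarget_histogram))) {
      seq_along(nontarget_histogram) - 1L
    } else {
      as.integer(names(nontarget_histogram))
    }
    n <- as.numeric(nontarget_histogram)
  }
  hist <- numeric(max(m, 0L) + 1L)
  hist[m + 1L] <- n
  res <- yield_one(as.integer(target_counts), hist, fdr, detail = detail)
  if (detail) tibble::as_tibble(res) else res
}

#' Target-gene yield from p-value scores at a false discovery rate
#'
#' Sorts genes by raw p-value and finds the largest cutoff p* such that the
#' fraction of non-targets among all genes with p-value at or below the
#' cutoff is strictly below the FDR; the yield is the number of targets in
#' that reported set. This is the variable-gene-size counterpart of
#' [yield_from_counts()]; with equal-size genes ranking by p-value is ranking
#' by count and the two rules agree on typical samples. The count rule
#' additionally demands the FDR bound at every threshold above its chosen
#' one, so on rare samples with a pathological non-target tail it reports one
#' gene fewer; the score rule never reports less than the count rule.
#'
#' @param scores A tibble with columns `p_raw` and logical `is_target`.
#' @param fdr False discovery rate in (0, 1).
#' @return Integer yield.
#' @export
yield_from_scores <- function(scores, fdr) {
  assert_scalar_number(fdr, "fdr", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (nrow(scores) == 0L) return(0L)
  if (!all(c("p_raw", "is_target") %in% names(scores))) {
    abort("`scores` needs columns `p_raw` and `is_target`.")
  }
  if (anyNA(scores$is_target)) abort("`is_target` labels must be present.")
  ord <- order(scores$p_raw)
  p <- scores$p_raw[ord]
  nt <- cumsum(!scores$is_target[ord])
  tg <- cumsum(scores$is_target[ord])
  # candidate cutoffs: complete p-value ties (a cutoff cannot split a tie)
  last_of_tie <- c(p[-1] > p[-length(p)], TRUE)
  admissible <- last_of_tie & (nt / (nt + tg)) < fdr
  if (!any(admissible)) return(0L)
  as.integer(tg[max(which(admissible))])
}

#' Empirical calibration of the null p-values
#'
#' Samples non-target mutation counts under the null model, computes their
#' Poisson-tail p-values, and pairs each sorted -log p with the negative log
#' of its empirical survival fraction (rank/N over the pooled sample). For
#' the uniform gene-size model the points fall on the y = x diagonal: the
#' p-value equals its realized frequency. With variable gene sizes the curve
#' sits on or above the diagonal, i.e. the p-values are slightly
#' conservative (a score is rarer in the sample than its value implies).
#'
#' @param config A [screen_config()]; the density/strain defaults mirror a
#'   heavily mutagenized screen (50 mutations per genome, 80 strains).
#' @param genes Optional gene model tibble for the variable-size model; by
#'   default every gene has the uniform size implied by `config`. May also be
#'   a bin tibble from [bin_genes_by_size()] to use a size-class
#'   approximation.
#' @param replicates Number of replicate genome samples.
#' @param thin Return at most this many points, rank-spaced logarithmically
#'   (the full pooled sample can exceed 4 million values); `Inf` keeps all.
#' @param seed Optional integer seed.
#' @return A tibble with columns `neg_log_p` and `neg_log_sf`, sorted by
#'   increasing significance.
#' @export
calibration_curve <- function(config, genes = NULL, replicates = 1000L,
                              thin = 2000L, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  replicates <- assert_count(replicates, "replicates", lower = 1L)
  if (is.null(genes)) {
    lam <- rep(config$n_strains * config$mu_per_gene, config$n_genes)
  } else if (all(c("mean_lambda", "n_genes") %in% names(genes))) {
    lam <- config$n_strains * rep(genes$mean_lambda, genes$n_genes)
  } else {
    lam <- config$n_strains * genes$lambda
  }
  with_seed_or_stream(seed, {
    lam_all <- rep(lam, replicates)
    counts <- rpois(length(lam_all), lam_all)
    p <- gene_pvalue(counts, lam_all)
    p <- sort(p) # most significant first
    n <- length(p)
    # a p-value's empirical survival fraction is the fraction of the sample
    # at or below it: evaluate at the last rank of each tie block (discrete
    # p-values tie heavily under the uniform-size model)
    keep <- which(c(p[-1] > p[-n], TRUE))
    if (is.finite(thin) && thin < length(keep)) {
      sel <- unique(round(seq(1, length(keep), length.out = thin)))
      keep <- keep[sel]
    }
    tibble(
      neg_log_p = -log(p[keep]),
      neg_log_sf = -log(keep / n)
    )
  })
}
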