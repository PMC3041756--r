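#' Sequencing design
#'
#' Parameters of a pooled sequencing design: mean per-library coverage `c`,
#' library-pooling factor `P` (strains mixed into one library, so a
#' single-strain mutation sits at allele fraction ~ 1/P), the per-specific-
#' nucleotide sequencing error rate `epsilon` (the chance of reading one
#' particular wrong base, a fraction of the total error probability), and the
#' mutation call threshold `k` (minimum alternate-read count to call a SNP).
#'
#' @param coverage Mean reads per site per library (c > 0). Non-integer
#'   coverage is rounded to the nearest integer when used as binomial trials.
#' @param pool_factor Strains per library (P >= 1).
#' @param error_rate Probability of reading one specific wrong nucleotide
#'   (0 < epsilon < 1); default 0.01, a conservative short-read estimate.
#' @param call_threshold Minimum alternate reads to call a SNP (k >= 1).
#' @param genome_length Genome size in nt; default the E. coli K-12 genome.
#' @param tag_pool Tagged libraries pooled per lane.
#' @param lane_capacity Sequence output per lane in nt (default 1.5 Gb).
#' @return An object of class `seq_design`.
#' @export
#' @examples
#' d <- seq_design(coverage = 75, pool_factor = 4, call_threshold = 10)
#' detection_failure_rate(d)
#' false_positive_rate(d)
seq_design <- function(coverage, pool_factor, error_rate = 0.01,
                       call_threshold = 1L, genome_length = 4641652,
                       tag_pool = 1L, lane_capacity = 1.5e9) {
  assert_scalar_number(coverage, "coverage", lower = 0, strict_lower = TRUE)
  pool_factor <- assert_count(pool_factor, "pool_factor", lower = 1L)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  call_threshold <- assert_count(call_threshold, "call_threshold", lower = 1L)
  structure(
    list(
      coverage = coverage, pool_factor = pool_factor, error_rate = error_rate,
      call_threshold = call_threshold, genome_length = genome_length,
      tag_pool = tag_pool, lane_capacity = lane_capacity
    ),
    class = "seq_design"
  )
}

#' @export
print.seq_design <- function(x, ...) {
  cat(sprintf(
    "<seq_design> c = %gx, P = %d, error = %g, k = %d\n",
    x$coverage, x$pool_factor, x$error_rate, x$call_threshold
  ))
  invisible(x)
}

#' Mutation detection failure rate
#'
#' A real mutation carried by one strain of a P-strain pool is read correctly
#' with probability (1 - epsilon)/P per read; the mutation is *missed* when
#' fewer than k of the c reads covering the site report it. Returns
#' P(X < k) for X ~ Binomial(round(c), (1 - epsilon)/P).
#'
#' @param design A [seq_design()].
#' @return The false-negative probability per real mutation.
#' @export
detection_failure_rate <- function(design) {
  stopifnot(inherits(design, "seq_design"))
  p_read <- (1 - design$error_rate) / design$pool_factor
  pbinom(design$call_threshold - 1L, round(design$coverage), p_read)
}

#' Mutation false positive rate
#'
#' Sequencing error alone produces a spurious SNP call at a site when at
#' least k of the c reads report the same specific wrong nucleotide. Returns
#' P(X >= k) for X ~ Binomial(round(c), epsilon).
#'
#' @param design A [seq_design()].
#' @return The per-site false-positive call probability.
#' @export
false_positive_rate <- function(design) {
  stopifnot(inherits(design, "seq_design"))
  pbinom(design$call_threshold - 1L, round(design$coverage),
         design$error_rate, lower.tail = FALSE)
}

#' Expected spurious mutation calls per genome
#'
#' @param fp_site_rate Per-site false-positive rate, or a [seq_design()] (in
#'   which case the rate and genome length are taken from it).
#' @param genome_length Genome size in nt.
#' @return Expected number of false calls over the genome.
#' @export
expected_false_calls <- function(fp_site_rate, genome_length = NULL) {
  if (inherits(fp_site_rate, "seq_design")) {
    genome_length <- genome_length %||% fp_site_rate$genome_length
    fp_site_rate <- false_positive_rate(fp_site_rate)
  }
  if (fp_site_rate < 0 || genome_length < 0) abort("inputs must be >= 0.")
  fp_site_rate * genome_length
}

#' Expected real mutations missed per genome
#'
#' @param design A [seq_design()].
#' @param n_mutations Real mutations per genome.
#' @return Expected number of false negatives over the genome.
#' @export
expected_missed_mutations <- function(design, n_mutations) {
  n_mutations * detection_failure_rate(design)
}

#' Error profile of a sequencing design
#'
#' @param design A [seq_design()].
#' @return A one-row tibble with `fail_rate` (per-mutation detection
#'   failure), `fp_site_rate` (per-site false-positive call rate) and
#'   `fp_genome_expect` (expected false calls genome-wide).
#' @export
error_profile <- function(design) {
  fp <- false_positive_rate(design)
  tibble(
    fail_rate = detection_failure_rate(design),
    fp_site_rate = fp,
    fp_genome_expect = fp * design$genome_length
  )
}

#' Inject sequencing effects into screen-model parameters
#'
#' Rescales the target-gene allocation probabilities by (1 - fail_rate) and
#' appends a detection-failure category whose drawn counts are discarded;
#' computes per-target-gene false-positive Poisson means; and adjusts each
#' non-target size bin's per-strain rate to
#' `lambda * (1 - fail_rate) + length_nt * fp_site_rate / pool_factor`.
#' False calls arise independently in each of the S/P sequenced libraries, so
#' over the whole experiment every gene (target or not) accrues spurious
#' events with mean `length_nt * fp_site_rate * S / P`.
#'
#' @param params A [screen_config()] (with optional `genes`), or the internal
#'   parameter list produced by the simulator.
#' @param design A [seq_design()] or `NULL` for error-free sequencing.
#' @param config The [screen_config()] (when `params` is the internal list).
#' @param genes Optional gene model tibble.
#' @param n_bins Size bins for the variable-size model.
#' @return A list with `alloc_probs` (target multinomial probabilities, plus
#'   a final discard category when `design` is given), `target_fp_mean`
#'   (per-target-gene false-positive Poisson mean for the whole experiment),
#'   `bins` (adjusted non-target size bins) and `profile` (see
#'   [error_profile()]).
#' @export
apply_sequencing_effects <- function(params, design = NULL, config = NULL,
                                     genes = NULL, n_bins = 10L) {
  if (inherits(params, "screen_config")) {
    config <- params
    params <- screen_parameters(config, genes, n_bins)
  }
  if (is.null(config)) abort("`config` is required.")
  if (is.null(design)) {
    return(list(
      alloc_probs = params$target_probs,
      target_fp_mean = rep(0, params$n_targets),
      bins = params$bins,
      profile = NULL
    ))
  }
  stopifnot(inherits(design, "seq_design"))
  prof <- error_profile(design)
  n_lib <- config$n_strains / design$pool_factor
  bins <- params$bins
  bins$mean_lambda <- bins$mean_lambda * (1 - prof$fail_rate) +
    bins$mean_length * prof$fp_site_rate / design$pool_factor
  list(
    alloc_probs = c(params$target_probs * (1 - prof$fail_rate), prof$fail_rate),
    target_fp_mean = params$target_length * prof$fp_site_rate * n_lib,
    bins = bins,
    profile = prof
  )
}

#' Scan mutation-call thresholds across pooling levels
#'
#' For each (pool_factor, call_threshold) pair, runs replicated screen
#' simulations with sequencing effects and reports the mean target-gene
#' discovery yield at the configured FDR. Thresholds that are too low flood
#' the genome with false-positive calls and collapse the yield; thresholds
#' approaching the coverage miss real mutations. The optimum sits in between
#' (see [optimal_thresholds()]).
#'
#' @param config A [screen_config()].
#' @param coverage Mean per-library coverage.
#' @param pool_factors Integer vector of library-pooling levels to scan.
#' @param k_values Integer vector of call thresholds to scan.
#' @param error_rate Per-specific-nucleotide sequencing error rate.
#' @param genome_length Genome size in nt.
#' @param replicates Simulated experiments per grid cell.
#' @param genes Optional gene model tibble (variable-size model).
#' @param seed Optional integer seed.
#' @return A tibble with columns `pool_factor`, `call_threshold`,
#'   `mean_yield`, `se_yield`, `fail_rate`, `fp_genome_expect`.
#' @export
scan_thresholds <- function(config, coverage, pool_factors, k_values,
                            error_rate = 0.01, genome_length = 4.6e6,
                            replicates = 200L, genes = NULL, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (length(pool_factors) == 0L || length(k_values) == 0L) {
    abort("`pool_factors` and `k_values` must be non-empty.")
  }
  grid <- tidyr::expand_grid(
    pool_factor = as.integer(pool_factors),
    call_threshold = as.integer(k_values)
  )
  with_seed_or_stream(seed, {
    res <- purrr::pmap(grid, function(pool_factor, call_threshold) {
      d <- seq_design(
        coverage = coverage, pool_factor = pool_factor,
        error_rate = error_rate, call_threshold = call_threshold,
        genome_length = genome_length
      )
      sim <- simulate_screen(config, genes = genes, design = d,
                             replicates = replicates)
      y <- screen_yields(sim)
      prof <- error_profile(d)
      tibble(
        mean_yield = mean(y), se_yield = se_mean(y),
        fail_rate = prof$fail_rate,
        fp_genome_expect = prof$fp_genome_expect
      )
    })
    out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
    class(out) <- c("threshold_scan", class(out))
    out
  })
}

#' Optimal call threshold per pooling level
#'
#' @param scan A tibble from [scan_thresholds()].
#' @return One row per `pool_factor`: the `call_threshold` maximising mean
#'   yield (smallest threshold on ties).
#' @export
optimal_thresholds <- function(scan) {
  scan |>
    group_by(.data$pool_factor) |>
    arrange(desc(.data$mean_yield), .data$call_threshold, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()
}
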