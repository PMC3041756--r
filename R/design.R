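#' Chance of picking a causal gene by hand
#'
#' The baseline that phenotype sequencing improves on: after sequencing one
#' mutant strain and finding `n_mutated` mutated genes, of which `n_causal`
#' actually cause the phenotype, a uniformly chosen candidate is causal with
#' probability `n_causal / n_mutated` (e.g. 1% for one causal gene among 100
#' mutated ones).
#'
#' @param n_mutated Number of mutated candidate genes observed.
#' @param n_causal Number of those that are true causal genes.
#' @return Probability in `[0, 1]`.
#' @export
naive_pick_probability <- function(n_mutated, n_causal = 1) {
  n_mutated <- assert_count(n_mutated, "n_mutated", lower = 1L)
  n_causal <- assert_count(n_causal, "n_causal", lower = 0L)
  if (n_causal > n_mutated) abort("`n_causal` cannot exceed `n_mutated`.")
  n_causal / n_mutated
}

#' Reagent cost model
#'
#' @param lib_cost Cost per tagged library preparation (default $50).
#' @param lane_cost Cost per sequencing lane (default $700).
#' @return A `cost_model` object.
#' @export
cost_model <- function(lib_cost = 50, lane_cost = 700) {
  assert_scalar_number(lib_cost, "lib_cost", lower = 0)
  assert_scalar_number(lane_cost, "lane_cost", lower = 0)
  structure(list(lib_cost = lib_cost, lane_cost = lane_cost),
            class = "cost_model")
}

#' Per-library coverage under tag-pooling
#'
#' Tag-pooling splits a lane's capacity among the tagged libraries it
#' carries: coverage per library = lane_capacity / (genome_length * tag_pool).
#' A 1500 Mb lane over the 4,641,652 nt E. coli genome gives about 323x for a
#' single library, 65x for five, 32x for ten.
#'
#' @param lane_capacity Lane output in nt.
#' @param genome_length Genome size in nt.
#' @param tag_pool Tagged libraries per lane.
#' @return Fold coverage (unrounded).
#' @export
#' @examples
#' coverage_per_library(1.5e9, 4641652, 5)
coverage_per_library <- function(lane_capacity, genome_length, tag_pool) {
  assert_scalar_number(lane_capacity, "lane_capacity", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(genome_length, "genome_length", lower = 0,
                       strict_lower = TRUE)
  tag_pool <- assert_count(tag_pool, "tag_pool", lower = 1L)
  lane_capacity / (genome_length * tag_pool)
}

#' Experiment cost
#'
#' Total reagent cost of a pooled design: libraries times the library-prep
#' cost plus (fractional) lanes times the lane cost, and the per-strain cost.
#'
#' @param n_strains Strains sequenced.
#' @param n_libraries Tagged libraries prepared.
#' @param lanes Sequencing lanes (fractional allowed; set
#'   `whole_lanes = TRUE` to bill whole lanes).
#' @param costs A [cost_model()].
#' @param whole_lanes Round lanes up to the next whole lane before billing.
#' @return A one-row tibble with `total_cost` and `cost_per_strain`.
#' @export
#' @examples
#' experiment_cost(32, n_libraries = 10, lanes = 1) # $1200, $37.50/strain
experiment_cost <- function(n_strains, n_libraries, lanes,
                            costs = cost_model(), whole_lanes = FALSE) {
  n_strains <- assert_count(n_strains, "n_strains", lower = 1L)
  if (whole_lanes) lanes <- ceiling(lanes)
  total <- n_libraries * costs$lib_cost + lanes * costs$lane_cost
  tibble(
    n_strains = n_strains, n_libraries = n_libraries, lanes = lanes,
    total_cost = total, cost_per_strain = total / n_strains
  )
}

#' Average target-gene discovery yield
#'
#' Mean and standard error of the yield at the configured FDR over replicated
#' screen simulations, optionally under a sequencing design's error model.
#'
#' @param config A [screen_config()].
#' @param genes Optional gene model tibble.
#' @param design Optional [seq_design()].
#' @param replicates Simulated experiments (>= 2); defaults to the config's.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `mean_yield`, `se_yield`, `replicates`.
#' @export
average_yield <- function(config, genes = NULL, design = NULL,
                          replicates = NULL, seed = NULL) {
  replicates <- replicates %||% config$replicates
  if (replicates < 2L) abort("`replicates` must be >= 2.")
  sim <- simulate_screen(config, genes = genes, design = design,
                         replicates = replicates, seed = seed)
  glance(sim)[, c("mean_yield", "se_yield", "replicates")]
}

#' Optimize library-pooling across tag-pooling levels
#'
#' For each tag-pooling level the per-library coverage follows from the lane
#' capacity; the library-pooling factor P is then pushed upward until the
#' mean discovery yield (at the per-P optimal call threshold) drops below
#' `yield_floor` times the unpooled (P = 1) yield. The maximum admissible P
#' fixes the number of libraries, lanes and total cost for sequencing all
#' strains.
#'
#' @param config A [screen_config()] describing the screen to optimise for.
#' @param tag_pools Integer vector of tagged-libraries-per-lane values.
#' @param costs A [cost_model()].
#' @param error_rate Sequencing error rate.
#' @param lane_capacity Lane output in nt.
#' @param genome_length Genome size in nt.
#' @param pool_factors Candidate library-pooling factors (scanned upward).
#' @param yield_floor Fraction of the unpooled yield that must be retained
#'   (default 0.9).
#' @param k_values Candidate call thresholds; `NULL` picks, for each pooling
#'   level, the thresholds whose genome-wide expected false calls are below
#'   10 and whose detection failure rate is below 50%.
#' @param replicates Simulated experiments per (P, k) cell.
#' @param whole_lanes Bill whole lanes instead of fractional.
#' @param seed Optional integer seed.
#' @return A tibble with one design point per tag-pooling level: coverage,
#'   chosen `pool_factor`, optimal `call_threshold`, `mean_yield`,
#'   `n_libraries`, `lanes`, `total_cost`, `cost_per_strain`.
#' @export
optimize_design <- function(config, tag_pools, costs = cost_model(),
                            error_rate = 0.01, lane_capacity = 1.5e9,
                            genome_length = 4641652, pool_factors = 1:12,
                            yield_floor = 0.9, k_values = NULL,
                            replicates = 200L, whole_lanes = FALSE,
                            seed = NULL) {
  if (length(tag_pools) == 0L) abort("`tag_pools` must be non-empty.")
  stopifnot(inherits(config, "screen_config"))
  s <- config$n_strains
  with_seed_or_stream(seed, {
    purrr::map(as.integer(tag_pools), function(tp) {
      cov <- coverage_per_library(lane_capacity, genome_length, tp)
      best_yield <- function(p) {
        ks <- k_values %||% candidate_thresholds(cov, p, error_rate,
                                                 genome_length)
        sc <- scan_thresholds(
          config, cov, p, ks, error_rate = error_rate,
          genome_length = genome_length, replicates = replicates
        )
        optimal_thresholds(sc)
      }
      base <- best_yield(1L)
      chosen <- base
      for (p in sort(pool_factors[pool_factors > 1L])) {
        cand <- best_yield(p)
        if (cand$mean_yield < yield_floor * base$mean_yield) break
        chosen <- cand
      }
      n_lib <- ceiling(s / chosen$pool_factor)
      lanes <- n_lib / tp
      cost <- experiment_cost(s, n_lib, lanes, costs, whole_lanes)
      tibble(
        tag_pool = tp, coverage = cov,
        pool_factor = chosen$pool_factor,
        call_threshold = chosen$call_threshold,
        mean_yield = chosen$mean_yield,
        unpooled_yield = base$mean_yield,
        n_libraries = n_lib, lanes = lanes,
        total_cost = cost$total_cost, cost_per_strain = cost$cost_per_strain
      )
    }) |>
      dplyr::bind_rows()
  })
}

# thresholds worth simulating: low enough to catch real mutations, high
# enough that false calls do not flood the genome
candidate_thresholds <- function(coverage, pool_factor, error_rate,
                                 genome_length) {
  n <- round(coverage)
  ks <- seq_len(n)
  fp <- pbinom(ks - 1, n, error_rate, lower.tail = FALSE) * genome_length
  fail <- pbinom(ks - 1, n, (1 - error_rate) / pool_factor)
  ok <- fp <= 10 & fail <= 0.5
  if (!any(ok)) {
    # no workable zone: fall back to the least-bad threshold
    return(ks[which.min(pmax(fp / genome_length, fail))])
  }
  ks[ok]
}
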