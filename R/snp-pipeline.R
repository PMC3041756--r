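#' Load single-nucleotide variants from per-library, per-lane VCFs
#'
#' Reads one VCF per (library, lane), splits multi-allelic records, keeps
#' biallelic single-nucleotide substitutions, and returns a tidy record
#' table. Non-SNV records (indels, symbolic alleles, identical ref/alt) are
#' skipped with a reported count.
#'
#' @param manifest A tibble (or path to a TSV) with columns `library_id`,
#'   `lane_id`, `path`.
#' @param af_field INFO field carrying the caller's allele-frequency
#'   estimate (default `"AF"`).
#' @param dp_field INFO field carrying read depth (default `"DP"`).
#' @param quiet Suppress per-file skip messages.
#' @return A tibble of SNP records: `chrom`, `position`, `ref`, `alt`,
#'   `allele_frequency`, `depth`, `library_id`, `lane_id`.
#' @export
read_snv_vcfs <- function(manifest, af_field = "AF", dp_field = "DP",
                          quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_gene_table(manifest)
  if (!all(c("library_id", "lane_id", "path") %in% names(manifest))) {
    abort("`manifest` needs columns library_id, lane_id, path.")
  }
  purrr::pmap(manifest, function(library_id, lane_id, path, ...) {
    vcf <- tryCatch(
      vcfR::read.vcfR(path, verbose = FALSE),
      error = function(e) {
        abort(sprintf("malformed VCF `%s`: %s", path, conditionMessage(e)))
      }
    )
    fix <- vcfR::getFIX(vcf)
    if (is.null(fix) || nrow(fix) == 0L) {
      return(tibble(
        chrom = character(), position = integer(), ref = character(),
        alt = character(), allele_frequency = numeric(), depth = numeric(),
        library_id = character(), lane_id = character()
      ))
    }
    af <- vcfR::extract.info(vcf, af_field)
    dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, dp_field)))
    alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                         fixed = TRUE)
    af_list <- strsplit(ifelse(is.na(af), "", af), ",", fixed = TRUE)
    reps <- lengths(alt_list)
    rec <- tibble(
      chrom = rep(fix[, "CHROM"], reps),
      position = rep(as.integer(fix[, "POS"]), reps),
      ref = toupper(rep(fix[, "REF"], reps)),
      alt = toupper(unlist(alt_list)),
      allele_frequency = suppressWarnings(as.numeric(unlist(
        purrr::map2(af_list, reps, function(a, n) rep_len(a, n))
      ))),
      depth = rep(dp, reps),
      library_id = as.character(library_id),
      lane_id = as.character(lane_id)
    )
    is_snv <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
      rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T") &
      rec$ref != rec$alt
    n_skip <- sum(!is_snv)
    if (n_skip > 0L && !quiet) {
      inform(sprintf("%s: skipped %d non-SNV record(s).", path, n_skip))
    }
    rec[is_snv, , drop = FALSE]
  }) |>
    bind_rows()
}

#' Filter SNPs for allele frequency and lane concordance
#'
#' Pooled true mutations sit at allele fraction ~ 1/P, well below 1, so
#' candidate SNPs are required to have an estimated allele frequency at or
#' below `max_af`. With replicate lanes, a call must additionally be detected
#' identically -- same (library, position, alt) -- in at least `min_lanes`
#' lanes. For single-lane data only the frequency filter applies. The filter
#' is idempotent.
#'
#' @param records SNP record tibble (see [read_snv_vcfs()]).
#' @param max_af Maximum allele frequency (default 0.5).
#' @param min_lanes Minimum number of lanes calling the variant (default 2).
#' @param n_lanes Total lanes sequenced; inferred from the records when
#'   `NULL`.
#' @return The filtered record tibble (all passing lane copies retained).
#' @export
filter_concordant <- function(records, max_af = 0.5, min_lanes = 2L,
                              n_lanes = NULL) {
  n_lanes <- n_lanes %||% dplyr::n_distinct(records$lane_id)
  if (!is.null(min_lanes) && n_lanes > 1L && min_lanes > n_lanes) {
    abort("`min_lanes` cannot exceed the number of lanes.")
  }
  out <- records |> filter(.data$allele_frequency <= max_af)
  if (n_lanes <= 1L) return(out)
  out |>
    group_by(.data$library_id, .data$position, .data$alt) |>
    filter(dplyr::n_distinct(.data$lane_id) >= min_lanes) |>
    ungroup()
}

#' Remove parental (ancestral) variants
#'
#' A variant present in the common parent of all mutant strains is seen at
#' ~100% allele frequency in every library; such sites carry no information
#' about the screen and are excluded. A site is parental when every library
#' reports it with allele frequency at or above `parental_af_floor` (0.95 by
#' default, tolerating caller noise around 100%). Idempotent.
#'
#' @param records SNP record tibble.
#' @param parental_af_floor Allele-frequency floor for the parental call.
#' @return Records with parental (position, alt) sites removed.
#' @export
remove_parental <- function(records, parental_af_floor = 0.95) {
  n_lib <- dplyr::n_distinct(records$library_id)
  parental <- records |>
    filter(.data$allele_frequency >= parental_af_floor) |>
    group_by(.data$position, .data$alt) |>
    summarise(n_lib_high = dplyr::n_distinct(.data$library_id),
              .groups = "drop") |>
    filter(.data$n_lib_high == n_lib)
  records |> anti_join(parental, by = c("position", "alt"))
}

#' Annotate coding effects of SNPs
#'
#' Maps each SNP to the CDS features containing it, translates the reference
#' and alternate codons with the standard genetic code, and classifies the
#' substitution as synonymous or non-synonymous; records outside every CDS
#' are intergenic. Reverse-strand CDS are read from the reverse complement
#' and amino-acid changes are reported in protein coordinates. CDS whose
#' length is not a multiple of 3 are skipped with a warning.
#'
#' @param records SNP record tibble.
#' @param genes Gene tibble with `gene_id`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @param genome Genome sequence (path, `DNAString(Set)` or string).
#' @param all_overlaps Count a SNP once for each overlapping CDS (default);
#'   `FALSE` keeps only the first annotated gene.
#' @return Records with added `gene_id`, `effect`
#'   (synonymous/nonsynonymous/intergenic) and `aa_change` columns; SNPs in
#'   overlapping CDS appear once per gene when `all_overlaps = TRUE`.
#' @export
annotate_effects <- function(records, genes, genome, all_overlaps = TRUE) {
  s <- as_genome_string(genome)
  bad <- (genes$end - genes$start + 1L) %% 3L != 0L
  if (any(bad)) {
    warn(sprintf(
      "skipping %d CDS with length not divisible by 3: %s",
      sum(bad), paste(utils::head(genes$gene_id[bad], 5L), collapse = ", ")
    ))
    genes <- genes[!bad, , drop = FALSE]
  }
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(records$position, records$position),
    IRanges::IRanges(genes$start, genes$end)
  )
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (!all_overlaps && length(qh)) {
    keep <- !duplicated(qh)
    qh <- qh[keep]
    sh <- sh[keep]
  }

  coding <- records[qh, , drop = FALSE]
  if (nrow(coding) == 0L) {
    out <- records
    if (nrow(out)) {
      out$gene_id <- NA_character_
      out$effect <- "intergenic"
      out$aa_change <- NA_character_
    } else {
      out$gene_id <- character()
      out$effect <- character()
      out$aa_change <- character()
    }
    return(out)
  }
  g <- genes[sh, , drop = FALSE]
  minus <- g$strand == "-"
  off <- ifelse(minus, g$end - coding$position, coding$position - g$start)
  codon_i <- off %/% 3L
  pos_in <- off %% 3L
  codon_start <- ifelse(minus, g$end - 3L * codon_i - 2L,
                        g$start + 3L * codon_i)
  codon_genomic <- substring(s, codon_start, codon_start + 2L)
  ref_codon <- ifelse(minus, revcomp(codon_genomic), codon_genomic)
  alt_in_codon <- ifelse(minus, complement_base(coding$alt), coding$alt)
  alt_codon <- paste0(
    substr(ref_codon, 1L, pos_in), alt_in_codon,
    substring(ref_codon, pos_in + 2L)
  )
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  coding$gene_id <- g$gene_id
  coding$effect <- ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous")
  coding$aa_change <- paste0(aa_ref, codon_i + 1L, aa_alt)

  inter <- records[setdiff(seq_len(nrow(records)), unique(qh)), , drop = FALSE]
  if (nrow(inter)) {
    inter$gene_id <- NA_character_
    inter$effect <- "intergenic"
    inter$aa_change <- NA_character_
  }
  bind_rows(coding, inter) |> arrange(.data$position, .data$library_id)
}

#' Genome-wide per-base mutation rates at GC and AT sites
#'
#' Chemical mutagenesis is often strongly base-biased; the observed per-base
#' mutation probability at G/C versus A/T sites, measured genome-wide, feeds
#' the effective gene sizes used for scoring.
#'
#' @param records SNP record tibble (distinct mutation events are counted as
#'   unique (library, position, alt) tuples when a `library_id` column is
#'   present).
#' @param genome Genome sequence.
#' @return One-row tibble with `mu_gc`, `mu_at` (per base) and their ratio
#'   `gc_at_ratio`.
#' @export
gc_mutation_rates <- function(records, genome) {
  comp <- genome_composition(genome)
  if (comp$n_gc == 0L || comp$n_at == 0L) {
    abort("genome has zero GC or AT sites; rates are undefined.")
  }
  ev <- if ("library_id" %in% names(records)) {
    distinct(records, .data$library_id, .data$position, .data$alt,
             .keep_all = TRUE)
  } else {
    distinct(records, .data$position, .data$alt, .keep_all = TRUE)
  }
  n_gc_snp <- sum(ev$ref %in% c("G", "C"))
  n_at_snp <- sum(ev$ref %in% c("A", "T"))
  mu_gc <- n_gc_snp / comp$n_gc
  mu_at <- n_at_snp / comp$n_at
  tibble(mu_gc = mu_gc, mu_at = mu_at,
         gc_at_ratio = ifelse(mu_at > 0, mu_gc / mu_at, Inf))
}

#' Score and rank genes by mutation burden
#'
#' Counts distinct mutation events per gene (optionally non-synonymous only),
#' computes each gene's null expectation from its GC-weighted effective size
#' normalized to the realized genome-wide mutagenesis intensity (expected
#' count = total observed SNPs x gene effective size / genome effective
#' size), scores genes with the Poisson upper tail and applies the Bonferroni
#' correction. The ranked table mirrors the top-hits layout of a phenotype
#' sequencing report.
#'
#' @param records Annotated SNP records (run through [annotate_effects()];
#'   un-annotated records are annotated on the fly).
#' @param genes Gene tibble (`gene_id`, `start`, `end`, `strand`).
#' @param genome Genome sequence.
#' @param nonsyn_only Count only non-synonymous SNPs (restricting to
#'   phenotypically relevant mutations typically sharpens the ranking).
#' @param bonferroni `"mutated"` multiplies by the number of genes observed
#'   mutated at least once (the reporting convention here); `"all"` uses the
#'   full gene count.
#' @param validated_targets Optional character vector of known target genes;
#'   fills the `is_target` column.
#' @param rates Optional precomputed [gc_mutation_rates()] row.
#' @return A `gene_scores` tibble: `rank`, `gene_id`, `hits`, `expected`,
#'   `p_raw`, `p_corrected` (and `is_target` when labels are given), sorted
#'   by `p_raw`, then hits (descending), then `gene_id`.
#' @export
score_genes <- function(records, genes, genome, nonsyn_only = FALSE,
                        bonferroni = c("mutated", "all"),
                        validated_targets = NULL, rates = NULL) {
  bonferroni <- match.arg(bonferroni)
  if (nrow(records) == 0L) {
    return(tibble(
      rank = integer(), gene_id = character(), hits = integer(),
      expected = numeric(), p_raw = numeric(), p_corrected = numeric()
    ))
  }
  if (!"effect" %in% names(records)) {
    records <- annotate_effects(records, genes, genome)
  }
  rates <- rates %||% gc_mutation_rates(records, genome)
  genes <- ensure_composition(genes, genome)
  gene_eff <- effective_gene_size(genes$n_gc, genes$n_at,
                                  rates$mu_gc, rates$mu_at)
  comp <- genome_composition(genome)
  genome_eff <- effective_gene_size(comp$n_gc, comp$n_at,
                                    rates$mu_gc, rates$mu_at)

  ev <- distinct(records, .data$library_id, .data$position, .data$alt,
                 .data$gene_id, .keep_all = TRUE)
  if (nonsyn_only) ev <- filter(ev, .data$effect == "nonsynonymous")
  total <- nrow(distinct(ev, .data$library_id, .data$position, .data$alt))
  hit_tab <- ev |>
    filter(!is.na(.data$gene_id)) |>
    count(.data$gene_id, name = "hits")

  out <- tibble(gene_id = genes$gene_id,
                expected = total * gene_eff / genome_eff) |>
    left_join(hit_tab, by = "gene_id") |>
    mutate(hits = dplyr::coalesce(.data$hits, 0L))
  n_tests <- switch(bonferroni,
    mutated = max(1L, sum(out$hits >= 1L)),
    all = nrow(out)
  )
  out <- out |>
    mutate(
      p_raw = gene_pvalue(.data$hits, .data$expected),
      p_corrected = bonferroni_correct(.data$p_raw, n_tests)
    ) |>
    arrange(.data$p_raw, desc(.data$hits), .data$gene_id) |>
    mutate(rank = row_number()) |>
    select("rank", "gene_id", "hits", "expected", "p_raw", "p_corrected")
  if (!is.null(validated_targets)) {
    out$is_target <- out$gene_id %in% validated_targets
  }
  class(out) <- c("gene_scores", class(out))
  out
}

#' Write a ranked gene table
#'
#' @param scores A `gene_scores` tibble from [score_genes()].
#' @param path Output TSV path.
#' @export
write_ranked_genes <- function(scores, path) {
  readr::write_tsv(
    scores[, c("rank", "gene_id", "hits", "expected", "p_raw", "p_corrected")],
    path
  )
  invisible(path)
}

#' Build a pooling layout
#'
#' @param pool_sizes Integer vector: strains per library, e.g.
#'   `c(rep(3, 8), rep(4, 2))` for the 8x3 + 2x4 split of 32 strains.
#' @param library_ids Optional library names.
#' @param strain_ids Optional strain names.
#' @return A tibble with one row per strain: `library_id`, `strain_id`.
#' @export
pool_layout <- function(pool_sizes, library_ids = NULL, strain_ids = NULL) {
  n <- sum(pool_sizes)
  library_ids <- library_ids %||% sprintf("lib%02d", seq_along(pool_sizes))
  strain_ids <- strain_ids %||% sprintf("strain%03d", seq_len(n))
  if (length(strain_ids) != n) abort("strain count must match pool sizes.")
  tibble(
    library_id = rep(library_ids, pool_sizes),
    strain_id = strain_ids
  )
}

#' Enumerate library subsets of a pooling layout
#'
#' Every non-empty subset of the tagged libraries is itself a valid (smaller)
#' phenotype-sequencing experiment; L libraries give 2^L - 1 of them.
#'
#' @param layout A [pool_layout()] tibble, or a tibble with `library_id` and
#'   `n_strains` per library.
#' @return A tibble with `subset_id`, `libraries` (list column) and
#'   `n_strains`.
#' @export
enumerate_subsets <- function(layout) {
  sizes <- layout_sizes(layout)
  l <- nrow(sizes)
  if (l > 20L) abort("more than 20 libraries: enumeration infeasible, sample instead.")
  ids <- seq_len(2^l - 1L)
  member <- vapply(ids, function(i) bitwAnd(i, bitwShiftL(1L, 0:(l - 1L))) > 0L,
                   logical(l))
  member <- matrix(member, nrow = l)
  tibble(
    subset_id = ids,
    libraries = purrr::map(ids, function(i) sizes$library_id[member[, i]]),
    n_strains = as.integer(colSums(member * sizes$n_strains))
  )
}

layout_sizes <- function(layout) {
  if ("n_strains" %in% names(layout)) {
    layout[, c("library_id", "n_strains")]
  } else {
    layout |> count(.data$library_id, name = "n_strains")
  }
}

#' Yield analysis over all library subsets
#'
#' Re-scores every non-empty subset of the tagged libraries as its own
#' experiment: per-gene hit counts are summed over the member libraries, the
#' null is rescaled to the subset's total SNP count, genes are ranked by
#' p-value, and the number of validated target genes appearing in the top
#' `top_k` is recorded. Subsets with the same total strain count are
#' averaged; each group is costed at the layout's per-strain cost.
#'
#' @param records Annotated SNP records.
#' @param genes Gene tibble.
#' @param genome Genome sequence.
#' @param layout A [pool_layout()] (or per-library strain counts).
#' @param validated_targets Character vector of known true target genes.
#' @param costs A [cost_model()].
#' @param top_k Report-list length (default 20).
#' @param nonsyn_only Count only non-synonymous SNPs.
#' @param n_lanes Lanes used by the full experiment (for costing).
#' @param max_enumerate Beyond this many libraries, subsets are Monte-Carlo
#'   sampled instead of enumerated.
#' @param n_subsets Number of sampled subsets in the Monte-Carlo regime.
#' @param seed Optional integer seed (sampling regime only).
#' @return A tibble with one row per subset size: `n_strains`,
#'   `n_experiments`, `mean_found`, `se_found`, `cost`.
#' @export
subset_yield_analysis <- function(records, genes, genome, layout,
                                  validated_targets, costs = cost_model(),
                                  top_k = 20L, nonsyn_only = FALSE,
                                  n_lanes = 1, max_enumerate = 20L,
                                  n_subsets = 1000L, seed = NULL) {
  if (length(validated_targets) == 0L) {
    abort("`validated_targets` must be non-empty.")
  }
  if (!"effect" %in% names(records)) {
    records <- annotate_effects(records, genes, genome)
  }
  sizes <- layout_sizes(layout)
  l <- nrow(sizes)
  subsets <- if (l <= max_enumerate) {
    enumerate_subsets(sizes)
  } else {
    sample_subsets(sizes, n_subsets, seed)
  }

  rates <- gc_mutation_rates(records, genome)
  genes <- ensure_composition(genes, genome)
  gene_eff <- effective_gene_size(genes$n_gc, genes$n_at,
                                  rates$mu_gc, rates$mu_at)
  comp <- genome_composition(genome)
  genome_eff <- effective_gene_size(comp$n_gc, comp$n_at,
                                    rates$mu_gc, rates$mu_at)
  gene_frac <- gene_eff / genome_eff

  ev <- distinct(records, .data$library_id, .data$position, .data$alt,
                 .data$gene_id, .keep_all = TRUE)
  if (nonsyn_only) ev <- filter(ev, .data$effect == "nonsynonymous")
  # per-library gene-hit matrix and per-library event totals
  hit_mat <- matrix(
    0L, nrow = nrow(genes), ncol = l,
    dimnames = list(genes$gene_id, sizes$library_id)
  )
  genic <- filter(ev, !is.na(.data$gene_id))
  tab <- genic |> count(.data$gene_id, .data$library_id)
  hit_mat[cbind(
    match(tab$gene_id, genes$gene_id), match(tab$library_id, sizes$library_id)
  )] <- tab$n
  totals <- ev |>
    distinct(.data$library_id, .data$position, .data$alt) |>
    count(.data$library_id)
  tot <- setNames(rep(0L, l), sizes$library_id)
  tot[totals$library_id] <- totals$n

  is_val <- genes$gene_id %in% validated_targets
  found <- vapply(subsets$libraries, function(libs) {
    hits <- rowSums(hit_mat[, libs, drop = FALSE])
    expected <- sum(tot[libs]) * gene_frac
    p <- gene_pvalue(hits, expected)
    mutated <- which(hits >= 1L)
    ord <- mutated[order(p[mutated], -hits[mutated], genes$gene_id[mutated])]
    top <- utils::head(ord, top_k)
    sum(is_val[top])
  }, numeric(1))

  per_strain <- (l * costs$lib_cost + n_lanes * costs$lane_cost) /
    sum(sizes$n_strains)
  tibble(n_strains = subsets$n_strains, found = found) |>
    group_by(.data$n_strains) |>
    summarise(
      n_experiments = dplyr::n(),
      mean_found = mean(.data$found),
      se_found = if (dplyr::n() > 1L) se_mean(.data$found) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(cost = .data$n_strains * per_strain)
}

sample_subsets <- function(sizes, n_subsets, seed = NULL) {
  l <- nrow(sizes)
  with_seed_or_stream(seed, {
    picks <- purrr::map(seq_len(n_subsets), function(i) {
      repeat {
        sel <- runif(l) < 0.5
        if (any(sel)) return(sizes$library_id[sel])
      }
    })
    tibble(
      subset_id = seq_len(n_subsets),
      libraries = picks,
      n_strains = vapply(picks, function(x) {
        sum(sizes$n_strains[match(x, sizes$library_id)])
      }, numeric(1))
    )
  })
}
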