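test_that("toy genomes are well-formed annotated CDS collections", {
  tg <- make_toy_genome(n_genes = 40, mean_gene_length = 900, seed = 81)
  expect_equal(nrow(tg$genes), 40)
  lens <- tg$genes$end - tg$genes$start + 1
  expect_true(all(lens %% 3 == 0))
  expect_equal(lens, tg$genes$length_nt)
  expect_equal(tg$genes$n_gc + tg$genes$n_at, tg$genes$length_nt)
  # non-overlapping, ordered features
  expect_true(all(tg$genes$start[-1] > tg$genes$end[-40]))

  # every CDS starts with ATG, ends with a stop, and is stop-free inside
  for (i in seq_len(40)) {
    seg <- substr(tg$sequence, tg$genes$start[i], tg$genes$end[i])
    cds <- if (tg$genes$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
    } else {
      seg
    }
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_equal(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }

  # determinism and GC control
  tg2 <- make_toy_genome(n_genes = 40, mean_gene_length = 900, seed = 81)
  expect_identical(tg$sequence, tg2$sequence)
  expect_identical(tg$genes, tg2$genes)
  comp <- genome_composition(tg$sequence)
  n <- comp$n_gc + comp$n_at
  expect_lt(abs(comp$n_gc / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("genome files round-trip through FASTA and GFF3", {
  dir <- withr::local_tempdir()
  tg <- make_toy_genome(n_genes = 8, mean_gene_length = 300, seed = 82)
  paths <- write_genome_files(tg$sequence, tg$genes, dir, name = tg$name)
  expect_true(file.exists(paths["fasta"]))
  expect_identical(genome_composition(paths[["fasta"]]),
                   genome_composition(tg$sequence))
  tab <- read_gene_table(paths[["gene_table"]])
  expect_equal(tab$gene_id, tg$genes$gene_id)
  skip_if_not_installed("rtracklayer")
  gff <- read_gff3_genes(paths[["gff3"]])
  expect_equal(nrow(gff), 8)
  expect_equal(gff$start, tg$genes$start)
  expect_equal(gff$end, tg$genes$end)
  expect_equal(gff$strand, tg$genes$strand)
})

test_that("strain simulation honors the screen condition and conditional mean", {
  tg <- make_toy_genome(n_genes = 30, mean_gene_length = 600, seed = 83)
  targets <- tg$genes$gene_id[c(4, 16, 25)]
  theta <- 2.5
  n_strains <- 400
  man <- simulate_strains(tg, targets, theta = theta, n_strains = n_strains,
                          seed = 84)
  per_strain <- man$mutations |>
    dplyr::group_by(strain_id) |>
    dplyr::summarise(total = dplyr::n(), causal = sum(causal))
  expect_equal(nrow(per_strain), n_strains)
  expect_true(all(per_strain$causal >= 1)) # the screen condition

  # conditioning inflates the mean total by the zero-truncation factor of
  # the target region only: E[total] = theta - lam_t + lam_t/(1-exp(-lam_t))
  tg_len <- sum(tg$genes$length_nt[tg$genes$gene_id %in% targets])
  lam_t <- theta * tg_len / nchar(tg$sequence)
  expected_total <- theta - lam_t + lam_t / (1 - exp(-lam_t))
  se <- sd(per_strain$total) / sqrt(n_strains)
  expect_lt(abs(mean(per_strain$total) - expected_total), 3 * se)

  # unbiased mutagenesis spreads over GC sites at the genome's GC fraction
  frac_gc <- mean(man$mutations$ref %in% c("G", "C"))
  comp <- genome_composition(tg$sequence)
  p <- comp$n_gc / (comp$n_gc + comp$n_at)
  expect_lt(abs(frac_gc - p),
            3 * sqrt(p * (1 - p) / nrow(man$mutations)))

  expect_error(
    simulate_strains(tg, targets, theta = 1e-4, n_strains = 2,
                     max_retries = 5, seed = 85),
    "rejection cap"
  )
})

test_that("pooled VCFs reflect pooling in allele frequency and are cross-valid", {
  tg <- make_toy_genome(n_genes = 25, mean_gene_length = 600, seed = 86)
  targets <- tg$genes$gene_id[c(5, 12)]
  man <- simulate_strains(tg, targets, theta = 4, n_strains = 16, seed = 87)
  lay <- pool_layout(rep(4, 4), strain_ids = sprintf("strain%03d", 1:16))

  # error-free sequencing: every emitted site is a manifest site, at ~1/P
  vc0 <- write_pooled_vcfs(man, lay, coverage = 80, error_rate = 1e-12,
                           n_lanes = 2, call_threshold = 5, seed = 88)
  rec0 <- read_snv_vcfs(vc0$files, quiet = TRUE)
  expect_true(all(rec0$position %in% man$mutations$position))
  singletons <- man$mutations |>
    dplyr::count(position) |>
    dplyr::filter(n == 1) |>
    dplyr::pull(position)
  af1 <- rec0$allele_frequency[rec0$position %in% singletons]
  expect_lt(abs(mean(af1) - 0.25), 3 * sd(af1) / sqrt(length(af1)))

  # with errors, spurious calls appear at the modeled genome-wide rate
  k <- 3
  cov <- 60
  eps <- 0.01
  d <- seq_design(cov, 4, eps, k, genome_length = nchar(tg$sequence))
  vc1 <- write_pooled_vcfs(man, lay, coverage = cov, error_rate = eps,
                           n_lanes = 1, call_threshold = k, seed = 89)
  rec1 <- read_snv_vcfs(vc1$files, quiet = TRUE)
  fp_obs <- sum(!rec1$position %in% man$mutations$position)
  lam_fp <- expected_false_calls(d) * length(unique(lay$library_id))
  expect_lt(abs(fp_obs - lam_fp), 3 * sqrt(lam_fp)) # Poisson-scale noise

  # determinism under a fixed seed
  vc2 <- write_pooled_vcfs(man, lay, coverage = cov, error_rate = eps,
                           n_lanes = 1, call_threshold = k,
                           seed = 89)
  rec2 <- read_snv_vcfs(vc2$files, quiet = TRUE)
  expect_identical(
    rec1[order(rec1$position, rec1$library_id),
         setdiff(names(rec1), "chrom")] |> as.data.frame(),
    rec2[order(rec2$position, rec2$library_id),
         setdiff(names(rec2), "chrom")] |> as.data.frame()
  )

  # parental marker sites appear at AF 1 in every library
  vc3 <- write_pooled_vcfs(man, lay, coverage = cov, error_rate = 1e-12,
                           n_lanes = 1, call_threshold = 5,
                           parental_sites = 3, seed = 90)
  rec3 <- read_snv_vcfs(vc3$files, quiet = TRUE)
  par_pos <- vc3$parental$position
  expect_equal(length(par_pos), 3)
  for (p in par_pos) {
    hit <- rec3[rec3$position == p, ]
    expect_equal(sort(unique(hit$library_id)), sort(unique(lay$library_id)))
    expect_true(all(hit$allele_frequency == 1))
  }
  # and the parental filter removes exactly those positions
  kept <- remove_parental(rec3)
  expect_equal(sort(setdiff(unique(rec3$position), unique(kept$position))),
               sort(par_pos))
})

test_that("the pipeline recovers nearly all planted mutations at the optimal threshold", {
  tg <- make_toy_genome(n_genes = 30, mean_gene_length = 700, seed = 91)
  targets <- tg$genes$gene_id[c(3, 14, 22)]
  man <- simulate_strains(tg, targets, theta = 5, n_strains = 16, seed = 92)
  lay <- pool_layout(rep(4, 4), strain_ids = sprintf("strain%03d", 1:16))
  vc <- write_pooled_vcfs(man, lay, coverage = 75, error_rate = 0.01,
                          n_lanes = 3, dir = withr::local_tempdir(),
                          seed = 93)
  rec <- read_snv_vcfs(vc$files, quiet = TRUE) |>
    filter_concordant(max_af = 0.5, min_lanes = 2)
  recovered <- mean(man$mutations$position %in% rec$position)
  expect_gte(recovered, 0.95)
})
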