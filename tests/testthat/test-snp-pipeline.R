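test_that("VCF loading keeps SNVs, splits multi-allelics, skips the rest", {
  dir <- withr::local_tempdir()
  # 11 simple SNVs + 1 multi-allelic (2 SNV alleles) + 2 indels
  rows <- c(
    lapply(1:11, function(i) {
      list(pos = 10L * i, ref = "A", alt = "G", af = "0.3")
    }),
    list(
      list(pos = 150L, ref = "C", alt = "G,T", af = "0.2,0.1"),
      list(pos = 160L, ref = "AT", alt = "A", af = "0.3"),
      list(pos = 170L, ref = "A", alt = "AT", af = "0.3")
    )
  )
  path <- write_plain_vcf(file.path(dir, "lib1_lane1.vcf"), rows)
  manifest <- tibble::tibble(library_id = "lib1", lane_id = "lane1",
                             path = path)
  expect_message(rec <- read_snv_vcfs(manifest), "skipped 2 non-SNV")
  expect_equal(nrow(rec), 13) # 11 + the two alleles of the multi-allelic
  expect_equal(sum(rec$position == 150), 2)
  expect_equal(rec$allele_frequency[rec$position == 150], c(0.2, 0.1))

  empty <- write_plain_vcf(file.path(dir, "empty.vcf"), list())
  rec0 <- read_snv_vcfs(tibble::tibble(library_id = "l", lane_id = "x",
                                       path = empty), quiet = TRUE)
  expect_equal(nrow(rec0), 0)

  bad <- file.path(dir, "bad.vcf")
  writeLines("not a vcf at all", bad)
  expect_error(
    read_snv_vcfs(tibble::tibble(library_id = "l", lane_id = "x",
                                 path = bad)),
    "malformed VCF.*bad.vcf"
  )
})

test_that("allele-frequency and lane-concordance filters behave and are idempotent", {
  rec <- dplyr::bind_rows(
    # called identically in 2/3 lanes at pooled frequency: keep
    snp_record(100, "A", "G", lane_id = "lane1"),
    snp_record(100, "A", "G", lane_id = "lane2"),
    # one lane only: drop
    snp_record(200, "C", "T", lane_id = "lane1"),
    # high allele frequency in all lanes: drop
    snp_record(300, "G", "A", lane_id = "lane1", af = 0.6),
    snp_record(300, "G", "A", lane_id = "lane2", af = 0.6),
    snp_record(300, "G", "A", lane_id = "lane3", af = 0.6)
  )
  out <- filter_concordant(rec, max_af = 0.5, min_lanes = 2, n_lanes = 3)
  expect_equal(sort(unique(out$position)), 100)
  expect_equal(nrow(out), 2)
  # idempotent
  expect_identical(filter_concordant(out, max_af = 0.5, min_lanes = 2,
                                     n_lanes = 3), out)

  # single-lane analyses: only the frequency filter applies
  single <- dplyr::bind_rows(
    snp_record(10, "A", "G"),
    snp_record(20, "C", "T", af = 0.8)
  )
  out1 <- filter_concordant(single, n_lanes = 1)
  expect_equal(out1$position, 10)

  expect_error(filter_concordant(rec, min_lanes = 4, n_lanes = 3),
               "min_lanes")
})

test_that("parental variants at ~100% frequency in every library are excluded", {
  rec <- dplyr::bind_rows(
    snp_record(400, "A", "G", library_id = "lib1", af = 1.0),
    snp_record(400, "A", "G", library_id = "lib2", af = 1.0),
    snp_record(400, "A", "G", library_id = "lib3", af = 0.99),
    snp_record(500, "C", "T", library_id = "lib1", af = 1.0), # one library
    snp_record(600, "G", "A", library_id = "lib2", af = 0.3)
  )
  out <- remove_parental(rec)
  expect_equal(sort(unique(out$position)), c(500, 600))
  expect_identical(remove_parental(out), out)

  # three planted parental sites vanish as exactly three positions
  planted <- dplyr::bind_rows(lapply(c(710, 720, 730), function(p) {
    dplyr::bind_rows(lapply(c("lib1", "lib2", "lib3"), function(l) {
      snp_record(p, "A", "G", library_id = l, af = 1.0)
    }))
  }))
  rec2 <- dplyr::bind_rows(rec, planted)
  out2 <- remove_parental(rec2)
  expect_equal(
    setdiff(unique(rec2$position), unique(out2$position)),
    c(400, 710, 720, 730)
  )
})

test_that("coding effects translate codons on both strands", {
  fx <- codon_fixture()
  rec <- dplyr::bind_rows(
    snp_record(8, "G", "A"),   # fwd ATG -> ATA, M1I
    snp_record(11, "G", "A"),  # fwd CTG -> CTA, L2L synonymous
    snp_record(2, "A", "G"),   # intergenic
    snp_record(23, "G", "T"),  # rev GCC -> GCA, A2A synonymous
    snp_record(24, "G", "A")   # rev GCC -> GTC, A2V
  )
  ann <- annotate_effects(rec, fx$genes, fx$genome)
  by_pos <- function(p) ann[ann$position == p, ]
  expect_equal(by_pos(8)$effect, "nonsynonymous")
  expect_equal(by_pos(8)$aa_change, "M1I")
  expect_equal(by_pos(11)$effect, "synonymous")
  expect_equal(by_pos(11)$aa_change, "L2L")
  expect_equal(by_pos(2)$effect, "intergenic")
  expect_true(is.na(by_pos(2)$gene_id))
  expect_equal(by_pos(23)$effect, "synonymous")
  expect_equal(by_pos(23)$aa_change, "A2A")
  expect_equal(by_pos(24)$effect, "nonsynonymous")
  expect_equal(by_pos(24)$aa_change, "A2V")

  # out-of-frame CDS are skipped with a warning; their records go intergenic
  genes_bad <- dplyr::bind_rows(
    fx$genes,
    tibble::tibble(gene_id = "broken", start = 29L, end = 33L, strand = "+")
  )
  expect_warning(
    ann2 <- annotate_effects(snp_record(30, "C", "T"), genes_bad, fx$genome),
    "broken"
  )
  expect_equal(ann2$effect, "intergenic")
})

test_that("planted mutations from the generator are annotated consistently", {
  tg <- make_toy_genome(n_genes = 15, mean_gene_length = 450, seed = 71)
  targets <- tg$genes$gene_id[c(3, 9)]
  man <- simulate_strains(tg, targets, theta = 3, n_strains = 8, seed = 72)
  rec <- man$mutations |>
    dplyr::transmute(
      chrom = "toy", position = position, ref = ref,
      alt = alt, allele_frequency = 0.3, depth = 30,
      library_id = strain_id, lane_id = "lane1"
    )
  ann <- annotate_effects(rec, tg$genes, tg$sequence)
  joined <- dplyr::left_join(
    man$mutations, dplyr::select(ann, "position", "library_id",
                                 ann_gene = "gene_id", "effect"),
    by = c(position = "position", strain_id = "library_id")
  )
  # the generator's gene assignment and the annotator agree everywhere
  expect_equal(is.na(joined$ann_gene), is.na(joined$gene_id))
  ok <- !is.na(joined$gene_id)
  expect_equal(joined$ann_gene[ok], joined$gene_id[ok])
  expect_true(all(joined$effect[!ok] == "intergenic"))
})

test_that("GC/AT mutation rates recover composition bias", {
  genome <- paste0(strrep("G", 500), strrep("C", 500),
                   strrep("A", 1500), strrep("T", 1500))
  rec <- dplyr::bind_rows(
    snp_record(1:90, "G", "A"),
    snp_record(1001:1010, "A", "G")
  )
  r <- gc_mutation_rates(rec, genome)
  expect_equal(r$mu_gc, 0.09)
  expect_equal(r$mu_at, 10 / 3000)
  expect_equal(r$gc_at_ratio, 27)
  expect_error(gc_mutation_rates(rec, strrep("A", 100)), "GC or AT")

  # parameter recovery: planted bias lands within 3 binomial SE
  tg <- make_toy_genome(n_genes = 20, mean_gene_length = 600,
                        gc_fraction = 0.5, seed = 73)
  bias <- 6
  man <- simulate_strains(tg, tg$genes$gene_id[1], theta = 10,
                          n_strains = 40, gc_bias = bias, seed = 74)
  comp <- genome_composition(tg$sequence)
  p_exp <- bias * comp$n_gc / (bias * comp$n_gc + comp$n_at)
  frac_gc <- mean(man$mutations$ref %in% c("G", "C"))
  n <- nrow(man$mutations)
  expect_lt(abs(frac_gc - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("gene scoring ranks a heavily hit gene first and handles empties", {
  tg <- make_toy_genome(n_genes = 12, mean_gene_length = 600, seed = 75)
  g5 <- tg$genes[5, ]
  # five independent strains hit gene 5; three other genes get one hit each
  plant <- function(pos, lib) {
    ref <- substr(tg$sequence, pos, pos)
    snp_record(pos, ref, if (ref == "A") "G" else "A", library_id = lib)
  }
  rec <- dplyr::bind_rows(
    lapply(1:5, function(i) plant(g5$start + 3L + 3L * i, paste0("lib", i))),
    lapply(c(2, 8, 11), function(g) plant(tg$genes$start[g] + 9L, "lib1"))
  )
  scores <- score_genes(rec, tg$genes, tg$sequence)
  expect_equal(scores$gene_id[1], g5$gene_id)
  expect_equal(scores$hits[1], 5)
  expect_equal(scores$rank, seq_len(nrow(scores)))
  # Bonferroni multiplier: mutated genes by default, all genes on request
  mutated <- sum(scores$hits >= 1)
  expect_equal(scores$p_corrected,
               pmin(1, scores$p_raw * mutated))
  all_mode <- score_genes(rec, tg$genes, tg$sequence, bonferroni = "all")
  expect_equal(all_mode$p_corrected, pmin(1, all_mode$p_raw * 12))

  empty <- score_genes(rec[0, ], tg$genes, tg$sequence)
  expect_equal(nrow(empty), 0)
})

test_that("library subsets enumerate exactly and bound the subset yield", {
  layout <- pool_layout(c(rep(3, 8), rep(4, 2)))
  subsets <- enumerate_subsets(layout)
  expect_equal(nrow(subsets), 1023) # 2^10 - 1
  expect_equal(sum(subsets$n_strains == 3), 8)
  expect_equal(range(subsets$n_strains), c(3, 32))

  tg <- make_toy_genome(n_genes = 12, mean_gene_length = 600, seed = 76)
  targets <- tg$genes$gene_id[c(2, 5, 9)]
  man <- simulate_strains(tg, targets, theta = 1.5, n_strains = 9, seed = 77)
  lay <- pool_layout(c(3, 3, 3), strain_ids = sprintf("strain%03d", 1:9))
  vc <- write_pooled_vcfs(man, lay, coverage = 60, error_rate = 0.01,
                          n_lanes = 1, seed = 78)
  rec <- read_snv_vcfs(vc$files, quiet = TRUE)
  rec <- filter_concordant(rec, n_lanes = 1)
  ann <- annotate_effects(rec, tg$genes, tg$sequence)
  sy <- subset_yield_analysis(ann, tg$genes, tg$sequence, lay, targets,
                              top_k = 4)
  expect_equal(nrow(sy), 3) # strain totals 3, 6, 9
  expect_equal(sum(sy$n_experiments), 7) # 2^3 - 1 subsets
  expect_true(all(sy$mean_found <= length(targets)))
  expect_equal(sy$cost, sy$n_strains * (3 * 50 + 700) / 9)
  expect_error(
    subset_yield_analysis(ann, tg$genes, tg$sequence, lay, character()),
    "non-empty"
  )
})
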