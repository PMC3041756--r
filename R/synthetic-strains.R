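#' Simulate mutant strains conditioned on passing the screen
#'
#' Forward-simulates mutagenesis over a toy genome: each strain draws Poisson
#' numbers of mutations at G/C and A/T sites (rates scaled so the expected
#' total per strain is `theta`, with a `gc_bias`-fold higher per-base rate at
#' G/C sites), and a strain is redrawn (rejection sampling) until it carries
#' at least one mutation inside a target gene -- the screen condition. Alt
#' bases are drawn uniformly from the three alternatives, optionally with a
#' transition bias.
#'
#' @param toy A [make_toy_genome()] object.
#' @param target_genes Character vector of target gene ids (subset of the
#'   toy genome's genes).
#' @param theta Expected total mutations per strain (before conditioning).
#' @param n_strains Number of strains passing the screen.
#' @param gc_bias Ratio of per-base mutation rates at G/C versus A/T sites
#'   (1 = unbiased; NTG-like mutagenesis is around 36).
#' @param transition_weight Relative weight of the transition alternative
#'   (1 = uniform over the three alternatives).
#' @param max_retries Per-strain rejection cap; exceeded means the target
#'   mutation rate is too low (increase `theta` or the target set).
#' @param seed Optional integer seed.
#' @return A `strain_manifest`: list with `mutations` (tibble: `strain_id`,
#'   `position`, `ref`, `alt`, `gene_id`, `causal`), `targets`, `params` and
#'   the generating `toy` genome.
#' @export
simulate_strains <- function(toy, target_genes, theta, n_strains,
                             gc_bias = 1, transition_weight = 1,
                             max_retries = 1000L, seed = NULL) {
  stopifnot(inherits(toy, "toy_genome"))
  if (!all(target_genes %in% toy$genes$gene_id)) {
    abort("`target_genes` must be a subset of the genome's genes.")
  }
  assert_scalar_number(theta, "theta", lower = 0, strict_lower = TRUE)
  n_strains <- assert_count(n_strains, "n_strains", lower = 1L)
  bases <- strsplit(toy$sequence, "", fixed = TRUE)[[1L]]
  is_gc <- bases %in% c("G", "C")
  n_gc <- sum(is_gc)
  n_at <- length(bases) - n_gc
  r_at <- theta / (n_at + gc_bias * n_gc)
  r_gc <- gc_bias * r_at
  gc_sites <- which(is_gc)
  at_sites <- which(!is_gc)

  targets <- toy$genes[toy$genes$gene_id %in% target_genes, , drop = FALSE]
  in_target <- function(pos) {
    idx <- findInterval(pos, targets$start)
    idx > 0L & pos <= targets$end[pmax(idx, 1L)]
  }

  with_seed_or_stream(seed, {
    strains <- purrr::map(seq_len(n_strains), function(s) {
      for (try in seq_len(max_retries)) {
        k_gc <- rpois(1L, n_gc * r_gc)
        k_at <- rpois(1L, n_at * r_at)
        pos <- c(
          if (k_gc > 0L) sample(gc_sites, min(k_gc, n_gc)) else integer(),
          if (k_at > 0L) sample(at_sites, min(k_at, n_at)) else integer()
        )
        if (any(in_target(pos))) {
          return(tibble(
            strain_id = sprintf("strain%03d", s),
            position = sort(pos)
          ))
        }
      }
      abort(paste0(
        "screen rejection cap exceeded: the target-region mutation rate is ",
        "too low; increase `theta` or the number of target genes."
      ))
    })
    mut <- bind_rows(strains)
    mut$ref <- bases[mut$position]
    mut$alt <- draw_alt_base(mut$ref, transition_weight)
    gidx <- findInterval(mut$position, toy$genes$start)
    hit <- gidx > 0L & mut$position <= toy$genes$end[pmax(gidx, 1L)]
    mut$gene_id <- ifelse(hit, toy$genes$gene_id[pmax(gidx, 1L)],
                          NA_character_)
    mut$causal <- !is.na(mut$gene_id) & mut$gene_id %in% target_genes
    structure(
      list(
        mutations = mut, targets = target_genes,
        params = list(theta = theta, gc_bias = gc_bias,
                      n_strains = n_strains,
                      transition_weight = transition_weight),
        toy = toy
      ),
      class = "strain_manifest"
    )
  })
}

#' @export
print.strain_manifest <- function(x, ...) {
  cat(sprintf(
    "<strain_manifest> %d strains, %d mutations (%d causal), targets: %s\n",
    x$params$n_strains, nrow(x$mutations), sum(x$mutations$causal),
    paste(x$targets, collapse = ", ")
  ))
  invisible(x)
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

draw_alt_base <- function(ref, transition_weight = 1) {
  vapply(ref, function(r) {
    alts <- setdiff(c("A", "C", "G", "T"), r)
    w <- ifelse(alts == TRANSITIONS[[r]], transition_weight, 1)
    sample(alts, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

#' Write pooled per-library, per-lane VCFs with sequencing error
#'
#' Emulates pooled sequencing of the manifest's strains: every site carries
#' `coverage` reads; a mutation carried by one of the P pooled strains is
#' read with probability (1 - error)/P per read, and a site is emitted when
#' the alternate-read count reaches the call threshold. Spurious calls are
#' planted genome-wide at the binomial false-positive rate of the design,
#' with conditional (>= k) read counts. Optional parental sites are written
#' at 100% allele frequency in every library and lane.
#'
#' @param manifest A [simulate_strains()] result.
#' @param layout A [pool_layout()] tibble assigning every strain to exactly
#'   one library.
#' @param coverage Mean reads per site per library.
#' @param error_rate Per-specific-nucleotide sequencing error rate.
#' @param n_lanes Replicate lanes (each lane re-draws read counts).
#' @param call_threshold Minimum alternate reads to emit a site; `NULL`
#'   picks the smallest threshold whose expected genome-wide false calls
#'   fall below one.
#' @param dir Output directory.
#' @param parental_sites Optional number of parental marker sites to plant
#'   (emitted at AF 1.0 in all libraries).
#' @param seed Optional integer seed.
#' @return A list with `files` (tibble: `library_id`, `lane_id`, `path`,
#'   `n_records`), `expected` (per-library expected true/false calls given
#'   the design), `call_threshold`, and `parental` (planted parental sites).
#' @export
write_pooled_vcfs <- function(manifest, layout, coverage, error_rate = 0.01,
                              n_lanes = 1L, call_threshold = NULL,
                              dir = tempfile("vcfs"), parental_sites = 0L,
                              seed = NULL) {
  stopifnot(inherits(manifest, "strain_manifest"))
  strains <- unique(manifest$mutations$strain_id)
  if (!all(strains %in% layout$strain_id)) {
    abort("every strain must appear in `layout`.")
  }
  if (anyDuplicated(layout$strain_id)) {
    abort("a strain cannot be pooled into two libraries.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_len <- nchar(manifest$toy$sequence)
  cint <- as.integer(round(coverage))
  if (is.null(call_threshold)) {
    fp_k <- function(k) {
      genome_len * pbinom(k - 1, cint, error_rate, lower.tail = FALSE)
    }
    call_threshold <- 1L
    while (fp_k(call_threshold) >= 1 && call_threshold < cint) {
      call_threshold <- call_threshold + 1L
    }
  }
  bases <- strsplit(manifest$toy$sequence, "", fixed = TRUE)[[1L]]
  libs <- unique(layout$library_id)

  with_seed_or_stream(seed, {
    parental <- if (parental_sites > 0L) {
      pos <- sample(setdiff(seq_len(genome_len),
                            manifest$mutations$position), parental_sites)
      tibble(position = sort(pos), ref = bases[sort(pos)],
             alt = draw_alt_base(bases[sort(pos)]))
    } else {
      tibble(position = integer(), ref = character(), alt = character())
    }

    rows <- list()
    expected <- list()
    for (lib in libs) {
      members <- layout$strain_id[layout$library_id == lib]
      p_factor <- length(members)
      true_sites <- manifest$mutations |>
        filter(.data$strain_id %in% members) |>
        group_by(.data$position, .data$ref, .data$alt) |>
        summarise(carriers = dplyr::n(), .groups = "drop")
      fp_rate <- pbinom(call_threshold - 1L, cint, error_rate,
                        lower.tail = FALSE)
      fail <- pbinom(call_threshold - 1L, cint,
                     (1 - error_rate) / p_factor)
      expected[[lib]] <- tibble(
        library_id = lib, pool_factor = p_factor,
        n_true_sites = nrow(true_sites),
        expected_true_calls = nrow(true_sites) * (1 - fail),
        expected_false_calls = genome_len * fp_rate
      )
      for (lane in seq_len(n_lanes)) {
        reads <- rbinom(nrow(true_sites), cint,
                        pmin(1, true_sites$carriers * (1 - error_rate) /
                               p_factor))
        keep <- reads >= call_threshold
        true_emit <- tibble(
          position = true_sites$position[keep],
          ref = true_sites$ref[keep],
          alt = true_sites$alt[keep],
          af = reads[keep] / cint
        )
        n_fp <- rbinom(1L, genome_len, fp_rate)
        fp_emit <- if (n_fp > 0L) {
          cand <- sample(setdiff(seq_len(genome_len), true_sites$position),
                         n_fp)
          fp_reads <- sample_conditional_binomial(n_fp, cint, error_rate,
                                                  call_threshold)
          tibble(
            position = cand, ref = bases[cand],
            alt = draw_alt_base(bases[cand]), af = fp_reads / cint
          )
        } else {
          tibble(position = integer(), ref = character(),
                 alt = character(), af = numeric())
        }
        par_emit <- if (nrow(parental)) {
          tibble(position = parental$position, ref = parental$ref,
                 alt = parental$alt, af = 1)
        } else {
          parental[, c("position", "ref", "alt")] |> mutate(af = numeric())
        }
        calls <- bind_rows(true_emit, fp_emit, par_emit) |>
          arrange(.data$position)
        lane_id <- sprintf("lane%d", lane)
        path <- file.path(dir, sprintf("%s_%s.vcf.gz", lib, lane_id))
        write_calls_vcf(calls, path, manifest$toy$name, genome_len, cint, lib)
        rows[[paste(lib, lane_id)]] <- tibble(
          library_id = lib, lane_id = lane_id, path = path,
          n_records = nrow(calls)
        )
      }
    }
    list(
      files = bind_rows(rows), expected = bind_rows(expected),
      call_threshold = call_threshold, parental = parental
    )
  })
}

# draw from Binomial(n, p) conditioned on X >= k
sample_conditional_binomial <- function(size, n, p, k) {
  support <- k:n
  pr <- dbinom(support, n, p)
  if (sum(pr) <= 0) return(rep(k, size))
  support[sample.int(length(support), size, replace = TRUE, prob = pr)]
}

write_calls_vcf <- function(calls, path, chrom, genome_len, depth, sample_id) {
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, genome_len),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  n <- nrow(calls)
  fix <- matrix(
    c(rep(chrom, n), as.character(calls$position), rep(NA_character_, n),
      calls$ref, calls$alt, rep("99", n), rep("PASS", n),
      sprintf("DP=%d;AF=%s", depth, formatC(calls$af, format = "g"))),
    nrow = n,
    dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO"))
  )
  gt <- matrix(rep(c("GT", "1"), each = n), nrow = n,
               dimnames = list(NULL, c("FORMAT", sample_id)))
  v <- methods::new(
    methods::getClass("vcfR", where = asNamespace("vcfR")),
    meta = meta, fix = fix, gt = gt
  )
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
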