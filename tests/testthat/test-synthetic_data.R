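test_that("configuration invariants are enforced", {
  expect_error(simulation_config(canonical_divergence = 0.2), "canonical_divergence")
  expect_error(simulation_config(degraded_divergence_range = c(0.01, 0.3)),
               "degraded_divergence_range")
  expect_error(simulation_config(fragment_length_range = c(20, 100)), "50 bp")
  expect_error(simulation_config(error_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(deletion_haplotype = c(500, 400, 0.1)),
               "deletion_haplotype")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- strain_config(seed = 11)
  a <- simulate_landscape(cfg); b <- simulate_landscape(cfg)
  expect_identical(a, b)
  ra <- simulate_dna_reads(a, cfg); rb <- simulate_dna_reads(b, cfg)
  expect_identical(ra, rb)
  sa <- simulate_small_rna(a$consensus_library, NULL, cfg)
  sb <- simulate_small_rna(b$consensus_library, NULL, cfg)
  expect_identical(sa, sb)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_landscape(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("landscape truth is complete and coordinates are valid", {
  cfg <- strain_config(seed = 3)
  ls1 <- simulate_landscape(cfg)
  tc <- ls1$truth$copies
  expect_equal(nrow(tc), cfg$n_canonical_copies + cfg$n_degraded_fragments)
  expect_equal(sum(tc$class == "canonical"), cfg$n_canonical_copies)
  expect_equal(sum(tc$class == "degraded"), cfg$n_degraded_fragments)
  for (i in seq_len(nrow(tc))) {
    expect_gte(tc$start[i], 0)
    expect_lte(tc$end[i], nchar(ls1$genome[[tc$contig[i]]]))
  }
  # emitted copy sequences really sit at the recorded coordinates
  canon <- tc[tc$class == "canonical", ][1, ]
  seq_at <- substr(ls1$genome[[canon$contig]], canon$start + 1, canon$end)
  if (canon$strand == "-") seq_at <- revcomp(seq_at)
  expect_equal(count_mismatches(seq_at, ls1$consensus_library[[1]]) /
                 cfg$consensus_length,
               canon$divergence, tolerance = 1e-9)
})

test_that("zero-divergence copies equal the consensus and empty landscapes stay empty", {
  cfg <- simulation_config(consensus_length = 800, n_canonical_copies = 3,
                           canonical_divergence = 0, n_degraded_fragments = 0,
                           gene_lengths = tiny_genes, seed = 5)
  ls1 <- simulate_landscape(cfg)
  expect_true(all(ls1$truth$copies$divergence == 0))
  for (i in seq_len(3)) {
    tc <- ls1$truth$copies[i, ]
    s <- substr(ls1$genome[[tc$contig]], tc$start + 1, tc$end)
    if (tc$strand == "-") s <- revcomp(s)
    expect_identical(s, unname(ls1$consensus_library[[1]]))
  }

  empty_cfg <- simulation_config(consensus_length = 800, n_canonical_copies = 0,
                                 n_degraded_fragments = 0,
                                 gene_lengths = tiny_genes, seed = 6)
  ls0 <- simulate_landscape(empty_cfg)
  ann <- annotate_fragments(ls0, ls0$consensus_library)
  expect_true(nrow(ann) == 0 || all(ann$divergence > 0.4))
})

test_that("realized degraded divergence, re-measured by alignment, matches the configured range", {
  hits <- 0; total <- 0
  for (seed in 1:5) {
    cfg <- strain_config(seed = seed, canonical_copies = 0, degraded = 5)
    ls1 <- simulate_landscape(cfg)
    tc <- ls1$truth$copies
    frags <- vapply(seq_len(nrow(tc)), function(i) {
      s <- substr(ls1$genome[[tc$contig[i]]], tc$start[i] + 1, tc$end[i])
      if (tc$strand[i] == "-") revcomp(s) else s
    }, character(1))
    aln <- align_to(frags, ls1$consensus_library, mode = "genomic",
                    max_divergence = 0.45, seed_k = 8)
    expect_true(all(aln$mapped))
    total <- total + nrow(aln)
    hits <- hits + sum(aln$divergence >= 0.10 - 0.03 &
                         aln$divergence <= 0.30 + 0.03)
  }
  expect_gte(hits / total, 0.99)
})

test_that("read simulation respects count arithmetic, origins and the error model", {
  genome <- c(chr = random_seq(20000, seed = 1))
  cfg <- simulation_config(consensus_length = 500, gene_lengths = tiny_genes,
                           n_degraded_fragments = 0,
                           read_length = 100, coverage_depth = 30,
                           error_rate = 0, seed = 2)
  rd <- simulate_dna_reads(genome, cfg)
  expect_equal(nrow(rd$reads), round(30 * 20000 / 100))
  expect_equal(nrow(rd$reads), nrow(rd$truth))
  # error-free reads are exact substrings of the genome (or reverse complement)
  for (i in sample(nrow(rd$reads), 50)) {
    t <- rd$truth[i, ]
    origin <- substr(genome[[t$contig]], t$start + 1, t$start + 100)
    if (t$strand == "-") origin <- revcomp(origin)
    expect_identical(rd$reads$seq[i], origin)
  }
  # read longer than the shortest contig is rejected
  cfg_long <- simulation_config(read_length = 30000, gene_lengths = tiny_genes,
                                n_degraded_fragments = 0,
                                consensus_length = 500, seed = 2)
  expect_error(simulate_dna_reads(genome, cfg_long), "shortest contig")

  # 1% errors: mean mismatches per 100 bp read within binomial expectation
  cfg_err <- simulation_config(consensus_length = 500, gene_lengths = tiny_genes,
                               n_degraded_fragments = 0,
                               read_length = 100, coverage_depth = 60,
                               error_rate = 0.01, seed = 3)
  rde <- simulate_dna_reads(genome, cfg_err)
  expect_gte(nrow(rde$reads), 10000)
  mm <- vapply(seq_len(nrow(rde$reads)), function(i) {
    t <- rde$truth[i, ]
    origin <- substr(genome[[t$contig]], t$start + 1, t$start + 100)
    if (t$strand == "-") origin <- revcomp(origin)
    count_mismatches(rde$reads$seq[i], origin)
  }, numeric(1))
  expect_gte(mean(mm), 0.8)
  expect_lte(mean(mm), 1.2)
})

test_that("small-RNA libraries honor lengths, sources and the ping-pong construction", {
  cfg <- simulation_config(consensus_length = 1000, gene_lengths = tiny_genes,
                           pirna_count = 400, mirna_count = 300,
                           pirna_pingpong_fraction = 1,
                           pirna_antisense_fraction = 0.5,
                           pirna_degraded_fraction = 0, seed = 8)
  ls1 <- simulate_landscape(cfg)
  sr <- simulate_small_rna(ls1$consensus_library, NULL, cfg)
  len <- nchar(sr$reads$seq)
  expect_equal(nrow(sr$reads), nrow(sr$truth))
  expect_equal(sum(sr$truth$class == "miRNA"), 300)
  pir <- sr$truth$class != "miRNA"
  expect_true(all(len[pir] >= 23 & len[pir] <= 29))
  expect_true(all(len[!pir] == cfg$mirna_length))
  # rho = 1: every antisense read pairs with a sense read at exactly 10 nt
  anti <- sr$truth[sr$truth$class == "piRNA_antisense", ]
  sense5 <- sr$truth$five_prime[sr$truth$class == "piRNA_sense"]
  expect_gt(nrow(anti), 0)
  expect_true(all((anti$five_prime - 9L) %in% sense5))
  # sources shorter than 29 nt are rejected
  expect_error(simulate_small_rna(c(short = "ACGTACGT"), NULL, cfg), "29 nt")
})
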