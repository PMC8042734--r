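test_that("coverage counts aligned bases with the unique/ambiguous split", {
  set.seed(51)
  cons <- c(te = random_seq(300))
  a <- align_to(substr(cons[["te"]], 1, 100), cons, mode = "genomic")
  cov <- compute_coverage(a, cons[["te"]])
  expect_equal(cov$total_depth, c(rep(1L, 100), rep(0L, 200)))
  expect_equal(cov$unique_depth, cov$total_depth)

  # every read ambiguous -> unique depth zero everywhere
  dup <- c(cons, te_copy = cons[["te"]])
  a2 <- align_to(substr(cons[["te"]], 51, 150), dup, mode = "genomic")
  expect_equal(a2$ambiguity, 2)
  cov2 <- compute_coverage(a2[a2$target_id == "te", ], cons[["te"]])
  expect_true(all(cov2$unique_depth == 0))
  expect_equal(sum(cov2$ambiguous_depth), 100)
})

test_that("coverage conservation holds exactly", {
  res <- run_strain(strain_config(seed = 52, coverage = 10))
  fam <- res$alignments[res$alignments$mapped &
                          res$alignments$target_id == "tirant", ]
  cov <- compute_coverage(fam, res$landscape$consensus_library[["tirant"]])
  aligned_bases <- sum(vapply(teinvasion:::parse_ops(fam$ops), function(o)
    sum(o$len[o$op %in% c("=", "X")]), numeric(1)))
  expect_equal(sum(cov$total_depth), aligned_bases)
})

test_that("allele frequencies follow raw counts: A=14, T=6 gives 0.7", {
  set.seed(53)
  cons <- c(te = random_seq(80))
  substr(cons[["te"]], 40, 40) <- "G"
  reads <- c(rep(substr(cons[["te"]], 11, 70), 20))
  # plant A in 14 reads and T in 6 at consensus position 39 (0-based)
  substr(reads[1:14], 30, 30) <- "A"
  substr(reads[15:20], 30, 30) <- "T"
  a <- align_to(reads, cons, mode = "genomic")
  v <- call_variants(a, cons[["te"]])
  site <- v[v$position == 39, ]
  expect_equal(site$A / site$total, 0.7)
  expect_equal(site$T / site$total, 0.3)
  expect_true(site$snp)
  # frequencies at covered sites sum to one
  f <- (v$A + v$C + v$G + v$T + v$del) / v$total
  expect_true(all(abs(f[v$total > 0] - 1) < 1e-9))
  # sites with only the consensus base observed are not flagged
  expect_false(any(v$snp[v$position != 39]))
})

test_that("a substitution carried by 7 of 10 copies is called near frequency 0.7", {
  set.seed(54)
  cons <- random_seq(600)
  copies <- rep(cons, 10)
  substr(copies[1:7], 301, 301) <- if (substr(cons, 301, 301) == "A") "C" else "A"
  gene_seqs <- setNames(vapply(tiny_genes, random_seq, character(1)),
                        names(tiny_genes))
  genome <- c(setNames(vapply(seq_len(10), function(i)
    paste0(random_seq(150), copies[i], random_seq(150)), character(1)),
    sprintf("chr%02d", 1:10)),
    genes = paste0(random_seq(100), paste(gene_seqs, collapse = ""),
                   random_seq(100)))
  cfg <- simulation_config(consensus_length = 600, gene_lengths = tiny_genes,
                           n_degraded_fragments = 0,
                           coverage_depth = 30, error_rate = 0.002, seed = 55)
  rd <- simulate_dna_reads(genome, cfg)
  refs <- c(te = cons, gene_seqs)
  aln <- align_reads(rd$reads, refs, mode = "genomic")
  v <- call_variants(aln, cons, family = "te")
  site <- v[v$position == 300, ]
  alt <- if (substr(cons, 301, 301) == "A") "C" else "A"
  expect_gte(site[[alt]] / site$total, 0.6)
  expect_lte(site[[alt]] / site$total, 0.8)
})

test_that("small deletions go to the variant table, large ones to arcs", {
  set.seed(56)
  cons <- c(te = random_seq(500))
  base <- substr(cons[["te"]], 101, 300)
  with_small_del <- paste0(substr(cons[["te"]], 101, 200),
                           substr(cons[["te"]], 211, 310))
  a <- align_to(c(rep(base, 6), rep(with_small_del, 2)), cons, mode = "genomic")
  expect_true(all(a$mapped))
  arcs <- detect_deletions(a, cons[["te"]], min_len = 20)
  expect_equal(nrow(arcs), 0)
  v <- call_variants(a, cons[["te"]])
  # the 10 bp gap registers as per-site small-deletion counts from both reads
  # (exact gap placement may shift where flanking bases repeat)
  expect_equal(sum(v$del), 20)
  expect_equal(max(v$del), 2)
  # gap-free data yields no arcs at all
  arcs0 <- detect_deletions(align_to(base, cons, mode = "genomic"), cons[["te"]])
  expect_equal(nrow(arcs0), 0)
})

test_that("a planted deletion haplotype at 5% is recovered at ~5% frequency", {
  cfg <- simulation_config(consensus_length = 1000, n_canonical_copies = 20,
                           canonical_divergence = 0.01,
                           n_degraded_fragments = 0,
                           deletion_haplotype = c(300, 600, 0.05),
                           gene_lengths = tiny_genes, coverage_depth = 50,
                           error_rate = 0.002, seed = 7)
  res <- run_strain(cfg)
  arcs <- res$profile$deletions
  main <- arcs[arcs$start == 300 & arcs$end == 600, ]
  expect_equal(nrow(main), 1)
  expect_gte(main$frequency, 0.02)
  expect_lte(main$frequency, 0.09)
})

test_that("copy number normalizes TE depth by single-copy gene depth", {
  mk_cov <- function(depth, L = 100)
    data.frame(position = seq_len(L) - 1L, unique_depth = depth,
               ambiguous_depth = 0L, total_depth = depth)
  genes <- list(tj = mk_cov(30), rpl32 = mk_cov(30), rhino = mk_cov(30))
  expect_equal(estimate_copy_number(mk_cov(30), genes), 1.0)
  expect_equal(estimate_copy_number(mk_cov(0), genes), 0.0)
  expect_warning(
    cn <- estimate_copy_number(mk_cov(30), c(genes[1:2], list(dead = mk_cov(0)))),
    "zero-coverage")
  expect_equal(cn, 1.0)
  expect_error(estimate_copy_number(mk_cov(30), list(g = mk_cov(0))),
               "cannot normalize")
})

test_that("copy-number estimates recover the planted truth", {
  for (seed in 1:3) {
    cfg <- strain_config(seed = 60 + seed, canonical_copies = 5, degraded = 0,
                         coverage = 30)
    res <- run_strain(cfg)
    expect_gte(res$profile$copy_number, 4)
    expect_lte(res$profile$copy_number, 6)
  }
})

test_that("rpm is scale-invariant and tracks copy number across families", {
  expect_equal(compute_rpm(10, 1e6), 10)
  expect_equal(compute_rpm(20, 2e6), compute_rpm(10, 1e6))
  expect_error(compute_rpm(5, 0), "positive")
  cns <- c(1, 3, 6, 10, 15)
  stats <- t(vapply(seq_along(cns), function(i) {
    cfg <- strain_config(seed = 70 + i, canonical_copies = cns[i], degraded = 0,
                         consensus_length = 600, coverage = 15)
    p <- run_strain(cfg)$profile
    c(p$rpm, p$copy_number)
  }, numeric(2)))
  expect_gt(suppressWarnings(cor(stats[, 1], stats[, 2], method = "spearman")),
            0.9)
})

test_that("halving coverage leaves the copy-number expectation unchanged", {
  diffs <- vapply(1:20, function(i) {
    hi <- strain_config(seed = 200 + i, canonical_copies = 3, degraded = 0,
                        consensus_length = 500, coverage = 24)
    lo <- strain_config(seed = 200 + i, canonical_copies = 3, degraded = 0,
                        consensus_length = 500, coverage = 12)
    run_strain(hi)$profile$copy_number - run_strain(lo)$profile$copy_number
  }, numeric(1))
  expect_gt(stats::t.test(diffs)$p.value, 0.01)
})
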