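test_that("the two-stage size filter applies inclusive boundaries", {
  reads <- data.frame(id = paste0("r", 1:6),
                      seq = vapply(c(17, 18, 22, 23, 29, 30), random_seq,
                                   character(1)),
                      stringsAsFactors = FALSE)
  f <- filter_small_rna(reads)
  expect_equal(nchar(f$broad$seq), c(18, 22, 23, 29, 30))
  expect_equal(nchar(f$pirna_sized$seq), c(23, 29))
  expect_equal(f$n_discarded_broad, 1)
  expect_equal(f$n_discarded_pirna, 3)

  # uniform lengths 18..36 retain 7/19 as piRNA-sized
  set.seed(61)
  lens <- sample(18:36, 1900, replace = TRUE)
  u <- data.frame(id = paste0("u", seq_along(lens)),
                  seq = vapply(lens, random_seq, character(1)))
  fu <- filter_small_rna(u)
  expect_equal(nrow(fu$pirna_sized) / nrow(fu$broad), 7 / 19, tolerance = 0.1)
})

test_that("partitioning assigns reads to categories with a mismatch cap of two", {
  set.seed(62)
  canon <- c(te = random_seq(500))
  mirna <- c(mir1 = random_seq(22))
  db <- small_rna_database(canon, NULL, mirna)
  exact <- substr(canon[["te"]], 101, 125)
  noisy <- exact
  substr(noisy, 3, 3) <- "A"; substr(noisy, 10, 10) <- "A"; substr(noisy, 18, 18) <- "A"
  reads <- data.frame(id = c("hit", "mir", "bad"),
                      seq = c(exact, mirna[["mir1"]], noisy),
                      stringsAsFactors = FALSE)
  pc <- partition_counts(reads, db)
  cnt <- pc$counts
  expect_equal(cnt$sense[cnt$category == "canonical"], 1)
  expect_equal(pc$mirna_count, 1)
  # a read needing 3 mismatches against every target stays unassigned
  bad_row <- pc$alignments[pc$alignments$read_id == "bad", ]
  expect_false(isTRUE(bad_row$mapped))
  expect_gte(pc$n_unassigned, 1)
})

test_that("partitioning recovers true read categories and conserves reads", {
  cfg <- simulation_config(consensus_length = 1000, gene_lengths = tiny_genes,
                           n_canonical_copies = 2, n_degraded_fragments = 4,
                           fragment_length_range = c(150, 500),
                           pirna_count = 600, mirna_count = 400,
                           pirna_degraded_fraction = 0.4, seed = 63)
  ls1 <- simulate_landscape(cfg)
  ann <- annotate_fragments(ls1, ls1$consensus_library)
  deg <- extract_degraded_reference(ann, ls1)
  sr <- simulate_small_rna(ls1$consensus_library, deg, cfg)
  fl <- filter_small_rna(sr$reads)
  db <- small_rna_database(ls1$consensus_library, deg, sr$mirna_ref)
  pc <- partition_counts(fl$broad, db)
  # conservation: assigned weight + unassigned equals the input reads
  assigned <- sum(pc$counts$sense + pc$counts$antisense) - pc$mirna_count +
    pc$mirna_count
  expect_equal(assigned + pc$n_unassigned, nrow(fl$broad), tolerance = 1e-9)
  # truth recovery on unambiguous reads
  truth <- sr$truth
  aln <- pc$alignments
  cls <- ifelse(truth$class == "miRNA", "mirna",
                ifelse(grepl("^contig", truth$origin), "degraded", "canonical"))
  names(cls) <- truth$id
  una <- aln[!is.na(aln$categories) & !grepl(",", aln$categories) &
               aln$mapped, ]
  expect_gte(mean(una$categories == cls[una$read_id]), 0.95)
})

test_that("normalization follows the ppm/ppk definitions", {
  n <- normalize_pirna(50, 1000)
  expect_equal(n$ppk, 50)
  expect_equal(n$ppm, 50000)
  expect_equal(normalize_pirna(0, 1000)$ppm, 0)
  d <- normalize_pirna(100, 2000)
  expect_equal(d$ppm, normalize_pirna(50, 1000)$ppm)
  expect_equal(d$ppk, d$ppm / 1000)
  expect_error(normalize_pirna(5, 0), "positive")
})

test_that("position profiles place 5' ends by strand convention and conserve counts", {
  set.seed(64)
  cons <- c(te = random_seq(400))
  plus <- substr(cons[["te"]], 101, 126)      # starts at 0-based 100
  minus <- revcomp(substr(cons[["te"]], 101, 126))  # covers [100, 126)
  a <- align_to(c(plus, minus), cons, mode = "smallrna")
  expect_equal(a$strand, c("+", "-"))
  prof <- position_profile(a, cons[["te"]], target = "te")
  expect_equal(prof$sense[prof$position == 100], 1)
  expect_equal(prof$antisense[prof$position == 125], 1)
  expect_equal(sum(prof$sense) + sum(prof$antisense), 2)
})

test_that("the ping-pong histogram counts exact 10 nt 5'-overlaps", {
  prof <- data.frame(position = 0:199, sense = 0, antisense = 0)
  prof$sense[prof$position == 50] <- 1
  prof$antisense[prof$position == 59] <- 1
  sig <- pingpong_signature(prof)
  expect_equal(unname(sig$overlap["k10"]), 1)
  expect_equal(sum(sig$overlap), 1)

  # z10 undefined for single-stranded data
  prof1 <- data.frame(position = 0:99, sense = rpois(100, 2), antisense = 0)
  s1 <- pingpong_signature(prof1)
  expect_false(s1$defined)

  # scaling all counts by an integer factor leaves z10 unchanged
  set.seed(65)
  prof2 <- data.frame(position = 0:299, sense = rpois(300, 3),
                      antisense = rpois(300, 3))
  z1 <- pingpong_signature(prof2)$z10
  prof3 <- prof2; prof3$sense <- prof3$sense * 7; prof3$antisense <- prof3$antisense * 7
  expect_equal(pingpong_signature(prof3)$z10, z1)

  # reverse-complement symmetry: swapping strands under coordinate mirroring
  prof4 <- prof2
  prof4$sense <- rev(prof2$antisense)
  prof4$antisense <- rev(prof2$sense)
  expect_equal(pingpong_signature(prof4)$overlap, pingpong_signature(prof2)$overlap)
})

pingpong_z <- function(rho, n, seed) {
  cfg <- simulation_config(consensus_length = 1000, gene_lengths = tiny_genes,
                           pirna_count = n, mirna_count = 100,
                           pirna_pingpong_fraction = rho,
                           pirna_degraded_fraction = 0, seed = seed)
  ls1 <- simulate_landscape(cfg)
  sr <- simulate_small_rna(ls1$consensus_library, NULL, cfg)
  fl <- filter_small_rna(sr$reads)
  aln <- align_reads(fl$pirna_sized, ls1$consensus_library, mode = "smallrna")
  prof <- position_profile(aln, ls1$consensus_library[["tirant"]],
                           target = "tirant")
  pingpong_signature(prof)$z10
}

test_that("the ping-pong z-score grows monotonically with the planted fraction", {
  means <- vapply(c(0, 0.25, 0.5, 1), function(rho)
    mean(vapply(1:6, function(i) pingpong_z(rho, 2000, 1000 * rho + i),
                numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1]), 2.5)
  expect_gt(means[4], 5)
})

test_that("the divergence gate passes consensus piRNAs and rejects diverged ones", {
  set.seed(66)
  cons <- random_seq(800)
  exact <- substr(cons, 301, 325)
  g <- divergence_gated_fraction(exact, cons)
  expect_equal(g$fraction, 1)
  expect_equal(g$divergence, 0)

  three_mm <- exact
  substr(three_mm, 4, 4) <- "A"; substr(three_mm, 12, 12) <- "A"
  substr(three_mm, 20, 20) <- "A"
  g3 <- divergence_gated_fraction(three_mm, cons)
  # 3 mismatches over 25 nt is 0.12: fails the strict < 0.10 gate
  expect_equal(g3$fraction, 0)
  expect_error(divergence_gated_fraction("ACGT", cons), "23 nt")

  # piRNAs drawn from 20-30% diverged fragments almost never pass; canonical
  # ones almost always do (aggregated over seeds to damp sampling noise)
  can_ok <- can_n <- deg_ok <- deg_n <- 0
  for (seed in 1:3) {
    cfg <- simulation_config(consensus_length = 800, gene_lengths = tiny_genes,
                             n_degraded_fragments = 3,
                             degraded_divergence_range = c(0.20, 0.30),
                             fragment_length_range = c(200, 400),
                             pirna_count = 100, mirna_count = 10,
                             pirna_degraded_fraction = 0, seed = 800 + seed)
    ls1 <- simulate_landscape(cfg)
    tc <- ls1$truth$copies
    tc <- tc[tc$class == "degraded", , drop = FALSE]
    frag_seqs <- vapply(seq_len(nrow(tc)), function(i) {
      s <- substr(ls1$genome[[tc$contig[i]]], tc$start[i] + 1, tc$end[i])
      if (tc$strand[i] == "-") revcomp(s) else s
    }, character(1))
    names(frag_seqs) <- tc$id
    sr_can <- simulate_small_rna(ls1$consensus_library, NULL, cfg)
    sr_deg <- simulate_small_rna(frag_seqs, NULL, cfg)
    cons_seq <- ls1$consensus_library[["tirant"]]
    can_pass <- divergence_gated_fraction(sr_can$reads$seq[
      sr_can$truth$class != "miRNA"], cons_seq)$pass
    deg_pass <- divergence_gated_fraction(sr_deg$reads$seq[
      sr_deg$truth$class != "miRNA"], cons_seq)$pass
    can_ok <- can_ok + sum(can_pass); can_n <- can_n + length(can_pass)
    deg_ok <- deg_ok + sum(deg_pass); deg_n <- deg_n + length(deg_pass)
  }
  expect_gt(can_ok / can_n, 0.95)
  expect_lt(deg_ok / deg_n, 0.05)
})

test_that("adapter trimming removes the 3' adapter and nothing else", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTACGTA"  # 25 nt
  reads <- data.frame(
    id = c("full", "partial", "none"),
    seq = c(paste0(insert, adapter),
            paste0(insert, substr(adapter, 1, 8)),
            insert),
    stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))
  tr <- trim_adapter(reads, adapter)
  expect_equal(tr$seq, rep(insert, 3))
  expect_equal(nchar(tr$qual), nchar(tr$seq))
  # a read shorter than the adapter overlap is left alone
  short <- trim_adapter(data.frame(id = "s", seq = "ACG"), adapter)
  expect_equal(short$seq, "ACG")
})
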