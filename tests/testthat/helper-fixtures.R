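# Shared fixtures: compact simulation configurations and pipeline shortcuts.
# Sizes are kept small so the full suite stays fast; the acceptance tests use
# the larger, criterion-level sizes.

tiny_genes <- c(tj = 600L, rpl32 = 600L, rhino = 600L)

# A strain carrying canonical copies (invaded) or only degraded fragments
# (naive), at desk scale.
strain_config <- function(seed, canonical_copies = 5, degraded = 4,
                          consensus_length = 1000, coverage = 25,
                          error_rate = 0.002, ...) {
  simulation_config(consensus_length = consensus_length,
                    n_canonical_copies = canonical_copies,
                    canonical_divergence = 0.02,
                    n_degraded_fragments = degraded,
                    fragment_length_range = c(100, min(600, consensus_length)),
                    gene_lengths = tiny_genes,
                    coverage_depth = coverage, error_rate = error_rate,
                    seed = seed, ...)
}

# simulate -> reads -> align -> profile
run_strain <- function(cfg) {
  ls1 <- simulate_landscape(cfg)
  rd <- simulate_dna_reads(ls1, cfg)
  aln <- align_reads(rd$reads, c(ls1$consensus_library, ls1$genes),
                     mode = "genomic")
  list(landscape = ls1, reads = rd, alignments = aln,
       profile = build_te_profile(aln, cfg$family, ls1$consensus_library,
                                  ls1$genes))
}

# Hand-built read set: each read an exact (optionally edited) copy of a
# consensus window, pre-aligned by construction through align_reads.
align_to <- function(seqs, refs, ...) {
  align_reads(data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
                         stringsAsFactors = FALSE),
              refs, ...)
}

# mean silhouette width of a 1-d embedding under known 2-group labels
silhouette_1d <- function(x, grp) {
  stopifnot(length(x) == length(grp))
  d <- abs(outer(x, x, "-"))
  mean(vapply(seq_along(x), function(i) {
    own <- grp == grp[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !(grp == grp[i])])
    (b - a) / max(a, b)
  }, numeric(1)))
}

count_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
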