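#' Configuration for the synthetic TE landscape generator
#'
#' Builds and validates the configuration driving [simulate_landscape()],
#' [simulate_dna_reads()] and [simulate_small_rna()].  The generator emulates
#' the genomic situation of a strain hit by a recent TE invasion on top of an
#' ancient one: low-divergence ("canonical") full-length copies of a family
#' consensus in contig interiors, highly diverged fragments near contig ends
#' (the heterochromatin-like compartment), three single-copy genes used for
#' coverage normalization, and small-RNA libraries mixing miRNAs with sense
#' and antisense piRNAs carrying a tunable ping-pong fraction.
#'
#' @param consensus_length length of the TE family consensus in bp.
#' @param family name of the TE family (used as the consensus record id).
#' @param n_canonical_copies number of full-length, low-divergence copies.
#' @param canonical_divergence substitution divergence of canonical copies,
#'   a fraction in `[0, 0.05]`.
#' @param n_degraded_fragments number of degraded fragments.
#' @param degraded_divergence_range length-2 numeric, divergence range of
#'   degraded fragments; must lie within `[0.05, 0.5]`.
#' @param fragment_length_range length-2 integer, fragment length range in bp
#'   (minimum 50).
#' @param deletion_haplotype `NULL`, or `c(start, end, frequency)`: a fraction
#'   `frequency` of canonical copies (rounded to a copy count) carries an
#'   internal deletion of consensus interval `[start, end)` (0-based).
#' @param gene_lengths named or unnamed length-3 integer vector of single-copy
#'   gene lengths in bp.
#' @param read_length sequencing read length in bp.
#' @param coverage_depth expected fold coverage of the genome.
#' @param error_rate per-base sequencing substitution error rate.
#' @param pirna_pingpong_fraction fraction `rho` of antisense piRNAs placed so
#'   that their 5' end overlaps a sense piRNA's 5' end by exactly 10 nt.
#' @param pirna_count,mirna_count numbers of piRNA and miRNA reads in the
#'   small-RNA library.
#' @param pirna_antisense_fraction fraction of piRNAs drawn antisense.
#' @param pirna_degraded_fraction fraction of piRNAs drawn from the degraded
#'   fragment set rather than the canonical consensus (0 when no degraded set
#'   is supplied).
#' @param n_mirna_genes,mirna_length size of the synthetic miRNA reference set
#'   and the (fixed) miRNA read length.
#' @param indel_rate optional per-base rate of small (1-3 bp) indels in
#'   degraded fragments; 0 keeps truth divergence exactly defined.
#' @param contig_length optional fixed contig length (scalar or one value per
#'   contig); when supplied, placement that cannot fit raises a sizing error.
#' @param n_contigs number of contigs in the synthetic assembly.
#' @param seed integer seed; identical configurations give byte-identical
#'   output.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(consensus_length = 5000,
                              family = "tirant",
                              n_canonical_copies = 10,
                              canonical_divergence = 0.02,
                              n_degraded_fragments = 8,
                              degraded_divergence_range = c(0.10, 0.30),
                              fragment_length_range = c(100, 800),
                              deletion_haplotype = NULL,
                              gene_lengths = c(tj = 1000, rpl32 = 1000, rhino = 1000),
                              read_length = 100,
                              coverage_depth = 30,
                              error_rate = 0.01,
                              pirna_pingpong_fraction = 0.3,
                              pirna_count = 2000,
                              mirna_count = 2000,
                              pirna_antisense_fraction = 0.5,
                              pirna_degraded_fraction = 0.3,
                              n_mirna_genes = 30,
                              mirna_length = 22,
                              indel_rate = 0,
                              contig_length = NULL,
                              n_contigs = 2,
                              seed = 1) {
  frac_ok <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)
  stopifnot(consensus_length > 0, read_length > 0, coverage_depth >= 0,
            n_canonical_copies >= 0, n_degraded_fragments >= 0,
            n_contigs >= 1, pirna_count >= 0, mirna_count >= 0,
            n_mirna_genes >= 1, mirna_length > 0)
  if (!frac_ok(canonical_divergence) || canonical_divergence > 0.05)
    stop("canonical_divergence must lie in [0, 0.05]")
  if (length(degraded_divergence_range) != 2 ||
      degraded_divergence_range[1] > degraded_divergence_range[2] ||
      degraded_divergence_range[1] < 0.05 || degraded_divergence_range[2] > 0.5)
    stop("degraded_divergence_range must lie within [0.05, 0.5]")
  if (length(fragment_length_range) != 2 || fragment_length_range[1] < 50 ||
      fragment_length_range[1] > fragment_length_range[2])
    stop("fragment_length_range minimum is 50 bp")
  if (n_degraded_fragments > 0 && fragment_length_range[2] > consensus_length)
    stop("fragments cannot be longer than the consensus")
  if (!is.null(deletion_haplotype)) {
    if (length(deletion_haplotype) != 3 ||
        deletion_haplotype[1] < 0 || deletion_haplotype[2] <= deletion_haplotype[1] ||
        deletion_haplotype[2] > consensus_length ||
        !frac_ok(deletion_haplotype[3]))
      stop("deletion_haplotype must be c(start, end, frequency) within the consensus")
  }
  if (length(gene_lengths) != 3 || any(gene_lengths <= 0))
    stop("gene_lengths must be three positive lengths")
  if (is.null(names(gene_lengths))) names(gene_lengths) <- c("tj", "rpl32", "rhino")
  if (!frac_ok(error_rate) || !frac_ok(pirna_pingpong_fraction) ||
      !frac_ok(pirna_antisense_fraction) || !frac_ok(pirna_degraded_fraction) ||
      !frac_ok(indel_rate))
    stop("all rate/fraction parameters must lie in [0, 1]")
  cfg <- list(consensus_length = as.integer(consensus_length), family = family,
              n_canonical_copies = as.integer(n_canonical_copies),
              canonical_divergence = canonical_divergence,
              n_degraded_fragments = as.integer(n_degraded_fragments),
              degraded_divergence_range = degraded_divergence_range,
              fragment_length_range = as.integer(fragment_length_range),
              deletion_haplotype = deletion_haplotype,
              gene_lengths = setNames(as.integer(gene_lengths), names(gene_lengths)),
              read_length = as.integer(read_length),
              coverage_depth = coverage_depth, error_rate = error_rate,
              pirna_pingpong_fraction = pirna_pingpong_fraction,
              pirna_count = as.integer(pirna_count),
              mirna_count = as.integer(mirna_count),
              pirna_antisense_fraction = pirna_antisense_fraction,
              pirna_degraded_fraction = pirna_degraded_fraction,
              n_mirna_genes = as.integer(n_mirna_genes),
              mirna_length = as.integer(mirna_length),
              indel_rate = indel_rate,
              contig_length = contig_length,
              n_contigs = as.integer(n_contigs),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Apply small indels (1-3 bp) to a sequence at the configured per-base rate.
#' @noRd
apply_small_indels <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_ev <- rbinom(1, length(chars), rate)
  if (n_ev == 0) return(seq)
  pos <- sort(sample.int(length(chars), n_ev))
  for (p in rev(pos)) {
    len <- sample.int(3, 1)
    if (runif(1) < 0.5) {
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      chars <- append(chars, ins, after = p)
    } else {
      drop <- p:min(p + len - 1, length(chars))
      chars <- chars[-drop]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a TE landscape with known ground truth
#'
#' Generates a TE family consensus, a multi-contig genome containing
#' `n_canonical_copies` low-divergence full-length copies and
#' `n_degraded_fragments` high-divergence fragments of that consensus plus
#' three single-copy genes, all embedded in iid random background sequence.
#' Degraded fragments are placed near contig ends; canonical copies and genes
#' in contig interiors.  Divergence is realized as uniform random
#' substitutions at the configured rate, so the truth table records exact
#' per-copy divergences.
#'
#' @param config a [simulation_config()].
#' @return a list of class `te_landscape` with elements `consensus_library`
#'   (named character, the TE consensus), `genes` (named character),
#'   `genome` (named character, one element per contig), `truth` (list with
#'   `copies` and `genes` coordinate tables, 0-based half-open) and `config`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_landscape_impl(config))
}

#' @noRd
simulate_landscape_impl <- function(cfg) {
  consensus <- random_dna(cfg$consensus_length)
  genes <- vapply(cfg$gene_lengths, random_dna, character(1))

  feats <- list()
  n_del <- 0L
  if (!is.null(cfg$deletion_haplotype) && cfg$n_canonical_copies > 0)
    n_del <- as.integer(round(cfg$deletion_haplotype[3] * cfg$n_canonical_copies))
  if (cfg$n_canonical_copies > 0) {
    for (i in seq_len(cfg$n_canonical_copies)) {
      s <- mutate_seq(consensus, cfg$canonical_divergence)
      div <- attr(s, "divergence")
      has_del <- i <= n_del
      if (has_del) {
        d0 <- cfg$deletion_haplotype[1]; d1 <- cfg$deletion_haplotype[2]
        s <- paste0(substr(s, 1, d0), substr(s, d1 + 1, nchar(s)))
      }
      feats[[length(feats) + 1]] <- list(
        id = sprintf("canonical_%02d", i), seq = as.character(s),
        strand = sample(c("+", "-"), 1), class = "canonical",
        divergence = div, has_deletion = has_del, zone = "interior")
    }
  }
  if (cfg$n_degraded_fragments > 0) {
    for (i in seq_len(cfg$n_degraded_fragments)) {
      len <- cfg$fragment_length_range[1] +
        sample.int(cfg$fragment_length_range[2] - cfg$fragment_length_range[1] + 1, 1) - 1L
      fs <- sample.int(cfg$consensus_length - len + 1, 1)
      div <- runif(1, cfg$degraded_divergence_range[1], cfg$degraded_divergence_range[2])
      s <- mutate_seq(substr(consensus, fs, fs + len - 1), div)
      rdiv <- attr(s, "divergence")
      s <- apply_small_indels(as.character(s), cfg$indel_rate)
      feats[[length(feats) + 1]] <- list(
        id = sprintf("degraded_%02d", i), seq = s,
        strand = sample(c("+", "-"), 1), class = "degraded",
        divergence = rdiv, has_deletion = FALSE, zone = "end")
    }
  }
  for (g in names(genes)) {
    feats[[length(feats) + 1]] <- list(id = g, seq = genes[[g]], strand = "+",
                                       class = "gene", divergence = 0,
                                       has_deletion = FALSE, zone = "interior")
  }

  # assign features to contigs: end-zone features to contig ends, the rest to
  # interiors, round-robin over a shuffled order
  contig_of <- function(n) if (n == 0) integer(0) else
    (sample.int(cfg$n_contigs, n, replace = TRUE))
  ends <- which(vapply(feats, function(f) f$zone == "end", logical(1)))
  ints <- which(vapply(feats, function(f) f$zone == "interior", logical(1)))
  end_contig <- contig_of(length(ends))
  int_contig <- contig_of(length(ints))

  contigs <- character(cfg$n_contigs)
  copies <- list(); gene_rows <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    my_ends <- ends[end_contig == ci]
    my_ints <- ints[int_contig == ci]
    # split end-zone features between left and right contig end
    left <- my_ends[seq_along(my_ends) %% 2 == 1]
    right <- my_ends[seq_along(my_ends) %% 2 == 0]
    ordered <- c(left, my_ints[sample.int(length(my_ints))], right)
    widths <- vapply(ordered, function(i) nchar(feats[[i]]$seq), integer(1))
    ngap <- length(ordered) + 1
    if (!is.null(cfg$contig_length)) {
      budget <- if (length(cfg$contig_length) == 1) cfg$contig_length
      else cfg$contig_length[ci]
      needed <- sum(widths) + ngap * 100
      if (needed > budget)
        stop(sprintf("contig %d too short for requested copies: need %d, have %d",
                     ci, needed, budget))
      extra <- budget - needed
      gaps <- rep(100L, ngap) +
        as.integer(stats::rmultinom(1, extra, rep(1, ngap)))
    } else {
      gaps <- sample(200:600, ngap, replace = TRUE)
    }
    segs <- character(0)
    pos <- 0L
    for (k in seq_along(ordered)) {
      segs <- c(segs, random_dna(gaps[k]))
      pos <- pos + gaps[k]
      f <- feats[[ordered[k]]]
      emitted <- if (f$strand == "-") revcomp(f$seq) else f$seq
      segs <- c(segs, emitted)
      row <- data.frame(id = f$id, contig = sprintf("contig_%d", ci),
                        start = pos, end = pos + nchar(emitted),
                        strand = f$strand, divergence = f$divergence,
                        class = f$class, has_deletion = f$has_deletion,
                        stringsAsFactors = FALSE)
      if (f$class == "gene") gene_rows[[length(gene_rows) + 1]] <- row
      else copies[[length(copies) + 1]] <- row
      pos <- pos + nchar(emitted)
    }
    segs <- c(segs, random_dna(gaps[ngap]))
    contigs[ci] <- paste(segs, collapse = "")
  }
  names(contigs) <- sprintf("contig_%d", seq_len(cfg$n_contigs))

  truth_copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(id = character(0), contig = character(0), start = integer(0),
               end = integer(0), strand = character(0), divergence = numeric(0),
               class = character(0), has_deletion = logical(0))
  truth_genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL

  out <- list(consensus_library = setNames(consensus, cfg$family),
              genes = genes, genome = contigs,
              truth = list(copies = truth_copies, genes = truth_genes),
              config = cfg)
  class(out) <- "te_landscape"
  out
}

#' Simulate short sequencing reads from a genome
#'
#' Draws single-end reads uniformly from the genome at the configured
#' coverage, with iid substitution errors at `error_rate` and constant
#' placeholder base qualities.  The read count is
#' `round(coverage_depth * genome_length / read_length)`.
#'
#' @param genome a `te_landscape` (its `$genome` is used) or a named character
#'   vector of contigs.
#' @param config a [simulation_config()].
#' @return list with `reads` (data.frame: id, seq, qual) and `truth`
#'   (data.frame: id, contig, start, strand) where `start` is the 0-based
#'   origin of the read on the forward strand of its contig.
#' @export
simulate_dna_reads <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(genome, "te_landscape")) genome <- genome$genome
  stopifnot(is.character(genome), length(genome) >= 1, !is.null(names(genome)))
  if (sum(nchar(genome)) == 0) stop("genome is empty")
  if (config$coverage_depth <= 0) stop("coverage_depth must be positive")
  if (config$read_length > min(nchar(genome)))
    stop("read_length exceeds the shortest contig")
  with_seed(config$seed + 1L, simulate_dna_reads_impl(genome, config))
}

#' @noRd
simulate_dna_reads_impl <- function(genome, cfg) {
  rl <- cfg$read_length
  glen <- sum(nchar(genome))
  n <- as.integer(round(cfg$coverage_depth * glen / rl))
  if (n == 0)
    return(list(reads = data.frame(id = character(0), seq = character(0),
                                   qual = character(0)),
                truth = data.frame(id = character(0), contig = character(0),
                                   start = integer(0), strand = character(0))))
  contig <- sample(names(genome), n, replace = TRUE, prob = nchar(genome))
  start <- integer(n)
  for (cn in unique(contig)) {
    idx <- which(contig == cn)
    start[idx] <- sample.int(nchar(genome[[cn]]) - rl + 1, length(idx),
                             replace = TRUE) - 1L
  }
  seqs <- substring(genome[contig], start + 1, start + rl)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  nerr <- rbinom(n, rl, cfg$error_rate)
  has <- which(nerr > 0)
  if (length(has)) {
    pos <- lapply(nerr[has], function(k) sample.int(rl, k))
    off <- lapply(nerr[has], function(k) sample.int(3, k, replace = TRUE))
    seqs[has] <- cpp_apply_subs(seqs[has], pos, off)
  }
  ids <- sprintf("read_%06d", seq_len(n))
  list(reads = data.frame(id = ids, seq = seqs, qual = strrep("I", rl),
                          stringsAsFactors = FALSE),
       truth = data.frame(id = ids, contig = contig, start = start,
                          strand = strand, stringsAsFactors = FALSE))
}

#' Simulate a small-RNA library with a tunable ping-pong fraction
#'
#' Generates piRNA reads (23-29 nt, uniform lengths) drawn from the canonical
#' consensus and/or a degraded-fragment set, plus miRNA reads drawn from a
#' synthetic miRNA reference.  A fraction `rho` of antisense piRNAs is placed
#' so that its 5' end overlaps a sampled sense piRNA's 5' end by exactly
#' 10 nt (the ping-pong configuration); remaining reads are placed uniformly.
#'
#' @param consensus_library named character vector of canonical TE consensus
#'   sequences (piRNA sources).
#' @param degraded_set named character vector of degraded fragment sequences,
#'   or `NULL`.
#' @param config a [simulation_config()].
#' @return list with `reads` (data.frame id, seq, qual), `truth` (data.frame
#'   id, class in piRNA_sense/piRNA_antisense/miRNA, origin record,
#'   five_prime 0-based position on the source), and `mirna_ref` (named
#'   character, the synthetic miRNA reference set).
#' @export
simulate_small_rna <- function(consensus_library, degraded_set, config) {
  stopifnot(inherits(config, "simulation_config"))
  consensus_library <- as_ref_vector(consensus_library)
  if (!is.null(degraded_set) && length(degraded_set) > 0)
    degraded_set <- as_ref_vector(degraded_set)
  else degraded_set <- NULL
  if (any(nchar(consensus_library) < 29) ||
      (!is.null(degraded_set) && any(nchar(degraded_set) < 29)))
    stop("piRNA source sequences must be at least 29 nt")
  with_seed(config$seed + 2L,
            simulate_small_rna_impl(consensus_library, degraded_set, config))
}

#' @noRd
draw_pirnas <- function(sources, n, rho, anti_frac, class_prefix = "") {
  if (n == 0) return(NULL)
  n_anti <- round(n * anti_frac)
  n_sense <- n - n_anti
  n_pp <- round(n_anti * rho)
  n_anti_unif <- n_anti - n_pp
  src_names <- names(sources)
  srclen <- nchar(sources)
  pick_src <- function(m) sample(src_names, m, replace = TRUE, prob = srclen)

  rows <- list()
  sense <- NULL
  if (n_sense > 0) {
    org <- pick_src(n_sense)
    len <- sample(23:29, n_sense, replace = TRUE)
    p <- vapply(seq_len(n_sense),
                function(i) sample.int(srclen[[org[i]]] - len[i] + 1, 1) - 1L,
                integer(1))
    sense <- data.frame(class = "piRNA_sense", origin = org, five_prime = p,
                        len = len,
                        seq = substring(sources[org], p + 1, p + len),
                        stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- sense
  }
  if (n_pp > 0) {
    if (is.null(sense)) stop("ping-pong antisense reads require sense reads")
    partners <- sense[sense$five_prime >= 13, , drop = FALSE]
    if (nrow(partners) == 0) stop("no sense reads far enough from the 5' end to pair")
    pick <- partners[sample.int(nrow(partners), n_pp, replace = TRUE), ]
    q <- pick$five_prime + 9L  # antisense 5' end (rightmost aligned base)
    len <- vapply(q, function(qq) {
      hi <- min(29L, qq + 1L)
      if (hi <= 23L) 23L else 22L + sample.int(hi - 22L, 1)
    }, integer(1))
    rows[[length(rows) + 1]] <- data.frame(
      class = "piRNA_antisense", origin = pick$origin, five_prime = q, len = len,
      seq = revcomp(substring(sources[pick$origin], q - len + 2, q + 1)),
      stringsAsFactors = FALSE)
  }
  if (n_anti_unif > 0) {
    org <- pick_src(n_anti_unif)
    len <- sample(23:29, n_anti_unif, replace = TRUE)
    p <- vapply(seq_len(n_anti_unif),
                function(i) sample.int(srclen[[org[i]]] - len[i] + 1, 1) - 1L,
                integer(1))
    q <- p + len - 1L
    rows[[length(rows) + 1]] <- data.frame(
      class = "piRNA_antisense", origin = org, five_prime = q, len = len,
      seq = revcomp(substring(sources[org], p + 1, p + len)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @noRd
simulate_small_rna_impl <- function(consensus_library, degraded_set, cfg) {
  mirna_ref <- setNames(
    vapply(seq_len(cfg$n_mirna_genes), function(i) random_dna(cfg$mirna_length),
           character(1)),
    sprintf("mir_%03d", seq_len(cfg$n_mirna_genes)))

  n_deg <- if (is.null(degraded_set)) 0L else
    as.integer(round(cfg$pirna_count * cfg$pirna_degraded_fraction))
  n_can <- cfg$pirna_count - n_deg

  parts <- list()
  parts[[1]] <- draw_pirnas(consensus_library, n_can,
                            cfg$pirna_pingpong_fraction,
                            cfg$pirna_antisense_fraction)
  if (n_deg > 0)
    parts[[2]] <- draw_pirnas(degraded_set, n_deg,
                              cfg$pirna_pingpong_fraction,
                              cfg$pirna_antisense_fraction)
  if (cfg$mirna_count > 0) {
    org <- sample(names(mirna_ref), cfg$mirna_count, replace = TRUE)
    parts[[length(parts) + 1]] <- data.frame(
      class = "miRNA", origin = org, five_prime = 0L,
      len = cfg$mirna_length, seq = unname(mirna_ref[org]),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, parts)
  if (is.null(all) || nrow(all) == 0)
    return(list(reads = data.frame(id = character(0), seq = character(0),
                                   qual = character(0)),
                truth = data.frame(id = character(0), class = character(0),
                                   origin = character(0), five_prime = integer(0)),
                mirna_ref = mirna_ref))
  ids <- sprintf("srna_%06d", seq_len(nrow(all)))
  list(reads = data.frame(id = ids, seq = all$seq,
                          qual = strrep("I", nchar(all$seq)),
                          stringsAsFactors = FALSE),
       truth = data.frame(id = ids, class = all$class, origin = all$origin,
                          five_prime = all$five_prime, stringsAsFactors = FALSE),
       mirna_ref = mirna_ref)
}
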