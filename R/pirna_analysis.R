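# Small-RNA evidence: size filtering, partitioned mapping to canonical vs
# degraded references with miRNA normalization, position profiles, the
# ping-pong signature, and divergence-gated targeting.

#' Trim a fixed 3' adapter from small-RNA reads
#'
#' Optional pre-step for real libraries: the earliest position where the
#' remainder of the read exactly matches a prefix of the adapter (at least
#' `min_overlap` bases) marks the adapter start; everything from there on is
#' removed.  Synthetic libraries need no trimming.
#'
#' @param reads data.frame with `id` and `seq` (and optionally `qual`).
#' @param adapter adapter sequence as read on the 3' end.
#' @param min_overlap minimum matching adapter prefix length.
#' @return the reads data.frame with trimmed `seq` (and `qual`).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5) {
  adapter <- toupper(adapter)
  trim_at <- function(seq) {
    n <- nchar(seq)
    if (n < min_overlap) return(n)
    for (p in seq_len(n - min_overlap + 1)) {
      tail_len <- n - p + 1
      if (substr(seq, p, n) == substr(adapter, 1, tail_len)) return(p - 1L)
    }
    n
  }
  cut <- vapply(toupper(reads$seq), trim_at, integer(1), USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1, cut)
  if (!is.null(reads$qual)) reads$qual <- substr(reads$qual, 1, cut)
  reads
}

#' Two-stage small-RNA size filter
#'
#' Reads are first restricted to 18-36 nt (the small-RNA window used for
#' mapping and miRNA normalization) and then to 23-29 nt (the piRNA-sized
#' subset); both filters are inclusive.
#'
#' @param reads data.frame with `id` and `seq` columns.
#' @return list: `broad` (18-36 nt reads), `pirna_sized` (23-29 nt reads),
#'   `n_input`, `n_discarded_broad` (outside 18-36),
#'   `n_discarded_pirna` (in 18-36 but outside 23-29).
#' @export
filter_small_rna <- function(reads) {
  len <- nchar(reads$seq)
  broad <- reads[len >= 18 & len <= 36, , drop = FALSE]
  blen <- nchar(broad$seq)
  pir <- broad[blen >= 23 & blen <= 29, , drop = FALSE]
  list(broad = broad, pirna_sized = pir, n_input = nrow(reads),
       n_discarded_broad = nrow(reads) - nrow(broad),
       n_discarded_pirna = nrow(broad) - nrow(pir))
}

#' Assemble a small-RNA mapping database
#'
#' @param canonical named character vector of canonical TE consensus
#'   sequences.
#' @param degraded named character vector of degraded fragment sequences
#'   (or `NULL`).
#' @param mirna named character vector of miRNA references.
#' @param other optional named character vector of other ncRNA references.
#' @return list with `refs` (combined named vector) and `category` (named
#'   character mapping record id to one of `canonical`, `degraded`,
#'   `mirna`, `other`).
#' @export
small_rna_database <- function(canonical, degraded = NULL, mirna, other = NULL) {
  canonical <- as_ref_vector(canonical)
  mirna <- as_ref_vector(mirna)
  sets <- list(canonical = canonical, mirna = mirna)
  if (!is.null(degraded) && length(degraded)) sets$degraded <- as_ref_vector(degraded)
  if (!is.null(other) && length(other)) sets$other <- as_ref_vector(other)
  ids <- unlist(lapply(sets, names), use.names = FALSE)
  if (anyDuplicated(ids)) stop("database categories must be disjoint by record id")
  refs <- unlist(unname(sets))
  category <- setNames(rep(names(sets), vapply(sets, length, integer(1))), ids)
  list(refs = refs, category = category)
}

#' Partition small-RNA reads across database categories
#'
#' Each 18-36 nt read is aligned (small-RNA mode, at most `mismatch_cap`
#' mismatches) and assigned to the category of its best alignment;
#' co-optimal ties across categories are split fractionally (equal weight
#' per tied category).  TE-category counts (canonical/degraded/other) keep
#' only piRNA-sized reads (23-29 nt) and are split by alignment strand into
#' sense/antisense; miRNA matches of any length in 18-36 feed the
#' normalizer.
#'
#' @param reads data.frame of 18-36 nt reads (`id`, `seq`), e.g.
#'   `filter_small_rna(x)$broad`.
#' @param database a [small_rna_database()].
#' @param mismatch_cap maximum mismatches (default 2).
#' @return list: `counts` (data.frame category/sense/antisense),
#'   `mirna_count`, `n_unassigned`, `alignments` (the per-read alignment
#'   table with an added `categories` column).
#' @export
partition_counts <- function(reads, database, mismatch_cap = 2) {
  aln <- align_reads(reads, database$refs, mode = "smallrna",
                     mismatch_cap = mismatch_cap)
  len <- nchar(reads$seq)[match(aln$read_id, reads$id)]
  cats <- strsplit(ifelse(is.na(aln$co_targets), "", aln$co_targets), ",")
  cats <- lapply(cats, function(ids) unique(unname(database$category[ids])))
  aln$categories <- vapply(cats, paste, character(1), collapse = ",")

  all_cats <- unique(unname(database$category))
  te_cats <- setdiff(all_cats, "mirna")
  counts <- data.frame(category = all_cats, sense = 0, antisense = 0,
                       stringsAsFactors = FALSE)
  mirna_count <- 0
  pir_sized <- len >= 23 & len <= 29
  for (i in seq_len(nrow(aln))) {
    cs <- cats[[i]]
    if (length(cs) == 0) next
    w <- 1 / length(cs)
    for (cc in cs) {
      if (cc == "mirna") {
        mirna_count <- mirna_count + w
      } else {
        if (!pir_sized[i]) next
        row <- counts$category == cc
        if (aln$strand[i] == "+") counts$sense[row] <- counts$sense[row] + w
        else counts$antisense[row] <- counts$antisense[row] + w
      }
    }
  }
  mrow <- counts$category == "mirna"
  counts$sense[mrow] <- mirna_count
  list(counts = counts, mirna_count = mirna_count,
       n_unassigned = sum(!aln$mapped), alignments = aln)
}

#' Normalize piRNA counts to miRNA abundance
#'
#' `ppm` is piRNAs per million miRNAs, `ppk` per thousand; `ppk` equals
#' `ppm / 1000` exactly.
#'
#' @param count piRNA count (possibly fractional).
#' @param mirna_count miRNA read count; must be positive.
#' @return list with `ppm` and `ppk`.
#' @export
normalize_pirna <- function(count, mirna_count) {
  if (mirna_count <= 0) stop("miRNA count must be positive for normalization")
  list(ppm = count * 1e6 / mirna_count, ppk = count * 1e3 / mirna_count)
}

#' Per-position 5' end profiles along a consensus
#'
#' Sense reads register their 5' end at the alignment start; antisense reads
#' at the rightmost aligned base.  Multimapping reads contribute
#' fractionally (1/ambiguity) unless `fractional = FALSE`.
#'
#' @param alignments `read_alignments` rows (e.g. from
#'   [partition_counts()]`$alignments`).
#' @param consensus consensus sequence the profile is indexed along.
#' @param target id of the consensus in the alignment table; defaults to the
#'   name of `consensus`.
#' @param pirna_sized_only keep only 23-29 nt reads (default `TRUE`).
#' @param fractional weight reads by 1/ambiguity (default `TRUE`).
#' @return data.frame: `position` (0-based), `sense`, `antisense`.
#' @export
position_profile <- function(alignments, consensus, target = NULL,
                             pirna_sized_only = TRUE, fractional = TRUE) {
  if (is.null(target)) {
    target <- names(consensus)
    if (is.null(target)) stop("supply `target` or a named consensus")
  }
  consensus <- as.character(consensus)[1]
  a <- alignments[!is.na(alignments$mapped) & alignments$mapped &
                    alignments$target_id == target, , drop = FALSE]
  if (pirna_sized_only)
    a <- a[a$aligned_bases >= 23 & a$aligned_bases <= 29, , drop = FALSE]
  L <- nchar(consensus)
  sense <- numeric(L); anti <- numeric(L)
  if (nrow(a)) {
    w <- if (fractional) 1 / a$ambiguity else rep(1, nrow(a))
    plus <- a$strand == "+"
    p5 <- ifelse(plus, a$target_start, a$target_end - 1L)
    for (i in seq_len(nrow(a))) {
      pos <- p5[i] + 1L
      if (pos < 1 || pos > L) next
      if (plus[i]) sense[pos] <- sense[pos] + w[i]
      else anti[pos] <- anti[pos] + w[i]
    }
  }
  data.frame(position = seq_len(L) - 1L, sense = sense, antisense = anti)
}

#' Ping-pong signature from position profiles
#'
#' For overlap `k` in 1..20, `c_k` is the sum over positions `p` of
#' `sense5(p) * antisense5(p + k - 1)` — the count of sense/antisense 5' end
#' pairs overlapping by exactly `k` nt (both end bases inclusive).  The
#' enrichment statistic `z10` is `(c_10 - mean(c_others)) / sd(c_others)`;
#' it is undefined (flagged) when the other bins carry no variance, e.g.
#' for single-stranded data.
#'
#' @param profile a [position_profile()] table.
#' @return list of class `pingpong_profile`: `overlap` (named numeric,
#'   k = 1..20), `z10`, `defined`.
#' @export
pingpong_signature <- function(profile) {
  s <- profile$sense
  a <- profile$antisense
  L <- length(s)
  ck <- vapply(1:20, function(k) {
    idx <- seq_len(L - k + 1)
    sum(s[idx] * a[idx + k - 1])
  }, numeric(1))
  names(ck) <- paste0("k", 1:20)
  others <- ck[-10]
  sdo <- stats::sd(others)
  z10 <- if (is.na(sdo) || sdo == 0) NA_real_ else (ck[[10]] - mean(others)) / sdo
  out <- list(overlap = ck, z10 = z10, defined = !is.na(z10))
  class(out) <- "pingpong_profile"
  out
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("5'-overlap histogram (k = 1..20):\n")
  print(round(x$overlap, 2))
  cat(sprintf("z10 = %s\n", ifelse(x$defined, sprintf("%.2f", x$z10),
                                   "undefined (no variance in other bins)")))
  invisible(x)
}

#' Fraction of piRNAs matching a consensus below a divergence gate
#'
#' Each piRNA is locally aligned to both strands of the consensus; it
#' passes when the best alignment spans at least `min_span` of the piRNA
#' with a mismatch fraction strictly below `max_div`.  This implements the
#' sequence-similarity requirement for piRNA-mediated silencing: piRNAs
#' from fragments more than ~10\% diverged rarely match the canonical
#' sequence below the gate.
#'
#' @param pirnas character vector of piRNA sequences (>= 23 nt).
#' @param consensus consensus sequence (character scalar).
#' @param max_div strict divergence bound (default 0.10).
#' @param min_span minimum aligned fraction of the piRNA (default 0.9).
#' @return list: `fraction` passing, `divergence` (per read, over the best
#'   local alignment; `NA` when the span requirement fails), `pass`
#'   (logical per read).
#' @export
divergence_gated_fraction <- function(pirnas, consensus, max_div = 0.10,
                                      min_span = 0.9) {
  stopifnot(length(pirnas) >= 1)
  if (any(nchar(pirnas) < 23)) stop("piRNAs must be at least 23 nt")
  subject <- Biostrings::DNAString(toupper(as.character(consensus)[1]))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  score_one <- function(seqs) {
    Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(seqs), subject,
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = 3, gapExtension = 1)
  }
  fw <- score_one(toupper(pirnas))
  rv <- score_one(revcomp(toupper(pirnas)))
  use_rv <- Biostrings::score(rv) > Biostrings::score(fw)
  stats_of <- function(pa) {
    pat <- Biostrings::pattern(pa)
    span <- Biostrings::end(pat) - Biostrings::start(pat) + 1
    mm <- Biostrings::nmismatch(pa)
    list(span = span, mm = mm)
  }
  sf <- stats_of(fw); sr <- stats_of(rv)
  span <- ifelse(use_rv, sr$span, sf$span)
  mm <- ifelse(use_rv, sr$mm, sf$mm)
  rl <- nchar(pirnas)
  ok_span <- span >= min_span * rl
  div <- ifelse(ok_span, mm / span, NA_real_)
  pass <- ok_span & !is.na(div) & div < max_div
  list(fraction = mean(pass), divergence = div, pass = pass)
}
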