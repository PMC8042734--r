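#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over Biostrings readers returning a plain data.frame with
#' lowercase folded to uppercase.  FASTQ records with a quality string whose
#' length differs from the sequence raise a parse error.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return data.frame with columns `id`, `seq` and `qual` (`NA` for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  res <- tryCatch({
    if (format == "fasta") {
      x <- Biostrings::readDNAStringSet(path, format = "fasta")
      data.frame(id = sub("\\s.*$", "", names(x)),
                 seq = toupper(as.character(x)),
                 qual = NA_character_, stringsAsFactors = FALSE)
    } else {
      x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      q <- as.character(S4Vectors::mcols(x)$qualities)
      if (any(nchar(q) != Biostrings::width(x)))
        stop("quality string length differs from sequence length")
      data.frame(id = sub("\\s.*$", "", names(x)),
                 seq = toupper(as.character(x)),
                 qual = q, stringsAsFactors = FALSE)
    }
  }, error = function(e) {
    stop(sprintf("failed to parse %s as %s: %s", path, format, conditionMessage(e)),
         call. = FALSE)
  })
  if (any(res$id == "") || any(res$seq == ""))
    stop(sprintf("failed to parse %s: empty record id or sequence", path),
         call. = FALSE)
  rownames(res) <- NULL
  res
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records data.frame with `id`, `seq` and (for FASTQ) `qual` columns,
#'   or a named character vector (FASTA only).
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(records))
    records <- data.frame(id = names(records), seq = unname(records),
                          qual = NA_character_, stringsAsFactors = FALSE)
  x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    if (is.null(records$qual) || anyNA(records$qual))
      stop("FASTQ output requires quality strings")
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(records$qual))
  }
  invisible(path)
}

#' Align reads to reference sequences with the internal micro-aligner
#'
#' Exact k-mer seeding followed by windowed gapped extension (glocal: the
#' full read is aligned, reference ends are free).  Long internal deletions
#' are supported through a flat long-gap cost so reads spanning large
#' internal TE deletions align contiguously with a `D` operation.  The best
#' scoring locus is reported per read together with the number of co-optimal
#' loci (`ambiguity`); ties are broken deterministically (first by strand
#' `+` over `-`, then lexicographic target id, then leftmost end).
#'
#' Two modes mirror the two mapping regimes of the pipeline: `"genomic"`
#' drops reads whose divergence (mismatches plus inserted bases over read
#' length) exceeds `max_divergence` (default 0.25, permissive enough to keep
#' 10-30\% diverged fragments mappable at the low end); `"smallrna"` drops
#' reads with more than `mismatch_cap` mismatches (default 2).
#'
#' @param reads data.frame with `id` and `seq` columns, or a character vector
#'   (named or not).
#' @param references named character vector or sequence data.frame.
#' @param mode `"genomic"` or `"smallrna"`.
#' @param max_divergence maximum divergence for genomic mode (`NULL` for the
#'   mode default).
#' @param mismatch_cap maximum mismatch count for small-RNA mode.
#' @param seed_k seed k-mer length (`NULL` for the mode default: 11 genomic,
#'   7 small-RNA); must not exceed the shortest read.
#' @param allow_gaps allow insertions/deletions (default `TRUE`).
#' @param pad,diag_join,max_candidates seeding window tuning: window padding
#'   in bp, maximum diagonal separation joined into one window (bounds the
#'   detectable deletion length), and candidate window cap per read.
#' @return a data.frame of class `read_alignments`, one row per read:
#'   `read_id`, `mapped`, `target_id`, `target_start`/`target_end` (0-based
#'   half-open), `strand`, `ops` (run-length string over `=XID`), `score`,
#'   `mismatch_count`, `aligned_bases`, `divergence`, `ambiguity`,
#'   `co_targets` (comma-separated ids of co-optimal targets) and
#'   `seq_oriented` (read sequence on the target's forward strand).
#'   Unalignable reads are returned unmapped, not dropped.
#' @export
align_reads <- function(reads, references, mode = c("genomic", "smallrna"),
                        max_divergence = NULL, mismatch_cap = NULL,
                        seed_k = NULL, allow_gaps = TRUE,
                        pad = 32, diag_join = 2000, max_candidates = 50) {
  mode <- match.arg(mode)
  if (is.character(reads))
    reads <- data.frame(id = if (is.null(names(reads)))
      sprintf("read_%06d", seq_along(reads)) else names(reads),
      seq = unname(reads), stringsAsFactors = FALSE)
  refs <- as_ref_vector(references)
  refs <- refs[order(names(refs), method = "radix")]
  if (mode == "genomic") {
    if (is.null(max_divergence)) max_divergence <- 0.25
    if (is.null(mismatch_cap)) mismatch_cap <- -1L
    if (is.null(seed_k)) seed_k <- 11L
  } else {
    if (is.null(max_divergence)) max_divergence <- -1
    if (is.null(mismatch_cap)) mismatch_cap <- 2L
    if (is.null(seed_k)) seed_k <- 7L
  }
  if (nrow(reads) == 0) {
    out <- data.frame(read_id = character(0), mapped = logical(0),
                      target_id = character(0), target_start = integer(0),
                      target_end = integer(0), strand = character(0),
                      ops = character(0), score = integer(0),
                      mismatch_count = integer(0), aligned_bases = integer(0),
                      divergence = numeric(0), ambiguity = integer(0),
                      co_targets = character(0), seq_oriented = character(0))
    class(out) <- c("read_alignments", "data.frame")
    return(out)
  }
  if (seed_k > min(nchar(reads$seq)))
    stop("seed_k exceeds the shortest read length")
  seqs <- toupper(reads$seq)
  raw <- cpp_align_reads(seqs, unname(refs), as.integer(seed_k),
                         max_divergence, as.integer(mismatch_cap),
                         allow_gaps, as.integer(pad), as.integer(diag_join),
                         as.integer(max_candidates))
  tid <- ifelse(is.na(raw$target), NA_character_, names(refs)[raw$target])
  cot <- vapply(seq_along(raw$cotargets), function(i) {
    if (is.na(raw$cotargets[i])) return(NA_character_)
    idx <- as.integer(strsplit(raw$cotargets[i], ",")[[1]])
    paste(names(refs)[idx], collapse = ",")
  }, character(1))
  oriented <- seqs
  neg <- !is.na(raw$strand) & raw$strand == "-"
  oriented[neg] <- revcomp(seqs[neg])
  oriented[!raw$mapped] <- seqs[!raw$mapped]
  nb <- nchar(seqs)
  out <- data.frame(read_id = reads$id, mapped = raw$mapped, target_id = tid,
                    target_start = raw$start, target_end = raw$end,
                    strand = raw$strand, ops = raw$cigar, score = raw$score,
                    mismatch_count = raw$nmm, aligned_bases = ifelse(raw$mapped, nb, NA),
                    divergence = ifelse(raw$mapped, raw$nmm / nb, NA),
                    ambiguity = raw$ambiguity, co_targets = cot,
                    seq_oriented = oriented, stringsAsFactors = FALSE)
  out$target_id[!out$mapped] <- NA_character_
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Write alignments as SAM
#'
#' Internal 0-based half-open coordinates become 1-based SAM `POS`; strand is
#' carried in flag bit 0x10.  The edit distance (mismatches plus gap bases)
#' is written in the standard `NM` tag; score, ambiguity and co-optimal
#' target set go to `AS`, `X0` and `XT`.
#'
#' @param alignments a `read_alignments` data.frame.
#' @param references named character vector (for the `@SQ` header).
#' @param path output path.
#' @export
write_sam <- function(alignments, references, path) {
  refs <- as_ref_vector(references)
  refs <- refs[order(names(refs), method = "radix")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  lines <- vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    if (!a$mapped)
      return(paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   a$seq_oriented, "*", sep = "\t"))
    opdf <- parse_ops(a$ops)[[1]]
    nm <- sum(opdf$len[opdf$op %in% c("X", "I", "D")])
    flag <- if (a$strand == "-") 16L else 0L
    paste(a$read_id, flag, a$target_id, a$target_start + 1L, 255L, a$ops,
          "*", 0L, 0L, a$seq_oriented, "*",
          sprintf("NM:i:%d", nm), sprintf("AS:i:%d", a$score),
          sprintf("X0:i:%d", a$ambiguity), sprintf("XT:Z:%s", a$co_targets),
          sep = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file back into a `read_alignments` data.frame
#'
#' @param path SAM file path.
#' @param references named character vector; an alignment to a reference
#'   name absent from this set is an error.
#' @return a `read_alignments` data.frame (see [align_reads()]).
#' @export
read_sam <- function(path, references) {
  refs <- as_ref_vector(references)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  fields <- strsplit(body, "\t")
  rows <- lapply(fields, function(f) {
    if (length(f) < 11) stop("malformed SAM record")
    flag <- as.integer(f[2])
    mapped <- bitwAnd(flag, 4L) == 0L
    if (mapped && !(f[3] %in% names(refs)))
      stop(sprintf("unknown reference name in SAM: %s", f[3]))
    tags <- if (length(f) > 11) f[12:length(f)] else character(0)
    tagval <- function(name) {
      hit <- tags[startsWith(tags, name)]
      if (length(hit) == 0) return(NA_character_)
      sub(sprintf("^%s:[AifZ]:", name), "", hit[1])
    }
    if (!mapped) {
      return(data.frame(read_id = f[1], mapped = FALSE, target_id = NA_character_,
                        target_start = NA_integer_, target_end = NA_integer_,
                        strand = NA_character_, ops = NA_character_,
                        score = NA_integer_, mismatch_count = NA_integer_,
                        aligned_bases = NA_integer_, divergence = NA_real_,
                        ambiguity = NA_integer_, co_targets = NA_character_,
                        seq_oriented = f[10], stringsAsFactors = FALSE))
    }
    opdf <- parse_ops(f[6])[[1]]
    consumed_read <- sum(opdf$len[opdf$op %in% c("=", "X", "I", "M")])
    consumed_ref <- sum(opdf$len[opdf$op %in% c("=", "X", "D", "M")])
    mm <- sum(opdf$len[opdf$op %in% c("X", "I")])
    start0 <- as.integer(f[4]) - 1L
    data.frame(read_id = f[1], mapped = TRUE, target_id = f[3],
               target_start = start0, target_end = start0 + consumed_ref,
               strand = if (bitwAnd(flag, 16L) == 16L) "-" else "+",
               ops = f[6],
               score = as.integer(tagval("AS")), mismatch_count = mm,
               aligned_bases = consumed_read,
               divergence = mm / consumed_read,
               ambiguity = as.integer(tagval("X0")),
               co_targets = tagval("XT"),
               seq_oriented = f[10], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Best exhaustive alignment scores (oracle)
#'
#' Full-matrix dynamic programming over every target, strand and position
#' under the same scoring scheme as [align_reads()], with no seeding or
#' windowing.  Intended as an independent check of the seeded aligner on
#' small instances; quadratic in reference length.
#'
#' @param reads character vector or sequence data.frame.
#' @param references named character vector or sequence data.frame.
#' @return integer vector of best scores, one per read.
#' @export
oracle_alignment_scores <- function(reads, references) {
  if (is.data.frame(reads)) reads <- reads$seq
  refs <- as_ref_vector(references)
  cpp_oracle_scores(toupper(reads), unname(refs))
}
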