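# Assembly annotation: find TE-homologous fragments by seed-and-extend local
# alignment, score divergence and length, and build the degraded-fragment
# reference used by the piRNA analysis.

#' @noRd
local_hit <- function(contig_seq, query_seq, glo, ghi, qlo, qhi) {
  al <- cpp_local_align(substr(contig_seq, glo + 1, ghi),
                        substr(query_seq, qlo + 1, qhi))
  list(gstart = glo + al$a_start, gend = glo + al$a_end,
       qstart = qlo + al$b_start, qend = qlo + al$b_end,
       score = al$score, mismatches = al$mismatches, columns = al$columns)
}

#' Annotate TE-homologous fragments in an assembly
#'
#' Exact k-mer seeds between the consensus and each contig (both strands)
#' are clustered by diagonal; clusters reaching `min_seeds` seeds are
#' extended by local alignment, hits to the same consensus separated by less
#' than `merge_gap` on both sequences are merged, and divergence is
#' recomputed from the final alignment as mismatches over alignment columns
#' (terminal gaps excluded by the local alignment itself).
#'
#' The seed length default of 8 keeps fragments up to ~30\% diverged
#' detectable; larger seeds are faster but lose sensitivity at high
#' divergence.
#'
#' @param genome named character vector of contigs, or a `te_landscape`.
#' @param consensus consensus sequence (character scalar, optionally named).
#' @param k seed k-mer length.
#' @param min_score minimum local alignment score of a reported fragment.
#' @param min_len minimum reportable fragment length in bp.
#' @param merge_gap merge hits separated by less than this many bp on both
#'   the contig and the consensus.
#' @param min_seeds seeds required in a diagonal cluster before extension.
#' @param pad window padding around seed clusters in bp.
#' @param binwidth diagonal bin width for seed clustering.
#' @return data.frame of class `fragment_annotations`: `contig`, `start`,
#'   `end` (0-based half-open), `strand`, `length`, `divergence`,
#'   `cons_start`, `cons_end` (matched consensus interval), `score`.
#' @export
annotate_fragments <- function(genome, consensus, k = 8, min_score = 18,
                               min_len = 50, merge_gap = 50, min_seeds = 2,
                               pad = 80, binwidth = 64) {
  if (inherits(genome, "te_landscape")) genome <- genome$genome
  stopifnot(is.character(genome), length(genome) >= 1)
  if (is.null(names(genome))) names(genome) <- sprintf("contig_%d", seq_along(genome))
  consensus <- toupper(as.character(consensus)[1])
  if (nchar(consensus) == 0 || sum(nchar(genome)) == 0)
    stop("genome and consensus must be nonempty")
  L <- nchar(consensus)
  queries <- c("+" = consensus, "-" = revcomp(consensus))

  hits <- list()
  for (cn in names(genome)) {
    cseq <- toupper(genome[[cn]])
    for (st in c("+", "-")) {
      cands <- cpp_seed_candidates(cseq, queries[[st]], as.integer(k),
                                   as.integer(binwidth), as.integer(min_seeds),
                                   as.integer(pad))
      if (nrow(cands) == 0) next
      for (i in seq_len(nrow(cands))) {
        h <- local_hit(cseq, queries[[st]], cands$glo[i], cands$ghi[i],
                       cands$qlo[i], cands$qhi[i])
        if (h$score <= 0) next
        # map query coordinates back to consensus forward coordinates
        if (st == "+") { cs <- h$qstart; ce <- h$qend }
        else { cs <- L - h$qend; ce <- L - h$qstart }
        hits[[length(hits) + 1]] <- data.frame(
          contig = cn, start = h$gstart, end = h$gend, strand = st,
          cons_start = cs, cons_end = ce, score = h$score,
          mismatches = h$mismatches, columns = h$columns,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), divergence = numeric(0),
                      cons_start = integer(0), cons_end = integer(0),
                      score = integer(0))
  class(empty) <- c("fragment_annotations", "data.frame")
  if (length(hits) == 0) return(empty)
  hits <- do.call(rbind, hits)

  # merge nearby hits per contig/strand, then re-align the merged window
  merged <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    g <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    cur <- g[1, , drop = FALSE]
    flush <- function(cur) merged[[length(merged) + 1]] <<- cur
    for (i in seq_len(nrow(g))[-1]) {
      ggap <- g$start[i] - cur$end
      cgap <- if (g$strand[i] == "+") g$cons_start[i] - cur$cons_end
      else cur$cons_start - g$cons_end[i]
      if (ggap < merge_gap && abs(cgap) < merge_gap) {
        cur$end <- max(cur$end, g$end[i])
        cur$start <- min(cur$start, g$start[i])
        cur$cons_start <- min(cur$cons_start, g$cons_start[i])
        cur$cons_end <- max(cur$cons_end, g$cons_end[i])
        cur$merged <- TRUE
      } else { flush(cur); cur <- g[i, , drop = FALSE]; cur$merged <- FALSE }
    }
    flush(cur)
  }
  out <- list()
  for (m in merged) {
    if (!is.null(m$merged) && isTRUE(m$merged)) {
      cseq <- toupper(genome[[m$contig]])
      if (m$strand == "+") { qlo <- m$cons_start; qhi <- m$cons_end }
      else { qlo <- L - m$cons_end; qhi <- L - m$cons_start }
      h <- local_hit(cseq, queries[[m$strand]], m$start, m$end, qlo, qhi)
      if (m$strand == "+") { cs <- h$qstart; ce <- h$qend }
      else { cs <- L - h$qend; ce <- L - h$qstart }
      m <- data.frame(contig = m$contig, start = h$gstart, end = h$gend,
                      strand = m$strand, cons_start = cs, cons_end = ce,
                      score = h$score, mismatches = h$mismatches,
                      columns = h$columns, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- m[, c("contig", "start", "end", "strand",
                                    "cons_start", "cons_end", "score",
                                    "mismatches", "columns")]
  }
  out <- do.call(rbind, out)
  out$length <- out$end - out$start
  out$divergence <- ifelse(out$columns > 0, out$mismatches / out$columns, NA)
  out <- out[out$score >= min_score & out$length >= min_len, , drop = FALSE]
  # suppress redundant sub-hits: greedily keep the best-scoring hit among
  # genome intervals overlapping a kept hit by >= 50% of the shorter one
  if (nrow(out) > 1) {
    out <- out[order(-out$score, out$start), , drop = FALSE]
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      ov <- FALSE
      for (j in which(keep & out$contig == out$contig[i])) {
        inter <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
        if (inter >= 0.5 * min(out$length[i], out$length[j])) { ov <- TRUE; break }
      }
      keep[i] <- !ov
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$contig, out$start),
             c("contig", "start", "end", "strand", "length", "divergence",
               "cons_start", "cons_end", "score")]
  rownames(out) <- NULL
  class(out) <- c("fragment_annotations", "data.frame")
  out
}

#' Extract the degraded-fragment reference
#'
#' Selects annotated fragments with divergence above `min_div` and length of
#' at least `min_len`, extracts their genomic sequence and
#' reverse-complements minus-strand fragments, yielding a multi-FASTA-ready
#' set usable as an alignment target for degraded-TE piRNAs.
#'
#' @param annotations a [annotate_fragments()] table.
#' @param genome named character vector of contigs (or a `te_landscape`).
#' @param min_div strict divergence lower bound (fragments with divergence
#'   `> min_div` are kept).
#' @param min_len inclusive length lower bound in bp (a 100 bp fragment is
#'   kept under the default).
#' @return named character vector of fragment sequences (names
#'   `contig:start-end(strand)`).
#' @export
extract_degraded_reference <- function(annotations, genome, min_div = 0.10,
                                       min_len = 100) {
  if (inherits(genome, "te_landscape")) genome <- genome$genome
  keep <- annotations[!is.na(annotations$divergence) &
                        annotations$divergence > min_div &
                        annotations$length >= min_len, , drop = FALSE]
  if (nrow(keep) == 0) return(setNames(character(0), character(0)))
  seqs <- vapply(seq_len(nrow(keep)), function(i) {
    cn <- keep$contig[i]
    if (!cn %in% names(genome)) stop("annotation refers to unknown contig: ", cn)
    if (keep$end[i] > nchar(genome[[cn]]) || keep$start[i] < 0)
      stop("annotation out of contig bounds")
    s <- substr(genome[[cn]], keep$start[i] + 1, keep$end[i])
    if (keep$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(seqs, sprintf("%s:%d-%d(%s)", keep$contig, keep$start, keep$end,
                         keep$strand))
}

#' Write fragment annotations as BED-compatible TSV
#'
#' Standard six BED columns (score is `int(divergence * 1000)`) plus the
#' extended columns of the annotation table.
#'
#' @param annotations a [annotate_fragments()] table.
#' @param path output path.
#' @param name feature name for column 4 (e.g. the TE family).
#' @export
write_fragment_bed <- function(annotations, path, name = "TE") {
  bed <- data.frame(annotations$contig, annotations$start, annotations$end,
                    name, as.integer(annotations$divergence * 1000),
                    annotations$strand,
                    annotations$length, annotations$divergence,
                    annotations$cons_start, annotations$cons_end)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
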