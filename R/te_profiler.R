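# Consensus-space TE profiling: coverage, variants, internal deletions,
# copy number normalized to single-copy genes, and reads-per-million.

#' @noRd
family_alignments <- function(alignments, target) {
  stopifnot(inherits(alignments, "data.frame"))
  alignments[!is.na(alignments$mapped) & alignments$mapped &
               alignments$target_id == target, , drop = FALSE]
}

#' @noRd
run_pileup <- function(aln, consensus, arc_min = 20L) {
  cpp_pileup(as.integer(aln$target_start), aln$ops, aln$seq_oriented,
             as.integer(aln$ambiguity), nchar(consensus), as.integer(arc_min))
}

#' Per-position coverage along a consensus
#'
#' Depth counts aligned read bases per consensus position, split into
#' uniquely (ambiguity 1) and ambiguously (ambiguity > 1) mapped reads.
#' Reference positions skipped by a deletion operation do not add depth;
#' they feed the deletion detector instead.
#'
#' @param alignments `read_alignments` rows; if `family` is given, rows are
#'   first subset to that target.
#' @param consensus the consensus sequence (character scalar).
#' @param family optional target id used to subset `alignments`.
#' @return data.frame: `position` (0-based), `unique_depth`,
#'   `ambiguous_depth`, `total_depth`.
#' @export
compute_coverage <- function(alignments, consensus, family = NULL) {
  if (!is.null(family)) alignments <- family_alignments(alignments, family)
  else alignments <- alignments[alignments$mapped, , drop = FALSE]
  L <- nchar(consensus)
  if (nrow(alignments) == 0)
    return(data.frame(position = seq_len(L) - 1L, unique_depth = 0L,
                      ambiguous_depth = 0L, total_depth = 0L))
  p <- run_pileup(alignments, consensus)
  data.frame(position = seq_len(L) - 1L,
             unique_depth = p$depth_unique,
             ambiguous_depth = p$depth_total - p$depth_unique,
             total_depth = p$depth_total)
}

#' Call variants along a consensus from aligned reads
#'
#' Per-site allele counts (A/C/G/T plus small deletions shorter than
#' `arc_min`) are accumulated from read bases; allele frequency at a site is
#' count over the site total, so a site where 14 copies carry "A" and 6 a
#' "T" has frequency 0.7 for A.  A site is flagged as a SNP when a
#' non-consensus base reaches both `min_count` and `min_freq`.
#'
#' @inheritParams compute_coverage
#' @param min_count,min_freq SNP thresholds on the non-consensus allele.
#' @param arc_min deletions at least this long are left to
#'   [detect_deletions()] instead of being counted per site.
#' @return data.frame: `position` (0-based), `consensus_base`, `A`, `C`,
#'   `G`, `T`, `del`, `total`, `snp`.  Zero-depth sites have `total` 0 and
#'   undefined frequencies.
#' @export
call_variants <- function(alignments, consensus, family = NULL,
                          min_count = 2, min_freq = 0.1, arc_min = 20L) {
  if (!is.null(family)) alignments <- family_alignments(alignments, family)
  else alignments <- alignments[alignments$mapped, , drop = FALSE]
  L <- nchar(consensus)
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (nrow(alignments) == 0) {
    cnt <- matrix(0L, 5, L)
  } else {
    cnt <- run_pileup(alignments, consensus, arc_min = arc_min)$counts
  }
  tot <- colSums(cnt)
  base_rows <- cnt[1:4, , drop = FALSE]
  rownames(base_rows) <- c("A", "C", "G", "T")
  cons_idx <- match(cons, c("A", "C", "G", "T"))
  snp <- logical(L)
  for (b in 1:4) {
    is_alt <- is.na(cons_idx) | cons_idx != b
    freq <- ifelse(tot > 0, base_rows[b, ] / tot, 0)
    snp <- snp | (is_alt & base_rows[b, ] >= min_count & freq >= min_freq)
  }
  data.frame(position = seq_len(L) - 1L, consensus_base = cons,
             A = base_rows[1, ], C = base_rows[2, ], G = base_rows[3, ],
             T = base_rows[4, ], del = cnt[5, ], total = as.integer(tot),
             snp = snp)
}

#' Allele frequencies from a variant table
#'
#' @param variants a [call_variants()] table.
#' @return numeric matrix (4 x positions) of A/C/G/T frequencies; columns at
#'   zero-depth sites are `NaN`.
#' @export
allele_frequencies <- function(variants) {
  m <- t(as.matrix(variants[, c("A", "C", "G", "T")]))
  sweep(m, 2, variants$total, "/")
}

#' Detect large internal deletions
#'
#' Deletion operations at least `min_len` long are aggregated by identical
#' breakpoints.  The frequency of an arc contrasts supporting reads with
#' reads crossing the deletion breakpoints without the gap: deletions are
#' typically longer than a read, so the gap-free evidence is the number of
#' reads aligned contiguously across each junction, averaged over the two
#' breakpoints, and `frequency = support / (support + crossing)`.
#'
#' @inheritParams compute_coverage
#' @param min_len minimum deletion length reported as an arc (shorter
#'   deletions are per-site indels in the variant table).
#' @return data.frame: `start`, `end` (0-based half-open on the consensus),
#'   `support`, `spanning` (mean gap-free junction-crossing reads),
#'   `frequency`.
#' @export
detect_deletions <- function(alignments, consensus, family = NULL,
                             min_len = 20L) {
  if (!is.null(family)) alignments <- family_alignments(alignments, family)
  else alignments <- alignments[alignments$mapped, , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      support = integer(0), spanning = numeric(0),
                      frequency = numeric(0))
  if (nrow(alignments) == 0) return(empty)
  p <- run_pileup(alignments, consensus, arc_min = min_len)
  arcs <- p$arcs
  if (nrow(arcs) == 0) return(empty)

  # lazily computed aligned (non-deleted) target intervals per read
  iv_cache <- vector("list", nrow(alignments))
  aligned_ivs <- function(i) {
    if (!is.null(iv_cache[[i]])) return(iv_cache[[i]])
    opdf <- parse_ops(alignments$ops[i])[[1]]
    tp <- alignments$target_start[i]
    rows <- list()
    for (r in seq_len(nrow(opdf))) {
      op <- opdf$op[r]; len <- opdf$len[r]
      if (op %in% c("=", "X", "M")) {
        rows[[length(rows) + 1]] <- c(tp, tp + len)
        tp <- tp + len
      } else if (op == "D") tp <- tp + len
    }
    iv <- do.call(rbind, rows)
    iv_cache[[i]] <<- iv
    iv
  }
  aligned_at <- function(i, pos) {
    iv <- aligned_ivs(i)
    any(iv[, 1] <= pos & iv[, 2] > pos)
  }
  crossing <- function(junction, supporters) {
    if (junction <= 0 || junction >= nchar(consensus)) return(NA_real_)
    cand <- which(p$span_start <= junction - 1L & p$span_end >= junction + 1L)
    cand <- setdiff(cand, supporters)
    sum(vapply(cand, function(i)
      aligned_at(i, junction - 1L) && aligned_at(i, junction), logical(1)))
  }

  key <- paste(arcs$start, arcs$end, sep = ":")
  out <- do.call(rbind, lapply(split(arcs, key), function(g) {
    s <- g$start[1]; e <- g$end[1]
    cl <- crossing(s, g$aln)
    cr <- crossing(e, g$aln)
    spanning <- mean(c(cl, cr), na.rm = TRUE)
    if (is.nan(spanning)) spanning <- 0
    support <- nrow(g)
    data.frame(start = s, end = e, support = support, spanning = spanning,
               frequency = support / (support + spanning))
  }))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate TE copy number per haploid genome
#'
#' Contrasts TE consensus coverage with single-copy gene coverage: the mean
#' total depth over the whole consensus divided by the mean over genes of
#' each gene's median depth.  Genes with zero coverage are excluded with a
#' warning; if all genes lack coverage, normalization fails.
#'
#' @param te_coverage a [compute_coverage()] table for the TE consensus.
#' @param gene_coverages named list of [compute_coverage()] tables, one per
#'   single-copy gene.
#' @return copies per haploid genome (numeric scalar).
#' @export
estimate_copy_number <- function(te_coverage, gene_coverages) {
  stopifnot(length(gene_coverages) >= 1)
  meds <- vapply(gene_coverages, function(g) median(g$total_depth), numeric(1))
  zero <- meds == 0
  if (all(zero)) stop("all single-copy genes have zero coverage; cannot normalize")
  if (any(zero))
    warning(sprintf("excluding zero-coverage gene(s): %s",
                    paste(names(gene_coverages)[zero], collapse = ", ")))
  mean(te_coverage$total_depth) / mean(meds[!zero])
}

#' Reads per million mapped reads
#'
#' @param family_read_count reads (possibly fractional) assigned to the
#'   family.
#' @param total_mapped_reads total mapped reads in the run.
#' @return rpm (numeric scalar).
#' @export
compute_rpm <- function(family_read_count, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop("total mapped read count must be positive")
  family_read_count * 1e6 / total_mapped_reads
}

#' Build a per-family TE profile for one strain
#'
#' Combines coverage, variant calls, deletion arcs, copy number (total and
#' restricted to low-divergence reads), rpm and summary statistics for one TE
#' family.  Reads with divergence below `lowdiv_cut` define the
#' canonical-supporting subset: `canonical_copy_number` and
#' `covered_fraction_lowdiv` are recomputed from them alone.  Ambiguous reads
#' contribute fractionally (1/ambiguity) to the rpm read count and with full
#' weight to coverage.
#'
#' @param alignments `read_alignments` against the combined reference
#'   (TE consensus sequences plus single-copy genes).
#' @param family TE family id (a name of `te_library`).
#' @param te_library named character vector of TE consensus sequences.
#' @param genes named character vector of single-copy gene sequences.
#' @param lowdiv_cut read-divergence cut separating canonical-supporting
#'   reads (default 0.10, the silencing-relevance boundary).
#' @param arc_min,snp_min_count,snp_min_freq see [detect_deletions()] and
#'   [call_variants()].
#' @return an object of class `te_profile`.
#' @export
build_te_profile <- function(alignments, family, te_library, genes,
                             lowdiv_cut = 0.10, arc_min = 20L,
                             snp_min_count = 2, snp_min_freq = 0.1) {
  te_library <- as_ref_vector(te_library)
  genes <- as_ref_vector(genes)
  if (!family %in% names(te_library)) stop("unknown TE family: ", family)
  consensus <- te_library[[family]]
  fam <- family_alignments(alignments, family)

  coverage <- compute_coverage(fam, consensus)
  variants <- call_variants(fam, consensus, min_count = snp_min_count,
                            min_freq = snp_min_freq, arc_min = arc_min)
  deletions <- detect_deletions(fam, consensus, min_len = arc_min)
  gene_covs <- lapply(names(genes), function(g)
    compute_coverage(family_alignments(alignments, g), genes[[g]]))
  names(gene_covs) <- names(genes)

  copy_number <- if (nrow(fam) == 0) {
    # still validate gene normalization
    estimate_copy_number(coverage, gene_covs) * 0
  } else estimate_copy_number(coverage, gene_covs)

  low <- fam[fam$divergence < lowdiv_cut, , drop = FALSE]
  cov_low <- compute_coverage(low, consensus)
  canonical_copy_number <- if (nrow(low) == 0) 0 else
    suppressWarnings(estimate_copy_number(cov_low, gene_covs))

  n_mapped_total <- sum(alignments$mapped, na.rm = TRUE)
  fam_count <- if (nrow(fam) == 0) 0 else sum(1 / fam$ambiguity)
  rpm <- if (n_mapped_total > 0) compute_rpm(fam_count, n_mapped_total) else 0

  out <- list(family = family,
              coverage = coverage,
              variants = variants,
              deletions = deletions,
              gene_coverages = gene_covs,
              copy_number = copy_number,
              canonical_copy_number = canonical_copy_number,
              rpm = rpm,
              family_read_count = fam_count,
              total_mapped_reads = n_mapped_total,
              mean_read_divergence = if (nrow(fam)) mean(fam$divergence) else NA_real_,
              covered_fraction = mean(coverage$total_depth > 0),
              covered_fraction_lowdiv = mean(cov_low$total_depth > 0),
              lowdiv_cut = lowdiv_cut)
  class(out) <- "te_profile"
  out
}

#' @export
print.te_profile <- function(x, ...) {
  cat(sprintf("TE profile: %s\n", x$family))
  cat(sprintf("  copy number           %.2f (canonical: %.2f)\n",
              x$copy_number, x$canonical_copy_number))
  cat(sprintf("  rpm                   %.1f\n", x$rpm))
  cat(sprintf("  covered fraction      %.2f (low-divergence: %.2f)\n",
              x$covered_fraction, x$covered_fraction_lowdiv))
  cat(sprintf("  mean read divergence  %s\n",
              ifelse(is.na(x$mean_read_divergence), "NA",
                     sprintf("%.3f", x$mean_read_divergence))))
  cat(sprintf("  SNP sites             %d; deletion arcs: %d\n",
              sum(x$variants$snp), nrow(x$deletions)))
  invisible(x)
}

#' Write a TE profile as tidy TSVs
#'
#' One row per consensus position (depths and allele counts) plus a one-row
#' family summary.
#'
#' @param profile a `te_profile`.
#' @param prefix output path prefix; writes `<prefix>_positions.tsv` and
#'   `<prefix>_summary.tsv`.
#' @export
write_te_profile <- function(profile, prefix) {
  pos <- cbind(family = profile$family,
               merge(profile$coverage, profile$variants, by = "position"))
  write.table(pos, paste0(prefix, "_positions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- data.frame(family = profile$family,
                     copy_number = profile$copy_number,
                     canonical_copy_number = profile$canonical_copy_number,
                     rpm = profile$rpm,
                     mean_read_divergence = profile$mean_read_divergence,
                     covered_fraction = profile$covered_fraction,
                     covered_fraction_lowdiv = profile$covered_fraction_lowdiv)
  write.table(summ, paste0(prefix, "_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
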