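# Cross-strain TE composition: SNP frequency matrix, arcsine-square-root
# PCA, pairwise FST and a neighbor-joining tree.

#' Build a strains-by-sites allele frequency matrix
#'
#' The site universe is the union over strains of flagged SNP alleles
#' (non-consensus bases reaching `min_count` and `min_freq` in at least one
#' strain).  Each cell holds that strain's frequency of the site allele
#' (zero when the site is covered but the allele absent); cells with
#' coverage below `min_support` are missing.  Strains without any coverage
#' of the family are excluded with a warning, mirroring families absent
#' from many samples for which frequencies cannot be calculated.
#'
#' @param variant_tables named list of [call_variants()] tables (one strain
#'   each, same consensus).
#' @param min_support minimum site coverage for a non-missing cell.
#' @param min_count,min_freq SNP allele thresholds (applied per strain when
#'   building the site universe).
#' @return list of class `frequency_matrix`: `freq` (strains x sites,
#'   `NA` = missing), `support` (coverage), `sites` (data.frame: position,
#'   allele, consensus_base).
#' @export
build_frequency_matrix <- function(variant_tables, min_support = 5,
                                   min_count = 2, min_freq = 0.1) {
  if (length(variant_tables) < 2) stop("need at least 2 strains")
  if (is.null(names(variant_tables))) stop("variant_tables must be named by strain")
  covered <- vapply(variant_tables, function(v) sum(v$total) > 0, logical(1))
  if (any(!covered))
    warning(sprintf("excluding strain(s) without family coverage: %s",
                    paste(names(variant_tables)[!covered], collapse = ", ")))
  variant_tables <- variant_tables[covered]
  if (length(variant_tables) < 2) stop("fewer than 2 strains with coverage")

  bases <- c("A", "C", "G", "T")
  site_keys <- character(0)
  site_rows <- list()
  for (v in variant_tables) {
    for (b in bases) {
      cnt <- v[[b]]
      freq <- ifelse(v$total > 0, cnt / v$total, 0)
      hit <- which(v$consensus_base != b & cnt >= min_count & freq >= min_freq)
      for (i in hit) {
        key <- sprintf("%d_%s", v$position[i], b)
        if (!key %in% site_keys) {
          site_keys <- c(site_keys, key)
          site_rows[[key]] <- data.frame(position = v$position[i], allele = b,
                                         consensus_base = v$consensus_base[i],
                                         stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(site_keys) == 0) stop("no SNP sites found across strains")
  sites <- do.call(rbind, site_rows[site_keys])
  ord <- order(sites$position, sites$allele)
  sites <- sites[ord, , drop = FALSE]
  site_keys <- site_keys[ord]
  rownames(sites) <- NULL

  strains <- names(variant_tables)
  freq <- matrix(NA_real_, length(strains), nrow(sites),
                 dimnames = list(strains, site_keys))
  support <- matrix(0L, length(strains), nrow(sites),
                    dimnames = list(strains, site_keys))
  for (s in strains) {
    v <- variant_tables[[s]]
    idx <- match(sites$position, v$position)
    tot <- v$total[idx]
    cnt <- vapply(seq_len(nrow(sites)),
                  function(j) v[[sites$allele[j]]][idx[j]], numeric(1))
    f <- ifelse(tot >= min_support, cnt / tot, NA_real_)
    freq[s, ] <- f
    support[s, ] <- tot
  }
  out <- list(freq = freq, support = support, sites = sites)
  class(out) <- "frequency_matrix"
  out
}

#' @noRd
complete_case_matrix <- function(x) {
  if (inherits(x, "frequency_matrix")) x <- x$freq
  stopifnot(is.matrix(x))
  keep <- colSums(is.na(x)) == 0
  if (any(!keep))
    message(sprintf("dropping %d site(s) with missing cells (complete-case)",
                    sum(!keep)))
  x[, keep, drop = FALSE]
}

#' Arcsine square root transform
#'
#' The variance-stabilizing transform `asin(sqrt(x))` applied to allele
#' frequencies before PCA: 0 maps to 0, 1 to pi/2, 0.25 to pi/6.
#'
#' @param x numeric vector/matrix of frequencies in `[0, 1]`.
#' @return transformed values.
#' @export
arcsine_sqrt_transform <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
  asin(sqrt(x))
}

#' Arcsine-square-root transformed PCA of allele frequencies
#'
#' Each frequency is transformed as `asin(sqrt(x))`, columns are centered
#' (not variance-scaled) and principal components obtained by singular value
#' decomposition.  Sites with missing cells are dropped (complete-case).
#'
#' @param x a `frequency_matrix` or a strains-by-sites numeric matrix.
#' @return list: `scores` (strains x PCs), `loadings`,
#'   `variance_fraction` (sums to 1), `constant` (`TRUE` when the matrix
#'   carries no variance, in which case fractions are zero).
#' @export
transform_and_pca <- function(x) {
  m <- complete_case_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 1) stop("need >= 2 strains and >= 1 site")
  t <- arcsine_sqrt_transform(m)
  p <- prcomp(t, center = TRUE, scale. = FALSE)
  tv <- sum(p$sdev^2)
  if (tv <= .Machine$double.eps) {
    return(list(scores = p$x, loadings = p$rotation,
                variance_fraction = rep(0, length(p$sdev)), constant = TRUE))
  }
  list(scores = p$x, loadings = p$rotation,
       variance_fraction = p$sdev^2 / tv, constant = FALSE)
}

#' Pairwise FST between strains from pooled allele frequencies
#'
#' Classical per-site estimator: with pooled frequencies `p1`, `p2` at a
#' site, `pi_within = mean(2 p1 (1 - p1), 2 p2 (1 - p2))`,
#' `pi_total = 2 pbar (1 - pbar)` with `pbar = (p1 + p2) / 2`, and site FST
#' `(pi_total - pi_within) / pi_total` (0 where `pi_total` is 0).  The
#' window FST is the mean over sites of one window spanning the whole
#' consensus.
#'
#' @param x a `frequency_matrix` or strains-by-sites matrix (complete-case
#'   applied).
#' @return symmetric strains-by-strains matrix of FST values with zero
#'   diagonal.
#' @export
pairwise_fst <- function(x) {
  m <- complete_case_matrix(x)
  if (ncol(m) < 1) stop("no shared covered SNP sites")
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p1 <- m[i, ]; p2 <- m[j, ]
      piw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
      pbar <- (p1 + p2) / 2
      pit <- 2 * pbar * (1 - pbar)
      fst <- ifelse(pit > 0, (pit - piw) / pit, 0)
      out[i, j] <- out[j, i] <- mean(fst)
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}) with negative branch lengths
#' clamped to zero; strains are ordered by name before tree construction so
#' ties break deterministically.
#'
#' @param d symmetric distance matrix (e.g. from [pairwise_fst()]) with at
#'   least 3 strains and no missing entries.
#' @return an \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("need at least 3 strains for a tree")
  if (anyNA(d))
    stop("distance matrix has missing entries; apply complete-case filtering first")
  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
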