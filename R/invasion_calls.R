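# Three-category strain classification (absent / degraded_only / canonical)
# and invasion-window inference over dated strains.

#' Classification thresholds
#'
#' Operational thresholds formalizing the three-category strain
#' classification: a family is called absent below `absent_max_copies`
#' copies; canonical when at least `canonical_min_copies` copies are
#' supported by low-divergence reads that cover at least
#' `canonical_min_covered` of the consensus; otherwise only degraded copies
#' are present.  The read-divergence cut separating canonical-supporting
#' reads lives in the profile (see [build_te_profile()], default 0.10).
#'
#' @param absent_max_copies copy-number floor below which the family is
#'   called absent.
#' @param canonical_min_copies minimum copy number recomputed from
#'   low-divergence reads.
#' @param canonical_min_covered minimum fraction of the consensus covered by
#'   low-divergence reads.
#' @return a list of thresholds.
#' @export
classification_thresholds <- function(absent_max_copies = 0.2,
                                      canonical_min_copies = 0.5,
                                      canonical_min_covered = 0.8) {
  list(absent_max_copies = absent_max_copies,
       canonical_min_copies = canonical_min_copies,
       canonical_min_covered = canonical_min_covered)
}

#' Classify a strain's TE content
#'
#' Applies the three-category rule to a [build_te_profile()] result and
#' records the evidence so every call is recomputable.
#'
#' @param profile a `te_profile`.
#' @param thresholds a [classification_thresholds()] list.
#' @param strain strain name.
#' @param sampling_year integer sampling year, or `NA` when unknown.
#' @return one-row data.frame: `strain`, `family`, `category` (one of
#'   `absent`, `degraded_only`, `canonical`), `sampling_year` and the
#'   evidence columns (`copy_number`, `canonical_copy_number`,
#'   `covered_fraction`, `covered_fraction_lowdiv`,
#'   `mean_read_divergence`).
#' @export
classify_strain <- function(profile, thresholds = classification_thresholds(),
                            strain = NA_character_, sampling_year = NA_integer_) {
  stopifnot(inherits(profile, "te_profile"))
  category <- if (profile$copy_number < thresholds$absent_max_copies) {
    "absent"
  } else if (profile$canonical_copy_number >= thresholds$canonical_min_copies &&
             profile$covered_fraction_lowdiv >= thresholds$canonical_min_covered) {
    "canonical"
  } else "degraded_only"
  data.frame(strain = strain, family = profile$family, category = category,
             sampling_year = as.integer(sampling_year),
             copy_number = profile$copy_number,
             canonical_copy_number = profile$canonical_copy_number,
             covered_fraction = profile$covered_fraction,
             covered_fraction_lowdiv = profile$covered_fraction_lowdiv,
             mean_read_divergence = profile$mean_read_divergence,
             stringsAsFactors = FALSE)
}

#' Infer an invasion window from dated strain calls
#'
#' `first_canonical_year` is the earliest sampling year among canonical
#' strains; `all_canonical_year` is the earliest canonical sampling year
#' strictly greater than every non-canonical strain's year (i.e. the first
#' sampled year from which every dated strain carries canonical copies).
#' Dated non-canonical strains sampled at or after `first_canonical_year`
#' violate the step-function expectation and are listed as discordant (the
#' stock-contamination case).  Strains without a year are classified but
#' excluded from window inference and listed separately.
#'
#' @param calls data.frame of [classify_strain()] rows (one family).
#' @param family optional family filter.
#' @return list of class `invasion_window`: `family`,
#'   `first_canonical_year`, `all_canonical_year`, `discordant_strains`,
#'   `undated_strains`, `status` (one of `invaded`, `not_detected`,
#'   `always_present`).
#' @export
infer_invasion_window <- function(calls, family = NULL) {
  if (!is.null(family)) calls <- calls[calls$family == family, , drop = FALSE]
  if (length(unique(calls$family)) > 1)
    stop("calls span multiple families; pass `family`")
  fam <- if (nrow(calls)) calls$family[1] else NA_character_
  undated <- calls$strain[is.na(calls$sampling_year)]
  dated <- calls[!is.na(calls$sampling_year), , drop = FALSE]
  if (nrow(dated) == 0) stop("no dated strains; cannot infer an invasion window")

  canon <- dated[dated$category == "canonical", , drop = FALSE]
  noncanon <- dated[dated$category != "canonical", , drop = FALSE]

  if (nrow(canon) == 0) {
    out <- list(family = fam, first_canonical_year = NA_integer_,
                all_canonical_year = NA_integer_,
                discordant_strains = character(0),
                undated_strains = undated, status = "not_detected")
  } else if (nrow(noncanon) == 0) {
    y <- min(canon$sampling_year)
    out <- list(family = fam, first_canonical_year = y,
                all_canonical_year = y, discordant_strains = character(0),
                undated_strains = undated, status = "always_present")
  } else {
    first <- min(canon$sampling_year)
    later <- canon$sampling_year[canon$sampling_year > max(noncanon$sampling_year)]
    all_year <- if (length(later)) min(later) else NA_integer_
    disc <- noncanon$strain[noncanon$sampling_year >= first]
    out <- list(family = fam, first_canonical_year = first,
                all_canonical_year = all_year,
                discordant_strains = disc, undated_strains = undated,
                status = "invaded")
  }
  class(out) <- "invasion_window"
  out
}

#' @export
print.invasion_window <- function(x, ...) {
  cat(sprintf("Invasion window for %s: %s\n", x$family, x$status))
  cat(sprintf("  first canonical year  %s\n", x$first_canonical_year))
  cat(sprintf("  all canonical from    %s\n", x$all_canonical_year))
  if (length(x$discordant_strains))
    cat("  discordant strains:  ", paste(x$discordant_strains, collapse = ", "), "\n")
  if (length(x$undated_strains))
    cat("  undated strains:     ", paste(x$undated_strains, collapse = ", "), "\n")
  invisible(x)
}

#' Read a strain metadata table
#'
#' @param path TSV with columns `strain`, `year`, `origin` (year may be
#'   empty/NA for undated strains).
#' @return data.frame.
#' @export
read_strain_metadata <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "year")
  if (!all(need %in% names(m)))
    stop("strain metadata must have columns strain, year (and optionally origin)")
  m$year <- suppressWarnings(as.integer(m$year))
  m
}
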