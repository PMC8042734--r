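#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plant `round(divergence * nchar)` substitutions at distinct positions;
# returns the mutated sequence with the realized divergence as an attribute.
#' @noRd
mutate_seq <- function(seq, divergence) {
  len <- nchar(seq)
  nsub <- round(divergence * len)
  if (nsub == 0) {
    attr(seq, "divergence") <- 0
    return(seq)
  }
  pos <- sample.int(len, nsub)
  off <- sample.int(3, nsub, replace = TRUE)
  out <- cpp_apply_subs(seq, list(pos), list(off))
  attr(out, "divergence") <- nsub / len
  out
}

# Parse run-length operation strings ("95=1X4=") into (length, op) pairs.
#' @noRd
parse_ops <- function(ops) {
  lens <- regmatches(ops, gregexpr("[0-9]+", ops))
  chars <- regmatches(ops, gregexpr("[=XIDM]", ops))
  Map(function(l, o) data.frame(len = as.integer(l), op = o,
                                stringsAsFactors = FALSE),
      lens, chars)
}

# Coerce a references argument (named character vector, or a data.frame from
# read_sequences) to a named character vector.
#' @noRd
as_ref_vector <- function(references) {
  if (is.data.frame(references)) {
    refs <- setNames(toupper(references$seq), references$id)
  } else if (is.character(references)) {
    refs <- toupper(references)
  } else stop("references must be a named character vector or a sequence data.frame")
  if (length(refs) == 0) stop("references must be nonempty")
  if (is.null(names(refs)) || anyNA(names(refs)) || any(names(refs) == ""))
    stop("all references must be named")
  if (anyDuplicated(names(refs))) stop("reference ids must be unique")
  refs
}
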