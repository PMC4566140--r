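# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
normalize_dna <- function(x) {
  chartr("acgtun", "ACGTTN", chartr("U", "T", toupper(x)))
}

#' @noRd
to_rna <- function(x) chartr("T", "U", toupper(x))

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings (ungapped).
#' @noRd
hamming <- function(a, b) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

#' @noRd
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot() with a formatted message
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
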