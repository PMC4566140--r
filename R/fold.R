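#' Folding energy model parameters
#'
#' The folding engine minimizes the energy of a single stem-loop (a ladder
#' of nested pairs; no multibranch loops) under a simplified
#' nearest-neighbor model: stacking two adjacent pairs is rewarded by pair
#' type, loops are penalised by kind independent of size, and hairpin loops
#' must hold at least `min_loop` unpaired bases. Only Watson-Crick and G:U
#' pairs are allowed. All energies are in kcal/mol.
#'
#' @param stack_wc Stack bonus when both pairs are Watson-Crick (default -2.0).
#' @param stack_wc_gu Stack bonus for a WC/G:U stack (default -1.0).
#' @param stack_gu Stack bonus for a G:U/G:U stack (default -0.5).
#' @param hairpin Hairpin loop penalty (default +3.0).
#' @param bulge Bulge loop penalty (default +2.0).
#' @param internal Internal loop penalty (default +1.5).
#' @param min_loop Minimum hairpin loop size in nt (default 3).
#' @param max_loop Maximum unpaired run on either side of an interior step
#'   (default 30; bounds the dynamic program).
#' @return A `fold_config` list.
#' @export
fold_config <- function(stack_wc = -2.0, stack_wc_gu = -1.0, stack_gu = -0.5,
                        hairpin = 3.0, bulge = 2.0, internal = 1.5,
                        min_loop = 3L, max_loop = 30L) {
  structure(list(stack_wc = stack_wc, stack_wc_gu = stack_wc_gu,
                 stack_gu = stack_gu, hairpin = hairpin, bulge = bulge,
                 internal = internal, min_loop = as.integer(min_loop),
                 max_loop = as.integer(max_loop)),
            class = "fold_config")
}

#' Fold an RNA sequence into its minimum-energy stem-loop
#'
#' Deterministic dynamic program over single-stem nested structures under
#' the [fold_config()] energy model. The empty structure scores 0, so the
#' reported minimum free energy is never positive.
#'
#' @param sequence RNA (or DNA; `T` is read as `U`) string, 10-400 nt.
#' @param config Energy model from [fold_config()].
#' @return List of class `fold_result`: `sequence` (RNA), `structure`
#'   (dot-bracket) and `mfe` (kcal/mol, <= 0).
#' @examples
#' fold_rna("GGGGAAAACCCC")
#' @export
fold_rna <- function(sequence, config = fold_config()) {
  rna <- to_rna(sequence)
  n <- nchar(rna)
  assert_that(n >= 10 && n <= 400,
              sprintf("sequence length %d outside the supported 10-400 nt", n))
  assert_that(grepl("^[ACGU]+$", rna), "sequence must be over {A,C,G,U/T}")
  res <- .fold_stem(rna, config$stack_wc, config$stack_wc_gu, config$stack_gu,
                    config$hairpin, config$bulge, config$internal,
                    config$min_loop, config$max_loop)
  structure(list(sequence = rna, structure = res$structure, mfe = res$mfe),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.1f", x$mfe), " kcal/mol)\n",
      sep = "")
  invisible(x)
}

#' Base-pair partners of a dot-bracket structure
#'
#' @param structure Dot-bracket string.
#' @return Integer vector: `pairs[i]` is the partner of position `i`
#'   (1-based), `NA` when unpaired.
#' @export
structure_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  out <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      assert_that(length(stack) > 0, "unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out[i] <- j
      out[j] <- i
    }
  }
  assert_that(length(stack) == 0, "unbalanced dot-bracket structure")
  out
}
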