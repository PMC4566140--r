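# Relative quantification of qPCR cycle-threshold tables by the Livak
# 2^-ddCt method, normalized to a reference gene and a calibrator condition.

#' Read a Ct table
#'
#' @param path TSV with columns `gene`, `condition`, `replicate`, `ct`.
#' @return Data frame with those columns.
#' @examples
#' ct <- read_ct_table(system.file("extdata", "example_ct.tsv",
#'                                 package = "mirduet"))
#' expression_series(ct, "miR5293", calibrator = "0h")
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  missing <- setdiff(need, names(ct))
  assert_that(length(missing) == 0,
              sprintf("Ct table lacks column(s): %s", paste(missing, collapse = ", ")))
  assert_that(all(ct$ct > 0), "Ct values must be positive")
  ct[need]
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_treat - ct_ref_treat) - (ct_target_cal - ct_ref_cal))`.
#'
#' @param ct_target_treat,ct_ref_treat Target and reference-gene Ct in the
#'   treated/test condition.
#' @param ct_target_cal,ct_ref_cal Target and reference-gene Ct in the
#'   calibrator condition.
#' @return Relative expression (fold over the calibrator).
#' @examples
#' ddct(24, 20, 26, 20)  # 4
#' @export
ddct <- function(ct_target_treat, ct_ref_treat, ct_target_cal, ct_ref_cal) {
  args <- list(ct_target_treat, ct_ref_treat, ct_target_cal, ct_ref_cal)
  assert_that(!any(vapply(args, anyNA, logical(1))), "missing Ct value")
  2^-((ct_target_treat - ct_ref_treat) - (ct_target_cal - ct_ref_cal))
}

#' Relative expression series across conditions
#'
#' For each condition, replicate-wise delta-Ct values (target minus the
#' reference gene, replicates matched by index where possible) are
#' averaged before the delta-delta step, so the calibrator condition's
#' mean is exactly 1. The standard error comes from the per-replicate fold
#' values around the calibrator's mean delta-Ct.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param gene Target gene identifier.
#' @param reference Reference gene (default `"5.8S rRNA"`).
#' @param calibrator Calibrator condition label (default `"0h"`).
#' @return Data frame: `condition`, `fold`, `se`, `n` (replicates), in the
#'   order conditions appear in the table.
#' @export
expression_series <- function(ct, gene, reference = "5.8S rRNA",
                              calibrator = "0h") {
  assert_that(gene %in% ct$gene, sprintf("gene '%s' absent from Ct table", gene))
  assert_that(calibrator %in% ct$condition[ct$gene == gene],
              sprintf("calibrator condition '%s' absent", calibrator))
  conds <- unique(ct$condition[ct$gene == gene])
  dct_by_cond <- lapply(conds, function(cond) {
    tgt <- ct[ct$gene == gene & ct$condition == cond, , drop = FALSE]
    ref <- ct[ct$gene == reference & ct$condition == cond, , drop = FALSE]
    assert_that(nrow(ref) > 0,
                sprintf("reference gene '%s' missing for condition '%s'",
                        reference, cond))
    ref_ct <- ref$ct[match(tgt$replicate, ref$replicate)]
    ref_ct[is.na(ref_ct)] <- mean(ref$ct)
    tgt$ct - ref_ct
  })
  names(dct_by_cond) <- conds
  cal_mean <- mean(dct_by_cond[[calibrator]])
  rows <- lapply(conds, function(cond) {
    d <- dct_by_cond[[cond]]
    folds <- 2^-(d - cal_mean)
    data.frame(condition = cond,
               fold = 2^-(mean(d) - cal_mean),
               se = if (length(d) > 1) stats::sd(folds) / sqrt(length(folds)) else 0,
               n = length(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
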