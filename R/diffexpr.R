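#' Reads-per-million normalization
#'
#' `count / total_clean * 1e6`, the standard normalization for two pooled
#' small RNA libraries.
#'
#' @param count Raw read count(s).
#' @param total_clean Library total clean reads (the denominator).
#' @return Normalized expression in RPM.
#' @examples
#' normalize_rpm(94427, 18127561)  # 5209.0295
#' @export
normalize_rpm <- function(count, total_clean) {
  assert_that(all(total_clean > 0), "total_clean must be > 0")
  assert_that(all(count >= 0), "counts must be non-negative")
  count / total_clean * 1e6
}

#' Substitute a floor for zero expression values
#'
#' Zero normalized values are replaced by a small pseudocount so fold
#' changes and ratios stay defined.
#'
#' @param norm Normalized expression value(s).
#' @param floor Substitution value (default 0.01 RPM).
#' @return `norm` with zeros replaced by `floor`.
#' @export
substitute_floor <- function(norm, floor = 0.01) {
  assert_that(floor > 0, "floor must be > 0")
  ifelse(norm == 0, floor, norm)
}

#' Log2 fold change between two libraries
#'
#' @param norm_tr Treated-library normalized expression (after flooring).
#' @param norm_ck Control-library normalized expression (after flooring).
#' @return `log2(norm_tr / norm_ck)`.
#' @export
log2_fold_change <- function(norm_tr, norm_ck) {
  assert_that(all(norm_tr > 0) && all(norm_ck > 0),
              "fold change inputs must be positive; apply substitute_floor() first")
  log2(norm_tr / norm_ck)
}

# log P(y' | x) for the Audic-Claverie conditional distribution, which is
# the negative binomial with size x+1 and success probability 1/(1+r):
# p(y'|x) = r^y' (x+y')! / (x! y'! (1+r)^(x+y'+1)),  r = n2/n1.
#' @noRd
ac_log_pmf <- function(yp, x, log_r, log_1pr) {
  yp * log_r + lgamma(x + yp + 1) - lgamma(x + 1) - lgamma(yp + 1) -
    (x + yp + 1) * log_1pr
}

#' Exact two-library count test (Audic-Claverie)
#'
#' Tests whether a tag's counts `x` and `y` in two libraries of sizes `n1`
#' and `n2` are consistent with equal underlying expression. With
#' `r = n2/n1`, the conditional probability of observing `y'` in library 2
#' given `x` in library 1 is `r^y' (x+y')! / (x! y'! (1+r)^(x+y'+1))`. The
#' two-sided p-value doubles the smaller of the lower and upper tail sums
#' at the observed `y` (capped at 1). Tails are accumulated in log space;
#' the upper tail is summed directly past the conditional mode so extreme
#' p-values keep full relative precision.
#'
#' @param x,y Raw counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 Total clean reads of libraries 1 and 2.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' two_library_pvalue(20, 0, 1e6, 1e6)  # ~2 * 2^-21 doubled lower tail
#' @export
two_library_pvalue <- function(x, y, n1, n2) {
  assert_that(all(x >= 0) && all(y >= 0), "counts must be non-negative")
  assert_that(all(n1 > 0) && all(n2 > 0), "library totals must be positive")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- n2[i] / n1[i]
    log_r <- log(r); log_1pr <- log1p(r)
    xi <- x[i]; yi <- y[i]
    lower <- exp(logsumexp(ac_log_pmf(0:yi, xi, log_r, log_1pr)))
    # upper tail: sum from y until terms vanish relative to the running max
    mode <- (xi + 1) * r
    span <- max(200, ceiling(mode + 20 * sqrt(mode + 1) - yi))
    lterms <- ac_log_pmf(yi:(yi + span), xi, log_r, log_1pr)
    upper <- exp(logsumexp(lterms))
    # extend if the last term has not decayed yet (y far below the mode)
    while (lterms[length(lterms)] > max(lterms) - 45) {
      from <- yi + length(lterms)
      lterms <- c(lterms, ac_log_pmf(from:(from + span), xi, log_r, log_1pr))
      upper <- exp(logsumexp(lterms))
    }
    out[i] <- min(1, 2 * min(lower, upper))
  }
  out
}

#' Differential expression thresholds
#'
#' Asymmetric log2 fold-change thresholds with an exact-test p-value bound:
#' a miRNA is significant when `log2fc >= up_min` or `log2fc < down_max`
#' and `p <= p_max`. miRNAs with normalized expression below `min_norm` in
#' both libraries (before flooring) are excluded as too low to test.
#'
#' @param up_min Minimum log2fc to call up-regulation (default 2).
#' @param down_max Exclusive upper bound on log2fc for down-regulation
#'   (default -0.5).
#' @param p_max Maximum p-value (default 0.05).
#' @param floor Zero-substitution value in RPM (default 0.01).
#' @param min_norm Exclusion bound in RPM (default 1).
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(up_min = 2, down_max = -0.5, p_max = 0.05,
                          floor = 0.01, min_norm = 1) {
  assert_that(up_min > 0 && down_max < 0, "need up_min > 0 > down_max")
  assert_that(p_max > 0 && p_max < 1, "p_max must be in (0, 1)")
  structure(list(up_min = up_min, down_max = down_max, p_max = p_max,
                 floor = floor, min_norm = min_norm),
            class = "de_thresholds")
}

#' Classify expression records as up/down/not significant
#'
#' @param records Data frame with columns `norm_ck`, `norm_tr` (pre-floor),
#'   `log2fc`, `pvalue`.
#' @param th Thresholds from [de_thresholds()].
#' @return `records` with logical `excluded`, `significant` and `direction`
#'   (`"up"`, `"down"`, `"none"`) columns added/replaced.
#' @export
classify_de <- function(records, th = de_thresholds()) {
  excluded <- records$norm_ck < th$min_norm & records$norm_tr < th$min_norm
  passes_fc <- records$log2fc >= th$up_min | records$log2fc < th$down_max
  significant <- !excluded & records$pvalue <= th$p_max & passes_fc
  records$excluded <- excluded
  records$significant <- significant
  records$direction <- ifelse(significant & records$log2fc > 0, "up",
                              ifelse(significant & records$log2fc < 0, "down", "none"))
  records
}

#' Build the two-library differential expression table
#'
#' Computes normalized expression, floored log2 fold change, exact
#' two-library p-values and significance calls for each miRNA, in the
#' order: normalize, exclude low-abundance records (pre-floor), floor,
#' fold change, test, classify.
#'
#' @param counts Data frame with `mirna_id`, a control count column and a
#'   treated count column (named by `labels`), optionally a `type` column
#'   (`"known"`/`"novel"`).
#' @param totals Named numeric of length 2: total clean reads per library,
#'   names matching the count columns; order = (control, treated).
#' @param th Thresholds from [de_thresholds()].
#' @param labels Count column names; default the two names of `totals`.
#' @return Data frame with columns `mirna_id`, (`type`,) `count_ck`,
#'   `count_tr`, `norm_ck`, `norm_tr`, `log2fc`, `pvalue`, `excluded`,
#'   `significant`, `direction`, ordered by (family, id). Summary tallies
#'   (n tested/significant/up/down, split by type) are in
#'   `attr(, "summary")`.
#' @export
de_table <- function(counts, totals, th = de_thresholds(), labels = names(totals)) {
  assert_that(length(labels) == 2 && all(labels %in% names(counts)),
              "counts must carry the two library count columns")
  x <- as.numeric(counts[[labels[1]]])
  y <- as.numeric(counts[[labels[2]]])
  norm_ck <- normalize_rpm(x, totals[[labels[1]]])
  norm_tr <- normalize_rpm(y, totals[[labels[2]]])
  lfc <- log2_fold_change(substitute_floor(norm_tr, th$floor),
                          substitute_floor(norm_ck, th$floor))
  out <- data.frame(mirna_id = counts$mirna_id, stringsAsFactors = FALSE)
  if (!is.null(counts$type)) out$type <- counts$type
  out$count_ck <- x
  out$count_tr <- y
  out$norm_ck <- norm_ck
  out$norm_tr <- norm_tr
  out$log2fc <- lfc
  out$pvalue <- rep(NA_real_, nrow(out))
  test_idx <- which(!(norm_ck < th$min_norm & norm_tr < th$min_norm))
  if (length(test_idx)) {
    out$pvalue[test_idx] <- two_library_pvalue(x[test_idx], y[test_idx],
                                               totals[[labels[1]]], totals[[labels[2]]])
  }
  out$pvalue[is.na(out$pvalue)] <- 1
  out <- classify_de(out, th)
  fam <- tryCatch(assign_family(out$mirna_id), error = function(e) out$mirna_id)
  out <- out[order(fam, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  summ <- list(
    n = nrow(out),
    n_excluded = sum(out$excluded),
    n_significant = sum(out$significant),
    n_up = sum(out$direction == "up"),
    n_down = sum(out$direction == "down")
  )
  if (!is.null(out$type)) {
    summ$n_up_known <- sum(out$direction == "up" & out$type == "known")
    summ$n_up_novel <- sum(out$direction == "up" & out$type == "novel")
    summ$n_down_known <- sum(out$direction == "down" & out$type == "known")
    summ$n_down_novel <- sum(out$direction == "down" & out$type == "novel")
  }
  attr(out, "summary") <- summ
  out
}

#' Write a differential expression table as TSV
#'
#' Normalized values are printed to 4 decimals, fold changes to 2, and the
#' significance label `**` marks p < 0.01, matching the conventional
#' two-library report layout.
#'
#' @param de Data frame from [de_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(
    miRNA = de$mirna_id,
    count_CK = de$count_ck,
    count_treated = de$count_tr,
    norm_CK = sprintf("%.4f", de$norm_ck),
    norm_treated = sprintf("%.4f", de$norm_tr),
    log2FC = sprintf("%.2f", de$log2fc),
    p_value = signif(de$pvalue, 3),
    sig = ifelse(de$significant & de$pvalue < 0.01, "**", ""),
    regulated = ifelse(de$direction == "none", "",
                       paste0(de$direction, "-regulated")),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
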