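#' Map tags to a reference by perfect match
#'
#' A tag is mapped iff its sequence occurs exactly (0 mismatches) in a
#' reference sequence or its reverse complement. All occurrence loci are
#' recorded.
#'
#' @param tags Tag table.
#' @param reference Named character vector or `DNAStringSet` of reference
#'   sequences (contigs/unigenes/ESTs).
#' @return List with `loci` (data frame `sequence`, `ref`, `start`, `end`,
#'   `strand`; 0-based half-open intervals) and `mapped` (logical vector
#'   aligned with the rows of `tags`).
#' @export
map_reference <- function(tags, reference) {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(normalize_dna(reference))
  }
  assert_that(length(reference) > 0, "reference must be non-empty")
  assert_that(!is.null(names(reference)) && all(nzchar(names(reference))),
              "reference sequences must be named")
  seqs <- tags$sequence
  rlens <- Biostrings::width(reference)
  # concatenate contigs with an N spacer wider than any tag; exact matching
  # is then a hash join between tags and the subject's k-mers per width
  spacer <- max(nchar(seqs), 0) + 10L
  offsets <- cumsum(c(1L, rlens[-length(rlens)] + spacer))  # 1-based starts
  concat <- paste(as.character(reference), collapse = strrep("N", spacer))
  concat_rc <- revcomp(concat)
  total <- nchar(concat)
  parts <- list()
  clean_idx <- which(!grepl("N", seqs, fixed = TRUE))  # N never maps
  if (length(clean_idx) && total >= min(nchar(seqs[clean_idx]))) {
    tagset <- seqs[clean_idx]
    w0 <- min(nchar(tagset))                # anchor width
    pref <- substr(tagset, 1L, w0)
    by_pref <- split(seq_along(tagset), pref)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") concat else concat_rc
      kmers <- substring(subj, 1:(total - w0 + 1), w0:total)
      hit_pos <- which(kmers %in% names(by_pref))
      if (!length(hit_pos)) next
      cand <- by_pref[kmers[hit_pos]]
      ti <- unlist(cand, use.names = FALSE)
      pos <- rep(hit_pos, lengths(cand))
      wlen <- nchar(tagset)[ti]
      ok <- substring(subj, pos, pos + wlen - 1L) == tagset[ti]
      ti <- ti[ok]; pos <- pos[ok]; wlen <- wlen[ok]
      if (!length(ti)) next
      starts <- if (strand == "+") pos else total - pos - wlen + 2L
      ci <- findInterval(starts, offsets)
      parts[[length(parts) + 1L]] <- data.frame(
        sequence = tagset[ti],
        ref = names(reference)[ci],
        start = starts - offsets[ci],               # 0-based
        end = starts - offsets[ci] + wlen,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(parts)) do.call(rbind, parts) else
    data.frame(sequence = character(), ref = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)
  loci <- loci[order(loci$ref, loci$start, loci$strand, loci$sequence), , drop = FALSE]
  rownames(loci) <- NULL
  list(loci = loci, mapped = tags$sequence %in% loci$sequence)
}

#' Read a class-labelled non-coding RNA FASTA
#'
#' Record headers must carry a `class=<rRNA|tRNA|snRNA|snoRNA>` token.
#'
#' @param path FASTA file.
#' @return Data frame with columns `id`, `class`, `sequence`.
#' @export
read_ncrna_fasta <- function(path) {
  fa <- Biostrings::readBStringSet(path)
  ids <- names(fa)
  cls <- regmatches(ids, regexpr("class=[A-Za-z]+", ids))
  has <- grepl("class=", ids)
  if (!all(has)) {
    stop(sprintf("ncRNA record '%s' lacks a class= label", ids[which(!has)[1]]),
         call. = FALSE)
  }
  data.frame(id = sub("\\s.*$", "", ids),
             class = sub("class=", "", cls),
             sequence = normalize_dna(as.character(fa)),
             stringsAsFactors = FALSE)
}

NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Exclude tags matching known non-coding RNA families
#'
#' A tag matching any ncRNA record exactly (as a substring, either strand)
#' is assigned that record's class and excluded from downstream miRNA
#' analysis. Multi-class hits resolve by the precedence
#' rRNA > tRNA > snRNA > snoRNA.
#'
#' @param tags Tag table.
#' @param ncrna_db Data frame from [read_ncrna_fasta()] (columns `id`,
#'   `class`, `sequence`).
#' @return List with `classified` (data frame `sequence`, `class`) and
#'   `remaining` (tag table of unclassified tags).
#' @export
filter_ncrna <- function(tags, ncrna_db) {
  bad <- setdiff(unique(ncrna_db$class), NCRNA_CLASSES)
  assert_that(length(bad) == 0,
              sprintf("unknown ncRNA class label(s): %s", paste(bad, collapse = ", ")))
  cls <- rep(NA_character_, nrow(tags))
  if (nrow(tags) && nrow(ncrna_db)) {
    seqs <- tags$sequence
    widths <- sort(unique(nchar(seqs)))
    # the ncRNA records are small: enumerate their k-mers (both strands)
    # per class and hash-join the tags against them, in precedence order
    for (class_i in NCRNA_CLASSES) {
      recs <- ncrna_db$sequence[ncrna_db$class == class_i]
      if (!length(recs)) next
      recs <- c(recs, revcomp(recs))
      kmers <- unlist(lapply(widths, function(w) {
        n <- nchar(recs)
        ok <- n >= w
        unlist(lapply(which(ok), function(i) {
          substring(recs[i], 1:(n[i] - w + 1), w:n[i])
        }))
      }))
      hit <- is.na(cls) & seqs %in% kmers
      cls[hit] <- class_i
    }
  }
  classified <- data.frame(sequence = tags$sequence[!is.na(cls)],
                           class = cls[!is.na(cls)], stringsAsFactors = FALSE)
  list(classified = classified,
       remaining = tags[is.na(cls), , drop = FALSE])
}

#' Match tags against a mature miRNA database
#'
#' End-anchored ungapped comparison: when tag and mature lengths differ (by
#' at most `max_len_diff` nt) the shorter sequence slides within the longer
#' and the minimum Hamming distance over offsets is taken; the length
#' difference itself is not penalised. For each tag the hit(s) with the
#' fewest mismatches are reported if within `max_mismatch`; ties break by
#' database order, with all co-optimal hits retained and the first flagged
#' primary.
#'
#' @param tags Tag table.
#' @param mature_db Named character vector (or `DNAStringSet`) of mature
#'   miRNA sequences, e.g. from a miRBase-style FASTA.
#' @param max_mismatch Maximum mismatches (default 2).
#' @param max_len_diff Maximum tag/mature length difference (default 2).
#' @return Data frame with columns `sequence`, `mirna_id`, `mismatches`,
#'   `primary`.
#' @export
match_mirbase <- function(tags, mature_db, max_mismatch = 2L, max_len_diff = 2L) {
  if (methods::is(mature_db, "XStringSet")) {
    mature_db <- stats::setNames(as.character(mature_db), names(mature_db))
  }
  mature_db <- stats::setNames(normalize_dna(mature_db), names(mature_db))
  seqs <- tags$sequence
  empty <- data.frame(sequence = character(), mirna_id = character(),
                      mismatches = integer(), primary = logical(),
                      stringsAsFactors = FALSE)
  if (!length(seqs) || !length(mature_db)) return(empty)

  tag_lens <- nchar(seqs)
  db_lens <- nchar(mature_db)
  best <- rep(Inf, length(seqs))
  # per-tag list of (db index, mismatches) at the current optimum
  hits <- vector("list", length(seqs))

  enc <- function(x, n) {
    # rows = sequences, cols = positions
    matrix(utf8ToInt(paste(x, collapse = "")), ncol = n, byrow = TRUE)
  }
  for (lt in sort(unique(tag_lens))) {
    ti <- which(tag_lens == lt)
    tm <- enc(seqs[ti], lt)
    for (di in seq_along(mature_db)) {
      ld <- db_lens[di]
      if (abs(lt - ld) > max_len_diff) next
      dv <- utf8ToInt(mature_db[di])
      if (lt <= ld) {
        offs <- 0:(ld - lt)
        mm <- rep(Inf, length(ti))
        for (o in offs) {
          mm <- pmin(mm, rowSums(tm != matrix(dv[(1 + o):(o + lt)], nrow = length(ti),
                                              ncol = lt, byrow = TRUE)))
        }
      } else {
        offs <- 0:(lt - ld)
        mm <- rep(Inf, length(ti))
        for (o in offs) {
          mm <- pmin(mm, rowSums(tm[, (1 + o):(o + ld), drop = FALSE] !=
                                   matrix(dv, nrow = length(ti), ncol = ld, byrow = TRUE)))
        }
      }
      upd <- which(mm <= max_mismatch & mm <= best[ti])
      for (k in upd) {
        i <- ti[k]
        if (mm[k] < best[i]) {
          best[i] <- mm[k]
          hits[[i]] <- list(c(di, mm[k]))
        } else {
          hits[[i]] <- c(hits[[i]], list(c(di, mm[k])))
        }
      }
    }
  }
  rows <- list()
  for (i in seq_along(seqs)) {
    if (is.null(hits[[i]])) next
    h <- do.call(rbind, hits[[i]])
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = seqs[i],
      mirna_id = names(mature_db)[h[, 1]],
      mismatches = as.integer(h[, 2]),
      primary = seq_len(nrow(h)) == 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default family merge map
#'
#' Families routinely reported together are merged under a joint label
#' (miR156/157 and miR165/166).
#' @return Named character vector mapping `miR<number>` to merged label.
#' @export
default_family_merge <- function() {
  c(miR156 = "miR156/157", miR157 = "miR156/157",
    miR165 = "miR165/166", miR166 = "miR165/166")
}

#' Assign a miRNA identifier to its family
#'
#' Strips any species prefix (e.g. `"osa-"`), the lettered member suffix and
#' the `-3p`/`-5p` arm suffix, yielding `miR<number>`, then applies the
#' merge map.
#'
#' @param mirna_id Character vector of miRNA identifiers
#'   (`[species-]miR<number>[letters][-3p|-5p]`).
#' @param merge_map Named vector of family merges; see
#'   [default_family_merge()].
#' @return Character vector of family labels.
#' @examples
#' assign_family(c("miR156a-3p", "miR408-5p", "osa-miR166g"))
#' @export
assign_family <- function(mirna_id, merge_map = default_family_merge()) {
  core <- sub("^[A-Za-z]{2,4}-", "", mirna_id)
  core <- sub("-(3p|5p)$", "", core)
  ok <- grepl("^miRn?[0-9]+[A-Za-z]*$", core)
  if (!all(ok)) {
    stop(sprintf("cannot parse miRNA id '%s'", mirna_id[which(!ok)[1]]), call. = FALSE)
  }
  fam <- sub("^(miRn?[0-9]+)[A-Za-z]*$", "\\1", core)
  merged <- unname(merge_map[fam])
  ifelse(is.na(merged), fam, merged)
}

#' Conserved plant miRNA families (default list)
#'
#' The 24 broadly conserved families used to split known miRNAs into
#' conserved and non-conserved sets; configurable because the distinction
#' is curatorial, not algorithmic.
#' @return Character vector of family labels.
#' @export
default_conserved_families <- function() {
  c("miR156/157", "miR158", "miR159", "miR160", "miR161", "miR162", "miR164",
    "miR165/166", "miR167", "miR168", "miR169", "miR171", "miR172", "miR319",
    "miR390", "miR391", "miR393", "miR394", "miR395", "miR396", "miR397",
    "miR398", "miR399", "miR408")
}

#' Per-miRNA raw counts from known-miRNA hits
#'
#' Sums tag counts per miRNA identifier over primary hits only, so each tag
#' contributes to exactly one miRNA.
#'
#' @param hits Data frame from [match_mirbase()].
#' @param tags Tag table with per-library counts.
#' @return Data frame `mirna_id` plus one count column per library label.
#' @export
mirna_counts <- function(hits, tags) {
  labs <- tag_labels(tags)
  prim <- hits[hits$primary, , drop = FALSE]
  m <- merge(prim[c("sequence", "mirna_id")], as.data.frame(tags), by = "sequence")
  if (nrow(m) == 0) {
    out <- data.frame(mirna_id = character(), stringsAsFactors = FALSE)
    for (l in labs) out[[l]] <- numeric()
    return(out)
  }
  agg <- rowsum(as.matrix(m[, labs, drop = FALSE]), group = m$mirna_id)
  out <- data.frame(mirna_id = rownames(agg), stringsAsFactors = FALSE)
  for (l in labs) out[[l]] <- as.numeric(agg[, l])
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family-level summary of known miRNA expression
#'
#' Aggregates per-miRNA counts into families with member numbers, raw
#' reads, reads-per-million and the log2 fold change between the two
#' libraries (zero counts floored before the ratio).
#'
#' @param counts Data frame from [mirna_counts()] (or any data frame with
#'   `mirna_id` plus two library count columns).
#' @param totals Named numeric: total clean reads per library (the
#'   normalization denominators), names matching the count columns.
#' @param conserved Character vector of conserved family labels.
#' @param merge_map Family merge map for [assign_family()].
#' @param floor Pseudocount substituted for zero normalized values.
#' @return Data frame: `family`, `conserved`, `n_members`, per-library
#'   `reads_*` and `norm_*` columns, `log2fc` (treated vs control, i.e.
#'   second library over first).
#' @export
family_summary <- function(counts, totals, conserved = default_conserved_families(),
                           merge_map = default_family_merge(), floor = 0.01) {
  labs <- names(totals)
  assert_that(length(labs) == 2 && all(labs %in% names(counts)),
              "totals must name the two library count columns")
  fam <- assign_family(counts$mirna_id, merge_map)
  agg1 <- rowsum(as.numeric(counts[[labs[1]]]), group = fam)
  agg2 <- rowsum(as.numeric(counts[[labs[2]]]), group = fam)
  nmem <- rowsum(rep(1L, length(fam)), group = fam)
  out <- data.frame(family = rownames(agg1),
                    conserved = rownames(agg1) %in% conserved,
                    n_members = as.integer(nmem[, 1]),
                    stringsAsFactors = FALSE)
  out[[paste0("reads_", labs[1])]] <- agg1[, 1]
  out[[paste0("reads_", labs[2])]] <- agg2[, 1]
  n1 <- normalize_rpm(agg1[, 1], totals[[labs[1]]])
  n2 <- normalize_rpm(agg2[, 1], totals[[labs[2]]])
  out[[paste0("norm_", labs[1])]] <- n1
  out[[paste0("norm_", labs[2])]] <- n2
  out$log2fc <- log2_fold_change(substitute_floor(n2, floor), substitute_floor(n1, floor))
  out <- out[order(!out$conserved, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
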