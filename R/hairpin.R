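# Novel miRNA calling: excise candidate precursor windows around a mapped
# tag, fold them, and apply stem-loop / miRNA:miRNA* duplex criteria.

#' Acceptance criteria for novel hairpin candidates
#'
#' Defaults reflect the usual plant stem-loop criteria: a 20-24 nt mature
#' on a single precursor arm, at most 4 unpaired mature bases in the
#' miRNA:miRNA* duplex, asymmetric bulges of at most 2 nt, a 2-nt 3'
#' overhang for the star, a 40-350 nt precursor, and a model minimum free
#' energy of at most -18 kcal/mol.
#'
#' @param mature_min,mature_max Mature length bounds in nt.
#' @param max_duplex_mismatch Maximum unpaired mature bases in the duplex.
#' @param max_asym_bulge Maximum asymmetric bulge within the duplex, nt.
#' @param star_overhang 3' overhang used to place the star, nt.
#' @param min_precursor,max_precursor Precursor length bounds, nt.
#' @param mfe_max Maximum (least negative) model MFE, kcal/mol.
#' @param min_reads Minimum read support for the mature tag.
#' @param star_tol Tolerance (nt) when matching observed tags to the star
#'   position.
#' @return A `hairpin_criteria` list.
#' @export
hairpin_criteria <- function(mature_min = 20L, mature_max = 24L,
                             max_duplex_mismatch = 4L, max_asym_bulge = 2L,
                             star_overhang = 2L, min_precursor = 40L,
                             max_precursor = 350L, mfe_max = -18,
                             min_reads = 1L, star_tol = 2L) {
  structure(list(mature_min = mature_min, mature_max = mature_max,
                 max_duplex_mismatch = max_duplex_mismatch,
                 max_asym_bulge = max_asym_bulge, star_overhang = star_overhang,
                 min_precursor = min_precursor, max_precursor = max_precursor,
                 mfe_max = mfe_max, min_reads = min_reads, star_tol = star_tol),
            class = "hairpin_criteria")
}

#' Excise candidate precursor windows around a mapped tag
#'
#' Windows place the tag alternately on the putative 5' arm (short
#' upstream flank, long downstream flank) and the 3' arm (mirror image),
#' with total lengths from `tag length + 30` up to `max_precursor` in
#' steps of `flank_step` nt, truncated at contig ends. Every window
#' contains the full tag.
#'
#' @param locus One row of the `loci` frame from [map_reference()]
#'   (`ref`, `start`, `end`, `strand`; 0-based half-open).
#' @param reference Named character vector of reference sequences.
#' @param max_precursor Maximum window length (default 350 nt).
#' @param flank_step Length increment between windows (default 10 nt).
#' @param short_flank Flank on the tag's loop-distal side (default 15 nt).
#' @return Data frame of windows: `ref`, `start`, `end` (0-based
#'   half-open), `strand`, `arm` (`"5p"`/`"3p"`), `precursor` (sequence in
#'   transcription orientation), `tag_offset` (1-based mature start within
#'   the precursor).
#' @export
excise_candidates <- function(locus, reference, max_precursor = 350L,
                              flank_step = 10L, short_flank = 15L) {
  rseq <- reference[[locus$ref]]
  rlen <- nchar(rseq)
  tlen <- locus$end - locus$start
  lens <- seq(tlen + 30L, max_precursor, by = flank_step)
  rows <- list()
  for (arm in c("5p", "3p")) {
    for (L in lens) {
      long_flank <- L - tlen - short_flank
      if (long_flank < 0) next
      # upstream/downstream in transcription orientation
      if (arm == "5p") { up <- short_flank; down <- long_flank }
      else { up <- long_flank; down <- short_flank }
      if (locus$strand == "+") {
        w_start <- locus$start - up
        w_end <- locus$end + down
      } else {
        w_start <- locus$start - down
        w_end <- locus$end + up
      }
      w_start <- max(0L, w_start)
      w_end <- min(rlen, w_end)
      seq_fwd <- substr(rseq, w_start + 1L, w_end)
      if (locus$strand == "+") {
        prec <- seq_fwd
        off <- locus$start - w_start + 1L
      } else {
        prec <- revcomp(seq_fwd)
        off <- w_end - locus$end + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ref = locus$ref, start = w_start, end = w_end, strand = locus$strand,
        arm = arm, precursor = prec, tag_offset = off, stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# asymmetric bulge: for consecutive paired mature bases i1 < i2 with
# partners j1 > j2, the step advances i2-i1 on the mature side and j1-j2 on
# the star side; the largest absolute difference is the asymmetry.
#' @noRd
duplex_geometry <- function(pairs, ms, me) {
  mat_idx <- ms:me
  partner <- pairs[mat_idx]
  paired <- which(!is.na(partner))
  mism <- length(mat_idx) - length(paired)
  asym <- 0L
  if (length(paired) >= 2) {
    di <- diff(mat_idx[paired])
    dj <- abs(diff(partner[paired]))
    asym <- max(abs(di - dj))
  }
  list(mismatches = mism, asym_bulge = asym, partner = partner)
}

#' Evaluate a precursor window against the hairpin criteria
#'
#' Folds the window, places the star sequence implied by the duplex with a
#' 2-nt 3' overhang, counts unpaired mature bases and the largest
#' asymmetric bulge in the mature:star duplex, checks whether any observed
#' tag supports the star position, and records an accept/reject verdict
#' with the failing criterion.
#'
#' @param window One row from [excise_candidates()] (needs `precursor`,
#'   `tag_offset`, plus locus columns for bookkeeping).
#' @param tag The mature tag sequence (DNA or RNA alphabet).
#' @param tag_table Optional tag table used to mark the star as observed.
#' @param criteria From [hairpin_criteria()].
#' @param config Folding energy model from [fold_config()].
#' @return A `hairpin_candidate` list: `locus`, `precursor`, `fold`,
#'   `mature` (sequence, arm, offset), `star` (sequence, offset,
#'   observed), `duplex_mismatches`, `asymmetric_bulge`, `accepted`,
#'   `reason`.
#' @export
evaluate_hairpin <- function(window, tag, tag_table = NULL,
                             criteria = hairpin_criteria(),
                             config = fold_config()) {
  prec <- window$precursor
  plen <- nchar(prec)
  tag <- normalize_dna(tag)
  tlen <- nchar(tag)
  ms <- window$tag_offset
  me <- ms + tlen - 1L
  res <- list(
    locus = window[intersect(c("ref", "start", "end", "strand", "arm"), names(window))],
    precursor = prec, fold = NULL,
    mature = list(sequence = to_rna(tag), arm = NA_character_, offset = ms),
    star = NULL, duplex_mismatches = NA_integer_, asymmetric_bulge = NA_integer_,
    accepted = FALSE, reason = ""
  )
  class(res) <- "hairpin_candidate"
  reject <- function(reason) { res$reason <- reason; res }

  if (plen < criteria$min_precursor || plen > criteria$max_precursor) {
    return(reject("precursor-length"))
  }
  if (tlen < criteria$mature_min || tlen > criteria$mature_max) {
    return(reject("mature-length"))
  }
  fold <- fold_rna(prec, config)
  res$fold <- fold
  if (fold$mfe > criteria$mfe_max) return(reject("mfe"))
  pairs <- structure_pairs(fold$structure)
  geo <- duplex_geometry(pairs, ms, me)
  paired_m <- which(!is.na(geo$partner))
  if (length(paired_m) == 0) return(reject("mature-unpaired"))
  partners <- geo$partner[paired_m]
  # single arm: all partners on one side of the mature interval
  if (!(all(partners > me) || all(partners < ms))) {
    return(reject("mature-spans-arms"))
  }
  res$mature$arm <- if (all(partners > me)) "5p" else "3p"
  # terminal loop of the (single) stem: interior of the innermost pair
  pe <- which(!is.na(pairs) & pairs > seq_along(pairs))
  inner <- pe[which.min(pairs[pe] - pe)]
  loop <- c(inner + 1L, pairs[inner] - 1L)
  if (ms <= loop[2] && me >= loop[1]) return(reject("mature-in-loop"))
  # star from the partner of the mature 5' end, with the 3' overhang
  k <- paired_m[1]                      # first paired mature position
  se <- pairs[ms - 1L + k] + criteria$star_overhang + (k - 1L)
  ss <- se - tlen + 1L
  if (ss < 1L || se > plen) return(reject("star-outside-precursor"))
  star_seq <- substr(prec, ss, se)
  observed <- FALSE
  if (!is.null(tag_table) && nrow(tag_table)) {
    cand <- tag_table$sequence[abs(tag_table$length - tlen) <= criteria$star_tol]
    if (length(cand)) {
      lo <- max(1L, ss - criteria$star_tol)
      hi <- min(plen, se + criteria$star_tol)
      region <- substr(prec, lo, hi)
      observed <- any(vapply(unique(cand), function(s) grepl(s, region, fixed = TRUE),
                             logical(1)))
    }
  }
  res$star <- list(sequence = to_rna(star_seq), offset = ss, observed = observed)
  res$duplex_mismatches <- geo$mismatches
  res$asymmetric_bulge <- geo$asym_bulge
  if (geo$mismatches > criteria$max_duplex_mismatch) return(reject("duplex-mismatches"))
  if (geo$asym_bulge > criteria$max_asym_bulge) return(reject("asymmetric-bulge"))
  res$accepted <- TRUE
  res$reason <- "ok"
  res
}

#' Call novel miRNAs from unannotated mapped tags
#'
#' For every unannotated tag locus, excises candidate precursor windows,
#' evaluates each against the hairpin criteria, keeps the best accepted
#' window per tag (lowest MFE, ties to the shortest precursor), merges
#' overlapping candidates on the same locus, and numbers the surviving
#' records `<prefix>-1`, `<prefix>-2`, ... by (reference, start) order.
#'
#' @param tags Tag table restricted to unannotated tags.
#' @param loci Loci frame from [map_reference()] for those tags.
#' @param reference Named character vector of reference sequences.
#' @param tag_table Full tag table (for star support); defaults to `tags`.
#' @param criteria From [hairpin_criteria()].
#' @param config Folding model from [fold_config()].
#' @param prefix Identifier prefix (default `"miRn"`).
#' @param max_loci_per_tag Skip promiscuous tags mapping to more loci than
#'   this (default 5).
#' @return List with `novel` (data frame: `novel_id`, `sequence` (RNA),
#'   `ref`, `start`, `end`, `strand`, `arm`, `precursor`, `structure`,
#'   `mfe`, `duplex_mismatches`, `asymmetric_bulge`, `star_observed`) and
#'   `candidates` (all evaluated `hairpin_candidate`s).
#' @export
call_novel <- function(tags, loci, reference, tag_table = tags,
                       criteria = hairpin_criteria(), config = fold_config(),
                       prefix = "miRn", max_loci_per_tag = 5L) {
  candidates <- list()
  best_rows <- list()
  counts <- if (length(tag_labels(tags))) {
    rowSums(as.data.frame(tags)[, tag_labels(tags), drop = FALSE])
  } else rep(1, nrow(tags))
  for (i in seq_len(nrow(tags))) {
    seq_i <- tags$sequence[i]
    if (counts[i] < criteria$min_reads) next
    tl <- loci[loci$sequence == seq_i, , drop = FALSE]
    if (nrow(tl) == 0 || nrow(tl) > max_loci_per_tag) next
    best <- NULL
    for (j in seq_len(nrow(tl))) {
      windows <- excise_candidates(tl[j, ], reference,
                                   max_precursor = criteria$max_precursor)
      for (w in seq_len(nrow(windows))) {
        cand <- evaluate_hairpin(windows[w, ], seq_i, tag_table, criteria, config)
        candidates[[length(candidates) + 1L]] <- cand
        if (!cand$accepted) next
        if (is.null(best) || cand$fold$mfe < best$fold$mfe ||
            (cand$fold$mfe == best$fold$mfe &&
             nchar(cand$precursor) < nchar(best$precursor))) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) {
      best_rows[[length(best_rows) + 1L]] <- data.frame(
        sequence = best$mature$sequence,
        ref = best$locus$ref, start = best$locus$start, end = best$locus$end,
        strand = best$locus$strand, arm = best$mature$arm,
        precursor = to_rna(best$precursor), structure = best$fold$structure,
        mfe = best$fold$mfe, duplex_mismatches = best$duplex_mismatches,
        asymmetric_bulge = best$asymmetric_bulge,
        star_observed = best$star$observed, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(novel_id = character(), sequence = character(),
                      ref = character(), start = integer(), end = integer(),
                      strand = character(), arm = character(), precursor = character(),
                      structure = character(), mfe = numeric(),
                      duplex_mismatches = integer(), asymmetric_bulge = integer(),
                      star_observed = logical(), stringsAsFactors = FALSE)
  if (!length(best_rows)) return(list(novel = empty, candidates = candidates))
  novel <- do.call(rbind, best_rows)
  novel <- novel[order(novel$ref, novel$start, novel$end), , drop = FALSE]
  # merge candidates whose precursor windows overlap on the same reference
  # (a hairpin's two arms map to both strands): keep the first (lowest start)
  keep <- rep(TRUE, nrow(novel))
  if (nrow(novel) > 1) {
    for (i in 2:nrow(novel)) {
      prev <- max(which(keep[1:(i - 1)]))
      same <- novel$ref[i] == novel$ref[prev]
      if (same && novel$start[i] < novel$end[prev]) {
        keep[i] <- FALSE
        if (novel$star_observed[i]) novel$star_observed[prev] <- TRUE
      }
    }
  }
  novel <- novel[keep, , drop = FALSE]
  novel <- cbind(data.frame(novel_id = sprintf("%s-%d", prefix, seq_len(nrow(novel))),
                            stringsAsFactors = FALSE), novel)
  rownames(novel) <- NULL
  list(novel = novel, candidates = candidates)
}
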