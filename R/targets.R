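# Allen-style expectation scoring of miRNA-target alignments and a
# banded complementarity scan over transcripts (psRNATarget-like).

#' Target-scoring penalty scheme
#'
#' @param mismatch Penalty per mismatched position (default 1).
#' @param gu Penalty per G:U wobble (default 0.5).
#' @param gap Penalty for the single allowed gap (default 2).
#' @param core Inclusive miRNA position range whose penalties are doubled
#'   (default 2-13, counted from the miRNA 5' end).
#' @return A `target_penalties` list.
#' @export
target_penalties <- function(mismatch = 1, gu = 0.5, gap = 2, core = c(2L, 13L)) {
  structure(list(mismatch = mismatch, gu = gu, gap = gap,
                 core = as.integer(core)), class = "target_penalties")
}

#' Expectation score of a miRNA-target alignment
#'
#' Sums per-position penalties (match 0, mismatch 1, G:U 0.5, gap 2 by
#' default), doubling each penalty whose miRNA position lies in the core
#' range. Positions are counted from the miRNA 5' end.
#'
#' @param states Character vector of per-column states: `"match"`,
#'   `"mismatch"`, `"GU"`, `"gap"`.
#' @param positions miRNA position of each column (default
#'   `seq_along(states)`); a bulged target base takes the position of the
#'   miRNA base it is inserted before.
#' @param penalties Scheme from [target_penalties()].
#' @return The expectation score E (>= 0; lower = better complementarity).
#' @examples
#' score_alignment(c("match", "match", "match", "GU", "mismatch"))
#' @export
score_alignment <- function(states, positions = seq_along(states),
                            penalties = target_penalties()) {
  assert_that(length(states) == length(positions),
              "states and positions must align")
  assert_that(sum(states == "gap") <= 1, "invalid alignment: more than one gap")
  pen <- c(match = 0, mismatch = penalties$mismatch, GU = penalties$gu,
           gap = penalties$gap)
  bad <- setdiff(unique(states), names(pen))
  assert_that(length(bad) == 0,
              sprintf("unknown alignment state(s): %s", paste(bad, collapse = ", ")))
  p <- pen[states]
  in_core <- positions >= penalties$core[1] & positions <= penalties$core[2]
  sum(p * (1 + in_core))
}

# Pairing state of miRNA base (5'->3') vs target base (sense strand):
# match = Watson-Crick complement, GU = wobble (miRNA G : target T, or
# miRNA T : target G, in the DNA alphabet), else mismatch.
#' @noRd
pair_states <- function(mirna_chars, target_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  st <- rep("mismatch", length(mirna_chars))
  st[comp[mirna_chars] == target_chars] <- "match"
  st[(mirna_chars == "G" & target_chars == "T") |
       (mirna_chars == "T" & target_chars == "G")] <- "GU"
  st
}

#' Classify the repression mode of a target alignment
#'
#' Cleavage requires full complementarity across the central positions
#' (9-11 from the miRNA 5' end); any non-match state there implies
#' translational inhibition.
#'
#' @inheritParams score_alignment
#' @param central Inclusive central position range (default 9-11).
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_mode <- function(states, positions = seq_along(states),
                          central = c(9L, 11L)) {
  centre <- states[positions >= central[1] & positions <= central[2]]
  if (any(centre != "match")) "translation" else "cleavage"
}

#' Structural filter rules for target alignments
#'
#' @param max_central_mismatch Maximum non-match states at positions 10-11
#'   (default 0).
#' @param max_seed_mismatch Maximum non-match states at positions 1-9
#'   (default 1).
#' @param max_consecutive Maximum run of consecutive non-match states
#'   (default 2).
#' @return A `schwab_rules` list.
#' @export
schwab_rules <- function(max_central_mismatch = 0L, max_seed_mismatch = 1L,
                         max_consecutive = 2L) {
  structure(list(max_central_mismatch = max_central_mismatch,
                 max_seed_mismatch = max_seed_mismatch,
                 max_consecutive = max_consecutive), class = "schwab_rules")
}

#' Apply structural filters to a target alignment
#'
#' G:U wobbles count as paired for these rules; only mismatches and gaps
#' are "mismatch" states.
#'
#' @inheritParams score_alignment
#' @param rules Rules from [schwab_rules()].
#' @return List: `pass` (logical) and `reasons` (character vector of failed
#'   rules, empty on pass).
#' @export
schwab_filter <- function(states, positions = seq_along(states),
                          rules = schwab_rules()) {
  mm <- states %in% c("mismatch", "gap")
  reasons <- character()
  if (sum(mm[positions %in% 10:11]) > rules$max_central_mismatch) {
    reasons <- c(reasons, "cleavage-site mismatch")
  }
  if (sum(mm[positions >= 1 & positions <= 9]) > rules$max_seed_mismatch) {
    reasons <- c(reasons, sprintf("seed mismatches > %d", rules$max_seed_mismatch))
  }
  runs <- rle(mm)
  if (any(runs$values & runs$lengths > rules$max_consecutive)) {
    reasons <- c(reasons, sprintf("more than %d consecutive mismatches",
                                  rules$max_consecutive))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Build the alignment (states + positions + interval) of a miRNA against a
# target window. gap_kind: "none"; "target" = one bulged target base
# inserted before miRNA position gap_pos (window is m+1 nt); "mirna" =
# miRNA base gap_pos unpaired (window is m-1 nt).
#' @noRd
align_window <- function(mirna_chars, window_chars, gap_kind = "none", gap_pos = NA) {
  m <- length(mirna_chars)
  # miRNA position 1 (5') pairs the window's last base
  tgt <- rev(window_chars)
  if (gap_kind == "none") {
    states <- pair_states(mirna_chars, tgt)
    positions <- seq_len(m)
  } else if (gap_kind == "target") {
    # tgt has m+1 bases; base at index gap_pos is bulged
    keep <- setdiff(seq_len(m + 1), gap_pos)
    states <- pair_states(mirna_chars, tgt[keep])
    states <- append(states, "gap", after = gap_pos - 1)
    positions <- append(seq_len(m), gap_pos, after = gap_pos - 1)
  } else { # mirna gap: miRNA base gap_pos unpaired, window has m-1 bases
    keep <- setdiff(seq_len(m), gap_pos)
    states <- rep("gap", m)
    states[keep] <- pair_states(mirna_chars[keep], tgt)
    positions <- seq_len(m)
  }
  list(states = states, positions = positions)
}

#' Find miRNA target sites on a transcript
#'
#' Scores every transcript window against the miRNA (position 1 = miRNA 5'
#' end pairing the window's 3' base), including single-gap variants: one
#' bulged target base or one unpaired miRNA base, never at miRNA positions
#' 10-11. Sites with expectation score `E <= max_expectation` are
#' reported.
#'
#' @param mirna miRNA sequence (18-26 nt, RNA or DNA alphabet).
#' @param transcript Transcript sequence (sense strand).
#' @param max_expectation Score cutoff (default 3.0).
#' @param penalties Scheme from [target_penalties()].
#' @param allow_gap Scan single-gap variants (default TRUE).
#' @return Data frame ordered by position: `start`, `end` (0-based
#'   half-open on the transcript), `expectation`, `mode`, `gap` (`"none"`,
#'   `"target"`, `"mirna"`), `gap_pos`, `alignment` (state string, miRNA 5'
#'   to 3'), `schwab_pass`, and `best` flagging the lowest-scoring site.
#' @export
find_sites <- function(mirna, transcript, max_expectation = 3.0,
                       penalties = target_penalties(), allow_gap = TRUE) {
  mirna <- normalize_dna(mirna)
  transcript <- normalize_dna(transcript)
  m <- nchar(mirna)
  assert_that(m >= 18 && m <= 26, "miRNA must be 18-26 nt")
  L <- nchar(transcript)
  assert_that(L >= m, "transcript shorter than the miRNA")
  mc <- strsplit(mirna, "")[[1]]
  tc <- strsplit(transcript, "")[[1]]
  state_code <- c(match = "|", GU = "o", mismatch = "x", gap = "-")
  # integer coding for vectorized window scoring
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
  comp <- c(4L, 3L, 2L, 1L)  # complement codes for A,C,G,T
  mcode <- code[mc]
  tcode <- code[tc]
  in_core <- function(pos) pos >= penalties$core[1] & pos <= penalties$core[2]

  # expectation of every window for one gap configuration, vectorized over
  # window starts; mirna positions `ks` pair transcript index s - 1 + off[k]
  scan_scores <- function(wlen, ks, off, base_pen) {
    nw <- L - wlen + 1L
    if (nw < 1L) return(NULL)
    pen <- matrix(0, nrow = nw, ncol = length(ks))
    for (a in seq_along(ks)) {
      k <- ks[a]
      tcol <- tcode[seq_len(nw) - 1L + off[a]]
      p <- rep(penalties$mismatch, nw)
      p[tcol == comp[mcode[k]]] <- 0
      p[(mcode[k] == 3L & tcol == 4L) | (mcode[k] == 4L & tcol == 3L)] <- penalties$gu
      pen[, a] <- p * (1 + in_core(k))
    }
    rowSums(pen) + base_pen
  }
  hits <- list()
  collect <- function(wlen, gap_kind, gap_pos, ks, off, base_pen) {
    E <- scan_scores(wlen, ks, off, base_pen)
    if (is.null(E)) return()
    for (s in which(E <= max_expectation)) {
      aln <- align_window(mc, tc[s:(s + wlen - 1)], gap_kind,
                          if (is.na(gap_pos)) NA else gap_pos)
      hits[[length(hits) + 1L]] <<- data.frame(
        start = s - 1L, end = s - 1L + wlen, expectation = E[s],
        mode = classify_mode(aln$states, aln$positions),
        gap = gap_kind,
        gap_pos = if (is.na(gap_pos)) NA_integer_ else as.integer(gap_pos),
        alignment = paste(state_code[aln$states], collapse = ""),
        schwab_pass = schwab_filter(aln$states, aln$positions)$pass,
        stringsAsFactors = FALSE)
    }
  }
  ks <- seq_len(m)
  collect(m, "none", NA, ks, m - ks + 1L, 0)
  if (allow_gap) {
    for (g in setdiff(2:m, 10:11)) {
      # bulged target base inserted before miRNA position g (window m+1 nt)
      off <- (m + 1L) - (ks + (ks >= g)) + 1L
      collect(m + 1L, "target", g, ks, off, penalties$gap * (1 + in_core(g)))
    }
    for (g in setdiff(2:(m - 1L), 10:11)) {
      # miRNA base g unpaired (window m-1 nt)
      kk <- setdiff(ks, g)
      off <- (m - 1L) - (kk - (kk > g)) + 1L
      collect(m - 1L, "mirna", g, kk, off, penalties$gap * (1 + in_core(g)))
    }
  }
  if (!length(hits)) {
    out <- data.frame(start = integer(), end = integer(), expectation = numeric(),
                      mode = character(), gap = character(), gap_pos = integer(),
                      alignment = character(), schwab_pass = logical(),
                      best = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end, out$expectation, out$gap, out$gap_pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$best <- seq_len(nrow(out)) == which.min(out$expectation)
  out
}

#' Predict targets for a set of miRNAs over a transcript set
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param max_expectation Score cutoff (default 3.0).
#' @param penalties Scheme from [target_penalties()].
#' @return Data frame: `mirna_id`, `transcript_id`, plus the [find_sites()]
#'   columns, ordered by (miRNA, transcript, position); `best` flags the
#'   best site per (miRNA, transcript) pair.
#' @export
predict_targets <- function(mirnas, transcripts, max_expectation = 3.0,
                            penalties = target_penalties()) {
  rows <- list()
  for (mi in names(mirnas)) {
    for (ti in names(transcripts)) {
      s <- find_sites(mirnas[[mi]], transcripts[[ti]], max_expectation, penalties)
      if (nrow(s)) {
        s <- cbind(data.frame(mirna_id = mi, transcript_id = ti,
                              stringsAsFactors = FALSE), s)
        rows[[length(rows) + 1L]] <- s
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), expectation = numeric(),
                      mode = character(), gap = character(), gap_pos = integer(),
                      alignment = character(), schwab_pass = logical(),
                      best = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
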