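# Independent oracles used by unit and acceptance tests. Each is written
# as a direct, enumeration-style implementation kept apart from the
# package's own (optimised) code paths.

# Direct-summation two-library p-value: terms of the conditional
# distribution computed by recurrence in plain double arithmetic.
oracle_pvalue <- function(x, y, n1, n2) {
  r <- n2 / n1
  t0 <- exp(-(x + 1) * log1p(r))  # p(0 | x)
  # lower tail 0..y
  term <- t0
  lower <- term
  yp <- 0
  while (yp < y) {
    term <- term * r * (x + yp + 1) / ((yp + 1) * (1 + r))
    yp <- yp + 1
    lower <- lower + term
  }
  # upper tail y..inf: continue the recurrence until terms vanish
  upper <- term  # term at y' = y
  repeat {
    term <- term * r * (x + yp + 1) / ((yp + 1) * (1 + r))
    yp <- yp + 1
    upper <- upper + term
    if (term < upper * 1e-17 && yp > (x + 1) * r) break
  }
  min(1, 2 * min(lower, upper))
}

# --- folding oracle -----------------------------------------------------

oracle_pair_type <- function(a, b) {
  if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")) return(1L)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(2L)
  0L
}

# Exhaustively enumerate every single-stem ladder top-down (no loop-size
# caps, no memoisation), scoring steps incrementally as the ladder grows,
# and return the minimum score (0 for the empty structure).
oracle_fold_energy <- function(seq, cfg = fold_config()) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(chars)
  ptype <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ptype[i, j] <- oracle_pair_type(chars[i], chars[j])
    }
  }
  best <- 0
  extend <- function(i, j, acc) {
    if (j - i - 1 >= cfg$min_loop && acc + cfg$hairpin < best) {
      best <<- acc + cfg$hairpin
    }
    if (j - i - 1 < 2) return()
    for (k in (i + 1):(j - 1)) {
      for (l in (j - 1):(k + 1)) {
        if (ptype[k, l] == 0L) next
        step <- if (k == i + 1 && l == j - 1) {
          if (ptype[i, j] == 1L && ptype[k, l] == 1L) cfg$stack_wc
          else if (ptype[i, j] == 2L && ptype[k, l] == 2L) cfg$stack_gu
          else cfg$stack_wc_gu
        } else if ((k > i + 1) != (l < j - 1)) cfg$bulge else cfg$internal
        extend(k, l, acc + step)
      }
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ptype[i, j] > 0L) extend(i, j, 0)
    }
  }
  best
}

# --- target-site oracle -------------------------------------------------

# Brute-force enumeration of all windows and single-gap placements. Each
# window is scored column by column from a (miRNA base, target base)
# penalty lookup built from first principles; the search itself is a plain
# per-window loop.
oracle_find_sites <- function(mirna, transcript, cutoff = 3,
                              pen = target_penalties()) {
  norm <- function(x) chartr("uU", "TT", toupper(x))
  mc <- strsplit(norm(mirna), "")[[1]]
  tc <- strsplit(norm(transcript), "")[[1]]
  m <- length(mc); L <- length(tc)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  one_pen <- function(mb, tb) {
    if (comp[[mb]] == tb) 0
    else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) pen$gu
    else pen$mismatch
  }
  ptab <- outer(bases, bases, Vectorize(one_pen))
  dimnames(ptab) <- list(bases, bases)
  core_mult <- ifelse(seq_len(m) >= pen$core[1] & seq_len(m) <= pen$core[2], 2, 1)
  gap_pen <- function(g) pen$gap * core_mult[g]
  rows <- list()
  emit <- function(s, wlen, kind, g, e) {
    if (e <= cutoff) {
      rows[[length(rows) + 1L]] <<- data.frame(
        start = s - 1L, end = s - 1L + wlen, gap = kind,
        gap_pos = if (is.na(g)) NA_integer_ else as.integer(g),
        expectation = e, stringsAsFactors = FALSE)
    }
  }
  for (s in seq_len(L - m + 1)) {
    tgt <- rev(tc[s:(s + m - 1)])                    # column k faces miRNA k
    e <- sum(ptab[cbind(mc, tgt)] * core_mult)
    emit(s, m, "none", NA, e)
  }
  for (g in setdiff(2:m, 10:11)) {       # bulged target base before pos g
    wlen <- m + 1
    if (L < wlen) next
    keep <- setdiff(seq_len(wlen), g)    # target columns facing miRNA 1..m
    for (s in seq_len(L - wlen + 1)) {
      tgt <- rev(tc[s:(s + wlen - 1)])
      e <- sum(ptab[cbind(mc, tgt[keep])] * core_mult) + gap_pen(g)
      emit(s, wlen, "target", g, e)
    }
  }
  for (g in setdiff(2:(m - 1), 10:11)) { # miRNA base g unpaired
    wlen <- m - 1
    if (L < wlen) next
    keep <- setdiff(seq_len(m), g)
    for (s in seq_len(L - wlen + 1)) {
      tgt <- rev(tc[s:(s + wlen - 1)])
      e <- sum(ptab[cbind(mc[keep], tgt)] * core_mult[keep]) + gap_pen(g)
      emit(s, wlen, "mirna", g, e)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), gap = character(),
                      gap_pos = integer(), expectation = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$expectation, out$gap, out$gap_pos), ,
      drop = FALSE]
}

# --- known-miRNA matching oracle ----------------------------------------

# All-pairs sliding Hamming scan, plainly looped.
oracle_match <- function(tag, db, max_mm = 2, max_diff = 2) {
  best <- Inf; ids <- character(0)
  for (d in seq_along(db)) {
    a <- tag; b <- db[[d]]
    if (abs(nchar(a) - nchar(b)) > max_diff) next
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    la <- nchar(a); lb <- nchar(b)
    mm_best <- Inf
    for (o in 0:(lb - la)) {
      mm <- 0
      for (p in seq_len(la)) {
        if (substr(a, p, p) != substr(b, o + p, o + p)) mm <- mm + 1
      }
      mm_best <- min(mm_best, mm)
    }
    if (mm_best <= max_mm) {
      if (mm_best < best) { best <- mm_best; ids <- names(db)[d] }
      else if (mm_best == best) ids <- c(ids, names(db)[d])
    }
  }
  list(mismatches = best, ids = ids)
}

# random DNA helper for tests
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
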