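#' Read a small RNA sequencing library
#'
#' Parses a raw small RNA library from FASTQ, FASTA or collapsed FASTA
#' (headers of the form `">id_xCOUNT"`, where `COUNT` is the read
#' multiplicity of the unique sequence). Sequences are stored in the DNA
#' alphabet; `U` is converted to `T` on input.
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"`, `"fastq"`, `"fasta"`, `"collapsed-fasta"`.
#'   `"auto"` guesses from the file extension (`.fq`/`.fastq` vs `.fa`/
#'   `.fasta`); collapsed FASTA is recognised by its `_x<count>` header
#'   suffix.
#' @param label Library label (e.g. `"CK"`); defaults to the file name
#'   without extension.
#' @return A `raw_library`: a data frame with columns `sequence`,
#'   `quality` (`NA` when absent) and `count` (read multiplicity), with the
#'   library label in `attr(, "label")`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1_x3", "TCGGACCAGGCTTCATTCCCC"), fa)
#' lib <- read_small_rna(fa, label = "CK")
#' sum(lib$count)  # 3
#' @export
read_small_rna <- function(path, format = c("auto", "fastq", "fasta", "collapsed-fasta"),
                           label = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    info <- file.info(path)
    if (info$size == 0) {
      return(raw_library(character(), label = label))
    }
    # readQualityScaledDNAStringSet warns about dropping header metadata
    fq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    return(raw_library(
      sequence = normalize_dna(as.character(fq)),
      quality = as.character(Biostrings::quality(fq)),
      label = label
    ))
  }
  # fasta / collapsed-fasta
  fa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  if (length(fa) == 0) {
    return(raw_library(character(), label = label))
  }
  seqs <- normalize_dna(as.character(fa))
  ids <- names(fa)
  counts <- rep(1L, length(seqs))
  has_count <- grepl("_x[0-9]+\\s*$", ids)
  if (format == "collapsed-fasta" && !all(has_count)) {
    bad <- which(!has_count)[1]
    stop(sprintf("collapsed-fasta record %d ('%s') lacks an _x<count> suffix", bad, ids[bad]),
         call. = FALSE)
  }
  if (format == "collapsed-fasta" || (format == "fasta" && all(has_count) && length(ids) > 0)) {
    if (all(has_count)) {
      counts <- as.integer(sub("^.*_x([0-9]+)\\s*$", "\\1", ids))
    }
  }
  bad <- which(!grepl("^[ACGTN]*$", seqs))
  if (length(bad)) {
    stop(sprintf("malformed record %d: non-nucleotide characters in sequence", bad[1]),
         call. = FALSE)
  }
  raw_library(sequence = seqs, count = counts, label = label)
}

#' Construct a raw library object
#'
#' @param sequence Character vector of read sequences (DNA or RNA alphabet).
#' @param quality Optional character vector of Phred+33 quality strings.
#' @param count Integer read multiplicities (collapsed input); default 1.
#' @param label Library label.
#' @return A `raw_library` data frame (columns `sequence`, `quality`, `count`).
#' @export
raw_library <- function(sequence, quality = NA_character_, count = 1L, label = "library") {
  sequence <- normalize_dna(as.character(sequence))
  n <- length(sequence)
  quality <- rep_len(as.character(quality), if (n) n else 0)
  count <- rep_len(as.integer(count), if (n) n else 0)
  assert_that(all(nzchar(sequence)), "sequences must be non-empty")
  ok <- is.na(quality) | nchar(quality) == nchar(sequence)
  assert_that(all(ok), "quality strings must match sequence lengths")
  assert_that(all(count >= 0L), "counts must be non-negative")
  out <- data.frame(sequence = sequence, quality = quality, count = count,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("raw_library", "data.frame")
  out
}

#' Number of reads in a raw library
#' @param lib A `raw_library`.
#' @return Total read count (sum of multiplicities).
#' @export
n_reads <- function(lib) sum(lib$count)

# Locate the 3' adapter in each read. Returns the 1-based start position of
# the adapter, NA when not found. Rule: leftmost exact match of the first
# `min_overlap` adapter bases; reads without an exact seed are re-scanned
# allowing `max_mismatch` mismatches over the full overlap (>= min_overlap nt).
#' @noRd
locate_adapter <- function(seqs, adapter, min_overlap = 8L, max_mismatch = 1L) {
  adapter <- normalize_dna(adapter)
  seed <- substr(adapter, 1L, min_overlap)
  pos <- as.integer(regexpr(seed, seqs, fixed = TRUE))
  pos[pos < 0L] <- NA_integer_
  if (max_mismatch > 0L) {
    todo <- which(is.na(pos))
    alen <- nchar(adapter)
    for (i in todo) {
      s <- utf8ToInt(seqs[i])
      a <- utf8ToInt(adapter)
      n <- length(s)
      for (st in seq_len(max(0L, n - min_overlap + 1L))) {
        L <- min(alen, n - st + 1L)
        if (L < min_overlap) break
        if (sum(s[st:(st + L - 1L)] != a[seq_len(L)]) <= max_mismatch) {
          pos[i] <- st
          break
        }
      }
    }
  }
  pos
}

#' Clean raw small RNA reads
#'
#' Locates and trims the 3' adapter, then discards reads that are
#' unusable: no 3' adapter found (`adapter3_null`), adapter at the very
#' start so the insert is empty (`insert_null`), insert contaminated by the
#' 5' adapter (`adapter5_contaminant`), poly-A inserts, and inserts whose
#' length falls at or outside the `(min_len, max_len)` bounds (both
#' exclusive, so the defaults keep 19-29 nt).
#'
#' Adapter matching takes the leftmost exact match of the first
#' `adapter_min_overlap` adapter bases, falling back to a scan that allows
#' `adapter_max_mismatch` mismatches over the overlap. 5' contamination is
#' flagged when the insert contains the 3'-most `adapter5_overlap` bases of
#' the 5' adapter.
#'
#' @param lib A `raw_library`.
#' @param adapter3 3' adapter sequence; `NULL` skips adapter location and
#'   the `adapter3_null`/`insert_null` filters (for pre-trimmed input).
#' @param adapter5 5' adapter sequence; `NULL` skips the contaminant filter.
#' @param min_len,max_len Exclusive insert length bounds (defaults 18 and
#'   30: inserts of 18 nt or shorter and 30 nt or longer are removed).
#' @param polya_frac Discard inserts whose A fraction is at least this
#'   value (default 0.8).
#' @param adapter_min_overlap,adapter_max_mismatch Adapter matcher
#'   parameters.
#' @param adapter5_overlap Length of the 5'-adapter suffix used to detect
#'   contamination.
#' @return A cleaned `raw_library` of trimmed inserts. Per-reason discard
#'   read tallies are in `attr(, "discards")`; `attr(, "total_raw")` holds
#'   the input read count.
#' @export
clean_reads <- function(lib, adapter3 = NULL, adapter5 = NULL,
                        min_len = 18L, max_len = 30L, polya_frac = 0.8,
                        adapter_min_overlap = 8L, adapter_max_mismatch = 1L,
                        adapter5_overlap = 12L) {
  assert_that(min_len < max_len, "min_len must be < max_len")
  label <- attr(lib, "label")
  total_raw <- sum(lib$count)
  discards <- c(adapter3_null = 0, insert_null = 0, adapter5_contaminant = 0,
                polyA = 0, too_short = 0, too_long = 0)
  seqs <- lib$sequence
  counts <- lib$count
  quals <- lib$quality

  if (length(seqs) && !is.null(adapter3)) {
    pos <- locate_adapter(seqs, adapter3, adapter_min_overlap, adapter_max_mismatch)
    null3 <- is.na(pos)
    discards["adapter3_null"] <- sum(counts[null3])
    keep <- !null3
    seqs <- seqs[keep]; counts <- counts[keep]; quals <- quals[keep]; pos <- pos[keep]
    empty <- pos == 1L
    discards["insert_null"] <- sum(counts[empty])
    keep <- !empty
    seqs <- seqs[keep]; counts <- counts[keep]; quals <- quals[keep]; pos <- pos[keep]
    seqs <- substr(seqs, 1L, pos - 1L)
    quals <- ifelse(is.na(quals), quals, substr(quals, 1L, pos - 1L))
  }
  if (length(seqs) && !is.null(adapter5)) {
    a5 <- normalize_dna(adapter5)
    tail5 <- substr(a5, max(1L, nchar(a5) - adapter5_overlap + 1L), nchar(a5))
    hit5 <- grepl(tail5, seqs, fixed = TRUE) | grepl(a5, seqs, fixed = TRUE)
    discards["adapter5_contaminant"] <- sum(counts[hit5])
    seqs <- seqs[!hit5]; counts <- counts[!hit5]; quals <- quals[!hit5]
  }
  if (length(seqs)) {
    a_frac <- (nchar(seqs) - nchar(gsub("A", "", seqs, fixed = TRUE))) / nchar(seqs)
    polya <- a_frac >= polya_frac
    discards["polyA"] <- sum(counts[polya])
    seqs <- seqs[!polya]; counts <- counts[!polya]; quals <- quals[!polya]
  }
  if (length(seqs)) {
    len <- nchar(seqs)
    short <- len <= min_len
    long <- len >= max_len
    discards["too_short"] <- sum(counts[short])
    discards["too_long"] <- sum(counts[long])
    keep <- !short & !long
    seqs <- seqs[keep]; counts <- counts[keep]; quals <- quals[keep]
  }
  out <- raw_library(sequence = seqs, quality = quals, count = counts, label = label)
  attr(out, "discards") <- discards
  attr(out, "total_raw") <- total_raw
  out
}

#' Collapse cleaned reads to unique tags
#'
#' @param lib A cleaned `raw_library`.
#' @param label Library label for the count column; defaults to the
#'   library's own label.
#' @return A tag table: data frame with columns `sequence`, `length` and one
#'   raw-count column per library label, sorted by sequence. The sum of the
#'   count column equals the library's clean read count.
#' @export
collapse_tags <- function(lib, label = NULL) {
  label <- label %||% attr(lib, "label") %||% "library"
  if (nrow(lib) == 0) {
    out <- data.frame(sequence = character(), length = integer())
    out[[label]] <- integer()
    return(tag_table(out))
  }
  agg <- rowsum(lib$count, group = lib$sequence)
  out <- data.frame(sequence = rownames(agg), length = nchar(rownames(agg)),
                    stringsAsFactors = FALSE)
  out[[label]] <- as.integer(agg[, 1])
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  tag_table(out)
}

#' @noRd
tag_table <- function(df) {
  class(df) <- c("tag_table", "data.frame")
  df
}

#' Library labels of a tag table
#' @param tags A tag table.
#' @return Character vector of count-column labels.
#' @export
tag_labels <- function(tags) setdiff(names(tags), c("sequence", "length"))

#' Merge two tag tables
#'
#' Unions the tag sets; counts for sequences absent from one table are 0.
#' Merging tables that share a library label is an error.
#'
#' @param a,b Tag tables from [collapse_tags()].
#' @return A merged tag table with one count column per library.
#' @export
merge_tag_tables <- function(a, b) {
  la <- tag_labels(a); lb <- tag_labels(b)
  dup <- intersect(la, lb)
  assert_that(length(dup) == 0,
              sprintf("duplicate library label(s) on merge: %s", paste(dup, collapse = ", ")))
  m <- merge(as.data.frame(a)[c("sequence", la)], as.data.frame(b)[c("sequence", lb)],
             by = "sequence", all = TRUE)
  for (l in c(la, lb)) m[[l]][is.na(m[[l]])] <- 0L
  m$length <- nchar(m$sequence)
  m <- m[order(m$sequence), c("sequence", "length", la, lb), drop = FALSE]
  rownames(m) <- NULL
  tag_table(m)
}

#' Write a tag table to collapsed FASTA
#'
#' Headers take the form `">tag<i>_x<count>"`; a round trip through
#' [read_small_rna()] and [collapse_tags()] reproduces the table.
#'
#' @param tags Tag table.
#' @param path Output file.
#' @param label Which library's counts to write (default: first label).
#' @param drop_zero Drop tags with zero count in `label` (default TRUE).
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path, label = tag_labels(tags)[1],
                                  drop_zero = TRUE) {
  cnt <- tags[[label]]
  keep <- if (drop_zero) cnt > 0 else rep(TRUE, length(cnt))
  seqs <- tags$sequence[keep]
  cnt <- cnt[keep]
  lines <- character(2 * length(seqs))
  if (length(seqs)) {
    lines[c(TRUE, FALSE)] <- sprintf(">tag%d_x%d", seq_along(seqs), cnt)
    lines[c(FALSE, TRUE)] <- seqs
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a raw library to FASTQ
#'
#' Reads with multiplicity > 1 are expanded; missing qualities are written
#' as constant `"I"`.
#'
#' @param lib A `raw_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  idx <- rep.int(seq_len(nrow(lib)), lib$count)
  seqs <- lib$sequence[idx]
  quals <- lib$quality[idx]
  quals[is.na(quals)] <- strrep("I", nchar(seqs[is.na(quals)]))
  lines <- character(4 * length(seqs))
  if (length(seqs)) {
    lines[c(TRUE, FALSE, FALSE, FALSE)] <- sprintf("@read%d", seq_along(seqs))
    lines[c(FALSE, TRUE, FALSE, FALSE)] <- seqs
    lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    lines[c(FALSE, FALSE, FALSE, TRUE)] <- quals
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read-length distribution of a library
#'
#' @param tags Tag table.
#' @param label Library label (default: first).
#' @return Data frame with columns `length` and `reads` (total reads of that
#'   length); the modal length is in `attr(, "modal_length")`.
#' @export
length_distribution <- function(tags, label = tag_labels(tags)[1]) {
  cnt <- tags[[label]]
  if (length(cnt) == 0 || sum(cnt) == 0) {
    out <- data.frame(length = integer(), reads = numeric())
    attr(out, "modal_length") <- NA_integer_
    return(out)
  }
  agg <- rowsum(as.numeric(cnt), group = tags$length)
  out <- data.frame(length = as.integer(rownames(agg)), reads = agg[, 1])
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "modal_length") <- out$length[which.max(out$reads)]
  out
}

SRNA_CATEGORIES <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unannotated")

#' Per-category accounting of a library's tags
#'
#' Tallies unique tags and total reads per small RNA category (miRNA, the
#' four non-coding RNA classes, and unannotated), with percentages against
#' the library's unique and total clean counts.
#'
#' @param tags Tag table.
#' @param categories Character vector (one of `r paste(SRNA_CATEGORIES,
#'   collapse=", ")`) aligned with the rows of `tags`.
#' @param label Library label.
#' @param total_raw Optional raw read count before cleaning.
#' @return A `library_stats` list: `label`, `total_raw`, `total_clean`,
#'   `unique_clean`, and `table` (category, unique, unique_pct, total,
#'   total_pct; percentages rounded to 2 decimals).
#' @export
category_accounting <- function(tags, categories, label = tag_labels(tags)[1],
                                total_raw = NA_real_) {
  assert_that(length(categories) == nrow(tags),
              "categories must assign every tag exactly one category")
  assert_that(!anyNA(categories), "unassigned tag: annotation stage bug")
  bad <- setdiff(unique(categories), SRNA_CATEGORIES)
  assert_that(length(bad) == 0,
              sprintf("unknown categories: %s", paste(bad, collapse = ", ")))
  cnt <- as.numeric(tags[[label]])
  present <- cnt > 0
  fcat <- factor(categories, levels = SRNA_CATEGORIES)
  uniq <- tapply(present, fcat, sum, default = 0)
  tot <- tapply(cnt, fcat, sum, default = 0)
  unique_clean <- sum(present)
  total_clean <- sum(cnt)
  tab <- data.frame(
    category = SRNA_CATEGORIES,
    unique = as.integer(uniq),
    unique_pct = round(100 * as.numeric(uniq) / unique_clean, 2),
    total = as.numeric(tot),
    total_pct = round(100 * as.numeric(tot) / total_clean, 2),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(tab$total) == total_clean)  # conservation
  structure(list(label = label, total_raw = total_raw, total_clean = total_clean,
                 unique_clean = unique_clean, table = tab),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("Library %s: %s clean reads (%s unique tags)\n", x$label,
              format(x$total_clean, big.mark = ","),
              format(x$unique_clean, big.mark = ",")))
  print(x$table, row.names = FALSE)
  invisible(x)
}
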