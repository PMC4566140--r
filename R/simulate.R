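# Seeded synthetic-data generator: a reference with planted known-miRNA
# loci, novel hairpin loci and ncRNA decoys, plus two sequencing libraries
# with chosen depths and per-miRNA fold changes. The generator's truth
# tables drive the package's parameter-recovery tests.

#' Default read-length profile of a plant small RNA library
#'
#' Insert lengths 16-30 nt with the 21-nt class modal and secondary mass
#' at 24 nt, the shape typical of plant small RNA libraries.
#' @return Named numeric vector of sampling weights by length.
#' @export
default_length_profile <- function() {
  w <- c(1, 1, 2, 4, 8, 30, 14, 6, 10, 5, 3, 2, 1, 1, 1)
  stats::setNames(w / sum(w), 16:30)
}

#' Specification of a synthetic two-library experiment
#'
#' The defaults describe the emulated study design: two pooled libraries
#' at a depth ratio of ~1.08 (treated over control), 50 planted known
#' miRNAs of which 10 carry true log2 fold changes of magnitude >= 2 with
#' expected counts >= 100, 20 planted novel hairpin precursors
#' (model MFE <= -18 kcal/mol), ncRNA contamination totalling ~8.4% of
#' reads, and a 16-30 nt insert length profile with mode 21 nt.
#'
#' @param seed Integer seed; all sampling happens in [generate_synthetic()]
#'   under this seed.
#' @param n_contigs,contig_length Reference shape (default 20 x 10 kb).
#' @param n_known_mirnas Planted known mature miRNAs (default 50).
#' @param n_novel_hairpins Planted novel hairpin loci (default 20).
#' @param n_ncrna_decoys ncRNA records planted in the reference and listed
#'   in the ncRNA database (default 12, cycled over rRNA/tRNA/snRNA/snoRNA).
#' @param library_labels Two library names (control first).
#' @param library_depths Reads per library; default `c(1e6, 1078589)`,
#'   preserving the emulated study's treated/control depth ratio.
#' @param de_spec Named numeric of true log2 fold changes (treated over
#'   control) for a subset of known miRNAs; `NULL` plants the default 10
#'   (lfc 2, -2, 3, -3, 4, -4, 2.5, -2.5, 5, -5 on the first ten miRNAs).
#' @param contamination Named fractions of reads per ncRNA class.
#' @param length_profile Insert length weights; see
#'   [default_length_profile()].
#' @param n_background_tags Unannotated background tags drawn from the
#'   reference (default 5000).
#' @param adapter3,adapter5 Adapter sequences carried by the reads.
#' @param read_length Raw read length before trimming (default 50).
#' @param error_rate Per-base uniform substitution rate (default 0.001).
#' @param star_fraction Fraction of novel hairpins whose star strand also
#'   receives reads (default 0.3).
#' @param corrupt_fracs Read fractions for the four corrupt classes
#'   (no 3' adapter, empty insert, 5'-adapter contamination, poly-A).
#' @param dispersion `NULL` for Poisson counts; otherwise the negative
#'   binomial size parameter for overdispersed counts.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L, n_contigs = 20L, contig_length = 10000L,
                            n_known_mirnas = 50L, n_novel_hairpins = 20L,
                            n_ncrna_decoys = 12L,
                            library_labels = c("CK", "Cr200"),
                            library_depths = c(1e6, 1078589),
                            de_spec = NULL,
                            contamination = c(rRNA = 0.074, tRNA = 0.009,
                                              snRNA = 0.001, snoRNA = 0.0003),
                            length_profile = default_length_profile(),
                            n_background_tags = 5000L,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            read_length = 50L, error_rate = 0.001,
                            star_fraction = 0.3,
                            corrupt_fracs = c(adapter3_null = 0.010,
                                              insert_null = 0.005,
                                              adapter5 = 0.005,
                                              polyA = 0.005),
                            dispersion = NULL) {
  assert_that(all(library_depths > 0), "library depths must be positive")
  assert_that(length(library_labels) == 2 && length(library_depths) == 2,
              "exactly two libraries are simulated")
  assert_that(all(names(contamination) %in% NCRNA_CLASSES),
              "contamination names must be ncRNA classes")
  assert_that(error_rate >= 0 && error_rate < 0.1, "error_rate out of range")
  spec <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
               contig_length = as.integer(contig_length),
               n_known_mirnas = as.integer(n_known_mirnas),
               n_novel_hairpins = as.integer(n_novel_hairpins),
               n_ncrna_decoys = as.integer(n_ncrna_decoys),
               library_labels = library_labels,
               library_depths = stats::setNames(library_depths, library_labels),
               de_spec = de_spec, contamination = contamination,
               length_profile = length_profile,
               n_background_tags = as.integer(n_background_tags),
               adapter3 = adapter3, adapter5 = adapter5,
               read_length = as.integer(read_length), error_rate = error_rate,
               star_fraction = star_fraction, corrupt_fracs = corrupt_fracs,
               dispersion = dispersion)
  class(spec) <- "simulation_spec"
  spec
}

# n random DNA sequences with the given lengths (vector), sampled fast
#' @noRd
rand_dna <- function(lens) {
  total <- sum(lens)
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  s <- paste(bases, collapse = "")
  substring(s, starts, ends)
}

# Construct a hairpin precursor around a mature sequence:
# flank5 | ext | mature-or-star arm | loop | other arm | rc(ext) | flank3.
# `n_mut` mismatches are injected into the star side of the duplex.
#' @noRd
build_hairpin <- function(mature, target_len, arm = "5p", n_mut = 0) {
  mlen <- nchar(mature)
  f5 <- sample(3:10, 1)
  f3 <- sample(3:10, 1)
  loop <- sample(8:30, 1)
  ext <- max(0L, (target_len - f5 - f3 - loop - 2L * mlen) %/% 2L)
  extseq <- if (ext > 0) rand_dna(ext) else ""
  star <- revcomp(mature)
  if (n_mut > 0) {
    pos <- sample(seq_len(mlen), n_mut)
    sv <- strsplit(star, "")[[1]]
    for (p in pos) sv[p] <- sample(setdiff(DNA_BASES, sv[p]), 1)
    star <- paste(sv, collapse = "")
  }
  if (arm == "5p") {
    prec <- paste0(rand_dna(f5), extseq, mature, rand_dna(loop), star,
                   revcomp(extseq), rand_dna(f3))
    offset <- f5 + nchar(extseq) + 1L
  } else {
    prec <- paste0(rand_dna(f5), extseq, star, rand_dna(loop), mature,
                   revcomp(extseq), rand_dna(f3))
    offset <- f5 + nchar(extseq) + nchar(star) + loop + 1L
  }
  list(precursor = prec, mature_offset = offset, star = star)
}

#' @noRd
draw_counts <- function(mu, dispersion = NULL) {
  if (is.null(dispersion)) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), size = dispersion, mu = mu)
}

#' Generate a synthetic two-library small RNA experiment
#'
#' Builds, deterministically from the spec's seed, a reference sequence
#' set with planted known-miRNA loci, novel hairpin precursors and ncRNA
#' decoys; a mature miRNA database; an ncRNA database; and two read
#' libraries whose per-miRNA counts follow the spec's depths and true fold
#' changes (Poisson by default). Reads carry the 3' adapter and are padded
#' to the read length; corrupt read classes exercise every cleaning
#' filter.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory for FASTA/FASTQ/TSV files; `NULL` keeps the
#'   experiment in memory only.
#' @param read_format `"collapsed"` writes collapsed FASTA libraries,
#'   `"fastq"` expands reads into 4-line FASTQ.
#' @return A list: `spec`, `reference` (named character), `mature` (named
#'   character), `ncrna_db` (data frame), `libraries` (named list of
#'   `raw_library`), `truth` (list of data frames `known`, `novel`,
#'   `ncrna`, `background`), and `files` (named paths when `dir` is
#'   given).
#' @export
generate_synthetic <- function(spec = simulation_spec(), dir = NULL,
                               read_format = c("collapsed", "fastq")) {
  read_format <- match.arg(read_format)
  set.seed(spec$seed)
  labels <- spec$library_labels
  depths <- spec$library_depths

  contigs <- rand_dna(rep(spec$contig_length, spec$n_contigs))
  names(contigs) <- sprintf("contig%02d", seq_len(spec$n_contigs))

  # slot grid for non-overlapping planting
  slot_w <- 400L
  per_contig <- spec$contig_length %/% slot_w
  slots <- expand.grid(contig = seq_len(spec$n_contigs), slot = seq_len(per_contig))
  n_feat <- spec$n_known_mirnas + spec$n_novel_hairpins + spec$n_ncrna_decoys
  assert_that(n_feat <= nrow(slots), "reference too small for requested features")
  picked <- slots[sample.int(nrow(slots), n_feat), , drop = FALSE]
  plant <- function(row, seq) {
    pos <- (picked$slot[row] - 1L) * slot_w + sample.int(slot_w - nchar(seq) - 2L, 1)
    ci <- picked$contig[row]
    substr(contigs[ci], pos + 1L, pos + nchar(seq)) <<- seq
    c(ci, pos)  # 0-based start
  }

  # --- known miRNAs -------------------------------------------------------
  nk <- spec$n_known_mirnas
  klens <- sample(20:24, nk, replace = TRUE, prob = c(0.15, 0.55, 0.15, 0.10, 0.05))
  kseqs <- rand_dna(klens)
  while (anyDuplicated(kseqs)) {
    dup <- which(duplicated(kseqs))
    kseqs[dup] <- rand_dna(klens[dup])
  }
  kids <- sprintf("syn-miR%03d", seq_len(nk))
  kloc <- t(vapply(seq_len(nk), function(i) plant(i, kseqs[i]), numeric(2)))

  de <- spec$de_spec
  if (is.null(de)) {
    nde <- min(10L, nk)
    de <- stats::setNames(c(2, -2, 3, -3, 4, -4, 2.5, -2.5, 5, -5)[seq_len(nde)],
                          kids[seq_len(nde)])
  }
  lfc <- stats::setNames(rep(0, nk), kids)
  lfc[names(de)] <- de
  # abundances are rates per million control reads (the emulated study's
  # scale): DE miRNAs sized so both libraries expect >= 100 reads at the
  # default 1e6 depth; null miRNAs log-uniform. Expected counts scale with
  # the spec's depths.
  rate_ck <- stats::setNames(exp(stats::runif(nk, log(20), log(3000))), kids)
  rate_ck[names(de)] <- ifelse(de >= 0, 150, 120 * 2^abs(de))
  exp_ck <- rate_ck / 1e6 * depths[1]
  exp_tr <- rate_ck / 1e6 * depths[2] * 2^lfc

  # --- novel hairpins -----------------------------------------------------
  nn <- spec$n_novel_hairpins
  novel <- NULL
  if (nn > 0) {
    nlens <- sample(20:23, nn, replace = TRUE, prob = c(0.2, 0.5, 0.2, 0.1))
    plens <- round(stats::runif(nn, 60, 332))
    narms <- sample(c("5p", "3p"), nn, replace = TRUE)
    nmuts <- sample(0:2, nn, replace = TRUE)
    rows <- vector("list", nn)
    for (i in seq_len(nn)) {
      for (try in seq_len(100L)) {
        mat <- rand_dna(nlens[i])
        hp <- build_hairpin(mat, plens[i], narms[i], nmuts[i])
        f <- fold_rna(hp$precursor)
        if (f$mfe <= -18) break
        if (try == 100L) stop("hairpin generation failed after 100 retries")
      }
      at <- plant(nk + i, hp$precursor)
      rows[[i]] <- data.frame(
        novel_id = sprintf("syn-novel%02d", i), mature = mat,
        star = hp$star, precursor = hp$precursor, arm = narms[i],
        contig = names(contigs)[at[1]],
        prec_start = at[2], prec_end = at[2] + nchar(hp$precursor),
        mature_start = at[2] + hp$mature_offset - 1L,
        mfe = f$mfe, stringsAsFactors = FALSE)
    }
    novel <- do.call(rbind, rows)
    novel$expected_ck <- round(exp(stats::runif(nn, log(50), log(300))) /
                                 1e6 * depths[1])
    novel$star_reads <- stats::runif(nn) < spec$star_fraction
  }

  # --- ncRNA decoys -------------------------------------------------------
  nd <- spec$n_ncrna_decoys
  ncrna_db <- NULL
  if (nd > 0) {
    classes <- rep(names(spec$contamination), length.out = nd)
    dlens <- sample(80:150, nd, replace = TRUE)
    dseqs <- rand_dna(dlens)
    for (i in seq_len(nd)) plant(nk + nn + i, dseqs[i])
    ncrna_db <- data.frame(id = sprintf("syn-ncrna%02d", seq_len(nd)),
                           class = classes, sequence = dseqs,
                           stringsAsFactors = FALSE)
  }

  # --- tag-level libraries ------------------------------------------------
  # background tags: random substrings of the reference (mappable)
  nb <- spec$n_background_tags
  bg_len <- as.integer(sample(names(spec$length_profile), nb, replace = TRUE,
                              prob = spec$length_profile))
  bg_contig <- sample.int(spec$n_contigs, nb, replace = TRUE)
  bg_pos <- floor(stats::runif(nb, 0, spec$contig_length - bg_len))
  bg_seq <- substring(contigs[bg_contig], bg_pos + 1L, bg_pos + bg_len)
  bg_w <- 1 / seq_len(nb)  # Zipf-ish abundance profile

  # ncRNA fragments per class
  frag_rows <- NULL
  if (nd > 0) {
    frag <- list()
    for (cl in names(spec$contamination)) {
      recs <- ncrna_db[ncrna_db$class == cl, , drop = FALSE]
      if (!nrow(recs)) next
      nf <- 40L
      ri <- sample.int(nrow(recs), nf, replace = TRUE)
      fl <- as.integer(sample(names(spec$length_profile), nf, replace = TRUE,
                              prob = spec$length_profile))
      fl <- pmin(fl, nchar(recs$sequence[ri]))
      fp <- floor(stats::runif(nf, 0, nchar(recs$sequence[ri]) - fl + 1))
      frag[[cl]] <- data.frame(sequence = substring(recs$sequence[ri], fp + 1L, fp + fl),
                               class = cl, w = stats::runif(nf, 0.2, 1),
                               stringsAsFactors = FALSE)
    }
    frag_rows <- do.call(rbind, frag)
  }

  make_library <- function(lab) {
    depth <- depths[[lab]]
    is_ck <- lab == labels[1]
    tag <- list()
    add <- function(sequence, count, origin, id = NA_character_) {
      keep <- count > 0
      if (!any(keep)) return()
      id <- rep_len(id, length(sequence))
      tag[[length(tag) + 1L]] <<- data.frame(
        sequence = sequence[keep], count = as.integer(count[keep]),
        origin = origin, id = id[keep],
        stringsAsFactors = FALSE)
    }
    mu_mi <- if (is_ck) exp_ck else exp_tr
    add(kseqs, draw_counts(mu_mi, spec$dispersion), "miRNA", kids)
    if (!is.null(novel)) {
      mu_nov <- novel$expected_ck * (if (is_ck) 1 else depths[2] / depths[1])
      add(novel$mature, draw_counts(mu_nov, spec$dispersion), "novel", novel$novel_id)
      star_mu <- ifelse(novel$star_reads, 3, 0)
      add(novel$star, draw_counts(star_mu, spec$dispersion), "novel_star",
          novel$novel_id)
    }
    if (!is.null(frag_rows)) {
      for (cl in unique(frag_rows$class)) {
        f <- frag_rows[frag_rows$class == cl, , drop = FALSE]
        size <- stats::rpois(1, spec$contamination[[cl]] * depth)
        cnt <- if (size > 0) stats::rmultinom(1, size, f$w)[, 1] else rep(0L, nrow(f))
        add(f$sequence, cnt, cl, f$sequence)
      }
    }
    corrupt_n <- round(spec$corrupt_fracs * depth)
    used <- sum(vapply(tag, function(d) sum(d$count), numeric(1))) + sum(corrupt_n)
    bg_total <- max(0, round(depth) - used)
    bg_cnt <- stats::rmultinom(1, bg_total, bg_w)[, 1]
    add(bg_seq, bg_cnt, "background", bg_seq)
    tags <- do.call(rbind, tag)
    list(tags = tags, corrupt_n = corrupt_n)
  }

  filler <- function(n) strrep("A", n)
  to_reads <- function(libtags, corrupt_n) {
    inserts <- libtags$sequence
    counts <- libtags$count
    # sequencing errors: per-read substitutions become singleton tags
    if (spec$error_rate > 0) {
      p_err <- 1 - (1 - spec$error_rate)^nchar(inserts)
      n_err <- stats::rbinom(length(inserts), counts, p_err)
      err_idx <- rep.int(seq_along(inserts), n_err)
      counts <- counts - n_err
      if (length(err_idx)) {
        s <- inserts[err_idx]
        p <- floor(stats::runif(length(s), 1, nchar(s) + 1))
        old <- substr(s, p, p)
        sub <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
        mut <- paste0(substr(s, 1, p - 1), sub, substring(s, p + 1))
        inserts <- c(inserts, mut)
        counts <- c(counts, rep(1L, length(mut)))
      }
    }
    reads <- substr(paste0(inserts, spec$adapter3, filler(spec$read_length)),
                    1L, spec$read_length)
    # corrupt classes
    a3 <- spec$adapter3; a5 <- spec$adapter5
    seed8 <- substr(a3, 1, 8)
    n_no3 <- corrupt_n[["adapter3_null"]]
    if (n_no3 > 0) {
      junk <- rand_dna(rep(spec$read_length, 20))
      while (any(grepl(seed8, junk, fixed = TRUE))) {
        bad <- grepl(seed8, junk, fixed = TRUE)
        junk[bad] <- rand_dna(rep(spec$read_length, sum(bad)))
      }
      reads <- c(reads, junk)
      counts <- c(counts, stats::rmultinom(1, n_no3, rep(1, 20))[, 1])
    }
    n_ins0 <- corrupt_n[["insert_null"]]
    if (n_ins0 > 0) {
      reads <- c(reads, substr(paste0(a3, filler(spec$read_length)), 1, spec$read_length))
      counts <- c(counts, n_ins0)
    }
    n_a5 <- corrupt_n[["adapter5"]]
    if (n_a5 > 0) {
      ins <- paste0(substr(a5, nchar(a5) - 11L, nchar(a5)), rand_dna(rep(9, 10)))
      reads <- c(reads, substr(paste0(ins, a3, filler(spec$read_length)),
                               1, spec$read_length))
      counts <- c(counts, stats::rmultinom(1, n_a5, rep(1, 10))[, 1])
    }
    n_pa <- corrupt_n[["polyA"]]
    if (n_pa > 0) {
      reads <- c(reads, substr(paste0(strrep("A", 21), a3, filler(spec$read_length)),
                               1, spec$read_length))
      counts <- c(counts, n_pa)
    }
    keep <- counts > 0
    raw_library(sequence = reads[keep], count = counts[keep])
  }

  libs <- list()
  truth_counts <- list()
  for (lab in labels) {
    ml <- make_library(lab)
    rl <- to_reads(ml$tags, ml$corrupt_n)
    attr(rl, "label") <- lab
    libs[[lab]] <- rl
    truth_counts[[lab]] <- ml$tags
  }

  truth_known <- data.frame(
    mirna_id = kids, sequence = kseqs, length = klens,
    contig = names(contigs)[kloc[, 1]], start = kloc[, 2],
    true_log2fc = unname(lfc),
    expected_ck = unname(exp_ck), expected_tr = unname(exp_tr),
    stringsAsFactors = FALSE)
  for (lab in labels) {
    tl <- truth_counts[[lab]]
    mi <- tl[tl$origin == "miRNA", , drop = FALSE]
    truth_known[[paste0("count_", lab)]] <-
      mi$count[match(truth_known$mirna_id, mi$id)]
    truth_known[[paste0("count_", lab)]][is.na(truth_known[[paste0("count_", lab)]])] <- 0L
  }

  out <- list(spec = spec, reference = contigs,
              mature = stats::setNames(kseqs, kids),
              ncrna_db = ncrna_db, libraries = libs,
              truth = list(known = truth_known, novel = novel,
                           ncrna = ncrna_db,
                           background = data.frame(sequence = bg_seq,
                                                   length = bg_len,
                                                   stringsAsFactors = FALSE)),
              files = NULL)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    files$reference <- file.path(dir, "reference.fasta")
    writeLines(as.vector(rbind(paste0(">", names(contigs)), contigs)), files$reference)
    files$mature <- file.path(dir, "mature.fasta")
    writeLines(as.vector(rbind(paste0(">", kids), kseqs)), files$mature)
    if (!is.null(ncrna_db)) {
      files$ncrna <- file.path(dir, "ncrna.fasta")
      writeLines(as.vector(rbind(sprintf(">%s class=%s", ncrna_db$id, ncrna_db$class),
                                 ncrna_db$sequence)), files$ncrna)
    }
    for (lab in labels) {
      if (read_format == "fastq") {
        f <- file.path(dir, sprintf("reads_%s.fq", lab))
        write_fastq(libs[[lab]], f)
      } else {
        f <- file.path(dir, sprintf("reads_%s.fa", lab))
        lib <- libs[[lab]]
        writeLines(as.vector(rbind(sprintf(">tag%d_x%d", seq_len(nrow(lib)), lib$count),
                                   lib$sequence)), f)
      }
      files[[paste0("reads_", lab)]] <- f
    }
    files$truth_known <- file.path(dir, "truth_known.tsv")
    utils::write.table(truth_known, files$truth_known, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(novel)) {
      files$truth_novel <- file.path(dir, "truth_novel.tsv")
      utils::write.table(novel, files$truth_novel, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    out$files <- files
  }
  out
}
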