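# End-to-end orchestration: clean -> collapse -> map -> ncRNA exclusion ->
# known-miRNA annotation -> novel calling -> differential expression ->
# (optional) target prediction, with TSV report writers.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters, validating ranges up front.
#' Unknown arguments are rejected.
#'
#' @param libraries Named character vector of two read-library paths
#'   (control first); names are the library labels.
#' @param reference Reference FASTA path.
#' @param mature_db Mature miRNA FASTA path.
#' @param ncrna_db Class-labelled ncRNA FASTA path (optional).
#' @param transcripts Transcript FASTA for target prediction (optional).
#' @param read_format Passed to [read_small_rna()].
#' @param adapter3,adapter5 Adapter sequences for [clean_reads()]; set
#'   `adapter3 = NULL` for pre-trimmed input.
#' @param min_len,max_len Exclusive insert length bounds.
#' @param max_mismatch Known-miRNA mismatch allowance.
#' @param hairpin [hairpin_criteria()].
#' @param fold [fold_config()].
#' @param thresholds [de_thresholds()].
#' @param max_expectation Target-score cutoff.
#' @param call_novel Run the novel-miRNA stage (default TRUE).
#' @param novel_prefix Identifier prefix for novel records.
#' @param seed Seed recorded in the run log.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(libraries, reference, mature_db, ncrna_db = NULL,
                            transcripts = NULL, read_format = "auto",
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            min_len = 18L, max_len = 30L, max_mismatch = 2L,
                            hairpin = hairpin_criteria(), fold = fold_config(),
                            thresholds = de_thresholds(), max_expectation = 3.0,
                            call_novel = TRUE, novel_prefix = "miRn", seed = 1L) {
  assert_that(length(libraries) == 2 && !is.null(names(libraries)),
              "exactly two named library paths are required")
  assert_that(min_len < max_len, "min_len must be < max_len")
  assert_that(max_mismatch >= 0, "max_mismatch must be >= 0")
  for (p in c(libraries, reference, mature_db, ncrna_db, transcripts)) {
    assert_that(file.exists(p), sprintf("input not found: %s", p))
  }
  structure(list(libraries = libraries, reference = reference,
                 mature_db = mature_db, ncrna_db = ncrna_db,
                 transcripts = transcripts, read_format = read_format,
                 adapter3 = adapter3, adapter5 = adapter5,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_mismatch = as.integer(max_mismatch), hairpin = hairpin,
                 fold = fold, thresholds = thresholds,
                 max_expectation = max_expectation, call_novel = call_novel,
                 novel_prefix = novel_prefix, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full two-library small RNA pipeline
#'
#' Stages run in order: read + clean + collapse each library, perfect-match
#' reference mapping, ncRNA exclusion, known-miRNA annotation, per-library
#' category accounting, family summary, known differential expression,
#' novel hairpin calling and novel differential expression, and target
#' prediction when transcripts are supplied. Every tag ends in exactly one
#' category; the category totals are asserted to sum to the clean totals
#' before reports are written.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing.
#' @return A list of stage results: `stats` (per-library
#'   `library_stats`), `tags`, `categories`, `known_hits`, `families`,
#'   `de_known`, `novel`, `de_novel`, `targets`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  labels <- names(config$libraries)
  say("pipeline start (seed %d); libraries: %s", config$seed,
      paste(labels, collapse = ", "))

  # clean + collapse
  tabs <- list()
  total_raw <- total_clean <- stats::setNames(numeric(2), labels)
  discards <- list()
  for (lab in labels) {
    lib <- read_small_rna(config$libraries[[lab]], config$read_format, label = lab)
    cl <- clean_reads(lib, adapter3 = config$adapter3, adapter5 = config$adapter5,
                      min_len = config$min_len, max_len = config$max_len)
    total_raw[lab] <- attr(cl, "total_raw")
    total_clean[lab] <- n_reads(cl)
    discards[[lab]] <- attr(cl, "discards")
    say("%s: %d raw -> %d clean reads (discards: %s)", lab,
        attr(cl, "total_raw"), n_reads(cl),
        paste(sprintf("%s=%d", names(discards[[lab]]), discards[[lab]]), collapse = " "))
    tabs[[lab]] <- collapse_tags(cl, lab)
  }
  tags <- merge_tag_tables(tabs[[1]], tabs[[2]])
  say("merged: %d unique tags", nrow(tags))

  # reference mapping
  reference <- stats::setNames(
    normalize_dna(as.character(Biostrings::readBStringSet(config$reference))),
    sub("\\s.*$", "", names(Biostrings::readBStringSet(config$reference))))
  mapping <- map_reference(tags, reference)
  say("mapped tags: %d / %d", sum(mapping$mapped), nrow(tags))

  # category partition: ncRNA classes first, then known miRNAs
  categories <- rep("unannotated", nrow(tags))
  mapped_tags <- tags[mapping$mapped, , drop = FALSE]
  nc_class <- NULL
  if (!is.null(config$ncrna_db)) {
    ncdb <- read_ncrna_fasta(config$ncrna_db)
    nc <- filter_ncrna(mapped_tags, ncdb)
    nc_class <- nc$classified
    categories[match(nc_class$sequence, tags$sequence)] <- nc_class$class
    mapped_tags <- nc$remaining
    say("ncRNA-excluded tags: %d", nrow(nc_class))
  }
  mature <- Biostrings::readBStringSet(config$mature_db)
  mature <- stats::setNames(normalize_dna(as.character(mature)),
                            sub("\\s.*$", "", names(mature)))
  hits <- match_mirbase(mapped_tags, mature, max_mismatch = config$max_mismatch)
  categories[tags$sequence %in% hits$sequence] <- "miRNA"
  say("known miRNA tags: %d (%d distinct miRNAs)",
      length(unique(hits$sequence)), length(unique(hits$mirna_id[hits$primary])))

  stats_by_lib <- lapply(labels, function(lab) {
    category_accounting(tags, categories, lab, total_raw = total_raw[lab])
  })
  names(stats_by_lib) <- labels

  # known-miRNA expression
  counts <- mirna_counts(hits, tags)
  counts$type <- "known"
  fam <- family_summary(counts, total_clean)
  de_known <- de_table(counts, total_clean, config$thresholds)
  s <- attr(de_known, "summary")
  say("known DE: %d significant (%d up, %d down) of %d",
      s$n_significant, s$n_up, s$n_down, s$n)

  # novel miRNA calling on unannotated mapped tags
  novel <- NULL
  de_novel <- NULL
  if (isTRUE(config$call_novel)) {
    un_idx <- categories == "unannotated" & mapping$mapped
    un_tags <- tags[un_idx, , drop = FALSE]
    loci <- mapping$loci[mapping$loci$sequence %in% un_tags$sequence, , drop = FALSE]
    res <- call_novel(un_tags, loci, reference, tag_table = tags,
                      criteria = config$hairpin, config = config$fold,
                      prefix = config$novel_prefix)
    novel <- res$novel
    say("novel miRNAs called: %d (of %d unannotated mapped tags)",
        nrow(novel), nrow(un_tags))
    if (nrow(novel)) {
      nseq <- chartr("U", "T", novel$sequence)
      ncounts <- data.frame(mirna_id = novel$novel_id, stringsAsFactors = FALSE)
      for (lab in labels) {
        ncounts[[lab]] <- tags[[lab]][match(nseq, tags$sequence)]
        ncounts[[lab]][is.na(ncounts[[lab]])] <- 0
      }
      ncounts$type <- "novel"
      de_novel <- de_table(ncounts, total_clean, config$thresholds)
      sn <- attr(de_novel, "summary")
      say("novel DE: %d significant (%d up, %d down)",
          sn$n_significant, sn$n_up, sn$n_down)
    }
  }

  # target prediction
  targets <- NULL
  if (!is.null(config$transcripts)) {
    tx <- Biostrings::readBStringSet(config$transcripts)
    tx <- stats::setNames(normalize_dna(as.character(tx)),
                          sub("\\s.*$", "", names(tx)))
    mir_set <- mature[unique(hits$mirna_id[hits$primary])]
    if (!is.null(novel) && nrow(novel)) {
      nm <- stats::setNames(chartr("U", "T", novel$sequence), novel$novel_id)
      mir_set <- c(mir_set, nm)
    }
    targets <- predict_targets(mir_set, tx, config$max_expectation)
    say("target sites: %d", nrow(targets))
  }

  out <- list(stats = stats_by_lib, tags = tags, categories = categories,
              mapping = mapping, known_hits = hits, families = fam,
              de_known = de_known, novel = novel, de_novel = de_novel,
              targets = targets, discards = discards, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) {
      utils::write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    cat_tab <- do.call(rbind, lapply(labels, function(lab) {
      st <- stats_by_lib[[lab]]
      stopifnot(sum(st$table$total) == st$total_clean)
      cbind(library = lab, st$table)
    }))
    wt(cat_tab, "table1_categories.tsv")
    hist_tab <- do.call(rbind, lapply(labels, function(lab) {
      cbind(library = lab, length_distribution(tags, lab))
    }))
    wt(hist_tab, "length_histogram.tsv")
    wt(hits, "known_hits.tsv")
    fam_out <- fam
    for (cn in grep("^norm_", names(fam_out), value = TRUE)) {
      fam_out[[cn]] <- sprintf("%.2f", fam_out[[cn]])
    }
    fam_out$log2fc <- sprintf("%.2f", fam_out$log2fc)
    wt(fam_out, "family_summary.tsv")
    write_de_table(de_known, file.path(out_dir, "de_known.tsv"))
    if (!is.null(de_novel)) write_de_table(de_novel, file.path(out_dir, "de_novel.tsv"))
    if (!is.null(novel)) {
      wt(novel[c("novel_id", "sequence", "ref", "start", "end", "strand", "arm",
                 "mfe", "duplex_mismatches", "asymmetric_bulge", "star_observed")],
         "novel_mirnas.tsv")
      writeLines(as.vector(rbind(paste0(">", novel$novel_id, " ",
                                        sprintf("%.1f", novel$mfe), " kcal/mol"),
                                 novel$precursor)),
                 file.path(out_dir, "precursors.fasta"))
      writeLines(as.vector(rbind(paste0(">", novel$novel_id),
                                 novel$precursor, novel$structure)),
                 file.path(out_dir, "structures.txt"))
    }
    if (!is.null(targets)) wt(targets, "targets.tsv")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}
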