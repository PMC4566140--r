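small_spec <- function(seed = 1, ...) {
  simulation_spec(seed = seed, n_contigs = 6, contig_length = 4000,
                  n_known_mirnas = 12, n_novel_hairpins = 3, n_ncrna_decoys = 8,
                  library_depths = c(2e4, 21572), n_background_tags = 300, ...)
}

test_that("generation is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_synthetic(small_spec(7), dir = d1)
  generate_synthetic(small_spec(7), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- tempfile()
  generate_synthetic(small_spec(8), dir = d3)
  expect_false(identical(readLines(file.path(d1, "reads_CK.fa")),
                         readLines(file.path(d3, "reads_CK.fa"))))
})

test_that("simulated library sizes honour the spec depths", {
  sim <- generate_synthetic(small_spec(2))
  for (lab in c("CK", "Cr200")) {
    depth <- sim$spec$library_depths[[lab]]
    expect_lt(abs(n_reads(sim$libraries[[lab]]) - depth) / depth, 0.05)
  }
})

test_that("planted truth flows through cleaning and annotation", {
  sim <- generate_synthetic(small_spec(3))
  lib <- clean_reads(sim$libraries$CK, sim$spec$adapter3, sim$spec$adapter5)
  tags <- collapse_tags(lib, "CK")
  # clean-read conservation through collapse
  expect_equal(sum(tags$CK), n_reads(lib))
  # the length mode is 21 nt
  expect_equal(attr(length_distribution(tags, "CK"), "modal_length"), 21L)
  # adequately expressed planted matures are present and mappable
  m <- map_reference(tags, sim$reference)
  planted <- sim$truth$known$sequence[sim$truth$known$expected_ck >= 10]
  expect_gt(mean(planted %in% tags$sequence), 0.9)
  expect_true(all(planted[planted %in% tags$sequence] %in% m$loci$sequence))
})

test_that("planted hairpins satisfy the acceptance criteria by construction", {
  sim <- generate_synthetic(small_spec(4))
  expect_true(all(sim$truth$novel$mfe <= -18))
  plen <- nchar(sim$truth$novel$precursor)
  expect_true(all(plen >= 47 & plen <= 350))
  # precursor really sits at the recorded locus
  for (i in seq_len(nrow(sim$truth$novel))) {
    tr <- sim$truth$novel[i, ]
    expect_equal(substr(sim$reference[[tr$contig]], tr$prec_start + 1, tr$prec_end),
                 tr$precursor)
  }
})

test_that("an infeasible hairpin spec fails with a generation error", {
  # force an impossible MFE by demanding hairpins from a 1-base alphabet:
  # impossible to express directly, so check the retry cap is honoured via
  # an absurd energy threshold instead
  sp <- small_spec(5)
  with_mocked_bindings(
    fold_rna = function(sequence, config = NULL) {
      list(mfe = 0, structure = "", sequence = sequence)
    },
    {
      expect_error(generate_synthetic(sp), "retries")
    }
  )
})

test_that("fixture tables are internally consistent", {
  tab <- radish_cr_tables()
  expect_equal(unname(tab$totals), c(18127561, 19552260))
  t1 <- tab$table1
  for (lab in c("CK", "Cr200")) {
    rows <- t1[t1$library == lab & t1$category != "total", ]
    tot <- t1[t1$library == lab & t1$category == "total", ]
    expect_equal(sum(rows$total), tot$total)
    expect_equal(sum(rows$unique), tot$unique)
  }
  expect_equal(nrow(tab$table3), 54)
  expect_equal(nrow(tab$table4), 16)
  r <- tab$table3[tab$table3$mirna_id == "miR156a", ]
  expect_equal(c(r$count_ck, r$count_tr), c(94427, 59654))
})
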