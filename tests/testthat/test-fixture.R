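test_that("identical spec and seed give byte-identical outputs", {
  a <- generate_fixture(fixture_spec("small", seed = 11L))
  b <- generate_fixture(fixture_spec("small", seed = 11L))
  expect_identical(a$y_contigs, b$y_contigs)
  expect_identical(a$female_reference, b$female_reference)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ct_table, b$ct_table)
  c <- generate_fixture(fixture_spec("small", seed = 12L))
  expect_false(identical(a$y_contigs$sequence, c$y_contigs$sequence))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(fixture_spec("small", par_identity = 0.8), "identity")
  expect_error(fixture_spec("small", microsat_fraction = 1.5), "fraction")
  sp <- fixture_spec("small")
  bad_plan <- dplyr::mutate(sp$ct_plan, sd = -0.1)
  expect_error(fixture_spec("small", ct_plan = bad_plan), "sd")
  # gene cassette larger than its host contig
  g <- sp$genes
  g$GENA$exons <- c(4000L, 4000L, 4000L)
  expect_error(fixture_spec("small", genes = g), "fit")
})

test_that("a spec without contaminants or junk plants only PAR/MSY contigs", {
  sp <- fixture_spec("small", seed = 3L,
                     contaminants = fixture_spec("small")$contaminants[0, ],
                     junk_lengths = NULL)
  fx <- generate_fixture(sp)
  classes <- unique(fx$truth$feature)
  expect_false(any(c("CONTAMINANT", "JUNK") %in% classes))
  expect_true(all(c("PAR_CONTIG", "MSY_CONTIG", "BOUNDARY_CONTIG") %in%
                    classes))
})

test_that("planted PAR identity is realized within half a point", {
  fx <- paper_fixture()
  xref <- dplyr::filter(fx$female_reference, scaffold_class == "X")
  idx <- build_index(xref)
  par_rows <- dplyr::filter(fx$truth, feature == "PAR_CONTIG")
  for (i in seq_len(nrow(par_rows))) {
    pr <- par_rows[i, ]
    seq <- fx$y_contigs$sequence[fx$y_contigs$id == pr$contig_id]
    qc <- query_coverage(local_hits(seq, idx, min_identity = 0.9),
                         nchar(seq))
    expect_gt(qc$covered_fraction, 0.99)
    expect_lt(abs(qc$mean_identity - pr$identity), 0.005)
  }
})

test_that("truth manifest and FASTA are mutually consistent", {
  fx <- paper_fixture()
  # planted exon intervals reproduce the reference exon sequences up to the
  # planted substitutions
  exons <- dplyr::filter(fx$truth, feature == "GENE_EXON", gene == "EIF1AY",
                         status == "full")
  tr <- fx$transcripts$sequence[fx$transcripts$gene == "EIF1AY"]
  contig <- fx$y_contigs$sequence[fx$y_contigs$id == exons$contig_id[1]]
  offs <- 0L
  for (i in seq_len(nrow(exons))) {
    ex <- exons[i, ]
    planted <- substr(contig, ex$start, ex$end)
    ref <- substr(tr, offs + 1L, offs + (ex$end - ex$start + 1L))
    mism <- sum(strsplit(planted, "")[[1]] != strsplit(ref, "")[[1]])
    expect_lt(mism / nchar(ref), 1 - 0.995 + 0.005)
    offs <- offs + nchar(ref)
  }
  # PAR contig intervals come from the recorded source coordinates
  pr <- dplyr::filter(fx$truth, feature == "PAR_CONTIG")[1, ]
  src <- fx$female_reference$sequence[fx$female_reference$id == pr$source_id]
  src_piece <- substr(src, pr$source_start, pr$source_end)
  planted <- fx$y_contigs$sequence[fx$y_contigs$id == pr$contig_id]
  expect_equal(nchar(src_piece), nchar(planted))
  mism <- sum(strsplit(src_piece, "")[[1]] != strsplit(planted, "")[[1]])
  expect_lt(abs(mism / nchar(planted) - (1 - pr$identity)), 0.005)
})

test_that("the default gene plan plants the published HSFY architecture", {
  fx <- paper_fixture()
  hs <- dplyr::filter(fx$truth, feature == "GENE_COPY", gene == "HSFY")
  counts <- dplyr::count(hs, contig_id, orientation)
  expect_equal(counts$n[counts$contig_id == "tig1" &
                          counts$orientation == "direct"], 15L)
  expect_equal(counts$n[counts$contig_id == "tig1" &
                          counts$orientation == "inverted"], 1L)
  expect_equal(counts$n[counts$contig_id == "tig223"], 9L)
  expect_equal(counts$n[counts$contig_id == "tig419"], 1L)
  bd <- dplyr::filter(fx$truth, feature == "BOUNDARY_CONTIG")
  expect_equal(bd$end, 307557L)
  expect_equal(bd$source_end, 177307)
})

test_that("simulate_ct reproduces exact dosage arithmetic without noise", {
  plan <- tibble::tibble(gene = c("REF", "G8"), true_ratio = c(1, 8),
                         efficiency = 1, sd = 0)
  ct <- simulate_ct(plan, seed = 1L)
  ref_ct <- unique(ct$ct[ct$gene == "REF"])
  expect_length(ref_ct, 1)
  expect_equal(unique(ct$ct[ct$gene == "G8"]), ref_ct - 3) # 2^3 = 8
  plan1 <- tibble::tibble(gene = c("REF", "G"), true_ratio = 1,
                          efficiency = 1, sd = 0)
  ct1 <- simulate_ct(plan1, seed = 1L)
  expect_equal(unique(ct1$ct), 25)
  expect_error(simulate_ct(dplyr::mutate(plan, sd = -1), 1L), "sd")
  expect_error(simulate_ct(dplyr::filter(plan, gene == "G8"), 1L),
               "reference")
})

test_that("the seed-7 thirteen-copy simulation lands in the expected band", {
  # expected band from the estimator's Monte-Carlo distribution (see the
  # qpcr tests for the full parameter-recovery suite)
  plan <- tibble::tibble(gene = c("UTY", "RBMY"), true_ratio = c(1, 13),
                         efficiency = 1, sd = 0.15)
  ct <- simulate_ct(plan, seed = 7L)
  est <- ddct_fold_change(ct, "RBMY", "UTY")
  expect_gte(est$fold_change, 11)
  expect_lte(est$fold_change, 15)
})

test_that("writing and re-reading a fixture preserves every component", {
  fx <- generate_fixture(fixture_spec("small", seed = 5L))
  d <- withr::local_tempdir()
  write_fixture(fx, d)
  y <- read_fasta(file.path(d, "y_contigs.fa"))
  expect_identical(y$sequence, fx$y_contigs$sequence)
  cls <- read_scaffold_classes(file.path(d, "scaffold_classes.tsv"))
  expect_equal(cls$scaffold_class,
               fx$female_reference$scaffold_class)
  ct <- read_ct_table(file.path(d, "ct_table.tsv"))
  expect_equal(ct$ct, fx$ct_table$ct)
  pr <- read_primers(file.path(d, "primers.tsv"))
  expect_equal(pr$forward, fx$primers$forward)
})
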