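mk_hits <- function(target_id, identity, qstart, qend) {
  tibble::tibble(target_id = target_id, strand = "+", identity = identity,
                 aligned_length = qend - qstart, qstart = qstart, qend = qend,
                 tstart = qstart, tend = qend,
                 score = as.integer(qend - qstart))
}

test_that("classification applies the length filter before homology", {
  classes <- c(x1 = "X", a1 = "AUTOSOME")
  ct <- list(id = "c", length = 5000L)
  hits <- mk_hits("x1", 0.99, 0L, 4000L)
  lab <- classify_contig(ct, hits, classes)
  expect_equal(lab$label, "TOO_SHORT")
})

test_that("identity and coverage gates decide PAR vs MSY labels", {
  classes <- c(x1 = "X", a1 = "AUTOSOME")
  ct <- list(id = "c", length = 100000L)
  lab <- classify_contig(ct, mk_hits("x1", 0.99, 0L, 60000L), classes)
  expect_equal(lab$label, "PAR_CANDIDATE")
  expect_equal(lab$coverage, 0.6)
  # coverage gate fails at 0.20 even at high identity
  lab <- classify_contig(ct, mk_hits("x1", 0.99, 0L, 20000L), classes)
  expect_equal(lab$label, "PUTATIVE_MSY")
  # identity below the gate never counts toward coverage
  lab <- classify_contig(ct, mk_hits("x1", 0.90, 0L, 60000L), classes)
  expect_equal(lab$label, "PUTATIVE_MSY")
  # autosomal contamination wins over a simultaneous X pass, tie recorded
  both <- dplyr::bind_rows(mk_hits("x1", 0.99, 0L, 40000L),
                           mk_hits("a1", 0.99, 40000L, 90000L))
  lab <- classify_contig(ct, both, classes)
  expect_equal(lab$label, "AUTOSOMAL_CONTAMINANT")
  expect_true(lab$gate_tie)
  expect_error(classify_contig(ct, mk_hits("zz", 0.99, 0L, 60000L), classes),
               "class annotation")
})

test_that("near-threshold contaminants stay MSY but are flagged", {
  classes <- c(a1 = "AUTOSOME")
  ct <- list(id = "c", length = 100000L)
  lab <- classify_contig(ct, mk_hits("a1", 0.94, 0L, 90000L), classes)
  expect_equal(lab$label, "PUTATIVE_MSY")
  expect_true(lab$near_threshold)
})

test_that("triage partitions the assembly and recovers planted labels", {
  fx <- paper_fixture()
  tri <- paper_triage()
  expect_equal(sum(tri$summary$bases),
               sum(as.numeric(fx$y_contigs$length)))
  lab <- tri$labels
  truth <- fx$truth
  expect_setequal(lab$contig_id[lab$label == "AUTOSOMAL_CONTAMINANT"],
                  truth$contig_id[truth$feature == "CONTAMINANT"])
  expect_setequal(lab$contig_id[lab$label == "TOO_SHORT"],
                  truth$contig_id[truth$feature == "JUNK"])
  expect_setequal(lab$contig_id[lab$label == "PUTATIVE_MSY"],
                  truth$contig_id[truth$feature == "MSY_CONTIG"])
  # the boundary-spanning contig carries majority X homology
  expect_equal(lab$label[lab$contig_id == "tig419"], "PAR_CANDIDATE")
  # empty assembly
  tri0 <- triage_assembly(fx$y_contigs[0, ], fx$female_reference)
  expect_true(all(tri0$summary$n_contigs == 0))
  expect_true(all(tri0$summary$bases == 0))
})

test_that("triage is deterministic", {
  fx <- paper_fixture()
  t1 <- triage_assembly(fx$y_contigs[1:5, ], fx$female_reference)
  t2 <- triage_assembly(fx$y_contigs[1:5, ], fx$female_reference)
  expect_identical(t1$labels, t2$labels)
})

test_that("label recovery holds across randomly seeded studies", {
  # the acceptance suite runs the full 20-fixture version; this spot-checks
  # a handful with the miniature preset
  hits <- 0L
  total <- 0L
  for (seed in 101:106) {
    fx <- generate_fixture(fixture_spec("small", seed = seed))
    tri <- triage_assembly(fx$y_contigs, fx$female_reference,
                           triage_params(length_threshold =
                                           fx$spec$length_threshold))
    lab <- tri$labels
    truth <- fx$truth
    expected <- c(
      stats::setNames(rep("PUTATIVE_MSY",
                          sum(truth$feature == "MSY_CONTIG")),
                      truth$contig_id[truth$feature == "MSY_CONTIG"]),
      stats::setNames(rep("PAR_CANDIDATE",
                          sum(truth$feature == "PAR_CONTIG")),
                      truth$contig_id[truth$feature == "PAR_CONTIG"]),
      stats::setNames(rep("AUTOSOMAL_CONTAMINANT",
                          sum(truth$feature == "CONTAMINANT")),
                      truth$contig_id[truth$feature == "CONTAMINANT"]),
      stats::setNames(rep("TOO_SHORT", sum(truth$feature == "JUNK")),
                      truth$contig_id[truth$feature == "JUNK"]))
    got <- stats::setNames(lab$label, lab$contig_id)[names(expected)]
    hits <- hits + sum(got == expected)
    total <- total + length(expected)
  }
  expect_equal(hits, total) # identities sit >= 2 points from the gates
})

test_that("in-silico PCR finds convergent sites with 3' fidelity", {
  withr::local_seed(31)
  g <- rand_seq(3000)
  fwd <- substr(g, 1001, 1022)
  rev <- ytriage:::revcomp(substr(g, 1379, 1400))
  pr <- tibble::tibble(name = "p", forward = fwd, reverse = rev)
  genome <- tibble::tibble(id = "c", sequence = g)
  amp <- in_silico_pcr(pr, genome)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, 400L)
  expect_equal(amp$size, amp$end - amp$start)
  # three mismatches exceed max_mismatch = 2
  fwd3 <- paste0("TTT", substr(fwd, 4, 22))
  if (identical(substr(fwd, 1, 3), "TTT")) fwd3 <- paste0("AAA", substr(fwd, 4, 22))
  amp3 <- in_silico_pcr(dplyr::mutate(pr, forward = fwd3), genome,
                        max_mismatch = 2)
  expect_equal(nrow(amp3), 0L)
  # a mismatch inside the 3'-exact window kills the site even under the
  # mismatch budget
  fwd_3p <- fwd
  substr(fwd_3p, 22, 22) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 22, 22))[1]
  expect_equal(nrow(in_silico_pcr(dplyr::mutate(pr, forward = fwd_3p),
                                  genome)), 0L)
})

test_that("fixture primers show their designed specificity classes", {
  fx <- paper_fixture()
  fem <- fx$female_reference
  calls <- purrr::map_dfr(seq_len(nrow(fx$primers)), function(i) {
    male_specificity(fx$primers[i, ], fx$y_contigs, fem)
  })
  expect_equal(calls$call, fx$primers$specificity)
  msy <- dplyr::filter(calls, call == "MALE_SPECIFIC")
  expect_true(all(msy$n_male >= 1 & msy$n_female == 0))
  amb <- dplyr::filter(calls, call == "AMBIGUOUS")
  expect_true(all(amb$n_male > 3)) # ladder-like
})

test_that("male-specificity edge cases classify as documented", {
  withr::local_seed(32)
  g <- rand_seq(2000)
  pr <- tibble::tibble(name = "p",
                       forward = substr(g, 101, 122),
                       reverse = ytriage:::revcomp(substr(g, 479, 500)))
  both <- tibble::tibble(id = "c", sequence = g)
  expect_equal(male_specificity(pr, both, both)$call, "BOTH")
  empty <- tibble::tibble(id = "e", sequence = rand_seq(2000))
  expect_equal(male_specificity(pr, empty, empty)$call, "NONE")
  ladder <- tibble::tibble(id = paste0("c", 1:5), sequence = g)
  expect_equal(male_specificity(pr, ladder, empty)$call, "AMBIGUOUS")
})

test_that("validated MSY combines the triage label with marker evidence", {
  fx <- paper_fixture()
  tri <- paper_triage()
  val <- validate_msy(tri, fx$primers, fx$y_contigs, fx$female_reference)
  sry_contig <- fx$truth$contig_id[fx$truth$feature == "GENE_COPY" &
                                     fx$truth$gene == "SRY"][1]
  expect_true(val$validated_msy[val$contig_id == sry_contig])
  expect_false(any(val$validated_msy[val$label != "PUTATIVE_MSY"]))
})
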