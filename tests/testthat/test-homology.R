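test_that("the seed index reports exact k-mer positions on both strands", {
  idx <- build_index(tibble::tibble(id = "r", sequence = "ACGTACGT"), k = 4)
  expect_equal(seed_positions(idx, "ACGT")$pos, c(0L, 4L))
  # palindromic seed: its reverse complement is itself, so a minus-strand
  # query lookup resolves to the same loci
  expect_equal(seed_positions(idx, "ACGT"),
               seed_positions(idx, ytriage:::revcomp("ACGT")))
  expect_error(build_index(tibble::tibble(id = "r", sequence = "ACG"), k = 8),
               "larger than every")
  expect_error(build_index(tibble::tibble(id = "r", sequence = "ACGTACGT"),
                           k = 3), "between")
})

test_that("an exact substring gives one full-identity hit", {
  withr::local_seed(21)
  ref <- tibble::tibble(id = "r", sequence = rand_seq(4000))
  idx <- build_index(ref)
  q <- substr(ref$sequence, 1501, 2500)
  h <- local_hits(q, idx)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1)
  expect_equal(c(h$qstart, h$qend), c(0L, 1000L))
  expect_equal(c(h$tstart, h$tend), c(1500L, 2500L))
})

test_that("substituted queries match the full-DP oracle identity", {
  withr::local_seed(22)
  ref <- tibble::tibble(id = "r", sequence = rand_seq(4000))
  idx <- build_index(ref)
  # exactly 50 substitutions over 1000 bases
  q <- mutate_at_rate(substr(ref$sequence, 1001, 2000), 0.95)
  h <- local_hits(q, idx)[1, ]
  expect_lt(abs(h$identity - 0.95), 0.005)
  orc <- dp_oracle(q, ref$sequence)
  expect_lt(abs(h$identity - orc$identity), 0.005)
})

test_that("engine agrees with the DP oracle on random mutated pairs", {
  withr::local_seed(23)
  for (i in 1:20) {
    tlen <- sample(500:2000, 1)
    target <- rand_seq(tlen)
    qlen <- sample(200:(tlen - 10), 1)
    at <- sample.int(tlen - qlen, 1)
    ident <- runif(1, 0.85, 1)
    q <- mutate_at_rate(substr(target, at, at + qlen - 1L), ident)
    idx <- build_index(tibble::tibble(id = "t", sequence = target), k = 11)
    h <- local_hits(q, idx, min_identity = 0.5, min_hit_length = 50)
    orc <- dp_oracle(q, target)
    expect_gt(nrow(h), 0)
    top <- h[1, ]
    expect_lt(abs(top$identity - orc$identity), 0.005)
    inter <- max(0, min(top$qend, orc$q_end) - max(top$qstart, orc$q_start))
    unin <- max(top$qend, orc$q_end) - min(top$qstart, orc$q_start)
    expect_gte(inter / unin, 0.9)
  }
})

test_that("hits are strand-symmetric and monotone in the identity gate", {
  withr::local_seed(24)
  ref <- tibble::tibble(id = "r", sequence = rand_seq(6000))
  idx <- build_index(ref)
  q <- mutate_at_rate(substr(ref$sequence, 2001, 3500), 0.93)
  fwd <- local_hits(q, idx, min_identity = 0.8)
  rev <- local_hits(ytriage:::revcomp(q), idx, min_identity = 0.8)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$tstart), sort(rev$tstart))
  expect_setequal(paste(fwd$strand), c("+"))
  expect_setequal(paste(rev$strand), c("-"))
  # mirrored query intervals
  qlen <- nchar(q)
  expect_equal(sort(fwd$qstart), sort(qlen - rev$qend))

  gates <- c(0.5, 0.7, 0.9, 0.95, 0.99)
  counts <- vapply(gates, function(g) {
    nrow(local_hits(q, idx, min_identity = g))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every planted PAR source interval is recoverable through seeds", {
  fx <- paper_fixture()
  idx <- build_index(fx$female_reference)
  par_rows <- dplyr::filter(fx$truth, feature == "PAR_CONTIG")
  for (i in seq_len(nrow(par_rows))) {
    pr <- par_rows[i, ]
    seq <- fx$y_contigs$sequence[fx$y_contigs$id == pr$contig_id]
    h <- local_hits(seq, idx, min_identity = 0.9)
    h <- dplyr::filter(h, target_id == pr$source_id)
    expect_gt(nrow(h), 0)
    expect_lte(min(h$tstart), pr$source_start + 100L)
    expect_gte(max(h$tend), pr$source_end - 100L)
  }
})

test_that("query coverage uses union semantics and length-weighted identity", {
  hits <- tibble::tibble(target_id = "t", strand = "+",
                         identity = c(0.99, 0.95),
                         aligned_length = c(100L, 150L),
                         qstart = c(0L, 500L), qend = c(100L, 650L),
                         tstart = 0L, tend = 1L, score = 1L)
  qc <- query_coverage(hits, 1000L)
  expect_equal(qc$covered_fraction, 0.25)
  expect_equal(qc$mean_identity, (0.99 * 100 + 0.95 * 150) / 250)

  overlapping <- dplyr::mutate(hits, qstart = c(100L, 100L),
                               qend = c(400L, 400L),
                               aligned_length = 300L)
  expect_equal(query_coverage(overlapping, 1000L)$covered_fraction, 0.3)
  expect_error(query_coverage(hits, 0L), "positive")
  expect_error(query_coverage(hits, 100L, target_class = "X"), "classes")
  expect_error(
    query_coverage(hits, 100L, target_class = "X", classes = c(z = "X")),
    "class annotation")
})

test_that("spliced alignment recovers contiguous and multi-exon structures", {
  withr::local_seed(25)
  contig <- rand_seq(8000)
  tr <- substr(contig, 2001, 3200)
  aln <- spliced_align(tr, contig)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$n_blocks, 1L)
  expect_equal(aln$covered_fraction, 1)
  expect_equal(aln$orientation, "direct")
})

test_that("fixture EIF1AY spliced alignments show the planted exon chains", {
  fx <- paper_fixture()
  tr <- fx$transcripts$sequence[fx$transcripts$gene == "EIF1AY"]
  bd <- fx$y_contigs$sequence[fx$y_contigs$id == "tig419"]
  aln <- spliced_align(tr, bd)
  expect_equal(nrow(aln), 2L)
  full <- dplyr::filter(aln, covered_fraction > 0.9)
  expect_equal(full$n_blocks, 7L)
  expect_equal(full$orientation, "direct")
  trunc <- dplyr::filter(aln, covered_fraction < 0.9)
  expect_equal(trunc$n_blocks, 4L)
  expect_equal(trunc$orientation, "inverted")
  # blocks colinear in transcript coordinates, descending on the contig for
  # the inverted chain
  b <- trunc$blocks[[1]]
  expect_true(all(diff(b$q_start) > 0))
  expect_true(all(diff(b$t_start) < 0))
})
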