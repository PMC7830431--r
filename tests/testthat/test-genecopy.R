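test_that("the planted HSFY array is recovered copy for copy", {
  models <- paper_models("HSFY")
  by_loc <- dplyr::count(models, contig_id, orientation)
  expect_equal(by_loc$n[by_loc$contig_id == "tig1" &
                          by_loc$orientation == "direct"], 15L)
  expect_equal(by_loc$n[by_loc$contig_id == "tig1" &
                          by_loc$orientation == "inverted"], 1L)
  expect_equal(by_loc$n[by_loc$contig_id == "tig223"], 9L)
  expect_equal(by_loc$n[by_loc$contig_id == "tig419"], 1L)
  cs <- copy_summary(models)
  expect_equal(cs$total_copies, 26L)
  expect_equal(cs$n_fragment, 0L)
})

test_that("EIF1AY yields one full and one truncated inverted copy", {
  models <- paper_models("EIF1AY")
  expect_equal(nrow(models), 2L)
  full <- dplyr::filter(models, status == "FULL")
  expect_equal(full$exon_count, 7L)
  expect_equal(full$orientation, "direct")
  tr <- dplyr::filter(models, status == "TRUNCATED")
  expect_equal(tr$exon_count, 4L)
  expect_equal(tr$orientation, "inverted")
  expect_equal(unique(models$contig_id), "tig419")
})

test_that("RBMY and TSPY report published copy counts with fragments aside", {
  rb <- copy_summary(paper_models("RBMY"))
  expect_equal(rb$total_copies, 3L)
  expect_equal(rb$n_fragment, 2L)
  ts <- copy_summary(paper_models("TSPY"))
  expect_equal(ts$total_copies, 3L)
  expect_equal(length(strsplit(ts$contigs, ",")[[1]]), 3L)
})

test_that("a transcript with no homology returns an empty model set", {
  withr::local_seed(51)
  contigs <- tibble::tibble(id = "c", sequence = rand_seq(20000))
  m <- detect_copies("NOPE", rand_seq(1500), contigs)
  expect_equal(nrow(m), 0L)
  expect_equal(copy_summary(m)$total_copies, integer())
})

test_that("the 200-base fragment rule separates fragments from truncations", {
  withr::local_seed(52)
  tr <- rand_seq(1200)
  # N-flanked planting pins the aligned length exactly at the planted size
  plant <- function(piece) {
    paste0(rand_seq(5000), strrep("N", 20), piece, strrep("N", 20),
           rand_seq(5000))
  }
  ref <- tibble::tibble(q_start = 0L, q_end = 1200L)
  status_of <- function(len) {
    g <- plant(substr(tr, 1, len))
    detect_copies("G", tr, tibble::tibble(id = "c", sequence = g),
                  ref_blocks = ref)$status
  }
  expect_equal(status_of(199L), "FRAGMENT")   # just under the rule
  expect_equal(status_of(201L), "TRUNCATED")  # just over it
  expect_equal(status_of(150L), "FRAGMENT")
  expect_equal(status_of(400L), "TRUNCATED")
})

test_that("reverse-complementing a contig flips orientations only", {
  fx <- paper_fixture()
  tr <- fx$transcripts$sequence[fx$transcripts$gene == "HSFY"]
  ct <- dplyr::filter(fx$y_contigs, id == "tig223")
  fwd <- detect_copies("HSFY", tr, ct)
  rc <- dplyr::mutate(ct, sequence = ytriage:::revcomp(sequence))
  rev <- detect_copies("HSFY", tr, rc)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(table(fwd$status)), sort(table(rev$status)))
  expect_equal(sum(fwd$orientation == "direct"),
               sum(rev$orientation == "inverted"))
  # footprints mirror across the contig
  expect_equal(sort(ct$length - rev$t_end), sort(fwd$t_start))
})

test_that("split-gene detection merges complementary truncated parts", {
  models <- paper_models("UTY")
  cs <- copy_summary(models)
  expect_equal(cs$n_truncated, 2L)
  expect_equal(cs$n_split, 1L)
  expect_equal(cs$total_copies, 1L)
  exA <- dplyr::filter(models, contig_id == "tig467")
  exB <- dplyr::filter(models, contig_id == "tig723")
  expect_equal(exA$exon_count, 16L)
  expect_equal(exB$exon_count, 12L)
})

test_that("overlapping truncated parts are never merged into a split call", {
  blocks1 <- tibble::tibble(q_start = 0L, q_end = 600L, t_start = 0L,
                            t_end = 600L, identity = 1)
  blocks2 <- tibble::tibble(q_start = 0L, q_end = 500L, t_start = 0L,
                            t_end = 500L, identity = 1)
  models <- tibble::tibble(
    gene = "G", contig_id = c("c1", "c2"), copy = 1L,
    orientation = "direct", status = "TRUNCATED", exon_count = 1L,
    covered_transcript_fraction = c(0.6, 0.5),
    matched_bases = c(600, 500), t_start = 0L, t_end = c(600L, 500L),
    blocks = list(blocks1, blocks2))
  sp <- detect_split_genes(models)
  expect_equal(nrow(sp$splits), 0L)
  expect_equal(copy_summary(sp$models)$total_copies, 2L)
  # a single full model raises no flag
  one <- dplyr::mutate(models[1, ], status = "FULL")
  expect_equal(nrow(detect_split_genes(one)$splits), 0L)
})

test_that("cross-species mode reports a located-only call when structure is unresolved", {
  withr::local_seed(53)
  tr <- rand_seq(1500)
  diverged <- mutate_at_rate(substr(tr, 400, 1000), 0.82)
  contig <- paste0(rand_seq(4000), diverged, rand_seq(4000))
  m <- detect_copies("AMELY_like", tr,
                     tibble::tibble(id = "c", sequence = contig),
                     cross_species = TRUE,
                     ref_blocks = tibble::tibble(q_start = 0L, q_end = 1500L),
                     fragment_max = 700L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$status, "LOCATED_ONLY")
})

test_that("ORF finding matches the published single-ORF arithmetic", {
  fx <- paper_fixture()
  tr <- fx$transcripts$sequence[fx$transcripts$gene == "SRY"]
  orfs <- find_orfs(tr)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$aa_length, 240L)
  expect_equal(nchar(unname(tr)), 3 * (240 + 1)) # 723 bases
  expect_equal(orfs$end - orfs$start, 723L)
  expect_false(orfs$partial)
})

test_that("short ORFs are filtered by the minimum length", {
  orfs <- find_orfs("ATGTAA", min_aa = 100L)
  expect_equal(nrow(orfs), 0L)
  orfs1 <- find_orfs("ATGTAA", min_aa = 1L)
  expect_gte(nrow(orfs1), 1L)
  expect_equal(orfs1$aa_length[1], 1L)
})

test_that("ORF finding is identical to a brute-force six-frame scan", {
  withr::local_seed(54)
  for (i in 1:5) {
    s <- rand_seq(8000)
    mine <- find_orfs(s, min_aa = 20L)
    orc <- orf_oracle(s, min_aa = 20L)
    key <- function(d) {
      d <- d[order(d$strand, d$frame, d$start), ]
      paste(d$strand, d$frame, d$start, d$end, d$aa_length, d$partial)
    }
    expect_equal(key(as.data.frame(mine)), key(orc))
  }
})
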