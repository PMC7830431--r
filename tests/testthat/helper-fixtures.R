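# Shared fixtures and independent oracles. The paper-preset fixture and its
# derived results are computed once per test run and cached.

yt_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = yt_cache)) assign(key, expr, envir = yt_cache)
  get(key, envir = yt_cache)
}

paper_fixture <- function() {
  memo("paper_fixture", generate_fixture(fixture_spec("paper", seed = 42L)))
}

paper_index <- function() {
  memo("paper_index", build_index(paper_fixture()$y_contigs))
}

paper_models <- function(gene) {
  memo(paste0("models_", gene), {
    fx <- paper_fixture()
    tr <- fx$transcripts
    m <- detect_copies(gene, tr$sequence[tr$gene == gene], paper_index())
    detect_split_genes(m)$models
  })
}

paper_triage <- function() {
  memo("paper_triage", {
    fx <- paper_fixture()
    triage_assembly(fx$y_contigs, fx$female_reference)
  })
}

paper_pab <- function() {
  memo("paper_pab", {
    fx <- paper_fixture()
    xref <- dplyr::filter(fx$female_reference, scaffold_class == "X")
    bd <- dplyr::filter(fx$y_contigs, id == "tig419")
    prof <- homology_profile(bd, xref, window = 10000L, step = 2000L)
    list(profile = prof, call = detect_boundary(prof, bd, xref))
  })
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at_rate <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round((1 - identity) * length(chars))
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# independent full dynamic-programming local-alignment oracle
dp_oracle <- function(query, target) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2),
    gapOpening = 6, gapExtension = 2)
  pat <- Biostrings::alignedPattern(al)[[1]]
  sub <- Biostrings::alignedSubject(al)[[1]]
  cols <- nchar(as.character(pat))
  matches <- sum(strsplit(as.character(pat), "")[[1]] ==
                   strsplit(as.character(sub), "")[[1]])
  list(identity = matches / cols,
       q_start = Biostrings::start(Biostrings::pattern(al)) - 1L,
       q_end = Biostrings::end(Biostrings::pattern(al)))
}

# exhaustive six-frame ATG-to-stop scan, written independently of find_orfs
orf_oracle <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n <- nchar(seq)
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      i <- frame + 1L
      while (i + 2L <= n) {
        if (substr(s, i, i + 2L) == "ATG") {
          j <- i
          aa <- 0L
          hit_stop <- FALSE
          while (j + 2L <= n) {
            cod <- substr(s, j, j + 2L)
            if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
              hit_stop <- TRUE
              break
            }
            aa <- aa + 1L
            j <- j + 3L
          }
          endpos <- if (hit_stop) j + 2L else j - 1L
          if (aa >= min_aa) {
            lo <- i - 1L
            hi <- endpos
            if (strand == "-") { tmp <- lo; lo <- n - hi; hi <- n - tmp }
            found[[length(found) + 1L]] <- data.frame(
              strand = strand, frame = frame, start = lo, end = hi,
              aa_length = aa, partial = !hit_stop)
          }
        }
        i <- i + 3L
      }
    }
  }
  if (!length(found)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      aa_length = integer(), partial = logical()))
  }
  do.call(rbind, found)
}

expect_tree_isomorphic <- function(t1, t2) {
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
}
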