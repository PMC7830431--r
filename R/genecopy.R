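#' Detect genomic copies of a gene from its transcript
#'
#' Every spliced transcript-to-contig alignment chain becomes one gene model.
#' Status is assigned from the matched homology of the chain: under 200
#' aligned bases is a `FRAGMENT` (incompletely assembled copy or pseudogene);
#' chains missing one or more reference exons but with at least 200 bases are
#' `TRUNCATED`; a `FULL` copy represents every reference exon at >= 80% of
#' its length. The reference exon structure is taken from the
#' best-covering chain (`ref_exons`/`ref_blocks` can override it, e.g. from a
#' curated model). Overlapping chains at one locus (contig footprints
#' overlapping >= 20%) are resolved to the higher-coverage chain; tandem
#' copies with footprints overlapping < 20% are counted individually.
#'
#' With `cross_species = TRUE` (annotation via a diverged transcript from
#' another species) the identity gate is relaxed to 0.75 and, when no chain
#' reaches `FULL`/`TRUNCATED`, the best chain is reported with status
#' `LOCATED_ONLY`: the gene is located but its exon-intron structure is not
#' resolved.
#'
#' @param gene Gene name.
#' @param transcript The gene's representative transcript (DNA string,
#'   length >= 100).
#' @param contigs Contig tibble, or a pre-built `yt_index`.
#' @param min_exon_identity Per-exon identity gate (default 0.9; 0.75 when
#'   `cross_species`).
#' @param min_exon_length Minimum exon block length (default 30).
#' @param max_intron Maximum intron size (default 10000).
#' @param fragment_max Matched-homology bound below which a chain is a
#'   fragment (default 200 bases).
#' @param full_exon_fraction Fraction of each reference exon required for a
#'   `FULL` call (default 0.8).
#' @param overlap_fraction Footprint overlap above which two chains are the
#'   same locus (default 0.2).
#' @param cross_species Relaxed-identity annotation mode (default FALSE).
#' @param ref_exons Optional reference exon count.
#' @param ref_blocks Optional tibble of reference exon transcript intervals
#'   (`q_start`, `q_end`).
#' @return Tibble of gene models: `gene`, `contig_id`, `copy`, `orientation`,
#'   `status`, `exon_count`, `covered_transcript_fraction`, `matched_bases`,
#'   `t_start`, `t_end`, `blocks` (list-column of exon blocks).
#' @export
detect_copies <- function(gene, transcript, contigs,
                          min_exon_identity = if (cross_species) 0.75 else 0.9,
                          min_exon_length = 30L, max_intron = 10000L,
                          fragment_max = 200L, full_exon_fraction = 0.8,
                          overlap_fraction = 0.2, cross_species = FALSE,
                          ref_exons = NULL, ref_blocks = NULL) {
  if (nchar(transcript) < 100L) abort("transcript shorter than 100 bases")
  idx <- if (inherits(contigs, "yt_index")) contigs else
    build_index(contigs, k = 15L)
  aln <- spliced_align(transcript, idx,
                       min_exon_identity = min_exon_identity,
                       min_exon_length = min_exon_length,
                       max_intron = max_intron)
  empty <- tibble(gene = character(), contig_id = character(),
                  copy = integer(), orientation = character(),
                  status = character(), exon_count = integer(),
                  covered_transcript_fraction = double(),
                  matched_bases = double(), t_start = integer(),
                  t_end = integer(), blocks = list())
  if (!nrow(aln)) return(empty)

  # resolve same-locus chains to the higher-coverage one
  aln <- arrange(aln, desc(.data$matched_bases), .data$target_id,
                 .data$t_start)
  kept <- aln[0, ]
  for (i in seq_len(nrow(aln))) {
    cand <- aln[i, ]
    if (nrow(kept)) {
      same <- kept$target_id == cand$target_id
      ov <- pmax(0, pmin(kept$t_end, cand$t_end) -
                   pmax(kept$t_start, cand$t_start))
      span <- pmin(kept$t_end - kept$t_start, cand$t_end - cand$t_start)
      if (any(same & ov / pmax(span, 1) >= overlap_fraction)) next
    }
    kept <- bind_rows(kept, cand)
  }
  aln <- kept

  # reference exon structure: best-covering chain unless supplied
  if (is.null(ref_blocks)) {
    best <- aln %>%
      arrange(desc(.data$covered_fraction), desc(.data$matched_bases)) %>%
      slice(1)
    ref_blocks <- best$blocks[[1]][, c("q_start", "q_end")]
  }
  if (is.null(ref_exons)) ref_exons <- nrow(ref_blocks)

  is_full <- function(blocks) {
    if (nrow(blocks) < ref_exons) return(FALSE)
    all(vapply(seq_len(nrow(ref_blocks)), function(e) {
      rs <- ref_blocks$q_start[e]; re <- ref_blocks$q_end[e]
      ov <- sum(pmax(0, pmin(blocks$q_end, re) - pmax(blocks$q_start, rs)))
      ov >= full_exon_fraction * (re - rs)
    }, logical(1)))
  }
  # FULL needs every reference exon AND most of the transcript: when the
  # reference structure is inferred from the best chain (itself possibly a
  # partial copy), the coverage condition stops a split part from being
  # declared complete against itself.
  qlen <- nchar(transcript)
  models <- aln %>%
    mutate(gene = gene,
           status = purrr::map_chr(.data$blocks, function(b) {
             mb <- sum((b$q_end - b$q_start) * b$identity)
             covered <- sum(b$q_end - b$q_start) / qlen
             if (mb < fragment_max) "FRAGMENT"
             else if (is_full(b) && covered >= 0.9) "FULL" else "TRUNCATED"
           })) %>%
    rename(contig_id = "target_id", exon_count = "n_blocks",
           covered_transcript_fraction = "covered_fraction") %>%
    group_by(.data$contig_id) %>%
    arrange(.data$t_start, .by_group = TRUE) %>%
    mutate(copy = row_number()) %>%
    ungroup() %>%
    select("gene", "contig_id", "copy", "orientation", "status",
           "exon_count", "covered_transcript_fraction", "matched_bases",
           "t_start", "t_end", "blocks") %>%
    arrange(.data$contig_id, .data$t_start)
  if (cross_species && !any(models$status %in% c("FULL", "TRUNCATED")) &&
      nrow(models)) {
    best <- which.max(models$matched_bases)
    models <- models[best, , drop = FALSE]
    models$status <- "LOCATED_ONLY"
    models$copy <- 1L
  }
  models
}

#' Per-exon table of gene models (for GFF3 output)
#'
#' Expands the `blocks` list-column into one row per exon with contig
#' coordinates; exon numbers follow transcript order, so they descend along
#' the contig for inverted copies.
#'
#' @param models Gene-model tibble from [detect_copies()].
#' @return Tibble with `gene`, `contig_id`, `copy`, `exon`, `start`, `end`,
#'   `orientation`, `status` (0-based half-open).
#' @export
gene_model_exons <- function(models) {
  if (!nrow(models)) {
    return(tibble(gene = character(), contig_id = character(),
                  copy = integer(), exon = integer(), start = integer(),
                  end = integer(), orientation = character(),
                  status = character()))
  }
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    b <- m$blocks[[1]] %>% arrange(.data$q_start)
    tibble(gene = m$gene, contig_id = m$contig_id, copy = m$copy,
           exon = seq_len(nrow(b)), start = b$t_start, end = b$t_end,
           orientation = m$orientation, status = m$status)
  })
}

#' Detect a gene split across two contigs
#'
#' Two `TRUNCATED` models on different contigs whose transcript coverage
#' partitions the transcript — no overlap beyond `overlap_tol` bases and
#' combined coverage of at least `min_combined` — are merged into one
#' `SPLIT` single-copy call (an assembly break inside the gene, not two
#' copies).
#'
#' @param models Gene-model tibble for one gene across all contigs.
#' @param overlap_tol Maximum transcript-interval overlap between the parts
#'   in bases (default 30).
#' @param min_combined Minimum combined transcript coverage (default 0.9).
#' @return List with `models` (input with a `split_id` column; members of a
#'   split call share an id) and `splits` (one row per split call).
#' @export
detect_split_genes <- function(models, overlap_tol = 30L,
                               min_combined = 0.9) {
  models$split_id <- NA_integer_
  splits <- tibble(gene = character(), split_id = integer(),
                   contigs = character(), exon_count = integer(),
                   covered_fraction = double())
  tr <- which(models$status == "TRUNCATED")
  next_id <- 1L
  if (length(tr) >= 2) {
    for (i in tr) {
      for (j in tr) {
        if (j <= i) next
        if (!is.na(models$split_id[i]) || !is.na(models$split_id[j])) next
        if (models$contig_id[i] == models$contig_id[j]) next
        bi <- models$blocks[[i]]; bj <- models$blocks[[j]]
        ov <- 0
        for (a in seq_len(nrow(bi))) {
          ov <- ov + sum(pmax(0, pmin(bi$q_end[a], bj$q_end) -
                                pmax(bi$q_start[a], bj$q_start)))
        }
        combined <- models$covered_transcript_fraction[i] +
          models$covered_transcript_fraction[j]
        if (ov <= overlap_tol && combined >= min_combined) {
          models$split_id[c(i, j)] <- next_id
          splits <- bind_rows(splits, tibble(
            gene = models$gene[i], split_id = next_id,
            contigs = paste(sort(c(models$contig_id[i],
                                   models$contig_id[j])), collapse = ","),
            exon_count = models$exon_count[i] + models$exon_count[j],
            covered_fraction = combined))
          next_id <- next_id + 1L
        }
      }
    }
  }
  list(models = models, splits = splits)
}

#' Copy-number summary of detected gene models
#'
#' Counts models per contig by orientation and status. `total_copies` counts
#' `FULL` plus `TRUNCATED` models, with the members of a split-gene call
#' counted once; fragments are reported separately and excluded from the
#' total.
#'
#' @param models Gene-model tibble (optionally with the `split_id` column
#'   from [detect_split_genes()]).
#' @return One row per gene: `gene`, `contigs`, `n_full`, `n_truncated`,
#'   `n_fragment`, `n_inverted`, `n_split`, `total_copies`.
#' @export
copy_summary <- function(models) {
  if (!nrow(models)) {
    return(tibble(gene = character(), contigs = character(),
                  n_full = integer(), n_truncated = integer(),
                  n_fragment = integer(), n_inverted = integer(),
                  n_split = integer(), total_copies = integer()))
  }
  if (!"split_id" %in% names(models)) models$split_id <- NA_integer_
  models %>%
    group_by(.data$gene) %>%
    summarise(
      contigs = paste(unique(.data$contig_id), collapse = ","),
      n_full = sum(.data$status == "FULL"),
      n_truncated = sum(.data$status == "TRUNCATED"),
      n_fragment = sum(.data$status == "FRAGMENT"),
      n_inverted = sum(.data$orientation == "inverted" &
                         .data$status != "FRAGMENT"),
      n_split = dplyr::n_distinct(.data$split_id[!is.na(.data$split_id)]),
      total_copies = {
        counted <- .data$status %in% c("FULL", "TRUNCATED")
        # each split group collapses its members to one copy
        split_members <- sum(counted & !is.na(.data$split_id))
        as.integer(sum(counted) - split_members +
                     dplyr::n_distinct(.data$split_id[!is.na(.data$split_id)]))
      },
      .groups = "drop")
}

#' Find open reading frames in a transcript
#'
#' All ATG-to-stop ORFs in the six reading frames with a translated length
#' of at least `min_aa` residues (stop codon excluded), longest first. An
#' ORF with no in-frame stop before the end of the sequence is reported with
#' `partial = TRUE`. Coordinates are 0-based half-open on the forward
#' sequence; for minus-strand ORFs they delimit the reverse-complemented
#' region.
#'
#' @param transcript A DNA string.
#' @param min_aa Minimum ORF length in amino acids (default 100, i.e. ORFs
#'   longer than 99 aa).
#' @return Tibble: `strand`, `frame`, `start`, `end`, `aa_length`,
#'   `partial`.
#' @export
find_orfs <- function(transcript, min_aa = 100L) {
  s_fwd <- toupper(transcript)
  n <- nchar(s_fwd)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") s_fwd else revcomp(s_fwd)
    for (frame in 0:2) {
      starts_at <- seq(frame + 1L, n - 2L, by = 3L)
      if (!length(starts_at)) next
      codons <- substring(s, starts_at, starts_at + 2L)
      atg_i <- which(codons == "ATG")
      stop_i <- which(codons %in% stops)
      for (a in atg_i) {
        nxt <- stop_i[stop_i > a]
        if (length(nxt)) {
          st <- nxt[1]
          aa <- st - a
          partial <- FALSE
          cod_end <- st            # stop codon included in the interval
        } else {
          aa <- length(codons) - a + 1L
          partial <- TRUE
          cod_end <- length(codons)
        }
        if (aa < min_aa) next
        lo <- starts_at[a] - 1L
        hi <- starts_at[cod_end] + 2L
        if (strand == "-") { tmp <- lo; lo <- n - hi; hi <- n - tmp }
        out[[length(out) + 1L]] <- tibble(
          strand = strand, frame = frame, start = lo, end = hi,
          aa_length = as.integer(aa), partial = partial)
      }
    }
  }
  if (!length(out)) {
    return(tibble(strand = character(), frame = integer(), start = integer(),
                  end = integer(), aa_length = integer(),
                  partial = logical()))
  }
  bind_rows(out) %>% arrange(desc(.data$aa_length), .data$strand,
                             .data$frame, .data$start)
}
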