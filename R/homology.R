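#' Build a k-mer seed index over a reference
#'
#' Exact-match k-mer positions are indexed for seed lookup; seeds containing
#' `N` are excluded. Both query strands are handled at query time by aligning
#' the reverse complement of the query, so only the forward reference strand
#' is stored.
#'
#' @param reference Tibble with `id` and `sequence` columns (e.g. from
#'   [read_fasta()]).
#' @param k Seed length, 4--31 (a practical floor below which seeds are
#'   uninformative). Default 15.
#' @return A `yt_index` object.
#' @export
build_index <- function(reference, k = 15L) {
  stopifnot(all(c("id", "sequence") %in% names(reference)))
  k <- as.integer(k)
  if (k < 4L || k > 31L) abort("k must be between 4 and 31")
  if (all(nchar(reference$sequence) < k)) {
    abort("k is larger than every reference sequence")
  }
  ptr <- .yt_index_build(reference$id, reference$sequence, k)
  structure(
    list(ptr = ptr, k = k, ids = reference$id,
         lengths = nchar(reference$sequence)),
    class = "yt_index")
}

#' @export
print.yt_index <- function(x, ...) {
  info <- .yt_index_info(x$ptr)
  cat(sprintf("<yt_index> k=%d, %d sequence(s), %.0f distinct k-mers\n",
              x$k, length(x$ids), info$n_kmers))
  invisible(x)
}

#' Seed positions of one exact k-mer (both implicit loci via forward storage)
#'
#' @param index A `yt_index`.
#' @param kmer A k-length DNA string.
#' @return Tibble with `target_id` and 0-based `pos`.
#' @export
seed_positions <- function(index, kmer) {
  df <- .yt_seed_positions(index$ptr, toupper(kmer))
  tibble(target_id = index$ids[df$target], pos = df$pos)
}

#' Local homology search of one query against an indexed reference
#'
#' Seeds are clustered per (target, strand) diagonal band, each cluster is
#' extended gaplessly with an x-drop criterion along its dominant diagonal,
#' and scored as matches minus mismatches. Identity is matches over aligned
#' columns (mismatches included in the denominator; `N` never matches). Hits
#' below `min_identity` or `min_hit_length` are dropped. Hits are sorted by
#' score descending with deterministic `(target_id, tstart)` tie-breaking.
#' Strand `-` means the query aligns to the reverse complement of the target.
#'
#' @param query A single DNA string, or a contig tibble (`id`, `sequence`) to
#'   search row-wise (adds a `query_id` column).
#' @param index A `yt_index` from [build_index()].
#' @param min_seed_chain Minimum seeds per cluster (default 2).
#' @param xdrop X-drop threshold for extension (default 20).
#' @param min_identity Minimum identity fraction to report (default 0.5).
#' @param min_hit_length Minimum aligned length in bases (default 100).
#' @param band Diagonal drift allowed within a seed cluster (default 30).
#' @param chain_gap Maximum query gap between consecutive seeds of one
#'   cluster (default 500).
#' @return Tibble of hits: `query_id` (if applicable), `target_id`, `strand`,
#'   `identity`, `aligned_length`, `qstart`, `qend`, `tstart`, `tend`,
#'   `score` (0-based half-open intervals).
#' @export
local_hits <- function(query, index, min_seed_chain = 2L, xdrop = 20L,
                       min_identity = 0.5, min_hit_length = 100L,
                       band = 30L, chain_gap = 500L) {
  stopifnot(inherits(index, "yt_index"))
  if (is.data.frame(query)) {
    res <- purrr::map2_dfr(query$id, query$sequence, function(qid, sq) {
      h <- local_hits(sq, index, min_seed_chain, xdrop, min_identity,
                      min_hit_length, band, chain_gap)
      if (nrow(h)) h$query_id <- qid
      h
    })
    if (nrow(res)) res <- select(res, "query_id", dplyr::everything())
    return(res)
  }
  query <- toupper(query)
  if (nchar(query) < index$k) abort("query shorter than seed length k")
  df <- .yt_local_hits(index$ptr, query, as.integer(min_seed_chain),
                       as.integer(xdrop), min_identity,
                       as.integer(min_hit_length), as.integer(band),
                       as.integer(chain_gap))
  tibble(
    target_id = index$ids[df$target],
    strand = df$strand,
    identity = ifelse(df$length > 0, df$matches / df$length, 0),
    aligned_length = df$length,
    qstart = df$qstart, qend = df$qend,
    tstart = df$tstart, tend = df$tend,
    score = 2L * df$matches - df$length
  ) %>%
    arrange(desc(.data$score), .data$target_id, .data$tstart)
}

#' Query coverage and mean identity over a class of reference targets
#'
#' Covered fraction is the length of the union of the query intervals of
#' hits to targets of `target_class`, divided by the query length (fully
#' overlapping hits count once). Mean identity is weighted by aligned length.
#'
#' @param hits Hit tibble from [local_hits()] for one query.
#' @param query_length Query length in bases (> 0).
#' @param target_class Optional class to restrict to (requires `classes`).
#' @param classes Named character vector mapping `target_id` to scaffold
#'   class.
#' @return Tibble with one row: `covered_fraction`, `mean_identity`, `n_hits`.
#' @export
query_coverage <- function(hits, query_length, target_class = NULL,
                           classes = NULL) {
  if (query_length <= 0) abort("query_length must be positive")
  if (!is.null(target_class)) {
    if (is.null(classes)) abort("classes mapping required with target_class")
    cls <- classes[hits$target_id]
    if (nrow(hits) && any(is.na(cls))) {
      abort("hit target without scaffold-class annotation")
    }
    hits <- hits[!is.na(cls) & cls == target_class, , drop = FALSE]
  }
  if (!nrow(hits)) {
    return(tibble(covered_fraction = 0, mean_identity = NA_real_, n_hits = 0L))
  }
  ir <- IRanges::reduce(IRanges::IRanges(hits$qstart + 1L, hits$qend))
  tibble(
    covered_fraction = sum(IRanges::width(ir)) / query_length,
    mean_identity = sum(hits$identity * hits$aligned_length) /
      sum(hits$aligned_length),
    n_hits = nrow(hits))
}

#' Spliced alignment of a transcript to a contig
#'
#' Exon-candidate local hits are chained by colinearity: blocks must ascend
#' in transcript coordinates and ascend (direct) or descend (inverted) in
#' contig coordinates, with contig gaps (introns) up to `max_intron`. Chains
#' are extracted greedily by total matched bases, so multiple gene copies on
#' one contig give multiple alignments. A chain may cover only a subset of
#' the transcript (truncated copies).
#'
#' @param transcript A DNA string (the gene's representative transcript).
#' @param contig A DNA string, or a pre-built `yt_index` of one or more
#'   contigs.
#' @param min_exon_identity Minimum per-block identity (default 0.9).
#' @param min_exon_length Minimum block length in bases (default 30).
#' @param max_intron Maximum contig gap between consecutive blocks
#'   (default 10000).
#' @param k Seed length when `contig` is a raw sequence (default 15).
#' @return Tibble with one row per alignment: `target_id`, `alignment`,
#'   `orientation`, `n_blocks`, `covered_fraction`, `matched_bases`,
#'   `t_start`, `t_end`, and a `blocks` list-column of per-exon tibbles
#'   (`q_start`, `q_end`, `t_start`, `t_end`, `identity`; 0-based half-open).
#' @export
spliced_align <- function(transcript, contig, min_exon_identity = 0.9,
                          min_exon_length = 30L, max_intron = 10000L,
                          k = 15L) {
  idx <- if (inherits(contig, "yt_index")) contig else {
    build_index(tibble(id = "contig", sequence = toupper(contig)), k = k)
  }
  if (nchar(transcript) < min_exon_length) {
    abort("transcript shorter than min_exon_length")
  }
  hits <- local_hits(transcript, idx, min_identity = min_exon_identity,
                     min_hit_length = min_exon_length)
  empty <- tibble(target_id = character(), alignment = integer(),
                  orientation = character(), n_blocks = integer(),
                  covered_fraction = double(), matched_bases = double(),
                  t_start = integer(), t_end = integer(), blocks = list())
  if (!nrow(hits)) return(empty)
  qlen <- nchar(transcript)
  out <- list()
  for (tid in unique(hits$target_id)) {
    for (str in c("+", "-")) {
      h <- filter(hits, .data$target_id == tid, .data$strand == str)
      while (nrow(h)) {
        chain_idx <- best_colinear_chain(h, str, max_intron)
        if (!length(chain_idx)) break
        blocks <- h[chain_idx, , drop = FALSE] %>% arrange(.data$qstart)
        blocks <- merge_split_blocks(blocks)
        out[[length(out) + 1L]] <- tibble(
          target_id = tid,
          orientation = if (str == "+") "direct" else "inverted",
          n_blocks = nrow(blocks),
          covered_fraction = {
            ir <- IRanges::reduce(IRanges::IRanges(blocks$qstart + 1L,
                                                   blocks$qend))
            sum(IRanges::width(ir)) / qlen
          },
          matched_bases = sum(blocks$identity * blocks$aligned_length),
          t_start = min(blocks$tstart), t_end = max(blocks$tend),
          blocks = list(tibble(
            q_start = blocks$qstart, q_end = blocks$qend,
            t_start = blocks$tstart, t_end = blocks$tend,
            identity = blocks$identity)))
        h <- h[-chain_idx, , drop = FALSE]
      }
    }
  }
  if (!length(out)) return(empty)
  bind_rows(out) %>%
    arrange(.data$target_id, .data$t_start) %>%
    mutate(alignment = row_number()) %>%
    select("target_id", "alignment", "orientation", "n_blocks",
           "covered_fraction", "matched_bases", "t_start", "t_end", "blocks")
}

# Greedy maximum-weight colinear chain (weight = matched bases, minus a
# small per-base intron penalty so tandem-array exons pair with their
# nearest colinear partner rather than an equivalent distant one) via DP
# over hits sorted by transcript start. Returns row indices of the input.
best_colinear_chain <- function(h, strand, max_intron, slack = 15L,
                                gap_penalty = 0.005) {
  ord <- order(h$qstart, h$tstart)
  hs <- h[ord, , drop = FALSE]
  n <- nrow(hs)
  w <- hs$identity * hs$aligned_length
  best <- w
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      ok_q <- hs$qstart[j] >= hs$qend[i] - slack
      gap <- if (strand == "+") hs$tstart[j] - hs$tend[i]
             else hs$tstart[i] - hs$tend[j]
      ok_t <- gap >= -slack && gap <= max_intron
      cand <- best[i] + w[j] - gap_penalty * max(0, gap)
      if (ok_q && ok_t && cand > best[j]) {
        best[j] <- cand
        prev[j] <- i
      }
    }
  }
  j <- which.max(best)
  chain <- integer()
  while (!is.na(j)) {
    chain <- c(j, chain)
    j <- prev[j]
  }
  ord[chain]
}

# Rejoin an exon that the extension stage split into colinear pieces on
# (nearly) the same diagonal: both gaps small and equal within a few bases.
merge_split_blocks <- function(blocks, join_gap = 50L, diag_tol = 5L) {
  if (nrow(blocks) < 2L) return(blocks)
  keep <- blocks[1, , drop = FALSE]
  for (i in 2:nrow(blocks)) {
    prev <- keep[nrow(keep), ]
    cur <- blocks[i, ]
    qgap <- cur$qstart - prev$qend
    tgap <- if (cur$strand == "+") cur$tstart - prev$tend
            else prev$tstart - cur$tend
    if (qgap >= 0 && qgap <= join_gap && abs(tgap - qgap) <= diag_tol) {
      m <- prev$identity * prev$aligned_length +
        cur$identity * cur$aligned_length
      keep$qend[nrow(keep)] <- cur$qend
      keep$tstart[nrow(keep)] <- min(prev$tstart, cur$tstart)
      keep$tend[nrow(keep)] <- max(prev$tend, cur$tend)
      keep$aligned_length[nrow(keep)] <- keep$qend[nrow(keep)] -
        keep$qstart[nrow(keep)]
      keep$identity[nrow(keep)] <- m / keep$aligned_length[nrow(keep)]
    } else {
      keep <- bind_rows(keep, cur)
    }
  }
  keep
}

#' Write a hit table as blast-tabular-like TSV
#'
#' Columns: query, target, identity, length, q.start, q.end, t.start, t.end,
#' strand, score (1-based inclusive coordinates in the report).
#'
#' @param hits Hit tibble from [local_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  tab <- tibble(
    query = if ("query_id" %in% names(hits)) hits$query_id else NA_character_,
    target = hits$target_id,
    identity = round(100 * hits$identity, 1),
    length = hits$aligned_length,
    q.start = hits$qstart + 1L, q.end = hits$qend,
    t.start = hits$tstart + 1L, t.end = hits$tend,
    strand = hits$strand, score = hits$score)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
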