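#' Assembly summary metrics
#'
#' N50 is the length of the contig at which the descending cumulative length
#' first reaches half the assembly; L50 is that contig's rank. Mean length is
#' rounded to the nearest integer base.
#'
#' @param lengths Integer vector of contig lengths (all >= 1).
#' @return One-row tibble: `total_bases`, `contig_count`, `n50`, `l50`,
#'   `largest`, `smallest`, `mean_length`.
#' @export
assembly_metrics <- function(lengths) {
  if (!length(lengths)) abort("no contig lengths supplied")
  if (any(lengths < 1)) abort("contig lengths must be >= 1")
  lengths <- as.numeric(lengths)
  srt <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(srt)
  l50 <- which(csum >= sum(lengths) / 2)[1]
  tibble(total_bases = sum(lengths), contig_count = length(lengths),
         n50 = srt[l50], l50 = as.integer(l50),
         largest = srt[1], smallest = srt[length(srt)],
         mean_length = round(sum(lengths) / length(lengths)))
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator.
#' An all-`N` sequence has undefined GC and is reported as `NA`.
#'
#' @param sequence A DNA string.
#' @return GC fraction in `[0, 1]`, or `NA` if undefined.
#' @export
gc_content <- function(sequence) {
  sequence <- toupper(sequence)
  gc <- stringr::str_count(sequence, "[GC]")
  at <- stringr::str_count(sequence, "[AT]")
  denom <- gc + at
  ifelse(denom > 0, gc / denom, NA_real_)
}

#' Interspersed and simple repeat annotation of one contig
#'
#' Library-based masking: homology hits of each labeled consensus
#' (LINE/SINE/LTR) against the contig above the identity and length gates are
#' masked under the consensus class; overlapping masks within a class are
#' merged. Simple repeats (tandem arrays / microsatellites) are detected with
#' [find_simple_repeats()] and masked as `SIMPLE`. `total_repetitive` is the
#' union of all masked bases over the contig length (never more than the sum
#' of the class fractions).
#'
#' @param contig One-row contig tibble or a DNA string.
#' @param repeat_library Tibble with `id`, `sequence`, `class` columns
#'   (classes `LINE`, `SINE`, `LTR`). May be empty.
#' @param min_identity Identity gate for masking (default 0.8).
#' @param min_length Minimum masked hit length (default 50).
#' @param k Seed length for the repeat search (default 11).
#' @param simple_params List of arguments for [find_simple_repeats()].
#' @return List with `class_fractions` (tibble class/fraction),
#'   `total_repetitive`, and `masked_intervals` (tibble class/start/end,
#'   0-based half-open).
#' @export
annotate_repeats <- function(contig, repeat_library = NULL,
                             min_identity = 0.8, min_length = 50L, k = 11L,
                             simple_params = list()) {
  seq <- if (is.data.frame(contig)) contig$sequence[1] else contig
  len <- nchar(seq)
  idx <- build_index(tibble(id = "contig", sequence = toupper(seq)), k = k)
  classes <- c("LINE", "SINE", "LTR")
  masks <- list()
  if (!is.null(repeat_library) && nrow(repeat_library)) {
    stopifnot(all(c("id", "sequence", "class") %in% names(repeat_library)))
    bad <- setdiff(unique(repeat_library$class), classes)
    if (length(bad)) abort(paste0("unknown repeat class: ", bad[1]))
    for (i in seq_len(nrow(repeat_library))) {
      cons <- repeat_library[i, ]
      if (nchar(cons$sequence) < k) next
      h <- local_hits(cons$sequence, idx, min_identity = min_identity,
                      min_hit_length = min_length, min_seed_chain = 1L)
      if (nrow(h)) {
        masks[[length(masks) + 1L]] <- tibble(
          class = cons$class, start = h$tstart, end = h$tend)
      }
    }
  }
  sr <- do.call(find_simple_repeats, c(list(seq), simple_params))
  if (nrow(sr)) {
    masks[[length(masks) + 1L]] <- tibble(class = "SIMPLE", start = sr$start,
                                          end = sr$end)
  }
  masked <- if (length(masks)) bind_rows(masks) else {
    tibble(class = character(), start = integer(), end = integer())
  }
  merged <- if (nrow(masked)) {
    purrr::map_dfr(unique(masked$class), function(cl) {
      m <- masked[masked$class == cl, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
      tibble(class = cl, start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir))
    })
  } else masked
  fractions <- purrr::map_dfr(c(classes, "SIMPLE"), function(cl) {
    m <- merged[merged$class == cl, , drop = FALSE]
    tibble(class = cl, fraction = sum(m$end - m$start) / len)
  })
  total <- if (nrow(merged)) {
    ir <- IRanges::reduce(IRanges::IRanges(merged$start + 1L, merged$end))
    sum(IRanges::width(ir)) / len
  } else 0
  list(class_fractions = fractions, total_repetitive = total,
       masked_intervals = merged)
}

#' Find simple tandem repeats (microsatellites)
#'
#' Maximal tandem arrays of unit size `min_unit`..`max_unit` with at least
#' `min_copies` copies, length at least `min_length`, and a mismatch fraction
#' (Hamming distance against a perfect tandem extension of the unit) of at
#' most `max_impurity`. Overlapping arrays are merged keeping the
#' higher-purity call (ties prefer the smaller unit).
#'
#' @param sequence A DNA string.
#' @param min_unit,max_unit Unit size range (defaults 1 and 6).
#' @param min_copies Minimum copies of the unit (default 5).
#' @param min_length Minimum array length in bases (default 12).
#' @param max_impurity Maximum mismatch fraction (default 0.1).
#' @return Tibble of masked intervals: `start`, `end` (0-based half-open),
#'   `unit`, `purity`.
#' @export
find_simple_repeats <- function(sequence, min_unit = 1L, max_unit = 6L,
                                min_copies = 5L, min_length = 12L,
                                max_impurity = 0.1) {
  df <- .yt_tandem_scan(toupper(sequence), as.integer(min_unit),
                        as.integer(max_unit), as.integer(min_copies),
                        as.integer(min_length), max_impurity)
  calls <- as_tibble(df)
  if (!nrow(calls)) return(calls)
  calls <- arrange(calls, desc(.data$purity), .data$unit, .data$start)
  kept <- calls[0, ]
  for (i in seq_len(nrow(calls))) {
    cand <- calls[i, ]
    overlaps <- nrow(kept) > 0 &
      kept$start < cand$end & cand$start < kept$end
    if (!any(overlaps)) kept <- bind_rows(kept, cand)
  }
  arrange(kept, .data$start)
}

#' Per-contig feature report with size-weighted summary row
#'
#' One row per contig sorted by size descending, plus a `Total/Average` row
#' holding the base-count total for the size column and size-weighted means
#' for every percentage column (the convention that reproduces published
#' contig-feature tables of this kind).
#'
#' @param features Tibble with `contig_id`, `size` and numeric percentage
#'   columns (e.g. `gc`, `line`, `sine`, `simple`, `ltr`,
#'   `total_repetitive`).
#' @return Tibble with the contig rows and the summary row appended; the
#'   summary keeps full precision (round for display).
#' @export
feature_report <- function(features) {
  stopifnot(all(c("contig_id", "size") %in% names(features)))
  pct_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                             logical(1))], "size")
  rows <- arrange(features, desc(.data$size))
  if (!nrow(rows)) return(rows)
  w <- rows$size / sum(rows$size)
  summary_row <- tibble(contig_id = "Total/Average",
                        size = sum(rows$size))
  for (col in pct_cols) summary_row[[col]] <- sum(w * rows[[col]])
  bind_rows(rows, summary_row)
}

#' Sequence features of a contig set
#'
#' Convenience wrapper computing GC and repeat-class percentages per contig
#' and assembling the [feature_report()] table.
#'
#' @param contigs Contig tibble.
#' @param repeat_library Repeat consensus tibble (see [annotate_repeats()]).
#' @param ... Passed to [annotate_repeats()].
#' @return Feature report tibble (percentages on the 0--100 scale).
#' @export
contig_features <- function(contigs, repeat_library = NULL, ...) {
  rows <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    ct <- contigs[i, ]
    ann <- annotate_repeats(ct$sequence, repeat_library, ...)
    fr <- stats::setNames(ann$class_fractions$fraction,
                          ann$class_fractions$class)
    tibble(contig_id = ct$id, size = ct$length,
           gc = 100 * gc_content(ct$sequence),
           line = 100 * fr[["LINE"]], sine = 100 * fr[["SINE"]],
           simple = 100 * fr[["SIMPLE"]], ltr = 100 * fr[["LTR"]],
           total_repetitive = 100 * ann$total_repetitive)
  })
  feature_report(rows)
}
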