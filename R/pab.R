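#' Windowed X-homology profile of a contig
#'
#' Scores sliding windows of the contig by coverage and identity of local
#' hits against the X reference. A contig shorter than the window gives a
#' single whole-contig window.
#'
#' @param contig One-row contig tibble or a DNA string (with `id` attr
#'   taken from the tibble when available).
#' @param x_reference X-scaffold tibble (`id`, `sequence`) or a pre-built
#'   `yt_index`.
#' @param window Window size in bases (>= 1000, default 10000).
#' @param step Step between window starts (<= window, default 2000).
#' @param min_identity Identity floor for hits entering the profile
#'   (default 0.9).
#' @return Tibble with one row per window: `window`, `start`, `end`,
#'   `covered_fraction`, `mean_identity` (0-based half-open window
#'   coordinates).
#' @export
homology_profile <- function(contig, x_reference, window = 10000L,
                             step = 2000L, min_identity = 0.9) {
  if (window < 1000L) abort("window must be >= 1000")
  if (step > window) abort("step must be <= window")
  seq <- if (is.data.frame(contig)) contig$sequence[1] else contig
  len <- nchar(seq)
  idx <- if (inherits(x_reference, "yt_index")) x_reference else
    build_index(x_reference)
  starts <- if (len <= window) 0L else
    as.integer(seq(0L, by = step, length.out = ceiling((len - window) / step) + 1L))
  purrr::map_dfr(seq_along(starts), function(i) {
    st <- starts[i]
    en <- min(len, st + window)
    wseq <- substr(seq, st + 1L, en)
    hits <- local_hits(wseq, idx, min_identity = min_identity,
                       min_hit_length = 100L)
    qc <- query_coverage(hits, en - st)
    tibble(window = i, start = st, end = en,
           covered_fraction = qc$covered_fraction,
           mean_identity = qc$mean_identity)
  })
}

#' Detect a pseudoautosomal boundary from a homology profile
#'
#' Finds the two-segment changepoint of the window coverage profile that
#' maximizes `mean(left) - mean(right)`, requiring a clearly pseudoautosomal
#' left flank (`mean >= left_min`) and a clearly X-free right flank
#' (`mean <= right_max`) with at least `min_flank_windows` windows each;
#' otherwise no boundary is called. The coarse window changepoint is then
#' refined to base precision by re-aligning the transition region against
#' the X reference and taking the end of the furthest X-homologous
#' alignment.
#'
#' @param profile Profile tibble from [homology_profile()].
#' @param contig The profiled contig (one-row tibble or DNA string) for
#'   base-level refinement; omit to return the coarse window boundary.
#' @param x_reference X reference tibble or `yt_index` (required with
#'   `contig`).
#' @param min_flank_windows Minimum windows on each side (default 5).
#' @param left_min,right_max Coverage means required of the two flanks
#'   (defaults 0.5 and 0.1).
#' @param min_identity Identity floor for the refinement alignment
#'   (default 0.9).
#' @return A one-row PAB-call tibble (`contig_id`, `boundary`,
#'   `par_side_identity`, `msy_side_identity`, `window`), or an empty tibble
#'   when no acceptable split exists. `boundary` is a 0-based offset = the
#'   number of pseudoautosomal bases (1-based reports print `1..boundary`
#'   as the PAR segment).
#' @export
detect_boundary <- function(profile, contig = NULL, x_reference = NULL,
                            min_flank_windows = 5L, left_min = 0.5,
                            right_max = 0.1, min_identity = 0.9) {
  empty <- tibble(contig_id = character(), boundary = integer(),
                  par_side_identity = double(), msy_side_identity = double(),
                  window = integer())
  n <- nrow(profile)
  if (n < 2L * min_flank_windows) return(empty)
  cov <- profile$covered_fraction
  splits <- seq(min_flank_windows, n - min_flank_windows)
  sep <- vapply(splits, function(s) {
    mean(cov[1:s]) - mean(cov[(s + 1L):n])
  }, numeric(1))
  s <- splits[which.max(sep)]
  if (mean(cov[1:s]) < left_min || mean(cov[(s + 1L):n]) > right_max) {
    return(empty)
  }
  cid <- if (is.data.frame(contig)) contig$id[1] else "contig"
  wsize <- profile$end[1] - profile$start[1]
  boundary <- profile$end[s]  # coarse: end of the last high-coverage window
  par_ident <- mean(profile$mean_identity[1:s], na.rm = TRUE)
  msy_ident <- suppressWarnings(
    mean(profile$mean_identity[(s + 1L):n], na.rm = TRUE))
  if (!is.null(contig) && !is.null(x_reference)) {
    seq <- if (is.data.frame(contig)) contig$sequence[1] else contig
    idx <- if (inherits(x_reference, "yt_index")) x_reference else
      build_index(x_reference)
    rs <- profile$start[s]
    re <- min(nchar(seq), profile$end[min(n, s + 1L)])
    region <- substr(seq, rs + 1L, re)
    hits <- local_hits(region, idx, min_identity = min_identity,
                       min_hit_length = 100L)
    if (nrow(hits)) boundary <- rs + max(hits$qend)
  }
  tibble(contig_id = cid, boundary = as.integer(boundary),
         par_side_identity = par_ident,
         msy_side_identity = if (is.nan(msy_ident)) NA_real_ else msy_ident,
         window = as.integer(wsize))
}

#' Sequence divergence between X and Y gametolog copies
#'
#' Identity of the best colinear chained alignment between the two
#' sequences. Sequences with no alignment above the identity floor are
#' reported as non-homologous.
#'
#' @param x_copy,y_copy DNA strings (each >= 200 bases).
#' @param min_identity Identity floor per hit (default 0.5).
#' @param k Seed length (default 15).
#' @return One-row tibble: `identity`, `aligned_length`, `homologous`.
#' @export
gametolog_divergence <- function(x_copy, y_copy, min_identity = 0.5,
                                 k = 15L) {
  if (nchar(x_copy) < 200L || nchar(y_copy) < 200L) {
    abort("gametolog sequences must be >= 200 bases")
  }
  idx <- build_index(tibble(id = "y", sequence = toupper(y_copy)), k = k)
  hits <- local_hits(x_copy, idx, min_identity = min_identity,
                     min_hit_length = 100L)
  if (!nrow(hits)) {
    return(tibble(identity = NA_real_, aligned_length = 0L,
                  homologous = FALSE))
  }
  best <- list(ident = NA_real_, len = 0)
  for (str in c("+", "-")) {
    h <- filter(hits, .data$strand == str)
    if (!nrow(h)) next
    chain <- best_colinear_chain(h, str, max_intron = nchar(y_copy))
    hc <- h[chain, , drop = FALSE]
    len <- sum(hc$aligned_length)
    if (len > best$len) {
      best <- list(ident = sum(hc$identity * hc$aligned_length) / len,
                   len = len)
    }
  }
  tibble(identity = best$ident, aligned_length = as.integer(best$len),
         homologous = TRUE)
}

#' Order pseudoautosomal contigs along a template X map
#'
#' Places each PAR contig at its best-hit interval on the template X
#' sequence and sorts placements by template start. Conflicting overlapping
#' placements are resolved to the higher identity; the loser is flagged
#' `UNPLACED`, as are contigs with no template hit.
#'
#' @param par_contigs Contig tibble.
#' @param template_x Template X tibble (`id`, `sequence`) or `yt_index`.
#' @param min_identity Identity floor (default 0.8).
#' @param overlap_fraction Overlap (of the smaller interval) above which two
#'   placements conflict (default 0.5).
#' @return Tibble: `contig_id`, `template_id`, `t_start`, `t_end`,
#'   `orientation`, `identity`, `status` (`PLACED`/`UNPLACED`), sorted by
#'   template start with unplaced contigs last.
#' @export
order_par_contigs <- function(par_contigs, template_x, min_identity = 0.8,
                              overlap_fraction = 0.5) {
  idx <- if (inherits(template_x, "yt_index")) template_x else
    build_index(template_x)
  placements <- purrr::map_dfr(seq_len(nrow(par_contigs)), function(i) {
    ct <- par_contigs[i, ]
    hits <- local_hits(ct$sequence, idx, min_identity = min_identity,
                       min_hit_length = 100L)
    if (!nrow(hits)) {
      return(tibble(contig_id = ct$id, template_id = NA_character_,
                    t_start = NA_integer_, t_end = NA_integer_,
                    orientation = NA_character_, identity = NA_real_,
                    status = "UNPLACED"))
    }
    by_t <- hits %>%
      group_by(.data$target_id) %>%
      summarise(total = sum(.data$identity * .data$aligned_length),
                .groups = "drop") %>%
      arrange(desc(.data$total))
    h <- filter(hits, .data$target_id == by_t$target_id[1])
    strand_w <- h %>%
      group_by(.data$strand) %>%
      summarise(w = sum(.data$aligned_length), .groups = "drop") %>%
      arrange(desc(.data$w))
    h <- filter(h, .data$strand == strand_w$strand[1])
    tibble(contig_id = ct$id, template_id = h$target_id[1],
           t_start = min(h$tstart), t_end = max(h$tend),
           orientation = ifelse(strand_w$strand[1] == "+",
                                "direct", "inverted"),
           identity = sum(h$identity * h$aligned_length) /
             sum(h$aligned_length),
           status = "PLACED")
  })
  placed <- placements %>% filter(.data$status == "PLACED") %>%
    arrange(desc(.data$identity))
  kept <- placed[0, ]
  for (i in seq_len(nrow(placed))) {
    cand <- placed[i, ]
    if (nrow(kept)) {
      same <- kept$template_id == cand$template_id
      ov <- pmax(0, pmin(kept$t_end, cand$t_end) -
                   pmax(kept$t_start, cand$t_start))
      span <- pmin(kept$t_end - kept$t_start, cand$t_end - cand$t_start)
      if (any(same & ov / pmax(span, 1) >= overlap_fraction)) {
        cand$status <- "UNPLACED"
      }
    }
    kept <- bind_rows(kept, cand)
  }
  unplaced <- placements %>% filter(.data$status == "UNPLACED")
  bind_rows(kept, unplaced) %>%
    arrange(.data$status != "PLACED", .data$template_id, .data$t_start)
}

#' Pseudoautosomal assembly coverage
#'
#' Fraction of an estimated full PAR length covered by assembled PAR
#' contigs. Reports the one-decimal percentage and the round-half-up integer
#' percentage; published figures of this kind are sometimes rounded from a
#' coarser size estimate, so both are exposed rather than silently matched.
#'
#' @param assembled_bases Summed length of placed PAR contigs.
#' @param estimated_par_bases Estimated full PAR size.
#' @return One-row tibble: `fraction`, `percent`, `percent_integer`.
#' @export
par_coverage <- function(assembled_bases, estimated_par_bases) {
  fr <- assembled_bases / estimated_par_bases
  tibble(fraction = fr, percent = round(100 * fr, 1),
         percent_integer = as.integer(floor(100 * fr + 0.5)))
}
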