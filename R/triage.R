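#' Triage parameters
#'
#' Defaults follow the study design this package models: contigs shorter than
#' the mean long-read length (8,034 bp) are discarded before homology
#' evaluation, and significant homology to the female reference means at
#' least 95% identity over at least 25% of the contig length.
#'
#' @param min_identity Identity gate (fraction), default 0.95.
#' @param min_coverage Coverage gate (fraction of contig length), default 0.25.
#' @param length_threshold Minimum contig length in bases, default 8034.
#' @param near_margin Identity margin used to flag near-threshold evidence in
#'   reports, default 0.02.
#' @return A `triage_params` list.
#' @export
triage_params <- function(min_identity = 0.95, min_coverage = 0.25,
                          length_threshold = 8034L, near_margin = 0.02) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 length_threshold = as.integer(length_threshold),
                 near_margin = near_margin),
            class = "triage_params")
}

class_gate_evidence <- function(hits, contig_length, classes, params) {
  if (nrow(hits)) {
    cls <- classes[hits$target_id]
    if (any(is.na(cls))) abort("hit target without scaffold-class annotation")
  }
  purrr::map_dfr(c("X", "AUTOSOME", "UNPLACED"), function(cl) {
    strict <- hits[nrow(hits) > 0 & hits$identity >= params$min_identity &
                     classes[hits$target_id] == cl, , drop = FALSE]
    near <- hits[nrow(hits) > 0 &
                   hits$identity >= params$min_identity - params$near_margin &
                   classes[hits$target_id] == cl, , drop = FALSE]
    qc <- query_coverage(strict, contig_length)
    qn <- query_coverage(near, contig_length)
    tibble(class = cl,
           coverage = qc$covered_fraction,
           identity = qc$mean_identity,
           near_coverage = qn$covered_fraction,
           near_identity = qn$mean_identity)
  })
}

#' Classify a single contig from its homology hits
#'
#' Rule order: contigs below the length threshold are `TOO_SHORT` (no
#' homology evaluation); contigs whose autosome- or unplaced-class coverage
#' passes both identity and coverage gates are `AUTOSOMAL_CONTAMINANT`;
#' otherwise passing X-class coverage gives `PAR_CANDIDATE`; anything left is
#' `PUTATIVE_MSY`. When both the autosomal and X gates pass, contamination
#' wins (removal precedes X assignment) and the tie is recorded in the
#' evidence. Contigs that would pass a gate within `near_margin` identity of
#' the threshold are flagged `near_threshold`.
#'
#' @param contig One-row contig tibble (or list with `id`, `length`).
#' @param hits Hit tibble from [local_hits()] against the full female
#'   reference (any identity floor at or below
#'   `min_identity - near_margin`).
#' @param classes Named vector mapping reference scaffold id to class.
#' @param params A [triage_params()] list.
#' @return One-row tibble: `contig_id`, `length`, `label`, `best_class`,
#'   `coverage`, `identity`, `near_threshold`, `gate_tie`.
#' @export
classify_contig <- function(contig, hits, classes, params = triage_params()) {
  lab_row <- function(label, best_class = NA_character_, coverage = 0,
                      identity = NA_real_, near = FALSE, tie = FALSE) {
    tibble(contig_id = contig$id, length = contig$length, label = label,
           best_class = best_class, coverage = coverage, identity = identity,
           near_threshold = near, gate_tie = tie)
  }
  if (contig$length < params$length_threshold) return(lab_row("TOO_SHORT"))
  ev <- class_gate_evidence(hits, contig$length, classes, params)
  pass <- ev$coverage >= params$min_coverage
  near_pass <- ev$near_coverage >= params$min_coverage & !pass
  auto_pass <- any(pass[ev$class %in% c("AUTOSOME", "UNPLACED")])
  x_pass <- pass[ev$class == "X"]
  best <- ev[order(-ev$coverage), ][1, ]
  near_any <- any(near_pass)
  if (auto_pass) {
    ba <- ev[ev$class %in% c("AUTOSOME", "UNPLACED"), ]
    ba <- ba[order(-ba$coverage), ][1, ]
    return(lab_row("AUTOSOMAL_CONTAMINANT", ba$class, ba$coverage,
                   ba$identity, near_any, tie = x_pass))
  }
  if (x_pass) {
    bx <- ev[ev$class == "X", ]
    return(lab_row("PAR_CANDIDATE", "X", bx$coverage, bx$identity, near_any))
  }
  lab_row("PUTATIVE_MSY",
          if (best$coverage > 0) best$class else NA_character_,
          best$coverage, best$identity, near_any)
}

#' Triage an assembly against a female reference
#'
#' Labels every contig (`TOO_SHORT`, `AUTOSOMAL_CONTAMINANT`,
#' `PAR_CANDIDATE`, `PUTATIVE_MSY`) and summarises per-class contig counts
#' and cumulative bases; the per-class totals partition the input bases
#' exactly.
#'
#' @param contigs Contig tibble (`id`, `sequence`, `length`).
#' @param reference Female reference tibble with `id`, `sequence`,
#'   `scaffold_class` columns (classes `X`/`AUTOSOME`/`UNPLACED`).
#' @param params A [triage_params()] list.
#' @param index Optional pre-built `yt_index` of the reference.
#' @return A `yt_triage` object with `$labels` (per-contig tibble) and
#'   `$summary` (per-class counts and bases).
#' @export
triage_assembly <- function(contigs, reference, params = triage_params(),
                            index = NULL) {
  stopifnot(all(c("id", "sequence", "scaffold_class") %in% names(reference)))
  classes <- stats::setNames(reference$scaffold_class, reference$id)
  floor_id <- max(0, params$min_identity - params$near_margin - 0.03)
  labels <- if (nrow(contigs) == 0) {
    tibble(contig_id = character(), length = integer(), label = character(),
           best_class = character(), coverage = double(), identity = double(),
           near_threshold = logical(), gate_tie = logical())
  } else {
    if (is.null(index)) index <- build_index(reference)
    purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
      ct <- contigs[i, ]
      if (ct$length < params$length_threshold) {
        return(classify_contig(ct, NULL, classes, params))
      }
      hits <- local_hits(ct$sequence, index, min_identity = floor_id,
                         min_hit_length = 100L)
      classify_contig(ct, hits, classes, params)
    })
  }
  all_labels <- c("TOO_SHORT", "AUTOSOMAL_CONTAMINANT", "PAR_CANDIDATE",
                  "PUTATIVE_MSY")
  summary <- purrr::map_dfr(all_labels, function(lb) {
    sel <- labels$label == lb
    tibble(label = lb, n_contigs = sum(sel),
           bases = sum(as.numeric(labels$length[sel])))
  })
  structure(list(labels = labels, summary = summary, params = params),
            class = "yt_triage")
}

#' @export
print.yt_triage <- function(x, ...) {
  cat("<yt_triage>", nrow(x$labels), "contigs,",
      format(sum(x$summary$bases), big.mark = ","), "bases\n")
  print(x$summary)
  invisible(x)
}

#' @rdname triage_assembly
#' @param x A `yt_triage` object.
#' @param ... Unused.
#' @method tidy yt_triage
#' @export
tidy.yt_triage <- function(x, ...) x$labels

#' @rdname triage_assembly
#' @method glance yt_triage
#' @export
glance.yt_triage <- function(x, ...) {
  tibble(n_contigs = nrow(x$labels),
         total_bases = sum(as.numeric(x$labels$length)),
         n_msy = sum(x$labels$label == "PUTATIVE_MSY"),
         n_par = sum(x$labels$label == "PAR_CANDIDATE"),
         n_contaminant = sum(x$labels$label == "AUTOSOMAL_CONTAMINANT"),
         n_too_short = sum(x$labels$label == "TOO_SHORT"))
}

# primer annealing sites on the forward strand of seq; orientation:
# "F" = primer itself (3' end rightmost), "R" = reverse complement of the
# primer (3' end leftmost).
primer_sites <- function(primer, seq, max_mismatch, three_prime_exact) {
  subject <- Biostrings::DNAString(seq)
  find <- function(pat, orient) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (!length(m)) return(NULL)
    st <- Biostrings::start(m) - 1L
    en <- Biostrings::end(m)
    keep <- vapply(seq_along(m), function(i) {
      site <- substr(seq, st[i] + 1L, en[i])
      if (orient == "F") {
        tail_site <- substr(site, nchar(site) - three_prime_exact + 1L,
                            nchar(site))
        tail_pat <- substr(pat, nchar(pat) - three_prime_exact + 1L,
                           nchar(pat))
        identical(tail_site, tail_pat)
      } else {
        identical(substr(site, 1L, three_prime_exact),
                  substr(pat, 1L, three_prime_exact))
      }
    }, logical(1))
    if (!any(keep)) return(NULL)
    tibble(start = st[keep], end = en[keep], orient = orient)
  }
  res <- bind_rows(find(primer, "F"), find(revcomp(primer), "R"))
  if (is.null(res) || !nrow(res)) NULL else res
}

#' In-silico PCR of one primer pair against a genome
#'
#' Finds convergent primer-site pairs on any contig: a site matches with at
#' most `max_mismatch` substitutions and zero mismatches in the 3'-terminal
#' `three_prime_exact` bases; a product requires the two primers to face each
#' other with a size in `[min_size, max_size]`. Product size is `end - start`
#' (0-based half-open).
#'
#' @param primer_pair One-row tibble with `name`, `forward`, `reverse`.
#' @param genome Contig tibble (`id`, `sequence`).
#' @param max_mismatch Maximum substitutions per site (default 2).
#' @param three_prime_exact 3'-terminal bases that must match exactly
#'   (default 5).
#' @param min_size,max_size Product size bounds (defaults 50 and 5000).
#' @return Tibble of products: `primer_name`, `contig_id`, `start`, `end`,
#'   `size`.
#' @export
in_silico_pcr <- function(primer_pair, genome, max_mismatch = 2L,
                          three_prime_exact = 5L, min_size = 50L,
                          max_size = 5000L) {
  stopifnot(nchar(primer_pair$forward) >= 15, nchar(primer_pair$reverse) >= 15)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    seq <- genome$sequence[i]
    fs <- primer_sites(primer_pair$forward, seq, max_mismatch,
                       three_prime_exact)
    rs <- primer_sites(primer_pair$reverse, seq, max_mismatch,
                       three_prime_exact)
    if (is.null(fs) || is.null(rs)) next
    pair_up <- function(left, right) {
      # left primer rightward on +, right primer as revcomp downstream
      left <- left[left$orient == "F", , drop = FALSE]
      right <- right[right$orient == "R", , drop = FALSE]
      if (!nrow(left) || !nrow(right)) return(NULL)
      grid <- expand.grid(il = seq_len(nrow(left)), ir = seq_len(nrow(right)))
      st <- left$start[grid$il]
      le <- left$end[grid$il]
      rs2 <- right$start[grid$ir]
      en <- right$end[grid$ir]
      keep <- rs2 >= le & (en - st) >= min_size & (en - st) <= max_size
      if (!any(keep)) return(NULL)
      tibble(start = st[keep], end = en[keep], size = en[keep] - st[keep])
    }
    pairs <- bind_rows(pair_up(fs, rs), pair_up(rs, fs))
    if (!is.null(pairs) && nrow(pairs)) {
      out[[length(out) + 1L]] <- tibble(
        primer_name = primer_pair$name, contig_id = genome$id[i],
        start = pairs$start, end = pairs$end, size = pairs$size)
    }
  }
  if (!length(out)) {
    return(tibble(primer_name = character(), contig_id = character(),
                  start = integer(), end = integer(), size = integer()))
  }
  bind_rows(out) %>% distinct()
}

#' Male-specificity of a primer pair from paired in-silico PCR
#'
#' `MALE_SPECIFIC` requires at least one product in the male genome and none
#' in the female genome; more than three male products is `AMBIGUOUS`
#' (ladder-like amplification typical of repeats); products in both genomes
#' is `BOTH`; no male product gives `NONE` (female-only amplification carries
#' no Y-specificity evidence).
#'
#' @param primer_pair One-row primer tibble.
#' @param male_genome,female_genome Contig tibbles.
#' @param ... Passed to [in_silico_pcr()].
#' @return One-row tibble: `primer_name`, `call`, `n_male`, `n_female`.
#' @export
male_specificity <- function(primer_pair, male_genome, female_genome, ...) {
  nm <- nrow(in_silico_pcr(primer_pair, male_genome, ...))
  nf <- nrow(in_silico_pcr(primer_pair, female_genome, ...))
  call <- if (nm > 3L) "AMBIGUOUS"
    else if (nm >= 1L && nf == 0L) "MALE_SPECIFIC"
    else if (nm >= 1L) "BOTH"
    else "NONE"
  tibble(primer_name = primer_pair$name, call = call,
         n_male = nm, n_female = nf)
}

#' Validated-MSY contigs
#'
#' A contig is validated MSY when labeled `PUTATIVE_MSY` and carrying at
#' least one `MALE_SPECIFIC` marker product.
#'
#' @param triage A `yt_triage` object.
#' @param primers Primer tibble.
#' @param male_genome,female_genome Contig tibbles for the paired in-silico
#'   PCR.
#' @param ... Passed to [in_silico_pcr()].
#' @return The label tibble with a `validated_msy` logical column.
#' @export
validate_msy <- function(triage, primers, male_genome, female_genome, ...) {
  calls <- purrr::map_dfr(seq_len(nrow(primers)), function(i) {
    pr <- primers[i, ]
    ms <- male_specificity(pr, male_genome, female_genome, ...)
    prods <- in_silico_pcr(pr, male_genome, ...)
    if (!nrow(prods)) return(NULL)
    mutate(prods, call = ms$call)
  })
  validated <- if (!is.null(calls) && nrow(calls)) {
    unique(calls$contig_id[calls$call == "MALE_SPECIFIC"])
  } else character()
  mutate(triage$labels,
         validated_msy = .data$label == "PUTATIVE_MSY" &
           .data$contig_id %in% validated)
}
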