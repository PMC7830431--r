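# Deterministic synthetic-study generator. All sequences are built from a
# single RNG stream seeded once, so identical spec + seed gives
# byte-identical outputs. Divergence is simulated by substitutions only
# (uniform positions, uniform alternative base, exact count), which keeps
# every planted coordinate exact in the truth manifest.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

rand_dna <- function(n) paste(rand_dna_chars(n), collapse = "")

# substitution-only divergence with an exact mutation count
mutate_chars <- function(chars, identity) {
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut == 0) return(chars)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  chars
}

mutate_seq <- function(seq, identity) {
  paste(mutate_chars(strsplit(seq, "")[[1]], identity), collapse = "")
}

revcomp_chars <- function(chars) {
  rev(chartr("ACGT", "TGCA", chars))
}

#' Specification of a synthetic flow-sorted Y study
#'
#' Builds the parameter set consumed by [generate_fixture()]. The `paper`
#' preset plants the multicopy architecture this package is designed to
#' recover: an HSFY array of 15 direct plus one inverted copy on one contig,
#' nine direct copies on a second and a single copy on the
#' boundary-spanning contig (26 countable copies in all); a 7-exon EIF1AY
#' full copy plus an inverted copy truncated to exons 1-4 on the boundary
#' contig; a 28-exon UTY split across two contigs (exons 1-16 / 17-28);
#' three RBMY copies plus two sub-200 bp fragments; three TSPY copies; a
#' single-exon SRY whose coding sequence is one 240-aa ORF. The boundary
#' contig is 307,557 bases with an X-derived prefix of 177,307 bases at
#' 99.1% identity. The `small` preset is a miniature of the same structure
#' for fast property tests (its matching length threshold is 1,000 bases).
#'
#' @param preset `"paper"` (default) or `"small"`.
#' @param seed Integer RNG seed (default 42).
#' @param ... Named overrides of preset fields (e.g. `par_identity`,
#'   `contaminant_identity`, `ct_plan`).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(preset = c("paper", "small"), seed = 42L, ...) {
  preset <- match.arg(preset)
  spec <- if (preset == "paper") fixture_spec_paper() else fixture_spec_small()
  spec$preset <- preset
  spec$seed <- as.integer(seed)
  dots <- list(...)
  for (nm in names(dots)) spec[[nm]] <- dots[[nm]]
  validate_fixture_spec(spec)
}

fixture_spec_paper <- function() {
  genes <- list(
    HSFY = list(
      exons = c(520L, 562L), intron = 800L,
      copies = tibble(
        contig = c(rep("tig1", 16), rep("tig223", 9), "tig419"),
        orientation = c(rep("direct", 15), "inverted", rep("direct", 10)),
        status = "full", exon_subset = vector("list", 26))),
    EIF1AY = list(
      exons = c(400L, 400L, 400L, 400L, 400L, 400L, 395L), intron = 450L,
      copies = tibble(
        contig = c("tig419", "tig419"),
        orientation = c("direct", "inverted"),
        status = c("full", "truncated"),
        exon_subset = list(NULL, 1:4))),
    UTY = list(
      exons = c(rep(227L, 27), 237L), intron = 300L,
      copies = tibble(
        contig = c("tig467", "tig723"),
        orientation = "direct",
        status = "truncated",
        exon_subset = list(1:16, 17:28))),
    RBMY = list(
      exons = c(958L, 958L, 958L, 957L), intron = 400L,
      copies = tibble(
        contig = c("tig713", "tig3300", "tig3301", "tig3300", "tig3301"),
        orientation = "direct",
        status = c("full", "full", "full", "fragment", "fragment"),
        exon_subset = vector("list", 5))),
    TSPY = list(
      exons = c(rep(697L, 6), 698L), intron = 400L,
      copies = tibble(
        contig = c("tig251", "tig3300", "tig3301"),
        orientation = "direct", status = "full",
        exon_subset = vector("list", 3))),
    SRY = list(
      exons = 723L, intron = 0L, coding = TRUE,
      copies = tibble(
        contig = "tig3262", orientation = "direct", status = "full",
        exon_subset = list(NULL))))
  list(
    x_scaffolds = c(chrX_1 = 200000L, chrX_2 = 100000L),
    autosomes = c(chr1_1 = 100000L, chr2_1 = 80000L),
    unplaced = c(scaf_u1 = 40000L),
    msy_contigs = c(tig1 = 80000L, tig223 = 45000L, tig467 = 30000L,
                    tig723 = 15000L, tig251 = 20000L, tig713 = 12000L,
                    tig3300 = 30000L, tig3301 = 30000L, tig3262 = 10000L),
    boundary = list(contig = "tig419", length = 307557L,
                    prefix_length = 177307L, prefix_source = "chrX_1",
                    prefix_identity = 0.991),
    par_contigs = tibble(
      id = c("par12", "par7", "par3", "par9"),
      source = "chrX_1",
      source_start = c(1L, 40001L, 80001L, 120001L),
      length = c(30000L, 25000L, 20000L, 15000L)),
    par_identity = 0.99,
    contaminants = tibble(
      id = c("cont1", "cont2", "cont3"),
      source = c("chr1_1", "chr2_1", "scaf_u1"),
      source_start = c(20001L, 10001L, 5001L),
      length = c(12000L, 10000L, 9000L)),
    contaminant_identity = 0.97,
    junk_lengths = c(junk1 = 3000L, junk2 = 5000L, junk3 = 7000L),
    genes = genes,
    copy_identity = 0.995,
    fragment_length = 150L,
    repeat_plan = tibble(
      class = c("LINE", "SINE", "LTR"),
      consensus_length = c(2500L, 300L, 600L),
      fraction = c(0.25, 0.01, 0.06)),
    repeat_identity = 0.95,
    microsat_fraction = 0.01,
    gametolog = list(gene = "SHROOM2", length = 1500L, identity = 0.984),
    ct_plan = tibble(
      gene = c("UTY", "RBMY", "HSFY", "TSPY", "EIF1AY", "CUL4BY"),
      true_ratio = c(1, 13, 9, 2, 1, 1),
      efficiency = 1, sd = 0.15),
    ct_seed = 7L, ct_base = 25, ct_assays = 2L, ct_replicates = 3L,
    length_threshold = 8034L)
}

fixture_spec_small <- function() {
  genes <- list(
    GENA = list(
      exons = c(300L, 300L, 300L), intron = 250L,
      copies = tibble(
        contig = c("mA", "mA", "mB"),
        orientation = c("direct", "inverted", "direct"),
        status = "full", exon_subset = vector("list", 3))))
  list(
    x_scaffolds = c(sX = 30000L),
    autosomes = c(sA = 15000L),
    unplaced = NULL,
    msy_contigs = c(mA = 8000L, mB = 5000L),
    boundary = list(contig = "mBound", length = 24000L,
                    prefix_length = 12000L, prefix_source = "sX",
                    prefix_identity = 0.99),
    par_contigs = tibble(
      id = c("p1", "p2"), source = "sX",
      source_start = c(1L, 15001L), length = c(5000L, 4000L)),
    par_identity = 0.99,
    contaminants = tibble(id = "c1", source = "sA", source_start = 2001L,
                          length = 4000L),
    contaminant_identity = 0.97,
    junk_lengths = c(j1 = 600L),
    genes = genes,
    copy_identity = 0.995,
    fragment_length = 150L,
    repeat_plan = tibble(class = c("LINE", "SINE", "LTR"),
                         consensus_length = c(800L, 200L, 300L),
                         fraction = c(0.15, 0.01, 0.04)),
    repeat_identity = 0.95,
    microsat_fraction = 0.01,
    gametolog = list(gene = "GAMA", length = 800L, identity = 0.984),
    ct_plan = tibble(gene = c("REF", "GENA"), true_ratio = c(1, 4),
                     efficiency = 1, sd = 0.15),
    ct_seed = 7L, ct_base = 25, ct_assays = 2L, ct_replicates = 3L,
    length_threshold = 1000L)
}

validate_fixture_spec <- function(spec) {
  stopifnot(is.numeric(spec$seed))
  for (ident in c(spec$par_identity, spec$contaminant_identity,
                  spec$copy_identity, spec$boundary$prefix_identity,
                  spec$repeat_identity)) {
    if (ident < 0.9 || ident > 1) {
      abort("requested identity outside [0.9, 1]")
    }
  }
  fr <- c(spec$repeat_plan$fraction, spec$microsat_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must be in [0, 1]")
  if (any(spec$ct_plan$sd < 0)) abort("Ct noise sd must be >= 0")
  hosts <- c(spec$msy_contigs,
             stats::setNames(spec$boundary$length - spec$boundary$prefix_length,
                             spec$boundary$contig))
  for (g in names(spec$genes)) {
    gp <- spec$genes[[g]]
    for (i in seq_len(nrow(gp$copies))) {
      cp <- gp$copies[i, ]
      exs <- if (is.null(cp$exon_subset[[1]])) seq_along(gp$exons) else
        cp$exon_subset[[1]]
      need <- if (cp$status == "fragment") spec$fragment_length else
        sum(gp$exons[exs]) + gp$intron * max(0, length(exs) - 1L)
      if (!cp$contig %in% names(hosts)) {
        abort(paste0("gene copy planted on unknown contig: ", cp$contig))
      }
      if (need > hosts[[cp$contig]]) {
        abort(paste0("gene ", g, " does not fit in contig ", cp$contig))
      }
    }
  }
  structure(spec, class = "fixture_spec")
}

# build the genomic cassette for one gene copy; returns the char vector and
# exon coordinates (0-based half-open, cassette-local, transcript order)
gene_cassette <- function(gene_ref, exon_subset, orientation, identity,
                          intron_len) {
  exs <- if (is.null(exon_subset)) seq_along(gene_ref$exon_seqs) else
    exon_subset
  chars <- character(0)
  coords <- tibble(exon = integer(), start = integer(), end = integer())
  for (i in seq_along(exs)) {
    e <- exs[i]
    if (i > 1 && intron_len > 0) chars <- c(chars, rand_dna_chars(intron_len))
    st <- length(chars)
    echars <- mutate_chars(strsplit(gene_ref$exon_seqs[e], "")[[1]], identity)
    chars <- c(chars, echars)
    coords <- bind_rows(coords, tibble(exon = e, start = st,
                                       end = length(chars)))
  }
  if (orientation == "inverted") {
    L <- length(chars)
    chars <- revcomp_chars(chars)
    coords <- mutate(coords, start2 = L - .data$end, end = L - .data$start,
                     start = .data$start2) %>% select(-"start2")
  }
  list(chars = chars, coords = coords)
}

#' Generate a complete synthetic study
#'
#' Builds the female reference (X scaffolds, autosomes, unplaced), the
#' flow-sorted Y contig set (PAR contigs as mutated substrings of X
#' scaffolds, MSY contigs with planted multicopy gene architecture and
#' interspersed/simple repeats, autosomal contaminants, sub-threshold junk
#' and a boundary-spanning contig), the representative transcripts, the
#' repeat consensus library, primer pairs with known specificity, a
#' simulated qPCR Ct table, and a ground-truth manifest recording every
#' planted feature. Identical spec and seed give byte-identical outputs.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, all components are written
#'   there as FASTA/TSV via the package writers.
#' @return A `yt_fixture` list: `female_reference`, `y_contigs`,
#'   `transcripts`, `repeat_library`, `primers`, `ct_table`, `truth`,
#'   `gametolog_pair`, `spec`. Manifest coordinates are 1-based inclusive.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  fx <- local_seed(spec$seed, build_fixture(spec))
  fx$ct_table <- simulate_ct(spec$ct_plan, seed = spec$ct_seed,
                             base_ct = spec$ct_base,
                             n_assays = spec$ct_assays,
                             n_replicates = spec$ct_replicates)
  fx$spec <- spec
  class(fx) <- "yt_fixture"
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

build_fixture <- function(spec) {
  truth <- list()
  note <- function(...) truth[[length(truth) + 1L]] <<- tibble(...)

  # ---- female reference -------------------------------------------------
  ref_seqs <- list()
  for (nm in names(spec$x_scaffolds)) {
    ref_seqs[[nm]] <- rand_dna(spec$x_scaffolds[[nm]])
  }
  for (nm in names(spec$autosomes)) {
    ref_seqs[[nm]] <- rand_dna(spec$autosomes[[nm]])
  }
  for (nm in names(spec$unplaced)) {
    ref_seqs[[nm]] <- rand_dna(spec$unplaced[[nm]])
  }
  ref_class <- c(stats::setNames(rep("X", length(spec$x_scaffolds)),
                                 names(spec$x_scaffolds)),
                 stats::setNames(rep("AUTOSOME", length(spec$autosomes)),
                                 names(spec$autosomes)),
                 stats::setNames(rep("UNPLACED", length(spec$unplaced)),
                                 names(spec$unplaced)))
  female <- tibble(id = names(ref_seqs),
                   sequence = unname(unlist(ref_seqs)),
                   scaffold_class = unname(ref_class[names(ref_seqs)]))
  female$length <- nchar(female$sequence)

  # ---- gene references and transcripts ----------------------------------
  gene_refs <- list()
  for (g in names(spec$genes)) {
    gp <- spec$genes[[g]]
    exon_seqs <- character(length(gp$exons))
    if (isTRUE(gp$coding)) {
      # single coding exon: ATG + sense codons (no internal ATG/stop) + TAA
      n_codons <- gp$exons[1] / 3L - 2L
      sense <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T")), 1, paste,
                     collapse = "")
      sense <- setdiff(sense, c("TAA", "TAG", "TGA", "ATG"))
      exon_seqs[1] <- paste0("ATG",
                             paste(sample(sense, n_codons, replace = TRUE),
                                   collapse = ""), "TAA")
    } else {
      for (i in seq_along(gp$exons)) exon_seqs[i] <- rand_dna(gp$exons[i])
    }
    gene_refs[[g]] <- list(exon_seqs = exon_seqs,
                           transcript = paste(exon_seqs, collapse = ""))
  }
  transcripts <- tibble(
    gene = names(gene_refs),
    id = paste0(names(gene_refs), "_transcript"),
    sequence = vapply(gene_refs, function(x) x$transcript, character(1)))

  # ---- MSY contigs with planted genes -----------------------------------
  contig_chars <- lapply(spec$msy_contigs, rand_dna_chars)
  occupied <- lapply(spec$msy_contigs, function(x) {
    tibble(start = integer(), end = integer())
  })
  # boundary contig: mutated X prefix + random suffix
  bd <- spec$boundary
  pref_src <- substr(ref_seqs[[bd$prefix_source]], 1L, bd$prefix_length)
  pref_chars <- mutate_chars(strsplit(pref_src, "")[[1]], bd$prefix_identity)
  contig_chars[[bd$contig]] <- c(pref_chars,
                                 rand_dna_chars(bd$length - bd$prefix_length))
  # genes (and repeats) go only in the male-specific suffix
  occupied[[bd$contig]] <- tibble(start = 0L, end = bd$prefix_length)
  note(feature = "BOUNDARY_CONTIG", contig_id = bd$contig, gene = NA, copy = NA,
       exon = NA, start = 1L, end = bd$length, orientation = NA,
       status = NA, identity = bd$prefix_identity,
       source_id = bd$prefix_source, source_start = 1L,
       source_end = bd$prefix_length)

  cursors <- lapply(contig_chars, function(x) 0L)
  place_block <- function(contig, chars_block) {
    # sequential placement after the current cursor with a small random gap
    cur <- cursors[[contig]]
    gap <- sample(300:800, 1)
    st <- cur + gap
    en <- st + length(chars_block)
    if (en > length(contig_chars[[contig]])) {
      abort(paste0("planted features overflow contig ", contig))
    }
    contig_chars[[contig]][(st + 1):en] <<- chars_block
    cursors[[contig]] <<- en
    occupied[[contig]] <<- bind_rows(occupied[[contig]],
                                     tibble(start = st, end = en))
    c(st, en)
  }
  cursors[[bd$contig]] <- bd$prefix_length + 2000L

  for (g in names(spec$genes)) {
    gp <- spec$genes[[g]]
    copies <- gp$copies
    for (i in seq_len(nrow(copies))) {
      cp <- copies[i, ]
      if (cp$status == "fragment") {
        tr <- gene_refs[[g]]$transcript
        fst <- sample.int(nchar(tr) - spec$fragment_length, 1)
        frag <- mutate_chars(
          strsplit(substr(tr, fst, fst + spec$fragment_length - 1L), "")[[1]],
          spec$copy_identity)
        at <- place_block(cp$contig, frag)
        note(feature = "GENE_FRAGMENT", contig_id = cp$contig, gene = g,
             copy = i, exon = NA, start = at[1] + 1L, end = at[2],
             orientation = cp$orientation, status = "fragment",
             identity = spec$copy_identity, source_id = paste0(g, "_transcript"),
             source_start = fst, source_end = fst + spec$fragment_length - 1L)
        next
      }
      cass <- gene_cassette(gene_refs[[g]], cp$exon_subset[[1]],
                            cp$orientation, spec$copy_identity, gp$intron)
      at <- place_block(cp$contig, cass$chars)
      note(feature = "GENE_COPY", contig_id = cp$contig, gene = g, copy = i,
           exon = NA, start = at[1] + 1L, end = at[2],
           orientation = cp$orientation, status = cp$status,
           identity = spec$copy_identity, source_id = NA,
           source_start = NA, source_end = NA)
      for (r in seq_len(nrow(cass$coords))) {
        note(feature = "GENE_EXON", contig_id = cp$contig, gene = g, copy = i,
             exon = cass$coords$exon[r], start = at[1] + cass$coords$start[r] + 1L,
             end = at[1] + cass$coords$end[r], orientation = cp$orientation,
             status = cp$status, identity = spec$copy_identity,
             source_id = NA, source_start = NA, source_end = NA)
      }
    }
  }

  # ---- repeats and microsatellites --------------------------------------
  repeat_library <- tibble(
    id = paste0(spec$repeat_plan$class, "_cons"),
    class = spec$repeat_plan$class,
    sequence = vapply(spec$repeat_plan$consensus_length, rand_dna,
                      character(1)))
  micro_units <- c("A", "AC", "AG", "AAT", "AGC", "ACGT")
  for (contig in names(contig_chars)) {
    len <- length(contig_chars[[contig]])
    usable_start <- if (contig == bd$contig) bd$prefix_length else 0L
    usable <- len - usable_start
    free_cursor <- max(cursors[[contig]], usable_start) + 500L
    put <- function(chars_block) {
      st <- free_cursor
      en <- st + length(chars_block)
      if (en + 200L > len) return(NULL)
      contig_chars[[contig]][(st + 1):en] <<- chars_block
      free_cursor <<- en + sample(150:400, 1)
      c(st, en)
    }
    for (ri in seq_len(nrow(spec$repeat_plan))) {
      cl <- spec$repeat_plan$class[ri]
      cons <- repeat_library$sequence[repeat_library$class == cl]
      target <- round(spec$repeat_plan$fraction[ri] * usable)
      planted <- 0L
      while (planted < target) {
        clen <- nchar(cons)
        want <- min(clen, target - planted)
        if (want < 100L && planted > 0L) break
        cst <- if (want < clen) sample.int(clen - want + 1L, 1) else 1L
        piece <- mutate_chars(
          strsplit(substr(cons, cst, cst + want - 1L), "")[[1]],
          spec$repeat_identity)
        at <- put(piece)
        if (is.null(at)) break
        note(feature = "REPEAT", contig_id = contig, gene = NA, copy = NA,
             exon = NA, start = at[1] + 1L, end = at[2], orientation = "direct",
             status = cl, identity = spec$repeat_identity,
             source_id = repeat_library$id[repeat_library$class == cl],
             source_start = cst, source_end = cst + want - 1L)
        planted <- planted + want
      }
    }
    target_ms <- round(spec$microsat_fraction * usable)
    planted <- 0L
    while (planted < target_ms) {
      unit <- sample(micro_units, 1)
      ncopy <- sample(10:30, 1)
      arr <- strsplit(strrep(unit, ncopy), "")[[1]]
      at <- put(arr)
      if (is.null(at)) break
      note(feature = "MICROSAT", contig_id = contig, gene = NA, copy = NA,
           exon = NA, start = at[1] + 1L, end = at[2], orientation = "direct",
           status = unit, identity = 1, source_id = NA, source_start = NA,
           source_end = NA)
      planted <- planted + length(arr)
    }
  }

  for (nm in names(spec$msy_contigs)) {
    note(feature = "MSY_CONTIG", contig_id = nm, gene = NA, copy = NA,
         exon = NA, start = 1L, end = spec$msy_contigs[[nm]],
         orientation = NA, status = NA, identity = NA, source_id = NA,
         source_start = NA, source_end = NA)
  }

  # ---- PAR contigs, contaminants, junk ----------------------------------
  y_rows <- list()
  for (nm in names(contig_chars)) {
    y_rows[[nm]] <- paste(contig_chars[[nm]], collapse = "")
  }
  for (i in seq_len(nrow(spec$par_contigs))) {
    pc <- spec$par_contigs[i, ]
    src <- substr(ref_seqs[[pc$source]], pc$source_start,
                  pc$source_start + pc$length - 1L)
    y_rows[[pc$id]] <- mutate_seq(src, spec$par_identity)
    note(feature = "PAR_CONTIG", contig_id = pc$id, gene = NA, copy = NA,
         exon = NA, start = 1L, end = pc$length, orientation = "direct",
         status = NA, identity = spec$par_identity, source_id = pc$source,
         source_start = pc$source_start,
         source_end = pc$source_start + pc$length - 1L)
  }
  for (i in seq_len(nrow(spec$contaminants))) {
    cc <- spec$contaminants[i, ]
    src <- substr(ref_seqs[[cc$source]], cc$source_start,
                  cc$source_start + cc$length - 1L)
    y_rows[[cc$id]] <- mutate_seq(src, spec$contaminant_identity)
    note(feature = "CONTAMINANT", contig_id = cc$id, gene = NA, copy = NA,
         exon = NA, start = 1L, end = cc$length, orientation = "direct",
         status = NA, identity = spec$contaminant_identity,
         source_id = cc$source, source_start = cc$source_start,
         source_end = cc$source_start + cc$length - 1L)
  }
  for (nm in names(spec$junk_lengths)) {
    y_rows[[nm]] <- rand_dna(spec$junk_lengths[[nm]])
    note(feature = "JUNK", contig_id = nm, gene = NA, copy = NA, exon = NA,
         start = 1L, end = spec$junk_lengths[[nm]], orientation = NA,
         status = NA, identity = NA, source_id = NA, source_start = NA,
         source_end = NA)
  }
  y_contigs <- tibble(id = names(y_rows), sequence = unname(unlist(y_rows)))
  y_contigs$length <- nchar(y_contigs$sequence)

  # ---- gametolog pair (X vs Y copy of the last pseudoautosomal gene) ----
  gx <- rand_dna(spec$gametolog$length)
  gy <- mutate_seq(gx, spec$gametolog$identity)
  gametolog_pair <- tibble(gene = spec$gametolog$gene,
                           x_copy = gx, y_copy = gy,
                           identity = spec$gametolog$identity)

  # ---- primers -----------------------------------------------------------
  primers <- build_primers(spec, gene_refs, y_rows, ref_seqs,
                           bind_rows(truth))

  list(female_reference = female, y_contigs = y_contigs,
       transcripts = transcripts, repeat_library = repeat_library,
       primers = primers, truth = bind_rows(truth),
       gametolog_pair = gametolog_pair)
}

# primer pairs with known specificity classes:
#  - one pair inside the planted copy of a single-copy MSY gene
#    (male-specific: exact in the male set, absent from the female)
#  - one pair from a multicopy gene's reference exon (ladder-like
#    amplification across the planted array in the male set)
#  - one pair from a pseudoautosomal contig, sited on windows the
#    divergence simulation left untouched so it amplifies in both genomes
#  - one pair from an autosomal region outside every contaminant source
#    interval (female-only)
build_primers <- function(spec, gene_refs, y_rows, ref_seqs, truth_df) {
  take <- function(seq, at, len = 22L) substr(seq, at, at + len - 1L)
  mk <- function(name, template, f_at, prod_len, class) {
    fwd <- take(template, f_at)
    rev_site <- take(template, f_at + prod_len - 22L)
    tibble(name = name, forward = fwd, reverse = revcomp(rev_site),
           expected_size = prod_len, specificity = class)
  }
  pairs <- list()
  single_gene <- names(spec$genes)[vapply(spec$genes, function(g) {
    nrow(g$copies) == 1 && g$copies$status[1] == "full"
  }, logical(1))][1]
  if (!is.na(single_gene)) {
    row <- truth_df[truth_df$feature == "GENE_COPY" &
                      truth_df$gene == single_gene, ][1, ]
    prod <- min(400L, row$end - row$start - 60L)
    pairs$msy <- mk(paste0(single_gene, "_msy"),
                    y_rows[[row$contig_id]], row$start + 30L, prod,
                    "MALE_SPECIFIC")
  }
  multi_gene <- names(spec$genes)[vapply(spec$genes, function(g) {
    sum(g$copies$status == "full") > 3
  }, logical(1))][1]
  if (!is.na(multi_gene)) {
    ex <- gene_refs[[multi_gene]]$exon_seqs[1]
    pairs$multi <- mk(paste0(multi_gene, "_multi"), ex, 20L,
                      min(350L, nchar(ex) - 50L), "AMBIGUOUS")
  }
  # pseudoautosomal pair: both primer windows must be mutation-free so the
  # pair anneals perfectly in the male PAR contig and the female X source
  pc <- spec$par_contigs[1, ]
  par_seq <- y_rows[[pc$id]]
  src_seq <- substr(ref_seqs[[pc$source]], pc$source_start,
                    pc$source_start + pc$length - 1L)
  prod <- 400L
  found <- FALSE
  for (at in seq(500L, nchar(par_seq) - prod - 30L, by = 7L)) {
    rat <- at + prod - 22L
    if (identical(take(par_seq, at), take(src_seq, at)) &&
        identical(take(par_seq, rat), take(src_seq, rat))) {
      pairs$par <- mk("par_marker", par_seq, at, prod, "BOTH")
      found <- TRUE
      break
    }
  }
  if (!found) pairs$par <- mk("par_marker", src_seq, 501L, prod, "BOTH")
  # autosomal primer beyond every contaminant source interval
  auto_id <- names(spec$autosomes)[1]
  cont_auto <- spec$contaminants[spec$contaminants$source == auto_id, ]
  safe_at <- if (nrow(cont_auto)) {
    max(cont_auto$source_start + cont_auto$length) + 2000L
  } else 1000L
  pairs$auto <- mk("auto_marker", ref_seqs[[auto_id]], safe_at, 400L, "NONE")
  bind_rows(pairs)
}

#' Simulate a qPCR Ct table
#'
#' For a gene with true copy ratio `r` and efficiency `e`, each replicate Ct
#' is drawn as `Normal(base_ct - log(r) / log(1 + e), sd)`; the default
#' efficiency 1 gives the textbook `base_ct - log2(r)`. The design is
#' `n_assays` independent assays of `n_replicates` replicate reactions per
#' gene (duplicate assays of triplicates by default).
#'
#' @param ct_plan Tibble with `gene`, `true_ratio`, `efficiency`, `sd`; the
#'   single-copy reference gene must have ratio 1.
#' @param seed RNG seed for the Ct noise.
#' @param base_ct Baseline cycle threshold of a single-copy target
#'   (default 25).
#' @param n_assays,n_replicates Assay design (defaults 2 and 3).
#' @return Ct tibble (`gene`, `assay`, `replicate`, `ct`).
#' @export
simulate_ct <- function(ct_plan, seed = 7L, base_ct = 25, n_assays = 2L,
                        n_replicates = 3L) {
  stopifnot(all(c("gene", "true_ratio") %in% names(ct_plan)))
  if (!"efficiency" %in% names(ct_plan)) ct_plan$efficiency <- 1
  if (!"sd" %in% names(ct_plan)) ct_plan$sd <- 0
  if (any(ct_plan$sd < 0)) abort("Ct noise sd must be >= 0")
  if (!any(ct_plan$true_ratio == 1)) {
    abort("ct_plan must contain a single-copy (ratio 1) reference gene")
  }
  local_seed(seed, {
    purrr::map_dfr(seq_len(nrow(ct_plan)), function(i) {
      g <- ct_plan[i, ]
      mu <- base_ct - log(g$true_ratio) / log(1 + g$efficiency)
      purrr::map_dfr(seq_len(n_assays), function(a) {
        tibble(gene = g$gene, assay = a, replicate = seq_len(n_replicates),
               ct = stats::rnorm(n_replicates, mu, g$sd))
      })
    })
  })
}

#' Write a generated fixture to disk
#'
#' @param fixture A `yt_fixture` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(fixture$female_reference, p("female_reference.fa"))
  readr::write_tsv(fixture$female_reference[, c("id", "scaffold_class")],
                   p("scaffold_classes.tsv"), progress = FALSE)
  write_fasta(fixture$y_contigs, p("y_contigs.fa"))
  write_fasta(tibble(id = fixture$transcripts$id,
                     sequence = fixture$transcripts$sequence),
              p("transcripts.fa"))
  write_fasta(tibble(id = paste0(fixture$repeat_library$id, " ",
                                 fixture$repeat_library$class),
                     sequence = fixture$repeat_library$sequence),
              p("repeat_library.fa"))
  readr::write_tsv(fixture$primers, p("primers.tsv"), progress = FALSE)
  readr::write_tsv(fixture$ct_table, p("ct_table.tsv"), progress = FALSE)
  readr::write_tsv(fixture$truth, p("truth_manifest.tsv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.yt_fixture <- function(x, ...) {
  cat("<yt_fixture>", x$spec$preset, "preset, seed", x$spec$seed, "\n")
  cat("  female reference:", nrow(x$female_reference), "scaffolds,",
      format(sum(x$female_reference$length), big.mark = ","), "bases\n")
  cat("  Y contigs:", nrow(x$y_contigs), "contigs,",
      format(sum(x$y_contigs$length), big.mark = ","), "bases\n")
  cat("  planted features:", nrow(x$truth), "\n")
  invisible(x)
}
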