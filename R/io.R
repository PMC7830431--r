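#' Read a FASTA file into a contig table
#'
#' Reads DNA sequences and returns one row per record, in file order. Sequences
#' are uppercased on input and validated to the alphabet `{A, C, G, T, N}`:
#' `U` (RNA) and IUPAC ambiguity codes other than `N` are rejected, as are
#' duplicate record ids and empty files. The record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-{A,C,G,T,N} characters in record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(id = unname(ids), sequence = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write a contig table to FASTA
#'
#' @param contigs Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(contigs)))
  set <- Biostrings::DNAStringSet(contigs$sequence)
  names(set) <- contigs$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a scaffold-class table for a female reference
#'
#' The female reference used for triage is partitioned into X scaffolds,
#' autosomes and unplaced scaffolds. The class table is a two-column TSV
#' (`id`, `scaffold_class`) with classes in `{X, AUTOSOME, UNPLACED}`.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `id`, `scaffold_class`.
#' @export
read_scaffold_classes <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot(all(c("id", "scaffold_class") %in% names(tab)))
  bad <- setdiff(unique(tab$scaffold_class), c("X", "AUTOSOME", "UNPLACED"))
  if (length(bad)) abort(paste0("unknown scaffold class: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(tab$id)) abort("duplicate scaffold ids in class table")
  tibble(id = tab$id, scaffold_class = tab$scaffold_class)
}

#' Read a primer-pair table
#'
#' TSV with columns `name`, `forward`, `reverse` and optional `expected_size`.
#' Primer sequences must be non-degenerate DNA of length 15--35.
#'
#' @param path Path to the TSV.
#' @return Tibble of primer pairs.
#' @export
read_primers <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("name", "forward", "reverse") %in% names(tab)))
  tab <- mutate(tab, forward = toupper(.data$forward),
                reverse = toupper(.data$reverse))
  for (col in c("forward", "reverse")) {
    sq <- tab[[col]]
    if (any(grepl("[^ACGT]", sq))) abort("degenerate or non-DNA primer sequence")
    if (any(nchar(sq) < 15 | nchar(sq) > 35)) abort("primer length outside 15-35")
  }
  if (!"expected_size" %in% names(tab)) tab$expected_size <- NA_integer_
  as_tibble(tab)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `gene`, `assay`, `replicate`, `ct` (cycle-threshold values,
#' in cycles). All Ct values must be positive and every `(gene, assay)` cell
#' must hold at least one replicate. When `reference` is given its presence in
#' every assay is checked.
#'
#' @param path Path to the TSV.
#' @param reference Optional single-copy reference gene name to validate.
#' @return Tibble with columns `gene`, `assay`, `replicate`, `ct`.
#' @export
read_ct_table <- function(path, reference = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", assay = "i", replicate = "i", ct = "d"), progress = FALSE)
  validate_ct_table(tab, reference)
  as_tibble(tab)
}

validate_ct_table <- function(tab, reference = NULL) {
  stopifnot(all(c("gene", "assay", "replicate", "ct") %in% names(tab)))
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0)) abort("Ct values must be positive")
  if (!is.null(reference)) {
    assays <- unique(tab$assay)
    ref_assays <- unique(tab$assay[tab$gene == reference])
    if (!setequal(assays, ref_assays)) {
      abort(paste0("reference gene '", reference, "' missing from some assays"))
    }
  }
  invisible(tab)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `exon` rows with 1-based inclusive coordinates.
#' The strand column is `+` for direct copies and `-` for inverted copies;
#' exon numbering follows transcript order, so for inverted copies exon
#' numbers descend along the contig. Rows are ordered by (contig, start,
#' gene) for deterministic output.
#'
#' @param models Gene-model table as returned by [detect_copies()]: one row
#'   per exon with columns `gene`, `contig_id`, `copy`, `exon`, `start`,
#'   `end` (0-based half-open), `orientation`, `status`.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for bounds
#'   checking.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path, contig_lengths = NULL) {
  needed <- c("gene", "contig_id", "copy", "exon", "start", "end",
              "orientation", "status")
  stopifnot(all(needed %in% names(models)))
  if (nrow(models)) {
    chk <- models %>%
      group_by(.data$gene, .data$contig_id, .data$copy) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      summarise(overlap = any(.data$start[-1] < .data$end[-n()]),
                .groups = "drop")
    if (any(chk$overlap)) abort("overlapping exons within one gene copy")
    if (!is.null(contig_lengths)) {
      lens <- contig_lengths[models$contig_id]
      if (any(is.na(lens)) || any(models$end > lens) || any(models$start < 0)) {
        abort("exon interval outside contig bounds")
      }
    }
  }
  lines <- "##gff-version 3"
  if (nrow(models)) {
    copies <- models %>%
      group_by(.data$contig_id, .data$gene, .data$copy) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                strand = ifelse(.data$orientation[1] == "inverted", "-", "+"),
                status = .data$status[1], n_exons = n(), .groups = "drop") %>%
      arrange(.data$contig_id, .data$start, .data$gene)
    for (i in seq_len(nrow(copies))) {
      cp <- copies[i, ]
      gid <- sprintf("%s.%s.copy%d", cp$contig_id, cp$gene, cp$copy)
      lines <- c(lines,
        sprintf("%s\tytriage\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;status=%s",
                cp$contig_id, cp$start + 1L, cp$end, cp$strand, gid, cp$gene,
                cp$status),
        sprintf("%s\tytriage\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                cp$contig_id, cp$start + 1L, cp$end, cp$strand, gid, gid))
      ex <- models %>%
        filter(.data$contig_id == cp$contig_id, .data$gene == cp$gene,
               .data$copy == cp$copy) %>%
        arrange(if (cp$strand == "+") .data$start else desc(.data$start))
      lines <- c(lines, sprintf(
        "%s\tytriage\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s.t1",
        cp$contig_id, ex$start + 1L, ex$end, cp$strand, gid, ex$exon, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models back from GFF3
#'
#' Inverse of [write_gene_models_gff3()]; returns the per-exon table with
#' internal 0-based half-open coordinates.
#'
#' @param path GFF3 path.
#' @return Tibble with one row per exon.
#' @export
read_gene_models_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(gene = character(), contig_id = character(), copy = integer(),
                  exon = integer(), start = integer(), end = integer(),
                  orientation = character(), status = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  mat <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    sub(paste0(key, "="), "", m)
  }
  is_exon <- mat[, 3] == "exon"
  is_gene <- mat[, 3] == "gene"
  status_by_gene <- stats::setNames(attr_field(mat[is_gene, 9], "status"),
                                    attr_field(mat[is_gene, 9], "ID"))
  ex <- mat[is_exon, , drop = FALSE]
  ids <- attr_field(ex[, 9], "ID")                # contig.gene.copyN.exonM
  parent <- sub("\\.t1$", "", attr_field(ex[, 9], "Parent"))
  copy <- as.integer(sub("^.*copy(\\d+)$", "\\1", parent))
  gene <- sub("^[^.]+\\.", "", sub("\\.copy\\d+$", "", parent))
  tibble(
    gene = gene, contig_id = ex[, 1], copy = copy,
    exon = as.integer(sub("^.*exon(\\d+)$", "\\1", ids)),
    start = as.integer(ex[, 4]) - 1L, end = as.integer(ex[, 5]),
    orientation = ifelse(ex[, 7] == "-", "inverted", "direct"),
    status = unname(status_by_gene[parent])
  ) %>% arrange(.data$contig_id, .data$gene, .data$copy, .data$exon)
}

#' Write triage labels as BED
#'
#' One row per contig, name column = triage label, 0-based half-open
#' coordinates. A pseudoautosomal-boundary call splits the boundary-spanning
#' contig into two rows (PAR segment then MSY segment) that partition it.
#'
#' @param labels Tibble with `contig_id`, `length`, `label` (one label per
#'   contig).
#' @param path Output path.
#' @param pab Optional PAB call tibble (`contig_id`, `boundary`) used to split
#'   the boundary contig.
#' @return `path`, invisibly.
#' @export
write_triage_bed <- function(labels, path, pab = NULL) {
  stopifnot(all(c("contig_id", "length", "label") %in% names(labels)))
  if (any(is.na(labels$label))) abort("unlabeled contig in triage BED input")
  if (anyDuplicated(labels$contig_id)) abort("multiple labels for one contig")
  if (!nrow(labels)) {
    warn("writing empty triage BED: no labeled contigs")
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- list()
  for (i in seq_len(nrow(labels))) {
    lb <- labels[i, ]
    b <- if (!is.null(pab) && lb$contig_id %in% pab$contig_id) {
      pab$boundary[match(lb$contig_id, pab$contig_id)]
    } else NA_integer_
    if (!is.na(b) && b > 0 && b < lb$length) {
      rows[[length(rows) + 1L]] <-
        sprintf("%s\t%d\t%d\t%s", lb$contig_id, 0L, b, "PAR_SEGMENT")
      rows[[length(rows) + 1L]] <-
        sprintf("%s\t%d\t%d\t%s", lb$contig_id, b, lb$length, "MSY_SEGMENT")
    } else {
      rows[[length(rows) + 1L]] <-
        sprintf("%s\t%d\t%d\t%s", lb$contig_id, 0L, lb$length, lb$label)
    }
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path.
#' @return Tibble with `contig_id`, `start`, `end`, `name` (0-based half-open).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), name = character()))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  tibble(contig_id = f[, 1], start = as.integer(f[, 2]),
         end = as.integer(f[, 3]),
         name = if (ncol(f) >= 4) f[, 4] else NA_character_)
}

#' Write a generic report tibble as TSV
#'
#' Fixed header row, tab-separated; percentage columns are expected to be
#' pre-rounded by the caller (reports use one decimal).
#'
#' @param tab Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Plain-text key-value configuration (YAML) controlling paths, thresholds and
#' the RNG seed for [run_all()].
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
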