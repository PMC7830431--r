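#' Run the full triage-and-annotation pipeline
#'
#' Orchestrates fixture/input loading, contig triage, sequence-feature
#' statistics, gene-copy detection, pseudoautosomal-boundary detection,
#' qPCR copy-number estimation and (optionally) tree building into one
#' reproducible run directory. All randomness flows from the single config
#' seed. A stage failure aborts the run naming the stage; a missing Ct
#' table only skips the qPCR stage with a warning.
#'
#' @param config Named list (see [read_config()]); recognised fields:
#'   `out_dir` (required), `seed` (default 42), `fixture_preset` (generate
#'   inputs with [generate_fixture()]; otherwise `y_contigs`,
#'   `female_reference`, `scaffold_classes`, `transcripts`,
#'   `repeat_library`, `primers`, `ct_table` paths), `triage` (list of
#'   [triage_params()] arguments), `pab` (list with `window`, `step`),
#'   `qpcr_reference` (default `"UTY"`), `aligned_fasta` and `outgroup`
#'   for the tree stage.
#' @return A `yt_run` list with each stage's result and the run directory.
#' @export
run_all <- function(config) {
  if (is.null(config$out_dir)) abort("config must name an out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
  log <- list()
  stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    log[[length(log) + 1L]] <<- list(stage = name, time = as.character(Sys.time()))
    res
  }

  inputs <- stage("inputs", {
    if (!is.null(config$fixture_preset)) {
      fx <- generate_fixture(fixture_spec(config$fixture_preset, seed = seed),
                             dir = file.path(config$out_dir, "inputs"))
      list(y_contigs = fx$y_contigs,
           reference = fx$female_reference,
           transcripts = fx$transcripts,
           repeat_library = fx$repeat_library,
           primers = fx$primers,
           ct_table = fx$ct_table,
           length_threshold = fx$spec$length_threshold)
    } else {
      ref <- read_fasta(config$female_reference)
      cls <- read_scaffold_classes(config$scaffold_classes)
      ref <- left_join(ref, cls, by = "id")
      if (any(is.na(ref$scaffold_class))) {
        abort("reference scaffold without class annotation")
      }
      tr <- if (!is.null(config$transcripts)) {
        fa <- read_fasta(config$transcripts)
        tibble(gene = sub("_transcript$", "", fa$id), id = fa$id,
               sequence = fa$sequence)
      }
      rl <- if (!is.null(config$repeat_library)) {
        fa <- Biostrings::readBStringSet(config$repeat_library)
        tibble(id = sub("\\s.*$", "", names(fa)),
               class = sub("^\\S+\\s+", "", names(fa)),
               sequence = toupper(as.character(fa)))
      }
      list(y_contigs = read_fasta(config$y_contigs), reference = ref,
           transcripts = tr, repeat_library = rl,
           primers = if (!is.null(config$primers)) read_primers(config$primers),
           ct_table = if (!is.null(config$ct_table))
             read_ct_table(config$ct_table),
           length_threshold = NULL)
    }
  })

  tri_args <- config$triage %||% list()
  if (!is.null(inputs$length_threshold) &&
      is.null(tri_args$length_threshold)) {
    tri_args$length_threshold <- inputs$length_threshold
  }
  params <- do.call(triage_params, tri_args)

  triage <- stage("triage", {
    tr <- triage_assembly(inputs$y_contigs, inputs$reference, params)
    write_report_tsv(tr$labels, file.path(config$out_dir, "triage_labels.tsv"))
    write_report_tsv(tr$summary, file.path(config$out_dir, "triage_summary.tsv"))
    tr
  })

  analysis_ids <- triage$labels$contig_id[
    triage$labels$label %in% c("PUTATIVE_MSY", "PAR_CANDIDATE")]
  msy_ids <- triage$labels$contig_id[triage$labels$label == "PUTATIVE_MSY"]
  analysis_contigs <- filter(inputs$y_contigs, .data$id %in% analysis_ids)

  stats <- stage("stats", {
    target <- filter(inputs$y_contigs, .data$id %in% msy_ids)
    ft <- if (nrow(target)) {
      contig_features(target, inputs$repeat_library)
    } else tibble()
    if (nrow(ft)) {
      disp <- mutate(ft, dplyr::across(dplyr::where(is.double), ~round(.x, 1)))
      write_report_tsv(disp, file.path(config$out_dir, "msy_features.tsv"))
    }
    ft
  })

  genes <- stage("genes", {
    if (is.null(inputs$transcripts) || !nrow(analysis_contigs)) {
      list(models = tibble(), summary = tibble(), splits = tibble())
    } else {
      idx <- build_index(analysis_contigs)
      models <- purrr::map_dfr(seq_len(nrow(inputs$transcripts)), function(i) {
        tr <- inputs$transcripts[i, ]
        m <- detect_copies(tr$gene, tr$sequence, idx)
        sp <- detect_split_genes(m)
        sp$models
      })
      summary <- copy_summary(models)
      splits <- models %>% filter(!is.na(.data$split_id))
      write_gene_models_gff3(
        gene_model_exons(filter(models, .data$status != "FRAGMENT")),
        file.path(config$out_dir, "gene_models.gff3"),
        stats::setNames(analysis_contigs$length, analysis_contigs$id))
      write_report_tsv(summary, file.path(config$out_dir, "copy_summary.tsv"))
      list(models = models, summary = summary, splits = splits)
    }
  })

  pab <- stage("pab", {
    x_ref <- filter(inputs$reference, .data$scaffold_class == "X")
    window <- config$pab$window %||% 10000L
    step <- config$pab$step %||% 2000L
    if (!nrow(x_ref)) tibble() else {
      x_idx <- build_index(x_ref)
      cand <- filter(triage$labels,
                     .data$label %in% c("PAR_CANDIDATE", "PUTATIVE_MSY"),
                     .data$length >= 3L * window)
      calls <- purrr::map_dfr(cand$contig_id, function(cid) {
        ct <- filter(inputs$y_contigs, .data$id == cid)
        prof <- homology_profile(ct, x_idx, window = window, step = step)
        detect_boundary(prof, ct, x_idx)
      })
      if (nrow(calls)) {
        write_report_tsv(calls, file.path(config$out_dir, "pab_calls.tsv"))
        lab <- filter(triage$labels, .data$contig_id %in% calls$contig_id)
        write_triage_bed(lab, file.path(config$out_dir, "pab_segments.bed"),
                         pab = calls)
      }
      calls
    }
  })

  qpcr <- stage("qpcr", {
    refgene <- config$qpcr_reference %||% "UTY"
    if (is.null(inputs$ct_table)) {
      warn("no Ct table in config; skipping qPCR stage")
      NULL
    } else {
      fit <- estimate_copy_numbers(inputs$ct_table, refgene)
      write_report_tsv(tidy(fit), file.path(config$out_dir,
                                            "copy_number_qpcr.tsv"))
      fit
    }
  })

  tree <- stage("tree", {
    if (is.null(config$aligned_fasta)) NULL else {
      aln <- read_fasta(config$aligned_fasta)
      d <- p_distance(aln)
      tr <- neighbor_joining(d)
      tr <- if (!is.null(config$outgroup)) root_tree(tr, config$outgroup)
            else root_tree(tr)
      write_newick(tr, file.path(config$out_dir, "tree.nwk"))
      tr
    }
  })

  # summary accounting: the per-class totals partition the assembly, and
  # the combined Y total is exactly MSY + PAR
  msy_bases <- triage$summary$bases[triage$summary$label == "PUTATIVE_MSY"]
  par_bases <- triage$summary$bases[triage$summary$label == "PAR_CANDIDATE"]
  summary_tab <- tibble(
    key = c("seed", "contigs_in", "bases_in",
            "msy_contigs", "msy_bases", "par_contigs", "par_bases",
            "combined_y_bases", "n_pab_calls",
            if (!is.null(qpcr)) "qpcr_max_fold"),
    value = c(seed, nrow(inputs$y_contigs),
              sum(as.numeric(inputs$y_contigs$length)),
              triage$summary$n_contigs[triage$summary$label == "PUTATIVE_MSY"],
              msy_bases,
              triage$summary$n_contigs[triage$summary$label == "PAR_CANDIDATE"],
              par_bases, msy_bases + par_bases, nrow(pab),
              if (!is.null(qpcr)) max(tidy(qpcr)$fold_change)))
  write_report_tsv(summary_tab, file.path(config$out_dir, "run_summary.tsv"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE)

  structure(list(dir = config$out_dir, seed = seed, inputs = inputs,
                 triage = triage, stats = stats, genes = genes, pab = pab,
                 qpcr = qpcr, tree = tree, summary = summary_tab),
            class = "yt_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.yt_run <- function(x, ...) {
  cat("<yt_run>", x$dir, "\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
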