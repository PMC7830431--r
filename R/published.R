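#' Published alpaca MSY summary tables
#'
#' Worked-example inputs shipped with the package: the published per-contig
#' sequence-feature table of the 18 PCR-validated alpaca MSY contigs
#' (`alpaca_msy_features()`: size, GC and repeat-class percentages) and the
#' published whole-assembly summary of the flow-sorted alpaca Y material
#' (`alpaca_assembly_summary()`: total bases, contig count, N50/L50, size
#' range, MSY/PAR partition and the estimated full PAR size). These drive
#' the package's reporting-convention checks, e.g. that the size-weighted
#' summary row of [feature_report()] reproduces the published totals.
#'
#' @return A tibble.
#' @export
alpaca_msy_features <- function() {
  readr::read_tsv(system.file("extdata", "alpaca_msy_features.tsv",
                              package = "ytriage"),
                  col_types = readr::cols(contig_id = "c", .default = "d"),
                  progress = FALSE)
}

#' @rdname alpaca_msy_features
#' @export
alpaca_assembly_summary <- function() {
  tab <- readr::read_tsv(system.file("extdata", "alpaca_assembly_summary.tsv",
                                     package = "ytriage"),
                         col_types = readr::cols(metric = "c", value = "d"),
                         progress = FALSE)
  stats::setNames(tab$value, tab$metric)
}
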