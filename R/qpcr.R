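#' Relative copy number by the 2^-ddCt method
#'
#' Single-animal design: there is no calibrator sample, so the double delta
#' collapses to a single delta against the single-copy reference gene. Per
#' assay, `dCt = mean Ct(target) - mean Ct(reference)` and the assay fold
#' change is `(1 + efficiency)^(-dCt)` (factor 2 per cycle at the default
#' efficiency of 1). The reported fold change is the geometric mean across
#' assays (fold changes are multiplicative); the dispersion is the pooled
#' standard deviation of per-replicate fold values within assays.
#'
#' @param ct_table Ct tibble (`gene`, `assay`, `replicate`, `ct`).
#' @param target_gene Gene to quantify.
#' @param reference_gene Single-copy reference gene (its own estimate is
#'   exactly 1).
#' @param efficiency Amplification efficiency; 1 means perfect doubling.
#' @return One-row tibble: `gene`, `fold_change`, `sd`, `n_assays`,
#'   `n_replicates`.
#' @export
ddct_fold_change <- function(ct_table, target_gene, reference_gene,
                             efficiency = 1) {
  validate_ct_table(ct_table)
  tgt <- filter(ct_table, .data$gene == target_gene)
  if (!nrow(tgt)) abort(paste0("target gene not in Ct table: ", target_gene))
  assays <- sort(unique(tgt$assay))
  ref <- filter(ct_table, .data$gene == reference_gene)
  missing_ref <- setdiff(assays, unique(ref$assay))
  if (length(missing_ref)) {
    abort(paste0("reference gene '", reference_gene,
                 "' missing from assay(s) ", paste(missing_ref, collapse = ", ")))
  }
  base <- 1 + efficiency
  per_assay <- purrr::map_dfr(assays, function(a) {
    ct_t <- tgt$ct[tgt$assay == a]
    ct_r <- ref$ct[ref$assay == a]
    dct <- mean(ct_t) - mean(ct_r)
    rep_folds <- base^(-(ct_t - mean(ct_r)))
    tibble(assay = a, fold = base^(-dct), n_rep = length(ct_t),
           var_rep = if (length(ct_t) > 1) stats::var(rep_folds) else NA_real_)
  })
  n_rep_total <- sum(per_assay$n_rep)
  pooled_sd <- if (all(is.na(per_assay$var_rep))) NA_real_ else {
    dfree <- per_assay$n_rep - 1L
    ok <- !is.na(per_assay$var_rep)
    sqrt(sum(dfree[ok] * per_assay$var_rep[ok]) / sum(dfree[ok]))
  }
  tibble(gene = target_gene,
         fold_change = exp(mean(log(per_assay$fold))),
         sd = pooled_sd,
         n_assays = length(assays),
         n_replicates = n_rep_total)
}

#' Copy-number estimates for every gene in a Ct table
#'
#' Runs [ddct_fold_change()] for each gene against the reference and wraps
#' the results in a `ddct_fit` object with [tidy()] / [glance()] methods and
#' an [ggplot2::autoplot()] bar chart.
#'
#' @inheritParams ddct_fold_change
#' @return A `ddct_fit` object.
#' @export
estimate_copy_numbers <- function(ct_table, reference_gene, efficiency = 1) {
  validate_ct_table(ct_table, reference_gene)
  genes <- unique(ct_table$gene)
  est <- purrr::map_dfr(genes, ddct_fold_change, ct_table = ct_table,
                        reference_gene = reference_gene,
                        efficiency = efficiency)
  structure(list(estimates = est, reference = reference_gene,
                 efficiency = efficiency, ct_table = ct_table),
            class = "ddct_fit")
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat("<ddct_fit> reference:", x$reference, "\n")
  print(x$estimates)
  invisible(x)
}

#' @rdname estimate_copy_numbers
#' @param x A `ddct_fit` object.
#' @param ... Unused.
#' @method tidy ddct_fit
#' @export
tidy.ddct_fit <- function(x, ...) x$estimates

#' @rdname estimate_copy_numbers
#' @method glance ddct_fit
#' @export
glance.ddct_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$estimates), reference = x$reference,
         efficiency = x$efficiency,
         n_assays = max(x$estimates$n_assays),
         max_fold = max(x$estimates$fold_change))
}
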