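#' Determine the active (expressed) genes from DAFS cutoffs
#'
#' Under the default `"mean"` rule a gene is active when all its TPM values
#' are strictly positive and the mean of its log2 TPM values is at least the
#' arithmetic mean of the per-sample cutoffs. The stricter `"per-sample"`
#' rule instead requires the gene's log2 TPM to reach the sample's own
#' cutoff in every sample (still with all-positive TPM).
#'
#' @param tpm genes x samples TPM matrix.
#' @param dafs a `dafs_result` from [dafs_cutoffs()] covering every sample
#'   of `tpm`.
#' @param rule `"mean"` (default) or `"per-sample"`.
#' @return character vector of active gene IDs (input row order), with the
#'   aggregated cutoff in attribute `"cutoff"` and the rule in `"rule"`.
#' @export
active_genes <- function(tpm, dafs, rule = c("mean", "per-sample")) {
  rule <- match.arg(rule)
  m <- as.matrix(tpm)
  cuts <- stats::setNames(dafs$cutoffs$cutoff, dafs$cutoffs$sample_id)
  missing <- setdiff(colnames(m), names(cuts))
  if (length(missing))
    stop("no DAFS cutoff for sample(s): ", paste(missing, collapse = ", "))
  cuts <- cuts[colnames(m)]
  pos <- rowSums(m > 0) == ncol(m)
  logm <- log2(pmax(m, .Machine$double.xmin))
  if (rule == "mean") {
    act <- pos & rowMeans(logm) >= mean(cuts)
  } else {
    act <- pos & rowSums(logm >= rep(cuts, each = nrow(m))) == ncol(m)
  }
  structure(rownames(m)[act], cutoff = mean(cuts), rule = rule)
}

#' Select the lowest-CV active genes as custom references
#'
#' Keeps the `max(min_genes, round(fraction * n_active))` active genes with
#' the smallest TPM coefficient of variation (rounding half-up; CV ties
#' broken by lexicographic gene ID).
#'
#' @param tpm genes x samples TPM matrix.
#' @param active character vector of active gene IDs (see [active_genes()]).
#' @param fraction fraction of active genes to keep, in (0, 1]; default
#'   0.005 (0.5 percent).
#' @param min_genes lower bound on the selected-set size; default 1.
#' @return object of class `reference_set`: data.frame with columns
#'   `gene_id`, `mean_tpm`, `cv_percent` ordered by ascending CV, with the
#'   selection parameters in attribute `"params"`.
#' @export
select_references <- function(tpm, active, fraction = 0.005,
                              min_genes = 1L) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (length(active) == 0L) stop("no expressed genes")
  m <- as.matrix(tpm)
  missing <- setdiff(active, rownames(m))
  if (length(missing))
    stop("active gene(s) absent from TPM matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  stats <- gene_cv_stats(m[active, , drop = FALSE])
  n_sel <- max(as.integer(min_genes), round_half_up(fraction *
                                                      length(active)))
  n_sel <- min(n_sel, length(active))
  ord <- order(stats$cv_percent, stats$gene_id)
  sel <- stats[ord[seq_len(n_sel)], c("gene_id", "mean_tpm", "cv_percent")]
  rownames(sel) <- NULL
  structure(sel,
            class = c("reference_set", "data.frame"),
            params = list(fraction = fraction,
                          min_genes = as.integer(min_genes),
                          n_active = length(active),
                          active_rule = attr(active, "rule") %||% "mean",
                          cutoff = attr(active, "cutoff") %||% NA_real_))
}

#' End-to-end custom reference-gene selection
#'
#' Composes [counts_to_tpm()], [dafs_cutoffs()], [active_genes()] and
#' [select_references()]; the result is identical to running the stages
#' manually.
#'
#' @inheritParams counts_to_tpm
#' @inheritParams select_references
#' @inheritParams active_genes
#' @inheritParams first_knot
#' @return a `reference_set` (see [select_references()]).
#' @export
custom_references <- function(counts, lengths, fraction = 0.005,
                              min_genes = 1L, rule = c("mean", "per-sample"),
                              knot_rule = c("min-positive", "min-interior")) {
  rule <- match.arg(rule)
  knot_rule <- match.arg(knot_rule)
  tpm <- counts_to_tpm(counts, lengths)
  dafs <- dafs_cutoffs(tpm, knot_rule)
  act <- active_genes(tpm, dafs, rule)
  select_references(tpm, act, fraction, min_genes)
}

# round() halves away from the even-digit convention: round-half-up.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reference_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "reference_set: %d genes (fraction %.4g of %d active, rule '%s')\n",
    nrow(x), p$fraction, p$n_active, p$active_rule))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
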