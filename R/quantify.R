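#' Convert read counts to transcripts per million (TPM)
#'
#' For gene g and sample j with count c_gj and gene length L_g (bp),
#' TPM_gj = 1e6 * (c_gj / L_g) / sum_i (c_ij / L_i), so every sample column
#' sums to one million. Length is the plain annotated (exonic-union) length;
#' an optional mean-fragment-length correction replaces it with the
#' effective length max(L_g - frag_len + 1, 1).
#'
#' @param counts a [count_matrix()] or a genes x samples numeric matrix with
#'   dimnames.
#' @param lengths named numeric vector of gene lengths in bp covering every
#'   gene of `counts`.
#' @param frag_len optional mean fragment length (bp) for the effective
#'   length correction; `NULL` (default) uses the annotated length.
#' @return numeric genes x samples matrix of TPM values, same dimnames and
#'   ordering as `counts`.
#' @export
counts_to_tpm <- function(counts, lengths, frag_len = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    stop("no length for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  L <- lengths[rownames(m)]
  if (any(L <= 0)) stop("gene lengths must be positive")
  if (!is.null(frag_len)) L <- pmax(L - frag_len + 1, 1)
  zero <- colSums(m) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[zero], collapse = ", "))
  rate <- m / L
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Per-gene expression summary: mean TPM, SD and coefficient of variation
#'
#' @param tpm genes x samples TPM matrix.
#' @param sample_subset optional character or integer vector of samples to
#'   summarize over (at least 2).
#' @return data.frame with columns `gene_id`, `mean_tpm`, `sd_tpm`
#'   (sample SD, n-1 denominator), `cv_percent` (100 * sd / mean, `NA` with
#'   `undefined = TRUE` when the mean is 0).
#' @export
gene_cv_stats <- function(tpm, sample_subset = NULL) {
  m <- as.matrix(tpm)
  if (!is.null(sample_subset)) m <- m[, sample_subset, drop = FALSE]
  if (ncol(m) < 2L) stop("need at least 2 samples to compute CV")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu > 0, 100 * sd / mu, NA_real_)
  data.frame(gene_id = rownames(m), mean_tpm = mu, sd_tpm = sd,
             cv_percent = cv, undefined = mu == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
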