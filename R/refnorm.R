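#' Median-of-ratios size factors restricted to a control-gene set
#'
#' For every usable reference gene g (all counts strictly positive) the
#' per-gene pseudo-reference is the geometric mean of its counts over
#' samples, G_g; the raw size factor of sample j is the median over usable
#' references of c_gj / G_g. Raw factors are rescaled to unit geometric
#' mean so factor sets are comparable across reference-gene choices. This
#' is the scaling a count-based DE tool consumes when told to normalize on
#' control genes only.
#'
#' @param counts a [count_matrix()] or genes x samples numeric matrix.
#' @param refs a `gene_list`, `reference_set` or character vector of
#'   reference gene IDs present in `counts`.
#' @return object of class `size_factor_set`: list with `size_factors`
#'   (named, unit geometric mean), `reference_set` (name) and
#'   `n_usable_refs`.
#' @export
size_factors_with_controls <- function(counts, refs) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (inherits(refs, "reference_set")) {
    ids <- refs$gene_id
    name <- attr(refs, "name") %||% "custom"
  } else if (inherits(refs, "gene_list")) {
    ids <- refs$gene_ids
    name <- refs$name
  } else {
    ids <- as.character(refs)
    name <- "refs"
  }
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("reference gene(s) absent from counts: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sub <- m[ids, , drop = FALSE]
  usable <- rowSums(sub > 0) == ncol(sub)
  if (!any(usable))
    stop("no usable reference gene (all contain zero counts)")
  sub <- sub[usable, , drop = FALSE]
  G <- exp(rowMeans(log(sub)))
  raw <- apply(sub / G, 2L, stats::median)
  if (any(raw <= 0))
    stop("zero size factor for sample(s): ",
         paste(colnames(m)[raw <= 0], collapse = ", "))
  s <- raw / exp(mean(log(raw)))
  structure(list(size_factors = s, reference_set = name,
                 n_usable_refs = sum(usable)),
            class = "size_factor_set")
}

#' @export
print.size_factor_set <- function(x, ...) {
  cat(sprintf("size_factor_set: %d samples, %d usable references ('%s')\n",
              length(x$size_factors), x$n_usable_refs, x$reference_set))
  print(round(x$size_factors, 4L))
  invisible(x)
}
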