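#' Construct a validated count matrix
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' optional sample group labels. Most users will obtain one from
#' [read_counts()] or [simulate_counts()] rather than calling this directly.
#'
#' @param counts numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene IDs) and colnames (sample IDs). All values must be
#'   non-negative integers (integer-valued doubles are accepted).
#' @param groups optional named character vector mapping every sample ID to a
#'   group label.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `groups` (named character vector or `NULL`).
#' @export
count_matrix <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (nrow(counts) == 0L) stop("no genes in count matrix")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene IDs: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    unknown <- setdiff(names(groups), colnames(counts))
    if (length(unknown))
      stop("group map references unknown samples: ",
           paste(unknown, collapse = ", "))
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples without a group label: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(counts)]
  }
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s=%s", names(x$groups), x$groups),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix from a tab-separated file
#'
#' The file must have a header row of sample IDs and gene IDs in the first
#' column; a leading `gene_id` header cell for that column is optional.
#'
#' @param path path to the tab-separated counts file.
#' @param group_map optional path to a two-column tab-separated file
#'   (sample ID, group label), no header required (a `sample`/`group` header
#'   row is detected and skipped).
#' @return a [count_matrix()] preserving the file's row and column order.
#' @export
read_counts <- function(path, group_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L) stop("no genes in counts file '", path, "'")
  if (ncol(df) < 2L) stop("counts file needs at least one sample column")
  gene_ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  rownames(m) <- gene_ids
  groups <- if (!is.null(group_map)) read_group_map(group_map) else NULL
  count_matrix(m, groups)
}

#' Read a sample-to-group map
#'
#' @param path two-column tab-separated file: sample ID, group label. A
#'   header row starting with `sample` is skipped.
#' @return named character vector of group labels, names are sample IDs.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("group map must have two columns")
  if (tolower(df[1L, 1L]) %in% c("sample", "sample_id"))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty group map")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read gene lengths from a TSV table or a GTF annotation
#'
#' For GTF input the length of a gene is the number of bases covered by the
#' union of all its exon intervals (overlapping exons merged, coordinates
#' 1-based inclusive, strand ignored). GTF parsing uses rtracklayer and
#' GenomicRanges when available.
#'
#' @param path input file path.
#' @param format `"tsv"` (two columns: gene ID, length in bp, no header
#'   required) or `"gtf"`.
#' @return named numeric vector of gene lengths in base pairs.
#' @export
read_gene_lengths <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = FALSE, quote = "",
                            colClasses = "character")
    if (tolower(df[1L, 1L]) %in% c("gene_id", "gene"))
      df <- df[-1L, , drop = FALSE]
    if (ncol(df) < 2L) stop("length table must have two columns")
    len <- suppressWarnings(as.numeric(df[[2L]]))
    if (anyNA(len)) stop("non-numeric length for gene '",
                         df[[1L]][which(is.na(len))[1L]], "'")
    if (any(len <= 0))
      stop("non-positive length for gene '",
           df[[1L]][which(len <= 0)[1L]], "'")
    return(stats::setNames(len, df[[1L]]))
  }
  gtf_exon_union_lengths(path)
}

# Exonic-union gene lengths from a GTF via rtracklayer/GenomicRanges.
gtf_exon_union_lengths <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("GTF input requires the rtracklayer and GenomicRanges packages")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF '", path, "'")
  byg <- GenomicRanges::split(gr, gr$gene_id)
  red <- GenomicRanges::reduce(byg, ignore.strand = TRUE)
  vapply(red, function(g) sum(GenomicRanges::width(g)), numeric(1))
}

#' Read a gene list (one gene ID per line)
#'
#' @param path text file, one gene ID per line; blank lines and lines
#'   starting with `#` are ignored.
#' @param name label for the list; defaults to the file name without
#'   extension.
#' @return an object of class `gene_list` with elements `name` and
#'   `gene_ids`.
#' @export
read_gene_list <- function(path, name = NULL) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stop("empty gene list '", path, "'")
  if (anyDuplicated(ids))
    stop("duplicate gene IDs in list '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_list(name, ids)
}

#' @rdname read_gene_list
#' @param gene_ids character vector of unique gene IDs.
#' @export
gene_list <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("gene list must be non-empty")
  if (anyDuplicated(gene_ids)) stop("gene list IDs must be unique")
  structure(list(name = as.character(name), gene_ids = gene_ids),
            class = "gene_list")
}

#' The 14 commonly used Arabidopsis reference genes
#'
#' Classic housekeeping genes (actins, tubulins, polyubiquitins, EF1-alpha,
#' eIF4A, APT1, NDUFA8) frequently used as qPCR/RNA-seq normalization
#' controls in Arabidopsis, shipped as a packaged gene list for comparison
#' against custom-selected reference sets.
#'
#' @return a `gene_list` of 14 TAIR gene IDs named `"common"`.
#' @export
common_reference_genes <- function() {
  path <- system.file("extdata", "common_reference_genes.txt",
                      package = "refpick", mustWork = TRUE)
  read_gene_list(path, name = "common")
}

#' Write a counts or TPM matrix as TSV
#'
#' Mirrors the input counts layout: header row of sample IDs, first column
#' `gene_id`.
#'
#' @param x a `count_matrix` or a numeric genes x samples matrix.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a report object to TSV or JSON
#'
#' Supported reports: `reference_set` (per-gene table plus selection
#' parameters), `stability_report` (per-gene table mirroring the
#' gene/rank/TPM/CV/intergroup/intragroup/stability column layout) and
#' `size_factor_set`. TSV and JSON round-trip with [read_report()];
#' floating-point values are written with 6 significant digits.
#'
#' @param report the report object.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  UseMethod("write_report")
}

#' @export
write_report.reference_set <- function(report, path,
                                       format = c("tsv", "json")) {
  format <- match.arg(format)
  genes <- data.frame(gene_id = report$gene_id,
                      mean_tpm = signif6(report$mean_tpm),
                      cv_percent = signif6(report$cv_percent),
                      stringsAsFactors = FALSE)
  params <- attr(report, "params")
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (p in names(params))
      writeLines(sprintf("# %s\t%s", p, format(params[[p]], digits = 15)),
                 con)
    utils::write.table(genes, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(params = params, genes = genes), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' @export
write_report.stability_report <- function(report, path,
                                          format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- report$genes
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif6)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(set = report$set, genes = tab,
           pairwise_variation = signif6(report$pairwise_variation),
           summary = lapply(report$summary, signif6)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' @export
write_report.size_factor_set <- function(report, path,
                                         format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- data.frame(sample_id = names(report$size_factors),
                    size_factor = signif6(report$size_factors),
                    stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(reference_set = report$reference_set,
           n_usable_refs = report$n_usable_refs, samples = tab),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' Read back a report written by [write_report()]
#'
#' @param path file path.
#' @param type `"reference_set"`, `"stability_report"` or
#'   `"size_factor_set"`.
#' @param format `"tsv"` or `"json"`.
#' @return the reconstructed report object (numeric content at the written
#'   6-significant-digit precision).
#' @export
read_report <- function(path, type = c("reference_set", "stability_report",
                                       "size_factor_set"),
                        format = c("tsv", "json")) {
  type <- match.arg(type)
  format <- match.arg(format)
  if (type == "reference_set") {
    if (format == "tsv") {
      lines <- readLines(path)
      hdr <- lines[startsWith(lines, "# ")]
      params <- list()
      for (h in hdr) {
        kv <- strsplit(sub("^# ", "", h), "\t")[[1L]]
        v <- suppressWarnings(as.numeric(kv[2L]))
        params[[kv[1L]]] <- if (is.na(v)) kv[2L] else v
      }
      tab <- utils::read.delim(text = lines[!startsWith(lines, "# ")],
                               stringsAsFactors = FALSE)
    } else {
      obj <- jsonlite::read_json(path, simplifyVector = TRUE)
      params <- obj$params
      tab <- obj$genes
    }
    out <- tab
    class(out) <- c("reference_set", "data.frame")
    attr(out, "params") <- params
    return(out)
  }
  if (type == "size_factor_set") {
    if (format == "tsv") {
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      return(structure(list(size_factors = stats::setNames(tab$size_factor,
                                                           tab$sample_id),
                            reference_set = NA_character_,
                            n_usable_refs = NA_integer_),
                       class = "size_factor_set"))
    }
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(structure(list(size_factors = stats::setNames(
      obj$samples$size_factor, obj$samples$sample_id),
      reference_set = obj$reference_set,
      n_usable_refs = obj$n_usable_refs), class = "size_factor_set"))
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(structure(list(set = NA_character_, genes = tab,
                          pairwise_variation = numeric(0), summary = list()),
                     class = "stability_report"))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(set = obj$set, genes = obj$genes,
                 pairwise_variation = obj$pairwise_variation,
                 summary = obj$summary), class = "stability_report")
}

signif6 <- function(x) signif(x, 6L)
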