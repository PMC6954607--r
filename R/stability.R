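#' geNorm expression-stability measure M
#'
#' For candidate genes i and k, V_ik is the standard deviation over samples
#' (n-1 denominator) of the pairwise log-ratio logexpr_i - logexpr_k; the
#' stability measure M_i is the mean of V_ik over all k != i. Lower M means
#' more stable expression.
#'
#' @param logexpr genes x samples matrix of log2 expression (log2 TPM); all
#'   entries must be finite.
#' @param candidates character vector of >= 3 gene IDs (default: all rows).
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(logexpr, candidates = rownames(logexpr)) {
  m <- check_logexpr(logexpr, candidates)
  n <- nrow(m)
  # SD of row differences from the row covariance: Var(x_i - x_k) =
  # C_ii + C_kk - 2 C_ik, with C the n-1-denominator covariance over samples.
  C <- stats::cov(t(m))
  v <- outer(diag(C), diag(C), "+") - 2 * C
  V <- sqrt(pmax(v, 0))
  stats::setNames(rowSums(V) / (n - 1L), rownames(m))
}

#' geNorm stepwise ranking and pairwise-variation series
#'
#' Iteratively recomputes M on the surviving candidate set and removes the
#' gene with the largest M (ties broken by removing the lexicographically
#' first gene ID) until two genes remain; those two share the top of the
#' ranking. The pairwise variation V_{n,n+1} is the SD over samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the per-sample geometric mean of
#' the linear expression of the n best-ranked genes.
#'
#' @inheritParams genorm_m
#' @param linexpr optional genes x samples matrix of linear expression (TPM)
#'   used for the normalization-factor geometric means; defaults to
#'   `2^logexpr`.
#' @return list with `ranking` (data.frame `gene_id`, `rank`, `M` at
#'   removal; the final two genes get ranks 1 and 2 in ID order but are
#'   tied), `M_final` (M on the full candidate set) and
#'   `pairwise_variation` (named vector V_{n,n+1} for n = 2..n_genes-1).
#' @export
genorm_rank <- function(logexpr, candidates = rownames(logexpr),
                        linexpr = NULL) {
  m <- check_logexpr(logexpr, candidates)
  if (is.null(linexpr)) linexpr <- 2^m else
    linexpr <- as.matrix(linexpr)[rownames(m), colnames(m), drop = FALSE]
  n <- nrow(m)
  order_removed <- character(0)
  M_at_removal <- numeric(0)
  surviving <- rownames(m)
  while (length(surviving) > 2L) {
    M <- genorm_m(m[surviving, , drop = FALSE])
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[1L]
    order_removed <- c(order_removed, worst)
    M_at_removal <- c(M_at_removal, M[[worst]])
    surviving <- setdiff(surviving, worst)
  }
  final_pair <- sort(surviving)
  M_pair <- genorm_m_pairless(m, final_pair)
  ranking <- data.frame(
    gene_id = c(final_pair, rev(order_removed)),
    rank = seq_len(n),
    M = c(M_pair, M_pair, rev(M_at_removal))[seq_len(n)],
    stringsAsFactors = FALSE)
  best_first <- ranking$gene_id
  V <- vapply(2:(n - 1L), function(k) {
    nf_n <- geom_mean_cols(linexpr[best_first[1:k], , drop = FALSE])
    nf_n1 <- geom_mean_cols(linexpr[best_first[1:(k + 1L)], , drop = FALSE])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  names(V) <- sprintf("V%d/%d", 2:(n - 1L), 3:n)
  list(ranking = ranking, M_final = genorm_m(m),
       pairwise_variation = V)
}

# M of the two final genes: the SD of their mutual log-ratio.
genorm_m_pairless <- function(m, pair) {
  stats::sd(m[pair[1L], ] - m[pair[2L], ])
}

geom_mean_cols <- function(m) exp(colMeans(log(m)))

#' NormFinder-style model-based stability values
#'
#' Decomposes log2 expression within each sample group into gene, sample and
#' residual effects. The per-group residual variance of gene i (raw v_ig,
#' n_g - 1 denominator) is shrunk by the group's average across genes,
#' sigma2_ig = max(0, v_ig - mean_i'(v_i'g) / (I - 1)); the intergroup
#' difference d_ig = (xbar_i.g - xbar_i..) - (xbar_..g - xbar_...) is shrunk
#' by an empirical-Bayes factor gamma_i = tau2 / (tau2 + mean_g(sigma2_ig /
#' n_g)) with tau2 = max(0, var_g(d_ig) - mean_g(sigma2_ig / n_g)). The
#' stability value is rho_i = mean_g(|d_ig * gamma_i| + sqrt(sigma2_ig /
#' n_g)); lower is more stable, and values below 0.5 are conventionally
#' deemed suitable for a reference gene. With a single group rho_i =
#' sqrt(sigma2_i1).
#'
#' @inheritParams genorm_m
#' @param groups named character vector mapping every sample of `logexpr`
#'   to a group label; every group needs >= 2 samples.
#' @return data.frame with one row per candidate gene: `gene_id`,
#'   `intergroup_diff` (mean |shrunk d_ig| over groups, log2 units; 0 with
#'   one group), `intragroup_sd` (mean over groups of sqrt(sigma2_ig), log2
#'   units) and `stability` (rho).
#' @export
normfinder_stability <- function(logexpr, candidates = rownames(logexpr),
                                 groups) {
  m <- check_logexpr(logexpr, candidates)
  I <- nrow(m)
  if (I < 3L) stop("need at least 3 candidate genes")
  if (is.null(names(groups))) stop("groups must be a named vector")
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing))
    stop("samples without group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(m)]
  glev <- unique(groups)
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(ng)[ng < 2L], collapse = ", "))
  G <- length(glev)

  sigma2 <- matrix(NA_real_, I, G, dimnames = list(rownames(m), glev))
  group_gene_mean <- sigma2
  for (g in glev) {
    xg <- m[, groups == g, drop = FALSE]
    gene_mean <- rowMeans(xg)
    sample_mean <- colMeans(xg)
    grand <- mean(xg)
    r <- xg - outer(gene_mean, rep(1, ncol(xg))) -
      outer(rep(1, I), sample_mean) + grand
    v <- rowSums(r^2) / (ncol(xg) - 1L)
    sigma2[, g] <- pmax(0, v - mean(v) / (I - 1L))
    group_gene_mean[, g] <- gene_mean
  }

  if (G == 1L) {
    rho <- sqrt(sigma2[, 1L])
    return(data.frame(gene_id = rownames(m), intergroup_diff = 0,
                      intragroup_sd = sqrt(sigma2[, 1L]), stability = rho,
                      row.names = NULL, stringsAsFactors = FALSE))
  }

  gene_mean_all <- rowMeans(m)
  group_mean <- vapply(glev, function(g) mean(m[, groups == g, drop = FALSE]),
                       numeric(1))
  grand_all <- mean(m)
  d <- sweep(sweep(group_gene_mean, 1L, gene_mean_all, "-"),
             2L, group_mean - grand_all, "-")

  per_group_var <- sweep(sigma2, 2L, as.numeric(ng), "/")
  mean_pg <- rowMeans(per_group_var)
  tau2 <- pmax(0, apply(d, 1L, stats::var) - mean_pg)
  gamma <- ifelse(tau2 + mean_pg > 0, tau2 / (tau2 + mean_pg), 0)
  d_shrunk <- d * gamma
  rho <- rowMeans(abs(d_shrunk) + sqrt(per_group_var))
  data.frame(gene_id = rownames(m),
             intergroup_diff = rowMeans(abs(d_shrunk)),
             intragroup_sd = rowMeans(sqrt(sigma2)),
             stability = rho, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare reference-gene sets by CV, geNorm and NormFinder
#'
#' Produces one stability report per gene set. Genes with a zero TPM value
#' in any sample are reported in the CV block but excluded from the
#' log-based geNorm and NormFinder metrics (with a warning); sets with
#' fewer than 3 usable genes are skipped with a warning.
#'
#' @param tpm genes x samples TPM matrix.
#' @param groups named character vector mapping samples to groups.
#' @param sets list of `gene_list` objects and/or `reference_set` objects
#'   (a `reference_set` is compared under its own name, default
#'   `"custom"`).
#' @param stability_threshold suitability threshold annotated in the
#'   summaries; default 0.5, the conventional NormFinder cutoff.
#' @return named list of `stability_report` objects, one per usable set:
#'   each has `genes` (gene_id, genorm_rank, genorm_m, mean_tpm,
#'   cv_percent, intergroup_diff, intragroup_sd, stability),
#'   `pairwise_variation` and a `summary` list (CV min/median/max, count
#'   and fraction of genes under the stability threshold).
#' @export
compare_reference_sets <- function(tpm, groups, sets,
                                   stability_threshold = 0.5) {
  m <- as.matrix(tpm)
  if (inherits(sets, "gene_list") || inherits(sets, "reference_set"))
    sets <- list(sets)
  out <- list()
  for (s in sets) {
    if (inherits(s, "reference_set")) {
      name <- attr(s, "name") %||% "custom"
      ids <- s$gene_id
    } else {
      name <- s$name
      ids <- s$gene_ids
    }
    present <- intersect(ids, rownames(m))
    absent <- setdiff(ids, present)
    if (length(absent))
      warning("set '", name, "': gene(s) absent from TPM matrix: ",
              paste(utils::head(absent, 5L), collapse = ", "))
    if (!length(present)) next
    sub <- m[present, , drop = FALSE]
    cvtab <- gene_cv_stats(sub)
    usable <- present[rowSums(sub > 0) == ncol(sub)]
    if (length(usable) < length(present))
      warning("set '", name, "': ", length(present) - length(usable),
              " gene(s) with zero TPM excluded from geNorm/NormFinder")
    if (length(usable) < 3L) {
      warning("set '", name, "' has fewer than 3 usable genes; skipped")
      next
    }
    logm <- log2(sub[usable, , drop = FALSE])
    gn <- genorm_rank(logm, linexpr = sub[usable, , drop = FALSE])
    nf <- normfinder_stability(logm, groups = groups)
    tab <- merge(cvtab[, c("gene_id", "mean_tpm", "cv_percent")],
                 gn$ranking, by = "gene_id", all.x = TRUE)
    tab$genorm_m <- gn$M_final[tab$gene_id]
    tab <- merge(tab, nf, by = "gene_id", all.x = TRUE)
    tab <- tab[order(ifelse(is.na(tab$rank), Inf, tab$rank), tab$gene_id),
               c("gene_id", "rank", "genorm_m", "mean_tpm", "cv_percent",
                 "intergroup_diff", "intragroup_sd", "stability")]
    names(tab)[2L] <- "genorm_rank"
    rownames(tab) <- NULL
    rho <- tab$stability[!is.na(tab$stability)]
    out[[name]] <- structure(list(
      set = name,
      genes = tab,
      pairwise_variation = gn$pairwise_variation,
      summary = list(
        n_genes = length(present),
        n_usable = length(usable),
        cv_min = min(cvtab$cv_percent, na.rm = TRUE),
        cv_median = stats::median(cvtab$cv_percent, na.rm = TRUE),
        cv_max = max(cvtab$cv_percent, na.rm = TRUE),
        median_stability = stats::median(rho),
        n_under_threshold = sum(rho < stability_threshold),
        frac_under_threshold = mean(rho < stability_threshold))),
      class = "stability_report")
  }
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report for set '%s' (%d genes, %d usable)\n",
              x$set, x$summary$n_genes, x$summary$n_usable))
  print(utils::head(x$genes, 10L), row.names = FALSE)
  if (nrow(x$genes) > 10L) cat("...\n")
  cat(sprintf("median stability %.4f; %d/%d genes under threshold\n",
              x$summary$median_stability, x$summary$n_under_threshold,
              x$summary$n_usable))
  invisible(x)
}

check_logexpr <- function(logexpr, candidates) {
  m <- as.matrix(logexpr)
  if (!is.null(candidates)) {
    missing <- setdiff(candidates, rownames(m))
    if (length(missing))
      stop("candidate gene(s) absent: ", paste(missing, collapse = ", "))
    m <- m[candidates, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("need at least 3 candidate genes")
  if (ncol(m) < 2L) stop("need at least 2 samples")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite log expression at gene '%s', sample '%s'",
                 rownames(m)[bad[1L, 1L]],
                 colnames(m)[bad[1L, 2L]] %||% as.character(bad[1L, 2L])))
  m
}
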