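#' Simulate an RNA-seq count matrix with known truth
#'
#' Generates a genes x samples matrix of negative-binomial counts that
#' emulates a two-genotype experiment with a fixed number of replicates per
#' genotype: a bimodal log2 base-expression distribution (a weakly
#' expressed "noise" mode and an expressed mode), a planted subset of truly
#' stable genes drawn from the upper half of the expressed mode with near
#' zero dispersion, a planted subset of differentially expressed genes, and
#' per-sample library size factors. Counts for gene g in sample j are drawn
#' as NB with mean mu_gj = s_j * theta_g * 2^(lambda_g * [j in group 2+]) *
#' L_g * kappa and variance mu + alpha_g * mu^2, where kappa scales the
#' expected sequencing depth to roughly 20 million fragments per sample.
#'
#' @param n_genes total number of genes (default 12000).
#' @param n_reps replicates per group (default 4).
#' @param n_groups number of groups/genotypes (default 2).
#' @param frac_noise fraction of genes in the weakly expressed mode
#'   (default 0.3).
#' @param n_stable number of planted stable genes (default 100).
#' @param frac_de fraction of genes differentially expressed between group
#'   1 and the other groups (default 0.1).
#' @param seed integer seed; a fixed seed gives bit-reproducible output.
#' @param depth expected fragments per sample at size factor 1 (default
#'   2e7).
#' @return list with `counts` (a [count_matrix()] with group labels
#'   `g1`, `g2`, ...), `lengths` (named vector, bp) and `truth` (list:
#'   per-gene data.frame `genes` with `theta` (TPM-scale base expression),
#'   `length`, `dispersion`, `log2fc`, `label` in {stable, noise, de,
#'   background}; per-sample data.frame `samples` with `size_factor` and
#'   `group`).
#' @export
simulate_counts <- function(n_genes = 12000L, n_reps = 4L, n_groups = 2L,
                            frac_noise = 0.3, n_stable = 100L,
                            frac_de = 0.1, seed = 1L, depth = 2e7) {
  stopifnot(n_genes > 0, n_reps > 0, n_groups > 0,
            frac_noise >= 0, frac_noise < 1, n_stable >= 0, frac_de >= 0)
  n_noise <- round(frac_noise * n_genes)
  n_de <- round(frac_de * n_genes)
  n_expressed <- n_genes - n_noise
  if (n_stable + n_de > n_expressed)
    stop("infeasible label counts: stable + DE genes exceed the expressed ",
         "mode")
  set.seed(seed)

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  L <- round(exp(stats::runif(n_genes, log(200), log(10000))))

  label <- rep("background", n_genes)
  noise_idx <- sample.int(n_genes, n_noise)
  label[noise_idx] <- "noise"
  expressed_idx <- setdiff(seq_len(n_genes), noise_idx)
  stable_idx <- sample(expressed_idx, n_stable)
  label[stable_idx] <- "stable"
  de_idx <- sample(setdiff(expressed_idx, stable_idx), n_de)
  label[de_idx] <- "de"

  log2theta <- numeric(n_genes)
  log2theta[noise_idx] <- stats::rnorm(n_noise, -2, 1)
  log2theta[expressed_idx] <- stats::rnorm(length(expressed_idx), 5, 2)
  # stable genes sit in the upper half of the expressed mode
  log2theta[stable_idx] <- 5 + abs(stats::rnorm(n_stable, 0, 2))
  theta <- 2^log2theta

  # biological-replicate dispersions: CV ~ 14-55 percent for most genes
  alpha <- stats::runif(n_genes, 0.02, 0.3)
  alpha[stable_idx] <- 1e-4

  lambda <- numeric(n_genes)
  lambda[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, 0.5, 3)

  n_samples <- n_reps * n_groups
  group <- rep(sprintf("g%d", seq_len(n_groups)), each = n_reps)
  sample_ids <- sprintf("%s_r%d", group, rep(seq_len(n_reps), n_groups))
  s <- exp(stats::runif(n_samples, log(0.5), log(2)))

  kappa <- depth / sum(theta * L)
  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    fc <- if (group[j] == "g1") 1 else 2^lambda
    mu <- s[j] * theta * fc * L * kappa
    counts[, j] <- rnbinom_mean_disp(n_genes, mu, alpha)
  }

  truth <- list(
    genes = data.frame(gene_id = gene_ids, theta = theta, length = L,
                       dispersion = alpha, log2fc = lambda, label = label,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids, size_factor = s,
                         group = group, stringsAsFactors = FALSE))
  list(counts = count_matrix(counts, stats::setNames(group, sample_ids)),
       lengths = stats::setNames(as.numeric(L), gene_ids),
       truth = truth)
}

# NB draw in the mean/dispersion parameterization (variance mu + alpha mu^2);
# alpha below 1e-8 degenerates to Poisson.
rnbinom_mean_disp <- function(n, mu, alpha) {
  out <- integer(n)
  pois <- alpha < 1e-8
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois))
    out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                 size = 1 / alpha[!pois])
  out
}
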