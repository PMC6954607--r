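test_that("geNorm M is zero for genes with constant log ratios", {
  base <- c(1, 4, 2, 3)
  m <- rbind(g1 = base, g2 = base + 2, g3 = base - 1.5)
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(genorm_m(m)), c(0, 0, 0))
})

test_that("geNorm M matches the hand-computed small instance", {
  m <- rbind(i = c(1, 2), k = c(2, 1), j = c(0, 0))
  colnames(m) <- c("s1", "s2")
  M <- genorm_m(m)
  # V_ik = sd(-1, 1) = sqrt(2); V_ij = sd(1, 2) = 1/sqrt(2)
  expect_equal(M[["i"]], mean(c(sqrt(2), sd(c(1, 2)))), tolerance = 1e-12)
  expect_equal(M[["i"]], 1.060660, tolerance = 1e-6)
})

test_that("geNorm M equals the double-loop oracle on random instances", {
  set.seed(3)
  for (rep in 1:3) {
    m <- matrix(rnorm(60, 8, 2), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
    expect_equal(genorm_m(m), genorm_m_oracle(m), tolerance = 1e-12)
  }
})

test_that("geNorm stepwise ranking removes a planted group-shifted gene
           first", {
  set.seed(31)
  m <- matrix(rnorm(24, 10, 0.1), nrow = 4,
              dimnames = list(c("a", "b", "c", "shifted"),
                              paste0("s", 1:6)))
  m["shifted", 4:6] <- m["shifted", 4:6] + 3
  rk <- genorm_rank(m)
  expect_equal(rk$ranking$rank[rk$ranking$gene_id == "shifted"], 4L)
  # worst gene also has the largest full-set M (oracle agreement)
  expect_equal(names(which.max(genorm_m_oracle(m))), "shifted")
})

test_that("exact scalar multiples rank by lexicographic tie-break with a
           zero V series", {
  # power-of-two multiples keep the log2 ratios exactly constant in
  # floating point, so the M ties are exact and the tie-break observable
  lin <- rbind(a = c(8, 2, 4, 6), b = 2 * c(8, 2, 4, 6),
               c = 0.5 * c(8, 2, 4, 6), d = 4 * c(8, 2, 4, 6))
  colnames(lin) <- paste0("s", 1:4)
  rk <- genorm_rank(log2(lin), linexpr = lin)
  # every M is 0; removals proceed from the lexicographically first ID,
  # so "a" then "b" are removed and "c","d" survive as the tied pair
  expect_identical(rk$ranking$gene_id, c("c", "d", "b", "a"))
  expect_equal(unname(rk$pairwise_variation), c(0, 0), tolerance = 1e-12)
})

test_that("geNorm ranking is invariant to sample-column permutation", {
  set.seed(17)
  m <- matrix(rnorm(48, 9, 1), nrow = 6,
              dimnames = list(sprintf("g%d", 1:6), paste0("s", 1:8)))
  rk1 <- genorm_rank(m)
  rk2 <- genorm_rank(m[, sample(ncol(m))])
  expect_identical(rk1$ranking$gene_id, rk2$ranking$gene_id)
  expect_equal(rk1$pairwise_variation, rk2$pairwise_variation)
})

test_that("NormFinder components vanish for perfectly stable genes", {
  m <- matrix(rep(c(3, 5, 4), each = 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  groups <- setNames(rep(c("g1", "g2"), each = 2), colnames(m))
  nf <- normfinder_stability(m, groups = groups)
  expect_equal(nf$stability, rep(0, 3))
  expect_equal(nf$intergroup_diff, rep(0, 3))
})

test_that("a gene tracking the per-sample mean has zero intra variance", {
  set.seed(12)
  m <- matrix(rnorm(16, 6, 1), nrow = 4,
              dimnames = list(c("a", "b", "c", "tracker"),
                              paste0("s", 1:4)))
  m["tracker", ] <- colMeans(m[1:3, ])
  m["tracker", ] <- colMeans(m)   # fixed point: equals the sample mean
  for (it in 1:20) m["tracker", ] <- colMeans(m)
  groups <- setNames(rep("g1", 4), colnames(m))
  nf <- normfinder_stability(m, groups = groups)
  expect_equal(nf$stability[nf$gene_id == "tracker"], 0, tolerance = 1e-10)
})

test_that("NormFinder equals the explicit-loop ANOVA oracle", {
  set.seed(9)
  m <- matrix(rnorm(30, 8, 1.5), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), paste0("s", 1:6)))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(m))
  nf <- normfinder_stability(m, groups = groups)
  ref <- normfinder_oracle(m, groups[colnames(m)])
  expect_equal(nf$stability, ref$stability, tolerance = 1e-12)
  expect_equal(nf$intergroup_diff, ref$intergroup, tolerance = 1e-12)
})

test_that("NormFinder validates its grouping preconditions", {
  m <- matrix(rnorm(12), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  groups <- setNames(c("A", "A", "A", "B"), colnames(m))
  expect_error(normfinder_stability(m, groups = groups), "fewer than 2")
  two <- m[1:2, ]
  expect_error(
    normfinder_stability(two, groups = setNames(rep("A", 4), colnames(m))),
    "3 candidate genes")
})

test_that("M and rho are invariant to per-sample normalization shifts", {
  set.seed(25)
  m <- matrix(rnorm(40, 7, 1), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), paste0("s", 1:8)))
  groups <- setNames(rep(c("A", "B"), each = 4), colnames(m))
  shift <- rnorm(8, 0, 2)
  m2 <- sweep(m, 2, shift, "+")
  expect_equal(genorm_m(m2), genorm_m(m), tolerance = 1e-12)
  expect_equal(normfinder_stability(m2, groups = groups)$stability,
               normfinder_stability(m, groups = groups)$stability,
               tolerance = 1e-10)
})

test_that("planted unstable genes get the worst stability and ranks", {
  hits_rho <- hits_rank <- logical(20)
  for (s in 1:20) {
    set.seed(100 + s)
    m <- matrix(rnorm(80, 9, 0.25), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
    groups <- setNames(rep(c("A", "B"), each = 4), colnames(m))
    m[c("g03", "g07"), groups == "B"] <-
      m[c("g03", "g07"), groups == "B"] + 1.2
    nf <- normfinder_stability(m, groups = groups)
    worst_rho <- nf$gene_id[order(-nf$stability)][1:2]
    rk <- genorm_rank(m)$ranking
    worst_rank <- rk$gene_id[order(-rk$rank)][1:2]
    hits_rho[s] <- setequal(worst_rho, c("g03", "g07"))
    hits_rank[s] <- setequal(worst_rank, c("g03", "g07"))
  }
  expect_gte(mean(hits_rho), 0.95)
  expect_gte(mean(hits_rank), 0.95)
})

test_that("set comparison excludes zero-TPM genes from log metrics only", {
  sim <- small_sim()
  tpm <- counts_to_tpm(sim$counts, sim$lengths)
  ok <- rownames(tpm)[rowSums(tpm > 0) == ncol(tpm)][1:5]
  zero <- rownames(tpm)[rowSums(tpm == 0) > 0][1]
  expect_false(is.na(zero))
  sets <- list(gene_list("mix", c(ok, zero)))
  rep <- suppressWarnings(
    compare_reference_sets(tpm, sim$counts$groups, sets))[["mix"]]
  row <- rep$genes[rep$genes$gene_id == zero, ]
  expect_false(is.na(row$cv_percent))
  expect_true(is.na(row$stability))
  expect_true(is.na(row$genorm_rank))
  expect_equal(rep$summary$n_usable, 5L)
})

test_that("identical sets give identical reports; tiny sets are skipped", {
  sim <- small_sim()
  tpm <- counts_to_tpm(sim$counts, sim$lengths)
  ok <- rownames(tpm)[rowSums(tpm > 0) == ncol(tpm)][1:6]
  reps <- compare_reference_sets(
    tpm, sim$counts$groups,
    list(gene_list("one", ok), gene_list("two", ok)))
  expect_equal(reps$one$genes, reps$two$genes)
  expect_warning(
    out <- compare_reference_sets(tpm, sim$counts$groups,
                                  list(gene_list("tiny", ok[1:2]))),
    "fewer than 3")
  expect_length(out, 0L)
})

test_that("the custom-selected set is more stable than a typical
           housekeeping-sized set", {
  sim <- default_sim()
  tpm <- counts_to_tpm(sim$counts, sim$lengths)
  refs <- custom_references(sim$counts, sim$lengths)
  tr <- sim$truth$genes
  set.seed(4242)
  typical <- sample(tr$gene_id[tr$label == "background" &
                                 tr$theta > 2^3], 14)
  reports <- compare_reference_sets(
    tpm, sim$counts$groups,
    list(gene_list("custom", refs$gene_id),
         gene_list("typical", typical)))
  expect_lt(reports$custom$summary$median_stability,
            reports$typical$summary$median_stability)
  expect_lt(reports$custom$summary$cv_median,
            reports$typical$summary$cv_median)
})
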