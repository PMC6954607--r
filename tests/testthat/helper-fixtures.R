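# Shared fixture builders: every fixture is constructed in code at test
# time; files go into per-test temp dirs.

write_counts_file <- function(counts, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_lengths_file <- function(lengths, path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(names(lengths), lengths), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  path
}

tiny_counts <- function() {
  m <- matrix(c(10, 20, 0, 5, 7, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

write_gtf_file <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(gene, start, end, chrom = "chr1", strand = "+") {
  sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.1";',
          chrom, start, end, strand, gene, gene)
}

# Bimodal log2-expression sample used by the DAFS tests: a weakly expressed
# mode and an expressed mode, returned on the linear TPM scale.
bimodal_tpm <- function(n_low = 2500, n_high = 2500, seed = 11,
                        low_mean = -2, low_sd = 0.7,
                        high_mean = 5, high_sd = 1) {
  set.seed(seed)
  2^c(rnorm(n_low, low_mean, low_sd), rnorm(n_high, high_mean, high_sd))
}

# Small cached simulation shared across tests (defaults except size).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_counts(n_genes = 4000, seed = 42)
    cache
  }
})

# Full-size default simulation at seed 42 (the study-condition dataset).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_counts(seed = 42)
    cache
  }
})
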