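# Shared fixtures, built in code at test time.

# Three-exon toy transcript on the + strand: exons 1-100, 201-300, 401-500.
toy_exons <- function(tx = "tx1", gene = "g1", strand = "+") {
  data.frame(transcript_id = tx, gene_id = gene, chrom = "chr1",
             start = c(1L, 201L, 401L), end = c(100L, 300L, 500L),
             strand = strand, stringsAsFactors = FALSE)
}

write_toy_gtf <- function(exons, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(paste0('%s\ttest\texon\t%d\t%d\t.\t%s\t.\t',
                          'gene_id "%s"; transcript_id "%s";'),
                   exons$chrom, exons$start, exons$end, exons$strand,
                   exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  path
}

write_toy_gff3 <- function(exons, path = tempfile(fileext = ".gff3")) {
  header <- "##gff-version 3"
  tx_lines <- unlist(lapply(unique(exons$transcript_id), function(tx) {
    e <- exons[exons$transcript_id == tx, ]
    sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            e$chrom[1], min(e$start), max(e$end), e$strand[1], tx,
            e$gene_id[1])
  }))
  ex_lines <- sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                      exons$chrom, exons$start, exons$end, exons$strand,
                      exons$transcript_id)
  writeLines(c(header, tx_lines, ex_lines), path)
  path
}

# Deterministic random genome as a named character vector.
toy_genome <- function(chrom = "chr1", len = 600, seed = 42) {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), chrom)
}

# The U1-70K-like alternative 3'ss scenario used across modules.
u1_scenario <- function(chx = FALSE, depth = 2000) {
  build_scenario("u1_70k", chx = chx, depth = depth)
}

u1_locus <- function() u1_scenario()$loci[[1]]

u1_genome <- function() {
  l <- u1_locus()
  setNames(l$seq, l$chrom)
}

# Independent two-sided Fisher oracle: direct hypergeometric enumeration
# with log-binomial coefficients (no shared code with the implementation).
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  lo <- max(0L, k - n)
  hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  lp <- vapply(lo:hi, logp, numeric(1))
  p_obs <- logp(a)
  sum(exp(lp[lp <= p_obs + log(1 + 1e-7)]))
}
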