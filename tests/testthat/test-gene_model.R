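test_that("GTF and GFF3 ingestion give identical gene models", {
  ex <- toy_exons()
  m_gtf <- load_annotation(write_toy_gtf(ex))
  m_gff <- load_annotation(write_toy_gff3(ex))
  expect_equal(nrow(m_gtf$exons), 3)
  expect_equal(length(unique(m_gtf$exons$transcript_id)), 1)
  expect_equal(m_gtf$exons[, c("chrom", "start", "end", "strand")],
               m_gff$exons[, c("chrom", "start", "end", "strand")])
  expect_equal(m_gtf$exons$transcript_id, m_gff$exons$transcript_id)
})

test_that("minus-strand exons are reordered 5' to 3' in transcript orientation", {
  ex <- toy_exons(strand = "-")
  ex <- ex[c(1, 3, 2), ]  # scrambled input order
  m <- load_annotation(write_toy_gtf(ex))
  # 5'->3' on the minus strand means descending genomic start
  expect_equal(m$exons$start, c(401L, 201L, 1L))
  expect_equal(m$exons$end, c(500L, 300L, 100L))
})

test_that("junction catalog equals brute-force adjacent-pair enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    exons <- do.call(rbind, lapply(1:10, function(i) {
      n_ex <- sample(2:5, 1)
      lens <- sample(30:120, n_ex, replace = TRUE)
      gaps <- sample(21:300, n_ex, replace = TRUE)
      starts <- cumsum(gaps + c(0, lens[-n_ex]))
      ends <- starts + lens
      data.frame(transcript_id = sprintf("t%d", i),
                 gene_id = "g", chrom = sample(c("chrA", "chrB"), 1),
                 start = starts, end = ends,
                 strand = sample(c("+", "-"), 1),
                 stringsAsFactors = FALSE)
    }))
    model <- gene_model(exons)
    got <- junction_catalog(model, min_intron = 1)
    # brute force over every transcript's adjacent exon pairs
    expected <- unique(do.call(rbind, lapply(
      split(model$exons, model$exons$transcript_id), function(e) {
        do.call(rbind, lapply(seq_len(nrow(e) - 1), function(i) {
          if (e$strand[1] == "+") {
            data.frame(chrom = e$chrom[1], donor = e$end[i],
                       acceptor = e$start[i + 1], strand = "+",
                       stringsAsFactors = FALSE)
          } else {
            data.frame(chrom = e$chrom[1], donor = e$start[i],
                       acceptor = e$end[i + 1], strand = "-",
                       stringsAsFactors = FALSE)
          }
        }))
      })))
    key <- function(j) sort(paste(j$chrom, j$donor, j$acceptor, j$strand))
    expect_equal(key(got), key(expected))
  }
})

test_that("shared junctions are deduplicated and micro-introns filtered", {
  ex <- rbind(toy_exons("t1"), toy_exons("t2"))
  cat1 <- junction_catalog(gene_model(ex))
  expect_equal(nrow(cat1), 2)  # each junction reported once
  # a 10-nt gap is below the default minimum intron length
  ex2 <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c",
                    start = c(1L, 111L), end = c(100L, 200L), strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(junction_catalog(gene_model(ex2))), 0)
  expect_equal(nrow(junction_catalog(gene_model(ex2), min_intron = 10)), 1)
})

test_that("interval gaps reproduce the minigene deletion arithmetic", {
  blocks <- genomic_interval("i7", c(1, 1928, 3077), c(844, 2227, 3162))
  expect_identical(interval_gaps(blocks), c(1083L, 849L))
  adjacent <- genomic_interval("c", c(1, 11), c(10, 20))
  expect_identical(interval_gaps(adjacent), 0L)
  expect_identical(interval_gaps(genomic_interval("c", 1, 10)), integer(0))
  overlapping <- genomic_interval("c", c(1, 50), c(100, 200))
  expect_error(interval_gaps(overlapping), "overlap")
})

test_that("intron offsets are 1-based from the first intronic base and invert", {
  intron <- genomic_interval("chr19", 121, 1047)
  expect_equal(genome_to_intron_offset(121, intron), 1L)
  expect_equal(genome_to_intron_offset(1047, intron), 927L)
  # alternative acceptor: last intronic base +642, first exonic base +643
  expect_equal(genome_to_intron_offset(762, intron), 642L)
  expect_equal(genome_to_intron_offset(763, intron), 643L)
  expect_equal(intron_offset_to_genome(643, intron), 763L)
  expect_error(genome_to_intron_offset(120, intron), "outside")
  set.seed(1)
  for (intr in list(intron, genomic_interval("chrM", 500, 900, "-"))) {
    pos <- sample(intr$start:intr$end, 100)
    expect_equal(intron_offset_to_genome(genome_to_intron_offset(pos, intr),
                                         intr), pos)
  }
})

test_that("minigene fusion preserves lengths and the coordinate bijection", {
  genome <- toy_genome("locus", len = 2000, seed = 7)
  # exon7-like 120 nt + retained intron blocks 844/300/86 + exon8-like 95 nt
  blocks <- genomic_interval("locus",
                             c(1, 121, 1048, 1431, 1517),
                             c(120, 964, 1347, 1516, 1611))
  mg <- build_minigene(genome, blocks, name = "wt")
  expect_equal(nchar(mg$sequence), 120 + 844 + 300 + 86 + 95)
  expect_equal(nchar(mg$sequence), 1445)
  expect_equal(sum(blocks$end[2:4] - blocks$start[2:4] + 1), 1230)
  # no mutations: fused sequence is the concatenation of the block sequences
  expect_equal(mg$sequence, paste(substr(rep(genome, 5), blocks$start,
                                         blocks$end), collapse = ""))
  # bijection: construct -> genomic -> construct is the identity
  cp <- seq_len(nchar(mg$sequence))
  expect_equal(minigene_map(mg, genomic_pos = minigene_map(mg, cp)), cp)
  expect_equal(anyDuplicated(mg$map$genomic_pos), 0L)
})

test_that("minigene mutations are verified against the reference base", {
  genome <- c(locus = "ACGTACGTACGT")
  blocks <- genomic_interval("locus", c(1, 9), c(4, 12))
  ref <- substr(genome, 9, 9)  # "A"
  mut <- data.frame(pos = 9L, ref = ref, alt = "G",
                    stringsAsFactors = FALSE)
  mg <- build_minigene(genome, blocks, mutations = mut)
  expect_equal(substr(mg$sequence, 5, 5), "G")
  bad <- data.frame(pos = 9L, ref = "T", alt = "G", stringsAsFactors = FALSE)
  expect_error(build_minigene(genome, blocks, mutations = bad),
               "mismatch.*position 9")
  outside <- data.frame(pos = 6L, ref = "C", alt = "G",
                        stringsAsFactors = FALSE)
  expect_error(build_minigene(genome, blocks, mutations = outside),
               "not retained")
})

test_that("donor GT>AC mutations change exactly two bases per site", {
  s <- "AAACAGGTAAGTTTT"
  out <- apply_donor_mutations(s, 7)  # GT at 7-8
  expect_equal(out, "AAACAGACAAGTTTT")
  expect_equal(nchar(out), nchar(s))
  expect_identical(apply_donor_mutations(s, integer(0)), s)
  # three sites: Hamming distance exactly 6
  s3 <- paste0("CCC", "GTAAGT", "CCC", "GTCCGT", "CCC", "GTTTTT", "CC")
  m3 <- apply_donor_mutations(s3, c(4, 13, 22))
  hamming <- sum(strsplit(s3, "")[[1]] != strsplit(m3, "")[[1]])
  expect_equal(hamming, 6)
  expect_error(apply_donor_mutations(s, 2), "no GT")
})

test_that("minigene output round-trips through FASTA and the map sidecar", {
  genome <- toy_genome("locus", 500, seed = 3)
  blocks <- genomic_interval("locus", c(10, 200), c(100, 300))
  mg <- build_minigene(genome, blocks)
  fa <- tempfile(fileext = ".fa")
  mp <- tempfile(fileext = ".tsv")
  write_minigene(mg, fa, mp)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs[[1]]), mg$sequence)
  map <- read.delim(mp)
  expect_equal(map$genomic_pos, mg$map$genomic_pos)
})
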