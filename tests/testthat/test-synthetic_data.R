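test_that("the alternative-3'ss preset encodes the knockdown PSI shift", {
  sc <- u1_scenario()
  expect_length(sc$loci, 1)
  l <- sc$loci[[1]]
  expect_equal(l$type, "alt3")
  expect_equal(l$psi_kd - l$psi_ctrl, -0.21196, tolerance = 1e-6)
  expect_equal(l$psi_ctrl, 0.2175)
  # isoform weights reproduce the truth PSI at the junction level
  w <- vapply(l$isoforms, `[[`, 0, "weight_ctrl")
  expect_equal(sum(w), 1)
  expect_equal(w[2] + w[3], 0.2175)  # both inclusion isoforms share 7->7a
  expect_equal(sc$read_length, 105)
  expect_equal(sc$junction_span_frac, 0.30)
})

test_that("the genome-wide mix preset has the six-category truth composition", {
  sc <- build_scenario("fig1b_mix")
  truth <- table(vapply(sc$loci, `[[`, "", "category"))
  expect_equal(as.integer(truth[c("skip_up", "inclusion_up", "proximal5_up",
                                  "distal5_up", "proximal3_up",
                                  "distal3_up")]),
               c(169L, 37L, 111L, 12L, 17L, 17L))
  expect_length(sc$loci, 363)
  with_null <- build_scenario("fig1b_mix", n_null = 25)
  expect_length(with_null$loci, 388)
  expect_equal(sum(vapply(with_null$loci, `[[`, "", "category") ==
                     "unchanged"), 25)
})

test_that("simulation is deterministic under a fixed seed", {
  sc <- u1_scenario()
  a <- simulate_counts(sc, seed = 42)
  b <- simulate_counts(sc, seed = 42)
  expect_identical(a$ctrl$counts, b$ctrl$counts)
  expect_identical(a$kd$counts, b$kd$counts)
  c <- simulate_counts(sc, seed = 43)
  expect_false(identical(a$ctrl$counts$count, c$ctrl$counts$count))
  ra <- simulate_reads(sc, seed = 42)
  rb <- simulate_reads(sc, seed = 42)
  expect_identical(ra$sam, rb$sam)
})

test_that("full NMD depletion removes the sensitive isoform's observations", {
  sc <- u1_scenario()
  sc$loci[[1]]$nmd_depletion <- 1.0
  sim <- simulate_counts(sc, seed = 7)
  cryptic <- sim$ctrl$counts[sim$ctrl$counts$donor == 882, ]
  expect_equal(cryptic$count, 0L)
  # with CHX the same isoform is fully visible
  sc$chx <- TRUE
  sim2 <- simulate_counts(sc, seed = 7)
  expect_gt(sim2$ctrl$counts$count[sim2$ctrl$counts$donor == 882], 0)
})

test_that("junction observations per locus sum to the configured depth", {
  sc <- build_scenario("fig1b_mix", depth = 500)
  sc$loci <- sc$loci[c(1, 200, 350)]
  sim <- simulate_counts(sc, seed = 3)
  for (l in sc$loci) {
    for (cond in c("ctrl", "kd")) {
      cts <- sim[[cond]]$counts
      expect_equal(sum(cts$count[cts$chrom == l$chrom]), 500)
    }
  }
})

test_that("mean simulated control PSI converges to the configured truth", {
  # deep counts with NMD disabled by the CHX flag; average over seeds
  sc <- u1_scenario(chx = TRUE, depth = 5000)
  ev <- discover_events(junction_catalog(scenario_gene_model(sc,
                                                             genome = FALSE)))
  psis <- vapply(1:100, function(seed) {
    sim <- simulate_counts(sc, seed = seed)
    compute_psi(ev[[1]], sim$ctrl)$psi
  }, numeric(1))
  expect_lt(abs(mean(psis) - 0.2175), 0.01)
})

test_that("negative-binomial noise perturbs the per-locus depth", {
  sc <- build_scenario("fig1b_mix", noise = "nb", nb_size = 5, depth = 500)
  sc$loci <- sc$loci[1]
  sim <- simulate_counts(sc, seed = 1)
  expect_false(sum(sim$ctrl$counts$count) == 500)
  expect_error(build_scenario("fig1b_mix", noise = "nb"), "nb_size")
})

test_that("reads from junction-free isoforms carry pure-M CIGARs", {
  mono <- make_sim_locus(
    "MONO", type = "cassette", category = "unchanged",
    psi_ctrl = 0.5, psi_kd = 0.5, depth = 50,
    annotation = list(list(id = "t1",
                           exons = data.frame(chrom = "MONO", start = 1L,
                                              end = 600L, strand = "+"))),
    isoforms = list(list(id = "i1",
                         exons = data.frame(chrom = "MONO", start = 1L,
                                            end = 600L, strand = "+"),
                         weight_ctrl = 1, weight_kd = 1)))
  sc <- build_scenario(loci = list(mono))
  rr <- simulate_reads(sc, seed = 1)
  sam <- read_sam(rr$sam$ctrl)
  expect_gt(nrow(sam), 0)
  expect_true(all(grepl("^105M$", sam$cigar)))
})

test_that("read placement reproduces the counts model in expectation", {
  sc <- build_scenario("fig1b_mix", depth = 2000)
  sc$loci <- sc$loci[c(1, 206)]  # one cassette, one alt5 locus
  cs <- simulate_counts(sc, seed = 13)
  rr <- simulate_reads(sc, seed = 13)
  jc <- junctions_from_sam(rr$sam$kd)
  exp_kd <- cs$expected[cs$expected$condition == "kd", ]
  exp_agg <- aggregate(expected ~ chrom + donor + acceptor, exp_kd, sum)
  m <- merge(exp_agg, jc$counts, by = c("chrom", "donor", "acceptor"))
  expect_equal(nrow(m), nrow(exp_agg))
  # within 5 sd of the binomial expectation
  expect_true(all(abs(m$count - m$expected) <=
                    5 * sqrt(m$expected) + 10))
})

test_that("reads are emitted as sorted, headered, parseable SAM", {
  sc <- u1_scenario(depth = 200)
  dir <- tempfile()
  rr <- simulate_reads(sc, seed = 4, dir = dir)
  expect_true(file.exists(rr$paths$ctrl))
  lines <- readLines(rr$paths$ctrl)
  expect_equal(lines[1], "@HD\tVN:1.6\tSO:coordinate")
  expect_true(any(startsWith(lines, "@SQ")))
  sam <- read_sam(rr$paths$ctrl)
  expect_false(is.unsorted(sam$pos))
  # read sequences match the reference at their aligned positions
  genome <- Biostrings::readDNAStringSet(rr$paths$genome)
  r1 <- sam[grepl("N", sam$cigar), ][1, ]
  cig <- psijunc:::.parse_cigar(r1$cigar)
  first_m <- cig$lens[1]
  ref_piece <- as.character(Biostrings::subseq(genome[["U170K_fixture"]],
                                               r1$pos,
                                               r1$pos + first_m - 1))
  # reconstruct the read's first segment from the SAM line
  fields <- strsplit(readLines(rr$paths$ctrl), "\t")
  seqcol <- vapply(fields[!startsWith(lines, "@")], `[`, "", 10L)
  names(seqcol) <- vapply(fields[!startsWith(lines, "@")], `[`, "", 1L)
  expect_equal(substr(seqcol[[r1$qname]], 1, first_m), ref_piece)
})

test_that("the scenario annotation is valid GTF for the standard importer", {
  sc <- u1_scenario()
  dir <- tempfile()
  rr <- simulate_reads(sc, seed = 1, dir = dir)
  model <- load_annotation(rr$paths$gtf)
  expect_equal(sort(unique(model$exons$transcript_id)),
               c("U170K_7_7a_ret", "U170K_7_8"))
  cat <- junction_catalog(model)
  expect_equal(nrow(cat), 2)
})

test_that("scenario configs round-trip through serialization", {
  sc <- u1_scenario()
  path <- tempfile(fileext = ".json")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$read_length, sc$read_length)
  expect_equal(sc2$junction_span_frac, sc$junction_span_frac)
  expect_equal(length(sc2$loci), length(sc$loci))
  expect_equal(sc2$loci[[1]]$isoforms, sc$loci[[1]]$isoforms)
  expect_equal(sc2$loci[[1]]$seq, sc$loci[[1]]$seq)
  expect_identical(simulate_counts(sc2, seed = 6)$ctrl$counts,
                   simulate_counts(sc, seed = 6)$ctrl$counts)
})

test_that("scenario validation rejects inconsistent configurations", {
  l <- u1_locus()
  l$isoforms[[1]]$weight_ctrl <- 2
  expect_error(make_sim_locus(l$id, l$type, l$category, l$psi_ctrl,
                              l$psi_kd, l$depth, l$annotation, l$isoforms),
               "sum to 1")
  expect_error(build_scenario(loci = list()), "no loci")
  expect_error(build_scenario("u1_70k", junction_span_frac = 1.2),
               "junction_span_frac")
})
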