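jdf <- function(donor, acceptor, chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, donor = donor, acceptor = acceptor,
             strand = strand, stringsAsFactors = FALSE)
}

jc_of <- function(counts_df, sample = "s") {
  junction_counts(counts_df, sample = sample)
}

test_that("junction patterns are classified into the three event types", {
  # cassette: two inclusion junctions bridged by one skipping junction
  ev <- discover_events(jdf(c(100, 300, 100), c(201, 401, 401)))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "cassette")
  expect_equal(ev[[1]]$exon, c(201, 300))
  expect_equal(nrow(ev[[1]]$inclusion), 2)
  expect_equal(ev[[1]]$exclusion$acceptor, 401)
  # alt5: shared acceptor; proximal donor is the downstream one
  ev5 <- discover_events(jdf(c(100, 150), c(500, 500)))
  expect_length(ev5, 1)
  expect_equal(ev5[[1]]$type, "alt5")
  expect_equal(ev5[[1]]$inclusion$donor, 150)  # proximal
  expect_equal(ev5[[1]]$exclusion$donor, 100)  # distal
  # alt3: shared donor; proximal acceptor nearer the donor
  ev3 <- discover_events(jdf(c(120, 120), c(763, 1048)))
  expect_length(ev3, 1)
  expect_equal(ev3[[1]]$type, "alt3")
  expect_equal(ev3[[1]]$inclusion$acceptor, 763)
  expect_equal(ev3[[1]]$exclusion$acceptor, 1048)
})

test_that("proximal/distal orientation follows the strand", {
  # minus strand: donor > acceptor; proximal = shorter intron
  ev5 <- discover_events(jdf(c(500, 450), c(100, 100), strand = "-"))
  expect_equal(ev5[[1]]$type, "alt5")
  expect_equal(ev5[[1]]$inclusion$donor, 450)
  ev3 <- discover_events(jdf(c(900, 900), c(700, 400), strand = "-"))
  expect_equal(ev3[[1]]$type, "alt3")
  expect_equal(ev3[[1]]$inclusion$acceptor, 700)
})

test_that("a cassette triple is not double-reported as alt5/alt3", {
  ev <- discover_events(jdf(c(100, 300, 100), c(201, 401, 401)))
  expect_equal(vapply(ev, `[[`, "", "type"), "cassette")
})

test_that("event discovery is deterministic and order-invariant", {
  cat1 <- jdf(c(100, 300, 100, 600, 650), c(201, 401, 401, 900, 900))
  for (seed in 1:3) {
    set.seed(seed)
    shuffled <- cat1[sample(nrow(cat1)), ]
    expect_equal(vapply(discover_events(shuffled), `[[`, "", "event_id"),
                 vapply(discover_events(cat1), `[[`, "", "event_id"))
  }
  expect_length(discover_events(cat1[0, ]), 0)
})

test_that("PSI estimates match the junction-count ratios", {
  ev3 <- discover_events(jdf(c(120, 120), c(763, 1048)))[[1]]
  ctrl <- jc_of(cbind(jdf(c(120, 120), c(763, 1048)),
                      count = c(107L, 385L)))
  kd <- jc_of(cbind(jdf(c(120, 120), c(763, 1048)), count = c(4L, 718L)))
  p_ctrl <- compute_psi(ev3, ctrl)
  p_kd <- compute_psi(ev3, kd)
  expect_equal(p_ctrl$psi, 107 / 492, tolerance = 1e-12)
  expect_equal(round(p_ctrl$psi, 4), 0.2175)
  expect_equal(p_kd$psi, 4 / 722, tolerance = 1e-12)
  expect_equal(round(p_kd$psi, 4), 0.0055)
  # supports are conserved
  expect_equal(p_ctrl$inclusion_support + p_ctrl$exclusion_support, 492)
  # cassette boundary: no skipping reads -> PSI 1
  evc <- discover_events(jdf(c(100, 300, 100), c(201, 401, 401)))[[1]]
  cc <- jc_of(cbind(jdf(c(100, 300, 100), c(201, 401, 401)),
                    count = c(10L, 10L, 0L)))
  expect_equal(compute_psi(evc, cc)$psi, 1.0)
  # cassette weighting: skip junction counted twice in the denominator
  cc2 <- jc_of(cbind(jdf(c(100, 300, 100), c(201, 401, 401)),
                     count = c(12L, 8L, 5L)))
  expect_equal(compute_psi(evc, cc2)$psi, 20 / 30)
  # absent support is flagged undefined, not an error
  empty <- jc_of(cbind(jdf(1, 100), count = 7L))
  p0 <- compute_psi(ev3, empty)
  expect_true(is.na(p0$psi))
  expect_false(p0$defined)
})

test_that("PSI is monotone in the proximal count", {
  ev <- discover_events(jdf(c(120, 120), c(763, 1048)))[[1]]
  psis <- vapply(seq(0, 200, by = 10), function(k) {
    compute_psi(ev, jc_of(cbind(jdf(c(120, 120), c(763, 1048)),
                                count = c(k, 50L))))$psi
  }, numeric(1))
  expect_true(all(diff(psis) >= 0))
})

test_that("the exact test agrees with independent enumeration oracles", {
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  t1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_2x2(t1), fisher_oracle(10, 0, 0, 10),
               tolerance = 1e-12)
  expect_equal(fisher_2x2(t1), stats::fisher.test(t1)$p.value,
               tolerance = 1e-12)
  # the alternative 3'ss junction table: 107/385 vs 4/718
  t2 <- matrix(c(107, 4, 385, 718), 2)
  expect_equal(fisher_2x2(t2), fisher_oracle(107, 385, 4, 718),
               tolerance = 1e-12)
  expect_lt(fisher_2x2(t2), 1e-10)
  # random tables against stats::fisher.test
  set.seed(99)
  for (i in 1:200) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_2x2(matrix(c(0.5, 1, 1, 1), 2)), "integer")
})

test_that("differential calls carry direction, BH q values, and thresholds", {
  ev <- discover_events(jdf(c(120, 120), c(763, 1048)))
  ctrl <- jc_of(cbind(jdf(c(120, 120), c(763, 1048)),
                      count = c(107L, 385L)))
  kd <- jc_of(cbind(jdf(c(120, 120), c(763, 1048)), count = c(4L, 718L)))
  calls <- call_differential(ev, ctrl, kd)
  expect_s3_class(calls, "splice_calls")
  expect_equal(calls$category, "distal3_up")
  expect_lt(calls$delta_psi, -0.1)
  # identical counts in both conditions: p = 1, unchanged
  same <- call_differential(ev, ctrl, ctrl)
  expect_equal(same$p, 1.0)
  expect_equal(same$category, "unchanged")
  # q values are BH-adjusted across the whole call set
  cat2 <- jdf(c(120, 120, 500, 500), c(763, 1048, 900, 980))
  evs <- discover_events(cat2)
  c2 <- jc_of(cbind(cat2, count = c(107L, 385L, 50L, 50L)))
  k2 <- jc_of(cbind(cat2, count = c(4L, 718L, 48L, 52L)))
  calls2 <- call_differential(evs, c2, k2)
  expect_equal(calls2$q, p.adjust(calls2$p, "BH"))
})

test_that("threshold ties are called significant and category is pure", {
  th <- list(min_support = 10, min_delta = 0.1, max_q = 0.05)
  expect_equal(classify_call("cassette", 0.1, 10, 10, 0.05, th),
               "inclusion_up")
  expect_equal(classify_call("cassette", -0.1, 10, 10, 0.05, th), "skip_up")
  expect_equal(classify_call("cassette", 0.0999, 100, 100, 0.001, th),
               "unchanged")
  expect_equal(classify_call("alt5", 0.3, 9, 100, 0.001, th), "unchanged")
  expect_equal(classify_call("alt3", 0.3, 100, 100, 0.051, th), "unchanged")
  expect_equal(classify_call("alt5", -0.3, 100, 100, 0.01, th),
               "distal5_up")
  expect_equal(classify_call("alt3", 0.3, 100, 100, 0.01, th),
               "proximal3_up")
})

test_that("a simulated knockdown shift is recovered across seeded replicates", {
  # cassette with true delta PSI = -0.4 at depth 300
  hits <- 0
  for (seed in 1:100) {
    locus <- psijunc:::.make_category_locus("L1", "skip_up", 0.7, 0.3, 300)
    sc <- build_scenario(loci = list(locus))
    sim <- simulate_counts(sc, seed = seed)
    model <- scenario_gene_model(sc, genome = FALSE)
    ev <- discover_events(junction_catalog(model))
    calls <- call_differential(ev, sim$ctrl, sim$kd)
    if (identical(calls$category, "skip_up")) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("category tallies are order-invariant bookkeeping", {
  ev <- discover_events(jdf(c(120, 120), c(763, 1048)))
  ctrl <- jc_of(cbind(jdf(c(120, 120), c(763, 1048)),
                      count = c(107L, 385L)))
  kd <- jc_of(cbind(jdf(c(120, 120), c(763, 1048)), count = c(4L, 718L)))
  calls <- call_differential(ev, ctrl, kd)
  t1 <- tally_categories(calls)
  expect_equal(sum(t1), nrow(calls))
  expect_equal(t1[["distal3_up"]], 1L)
  shuffled <- calls[rev(seq_len(nrow(calls))), ]
  expect_equal(tally_categories(shuffled), t1)
  t0 <- tally_categories(calls[0, ])
  expect_true(all(t0 == 0L))
  expect_equal(names(t0), c("skip_up", "inclusion_up", "proximal5_up",
                            "distal5_up", "proximal3_up", "distal3_up",
                            "unchanged"))
})
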