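# Seeded two-condition splicing simulator with known truth.
#
# A scenario is a set of loci, each carrying an annotation (transcript
# structures used for the junction catalog), a set of mature isoforms with
# per-condition mixture weights, and a truth label. Junction observations
# are drawn multinomially over (isoform, junction) cells with probability
# proportional to the isoform weight -- each junction of a molecule is
# covered in proportion to the molecule's abundance -- so the junction-read
# PSI estimators recover the configured isoform fractions in expectation.
# Counts attributed to NMD-sensitive isoforms are thinned by the locus
# depletion factor unless the cycloheximide (CHX) flag is on; CHX models a
# translation block that disables NMD, nothing more.
#
# Read-level simulation places single-end reads (default 105 nt, the
# read length of the emulated experiment) on mature isoforms: a read is
# junction-spanning with the configured probability (default 0.30, the
# observed genome-wide junction-spanning fraction) and its start is uniform
# within the chosen junction's spanning window, giving gapped (N CIGAR)
# SAM alignments that round-trip through the junction extractor.

FIG1B_MIX <- c(skip_up = 169L, inclusion_up = 37L, proximal5_up = 111L,
               distal5_up = 12L, proximal3_up = 17L, distal3_up = 17L)

#' Build a simulation scenario
#'
#' Two presets are provided. `"u1_70k"` is a single-locus alternative
#' 3' splice-site scenario modelled on the U1-70K exon 7-8 region: a
#' productive exon 7-8 isoform, a non-productive isoform using an
#' intron-internal acceptor 642 nt into the intron (first exonic base at
#' offset +643), and a low-abundance, NMD-sensitive exon 7a inclusion
#' isoform spliced through a cryptic donor that is absent from the
#' annotation. Truth PSI is 0.2175 in control versus 0.00554 in knockdown
#' (the 107/492 and 4/722 junction-read ratios). `"fig1b_mix"` is a
#' genome-wide mix of 363 loci in the six-category truth composition
#' 169 : 37 : 111 : 12 : 17 : 17 (cassette skipping-up / inclusion-up,
#' proximal / distal alternative 5'ss, proximal / distal alternative 3'ss).
#'
#' @param preset `"u1_70k"`, `"fig1b_mix"`, or `NULL` (supply `loci`).
#' @param loci List of loci built by [make_sim_locus()] (when no preset).
#' @param read_length Read length in nt (default 105).
#' @param junction_span_frac Target fraction of reads spanning a junction
#'   (default 0.30).
#' @param noise `"multinomial"` (single library per condition) or `"nb"`
#'   (negative-binomial overdispersion of the per-locus depth).
#' @param nb_size Negative-binomial size parameter when `noise = "nb"`.
#' @param chx Cycloheximide flag: when `TRUE`, NMD thinning is disabled.
#' @param depth Expected junction observations per locus (preset defaults:
#'   2000 for `u1_70k`, 500 for `fig1b_mix`).
#' @param delta_psi Absolute PSI difference for `fig1b_mix` signal loci
#'   (default 0.3; pairs are `0.5 +/- delta_psi/2`).
#' @param n_null Number of additional no-change cassette loci (PSI 0.5 in
#'   both conditions) appended to `fig1b_mix`.
#' @param scale Integer multiplier on the `fig1b_mix` category counts.
#' @return Object of class `sim_scenario`.
#' @export
build_scenario <- function(preset = NULL, loci = NULL, read_length = 105,
                           junction_span_frac = 0.30,
                           noise = c("multinomial", "nb"), nb_size = NULL,
                           chx = FALSE, depth = NULL, delta_psi = 0.3,
                           n_null = 0, scale = 1) {
  noise <- match.arg(noise)
  if (read_length < 2) .fail("read_length must be >= 2")
  if (junction_span_frac <= 0 || junction_span_frac >= 1) {
    .fail("junction_span_frac must be in (0, 1)")
  }
  if (noise == "nb" && (is.null(nb_size) || nb_size <= 0)) {
    .fail("nb noise requires a positive nb_size")
  }
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("u1_70k", "fig1b_mix"))
    loci <- switch(preset,
      u1_70k = list(.u1_70k_locus(depth = if (is.null(depth)) 2000 else depth)),
      fig1b_mix = .fig1b_loci(depth = if (is.null(depth)) 500 else depth,
                              delta_psi = delta_psi, n_null = n_null,
                              scale = scale))
  }
  if (is.null(loci) || length(loci) == 0) .fail("scenario has no loci")
  ids <- vapply(loci, `[[`, "", "id")
  if (anyDuplicated(ids)) .fail("duplicate locus ids")
  structure(list(name = if (is.null(preset)) "custom" else preset,
                 loci = loci, read_length = read_length,
                 junction_span_frac = junction_span_frac, noise = noise,
                 nb_size = nb_size, chx = chx),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario '%s': %d loci, %d-nt reads, junction-spanning fraction %.2f, noise %s, CHX %s\n",
              x$name, length(x$loci), x$read_length, x$junction_span_frac,
              x$noise, if (x$chx) "on" else "off"))
  invisible(x)
}

#' Define a simulated locus
#'
#' @param id Locus identifier (also used as chromosome name).
#' @param type Event type generated at this locus.
#' @param category Truth category (`"unchanged"` for null loci).
#' @param psi_ctrl,psi_kd True isoform fractions of the
#'   inclusion/proximal isoform per condition.
#' @param depth Expected junction observations per condition.
#' @param annotation List of transcripts (`list(id =, exons = data.frame)`)
#'   used for the junction catalog.
#' @param isoforms List of isoforms: `list(id =, exons =, weight_ctrl =,
#'   weight_kd =, nmd = FALSE)`. Weights per condition must sum to 1.
#' @param nmd_depletion Fraction of NMD-sensitive isoform observations
#'   removed when CHX is off (default 0.95).
#' @param cds_start Optional named vector of translation-start mRNA
#'   positions per isoform id.
#' @param seq Optional fixed locus sequence (generated at random when
#'   absent).
#' @return A locus list usable in [build_scenario()].
#' @export
make_sim_locus <- function(id, type, category, psi_ctrl, psi_kd, depth,
                           annotation, isoforms, nmd_depletion = 0.95,
                           cds_start = NULL, seq = NULL) {
  for (cond in c("weight_ctrl", "weight_kd")) {
    w <- vapply(isoforms, `[[`, 0, cond)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      .fail("locus '%s': %s must be non-negative and sum to 1", id, cond)
    }
  }
  if (psi_ctrl < 0 || psi_ctrl > 1 || psi_kd < 0 || psi_kd > 1) {
    .fail("PSI must lie in [0, 1]")
  }
  if (nmd_depletion < 0 || nmd_depletion > 1) {
    .fail("nmd_depletion must lie in [0, 1]")
  }
  if (depth <= 0) .fail("depth must be positive")
  isoforms <- lapply(isoforms, function(iso) {
    if (is.null(iso$nmd)) iso$nmd <- FALSE
    iso
  })
  list(id = id, chrom = id, strand = "+", type = type, category = category,
       psi_ctrl = psi_ctrl, psi_kd = psi_kd, depth = depth,
       annotation = annotation, isoforms = isoforms,
       nmd_depletion = nmd_depletion, cds_start = cds_start, seq = seq)
}

# ---- preset loci -----------------------------------------------------------

.exdf <- function(chrom, starts, ends, strand = "+") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), strand = strand,
             stringsAsFactors = FALSE)
}

# U1-70K-like fixture locus. Coordinates (1-based, + strand):
#   exon 7    1-120      (translation start at mRNA 1)
#   intron 7  121-1047   alternative acceptor: last intronic base at +642
#                        (genomic 762), alternative exon starts +643 (763)
#   exon 7a   763-882    carries the PTC; cryptic donors A (GT at 883),
#                        B (GT at 913), C (GT at 943) downstream
#   exon 8    1048-1142  carries the normal stop codon
.u1_70k_seq <- function() {
  paste0(
    "ATG", strrep("GCT", 39),                       # exon 7 (120 nt)
    "GTAAGT", strrep("CCT", 206), strrep("T", 16), "AG",  # intron to 7a
    strrep("GCT", 9), "TAA", strrep("GCA", 30),     # exon 7a (120), PTC at 7a pos 28
    "GTAAGT", strrep("CCT", 7),                     # donor A + spacer
    "CAG", "GTATGT", strrep("CCT", 7),              # donor B (weak)
    "CAG", "GTAAGT",                                # donor C (consensus-like)
    strrep("CT", 41), strrep("T", 15), "AG",        # intron tail to exon 8
    strrep("GGC", 8), "TAA", strrep("GGC", 22), "GG"  # exon 8 (95 nt)
  )
}

.u1_70k_locus <- function(depth = 2000) {
  ch <- "U170K_fixture"
  e7 <- c(1L, 120L)
  e7a <- c(763L, 882L)
  e8 <- c(1048L, 1142L)
  ann <- list(
    list(id = "U170K_7_8", exons = .exdf(ch, c(e7[1], e8[1]),
                                         c(e7[2], e8[2]))),
    list(id = "U170K_7_7a_ret", exons = .exdf(ch, c(e7[1], e7a[1]),
                                              c(e7[2], e8[2]))))
  isoforms <- list(
    list(id = "iso_7_8", exons = .exdf(ch, c(e7[1], e8[1]), c(e7[2], e8[2])),
         weight_ctrl = 0.7825, weight_kd = 0.99446, nmd = FALSE),
    list(id = "iso_7_7a", exons = .exdf(ch, c(e7[1], e7a[1]),
                                        c(e7[2], e8[2])),
         weight_ctrl = 0.1875, weight_kd = 0.00454, nmd = FALSE),
    list(id = "iso_7_7a_8",
         exons = .exdf(ch, c(e7[1], e7a[1], e8[1]), c(e7[2], e7a[2], e8[2])),
         weight_ctrl = 0.03, weight_kd = 0.001, nmd = TRUE))
  make_sim_locus(ch, type = "alt3", category = "distal3_up",
                 psi_ctrl = 0.2175, psi_kd = 0.00554, depth = depth,
                 annotation = ann, isoforms = isoforms,
                 nmd_depletion = 0.98,
                 cds_start = c(iso_7_8 = 1L, iso_7_7a = 1L, iso_7_7a_8 = 1L),
                 seq = .u1_70k_seq())
}

# Generic signal loci for the six categories. All on "+" with exon/intron
# geometry wide enough for 105-nt reads to fit inside single exons.
.make_category_locus <- function(id, category, psi_ctrl, psi_kd, depth) {
  type <- switch(category,
                 skip_up = , inclusion_up = , unchanged = "cassette",
                 proximal5_up = , distal5_up = "alt5",
                 proximal3_up = , distal3_up = "alt3")
  ch <- id
  if (type == "cassette") {
    inc <- .exdf(ch, c(101, 661, 1111), c(360, 810, 1370))
    skp <- .exdf(ch, c(101, 1111), c(360, 1370))
    ann <- list(list(id = paste0(id, "_inc"), exons = inc),
                list(id = paste0(id, "_skp"), exons = skp))
    isoforms <- list(
      list(id = "inc", exons = inc, weight_ctrl = psi_ctrl,
           weight_kd = psi_kd),
      list(id = "skp", exons = skp, weight_ctrl = 1 - psi_ctrl,
           weight_kd = 1 - psi_kd))
  } else if (type == "alt5") {
    prox <- .exdf(ch, c(101, 761), c(460, 1020))  # downstream donor, intron 300
    dist <- .exdf(ch, c(101, 761), c(360, 1020))  # upstream donor, intron 400
    ann <- list(list(id = paste0(id, "_prox"), exons = prox),
                list(id = paste0(id, "_dist"), exons = dist))
    isoforms <- list(
      list(id = "prox", exons = prox, weight_ctrl = psi_ctrl,
           weight_kd = psi_kd),
      list(id = "dist", exons = dist, weight_ctrl = 1 - psi_ctrl,
           weight_kd = 1 - psi_kd))
  } else {
    prox <- .exdf(ch, c(101, 661), c(360, 1020))  # upstream acceptor, intron 300
    dist <- .exdf(ch, c(101, 761), c(360, 1020))  # downstream acceptor, intron 400
    ann <- list(list(id = paste0(id, "_prox"), exons = prox),
                list(id = paste0(id, "_dist"), exons = dist))
    isoforms <- list(
      list(id = "prox", exons = prox, weight_ctrl = psi_ctrl,
           weight_kd = psi_kd),
      list(id = "dist", exons = dist, weight_ctrl = 1 - psi_ctrl,
           weight_kd = 1 - psi_kd))
  }
  make_sim_locus(id, type = type, category = category, psi_ctrl = psi_ctrl,
                 psi_kd = psi_kd, depth = depth, annotation = ann,
                 isoforms = isoforms)
}

.fig1b_loci <- function(depth = 500, delta_psi = 0.3, n_null = 0,
                        scale = 1) {
  lo <- 0.5 - delta_psi / 2
  hi <- 0.5 + delta_psi / 2
  psi_pairs <- list(skip_up = c(hi, lo), inclusion_up = c(lo, hi),
                    proximal5_up = c(lo, hi), distal5_up = c(hi, lo),
                    proximal3_up = c(lo, hi), distal3_up = c(hi, lo))
  loci <- list()
  for (cat in names(FIG1B_MIX)) {
    for (i in seq_len(FIG1B_MIX[[cat]] * scale)) {
      id <- sprintf("L%s_%03d", sub("_up$", "", cat), i)
      pp <- psi_pairs[[cat]]
      loci[[length(loci) + 1L]] <- .make_category_locus(id, cat, pp[1],
                                                        pp[2], depth)
    }
  }
  for (i in seq_len(n_null)) {
    id <- sprintf("Lnull_%04d", i)
    loci[[length(loci) + 1L]] <- .make_category_locus(id, "unchanged",
                                                      0.5, 0.5, depth)
  }
  loci
}

# ---- counts simulation -----------------------------------------------------

.iso_junctions <- function(iso) {
  e <- iso$exons
  if (nrow(e) < 2) {
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  }
  if (e$strand[1] == "+") {
    data.frame(donor = e$end[-nrow(e)], acceptor = e$start[-1])
  } else {
    data.frame(donor = e$start[-nrow(e)], acceptor = e$end[-1])
  }
}

# (isoform, junction) cell table for one locus.
.locus_cells <- function(locus) {
  rows <- list()
  for (iso in locus$isoforms) {
    jx <- .iso_junctions(iso)
    if (nrow(jx) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      iso = iso$id, chrom = locus$chrom, donor = jx$donor,
      acceptor = jx$acceptor, strand = locus$strand,
      w_ctrl = iso$weight_ctrl, w_kd = iso$weight_kd,
      nmd = isTRUE(iso$nmd), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate junction counts for both conditions
#'
#' Per locus and condition, `depth` junction observations are distributed
#' multinomially over (isoform, junction) cells with probability
#' proportional to the isoform weight; observations from NMD-sensitive
#' isoforms are then thinned binomially by the locus depletion factor
#' unless the scenario's CHX flag is on. Per-locus random streams are
#' derived deterministically from the master seed and the locus id, so
#' results are reproducible and independent of locus order.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Master seed (integer).
#' @return List with `ctrl` and `kd` (`junction_counts`), `truth` (one row
#'   per locus: id, type, category, true PSI pair, depth), and `expected`
#'   (per-junction expected post-thinning counts per condition).
#' @export
simulate_counts <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  per_cond <- list(ctrl = list(), kd = list())
  expected <- list()
  for (locus in scenario$loci) {
    cells <- .locus_cells(locus)
    if (is.null(cells)) next
    for (cond in c("ctrl", "kd")) {
      w <- if (cond == "ctrl") cells$w_ctrl else cells$w_kd
      set.seed(derive_seed(seed, paste("counts", locus$id, cond)))
      depth <- locus$depth
      if (scenario$noise == "nb") {
        depth <- stats::rnbinom(1, size = scenario$nb_size, mu = depth)
      }
      cnt <- if (sum(w) == 0 || depth == 0) {
        integer(nrow(cells))
      } else {
        as.integer(rmultinom(1, depth, w))
      }
      thin <- cells$nmd & !scenario$chx
      if (any(thin)) {
        cnt[thin] <- rbinom(sum(thin), cnt[thin],
                            1 - locus$nmd_depletion)
      }
      per_cond[[cond]][[locus$id]] <- data.frame(
        chrom = cells$chrom, donor = cells$donor,
        acceptor = cells$acceptor, strand = cells$strand, count = cnt,
        stringsAsFactors = FALSE)
      p <- if (sum(w) > 0) w / sum(w) else w
      ethin <- ifelse(cells$nmd & !scenario$chx,
                      1 - locus$nmd_depletion, 1)
      expected[[paste(locus$id, cond)]] <- data.frame(
        locus = locus$id, condition = cond, chrom = cells$chrom,
        donor = cells$donor, acceptor = cells$acceptor,
        expected = locus$depth * p * ethin, stringsAsFactors = FALSE)
    }
  }
  f <- scenario$junction_span_frac
  agg <- function(cond) {
    df <- do.call(rbind, per_cond[[cond]])
    key <- paste(df$chrom, df$donor, df$acceptor)
    cts <- stats::aggregate(df$count, by = list(key = key), FUN = sum)
    first <- df[!duplicated(key), , drop = FALSE]
    first <- first[match(cts$key, paste(first$chrom, first$donor,
                                        first$acceptor)), ]
    total_j <- sum(df$count)
    junction_counts(data.frame(chrom = first$chrom, donor = first$donor,
                               acceptor = first$acceptor,
                               strand = first$strand,
                               count = as.integer(cts$x),
                               stringsAsFactors = FALSE),
                    sample = cond, total_unique = round(total_j / f),
                    total_junction = total_j)
  }
  exp_df <- do.call(rbind, expected)
  rownames(exp_df) <- NULL
  truth <- do.call(rbind, lapply(scenario$loci, function(l) {
    data.frame(locus = l$id, type = l$type, category = l$category,
               psi_ctrl = l$psi_ctrl, psi_kd = l$psi_kd, depth = l$depth,
               stringsAsFactors = FALSE)
  }))
  list(ctrl = agg("ctrl"), kd = agg("kd"), truth = truth,
       expected = exp_df)
}

# ---- read simulation -------------------------------------------------------

.random_locus_seq <- function(locus, seed) {
  len <- max(vapply(locus$isoforms, function(i) max(i$exons$end), 0),
             vapply(locus$annotation, function(t) max(t$exons$end), 0)) + 50L
  set.seed(derive_seed(seed, paste("genome", locus$id)))
  s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  # canonical dinucleotides at annotated intron boundaries
  ch <- strsplit(s, "")[[1]]
  for (tx in locus$annotation) {
    jx <- .iso_junctions(list(exons = tx$exons))
    for (i in seq_len(nrow(jx))) {
      ch[jx$donor[i] + 1L] <- "G"; ch[jx$donor[i] + 2L] <- "T"
      ch[jx$acceptor[i] - 2L] <- "A"; ch[jx$acceptor[i] - 1L] <- "G"
    }
  }
  paste(ch, collapse = "")
}

.scenario_genome <- function(scenario, seed = 1) {
  seqs <- vapply(scenario$loci, function(l) {
    if (!is.null(l$seq)) l$seq else .random_locus_seq(l, seed)
  }, character(1))
  setNames(seqs, vapply(scenario$loci, `[[`, "", "chrom"))
}

#' Gene model of a scenario's annotation
#'
#' @param scenario A `sim_scenario`.
#' @param genome Attach locus sequences (default `TRUE`).
#' @param seed Seed used to generate sequences for loci without a fixed
#'   one.
#' @return A `gene_model` covering every locus transcript.
#' @export
scenario_gene_model <- function(scenario, genome = TRUE, seed = 1) {
  exons <- do.call(rbind, lapply(scenario$loci, function(l) {
    do.call(rbind, lapply(l$annotation, function(tx) {
      cbind(data.frame(transcript_id = tx$id, gene_id = l$id,
                       stringsAsFactors = FALSE), tx$exons)
    }))
  }))
  gene_model(exons,
             genome = if (genome) .scenario_genome(scenario, seed) else NULL)
}

# GTF lines for the scenario annotation.
.scenario_gtf <- function(scenario) {
  unlist(lapply(scenario$loci, function(l) {
    unlist(lapply(l$annotation, function(tx) {
      e <- tx$exons
      sprintf(paste0('%s\tpsijunc\texon\t%d\t%d\t.\t%s\t.\t',
                     'gene_id "%s"; transcript_id "%s";'),
              e$chrom, e$start, e$end, e$strand, l$id, tx$id)
    }))
  }))
}

# Mature structure of an isoform: sequence, junction positions, and the
# cumulative exon offsets needed to map mature coordinates to the genome.
.mature_structure <- function(iso, chromseq) {
  e <- iso$exons
  lens <- e$end - e$start + 1L
  M <- sum(lens)
  segs <- vapply(seq_len(nrow(e)), function(i) {
    substr(chromseq, e$start[i], e$end[i])
  }, character(1))
  list(exons = e, lens = lens, M = M,
       offsets = cumsum(c(0L, lens[-length(lens)])),
       junctions = if (nrow(e) > 1) cumsum(lens)[-length(lens)] else integer(0),
       seq = paste(segs, collapse = ""))
}

# CIGAR and genomic start for a read [start, start+rl-1] in mature coords.
.read_alignment <- function(ms, start, rl) {
  end <- start + rl - 1L
  exon_of <- findInterval(start - 1L, ms$offsets)  # 1-based exon index
  gpos <- ms$exons$start[exon_of] + (start - 1L - ms$offsets[exon_of])
  cig <- character(0)
  remaining <- rl
  cur_exon <- exon_of
  cur_m <- min(ms$offsets[cur_exon] + ms$lens[cur_exon], end) -
    (start - 1L)
  repeat {
    cig <- c(cig, sprintf("%dM", cur_m))
    remaining <- remaining - cur_m
    if (remaining <= 0) break
    gap <- ms$exons$start[cur_exon + 1L] - ms$exons$end[cur_exon] - 1L
    cig <- c(cig, sprintf("%dN", gap))
    cur_exon <- cur_exon + 1L
    cur_m <- min(ms$lens[cur_exon], remaining)
  }
  list(pos = gpos, cigar = paste(cig, collapse = ""))
}

#' Simulate gapped SAM reads for both conditions
#'
#' Emits per-condition SAM (sorted, with `@HD`/`@SQ` headers), the locus
#' FASTA, the annotation GTF, and the truth table. Reads are placed on
#' mature isoforms: junction-spanning with probability
#' `junction_span_frac` (start uniform within the spanning window of an
#' (isoform, junction) cell drawn proportionally to isoform weight),
#' otherwise uniform over junction-free start positions. Reads from
#' NMD-sensitive isoforms are dropped with the depletion probability
#' unless CHX is on. The number of reads per locus is
#' `depth / junction_span_frac`, so junction observations match
#' [simulate_counts()] in expectation.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Master seed.
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `ctrl.sam`, `kd.sam`, `truth.tsv`.
#' @return List with `sam` (list of per-condition SAM line vectors),
#'   `genome`, `gtf`, `truth`, and (when `dir` is given) `paths`.
#' @export
simulate_reads <- function(scenario, seed = 1, dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  genome <- .scenario_genome(scenario, seed)
  rl <- scenario$read_length
  f <- scenario$junction_span_frac
  recs <- list(ctrl = list(), kd = list())
  skipped_loci <- character(0)
  for (locus in scenario$loci) {
    chromseq <- genome[[locus$chrom]]
    ms_list <- lapply(locus$isoforms, .mature_structure,
                      chromseq = chromseq)
    names(ms_list) <- vapply(locus$isoforms, `[[`, "", "id")
    if (any(vapply(ms_list, `[[`, 0L, "M") < rl)) {
      warning(sprintf("locus '%s' skipped: isoform shorter than read length",
                      locus$id))
      skipped_loci <- c(skipped_loci, locus$id)
      next
    }
    # spanning windows per (isoform, junction) and junction-free starts
    span <- list()
    free <- list()
    for (k in seq_along(ms_list)) {
      ms <- ms_list[[k]]
      max_start <- ms$M - rl + 1L
      wins <- lapply(ms$junctions, function(j) {
        a <- max(1L, j - rl + 2L)
        b <- min(j, max_start)
        if (a <= b) a:b else integer(0)
      })
      span[[k]] <- wins
      covered <- unique(unlist(wins))
      free[[k]] <- setdiff(seq_len(max_start), covered)
    }
    w_iso <- list(
      ctrl = vapply(locus$isoforms, `[[`, 0, "weight_ctrl"),
      kd = vapply(locus$isoforms, `[[`, 0, "weight_kd"))
    nmd <- vapply(locus$isoforms, function(i) isTRUE(i$nmd), logical(1))
    nj <- vapply(ms_list, function(m) length(m$junctions), integer(1))
    for (cond in c("ctrl", "kd")) {
      set.seed(derive_seed(seed, paste("reads", locus$id, cond)))
      w <- w_iso[[cond]]
      nreads <- round(locus$depth / f)
      # (isoform, junction) cells with weight w_iso
      cell_iso <- rep(seq_along(ms_list), nj)
      cell_j <- unlist(lapply(nj, seq_len))
      cell_w <- w[cell_iso]
      out <- character(nreads)
      n_out <- 0L
      for (r in seq_len(nreads)) {
        spanning <- runif(1) < f && sum(cell_w) > 0
        if (spanning) {
          cell <- sample.int(length(cell_w), 1L, prob = cell_w)
          iso_i <- cell_iso[cell]
          win <- span[[iso_i]][[cell_j[cell]]]
          if (length(win) == 0) next
          start <- win[sample.int(length(win), 1L)]
        } else {
          iso_i <- sample.int(length(w), 1L, prob = w)
          pool <- free[[iso_i]]
          if (length(pool) == 0) {
            pool <- seq_len(ms_list[[iso_i]]$M - rl + 1L)
          }
          start <- pool[sample.int(length(pool), 1L)]
        }
        if (nmd[iso_i] && !scenario$chx &&
            runif(1) < locus$nmd_depletion) {
          next  # transcript degraded: read never observed
        }
        ms <- ms_list[[iso_i]]
        aln <- .read_alignment(ms, start, rl)
        n_out <- n_out + 1L
        out[n_out] <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                              sprintf("%s_%s_%06d", locus$id, cond, r),
                              locus$chrom, aln$pos, aln$cigar,
                              substr(ms$seq, start, start + rl - 1L))
      }
      recs[[cond]][[locus$id]] <- out[seq_len(n_out)]
    }
  }
  chroms <- setdiff(vapply(scenario$loci, `[[`, "", "chrom"), skipped_loci)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  sam <- lapply(recs, function(cond_recs) {
    body <- unlist(cond_recs, use.names = FALSE)
    if (length(body)) {
      fs <- strsplit(body, "\t", fixed = TRUE)
      ch <- vapply(fs, `[`, "", 3L)
      po <- as.integer(vapply(fs, `[`, "", 4L))
      body <- body[order(match(ch, names(genome)), po)]
    }
    c(header, body)
  })
  truth <- do.call(rbind, lapply(scenario$loci, function(l) {
    data.frame(locus = l$id, type = l$type, category = l$category,
               psi_ctrl = l$psi_ctrl, psi_kd = l$psi_kd, depth = l$depth,
               stringsAsFactors = FALSE)
  }))
  res <- list(sam = sam, genome = genome, gtf = .scenario_gtf(scenario),
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  ctrl = file.path(dir, "ctrl.sam"),
                  kd = file.path(dir, "kd.sam"),
                  truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                paths$genome)
    writeLines(res$gtf, paths$gtf)
    writeLines(sam$ctrl, paths$ctrl)
    writeLines(sam$kd, paths$kd)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$paths <- paths
  }
  res
}

#' Simulate a full synthetic catalog experiment
#'
#' Convenience wrapper: builds the `fig1b_mix` scenario (optionally with
#' null loci), simulates counts for both conditions, and returns the
#' pieces needed to run the caller.
#'
#' @param delta_psi Absolute PSI change at signal loci.
#' @param depth Expected junction observations per locus.
#' @param n_null Number of additional null loci.
#' @param scale Multiplier on the category counts.
#' @param seed Master seed.
#' @param chx CHX flag.
#' @return List with `scenario`, `model` (annotation `gene_model`, no
#'   sequence), `ctrl`, `kd`, `truth`.
#' @export
simulate_catalog <- function(delta_psi = 0.3, depth = 500, n_null = 0,
                             scale = 1, seed = 1, chx = FALSE) {
  scenario <- build_scenario("fig1b_mix", delta_psi = delta_psi,
                             depth = depth, n_null = n_null, scale = scale,
                             chx = chx)
  sim <- simulate_counts(scenario, seed)
  list(scenario = scenario,
       model = scenario_gene_model(scenario, genome = FALSE),
       ctrl = sim$ctrl, kd = sim$kd, truth = sim$truth)
}

# ---- scenario serialization ------------------------------------------------

#' Write a scenario to a JSON config file
#'
#' @param scenario A `sim_scenario`.
#' @param path Output path.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$loci <- lapply(x$loci, function(l) {
    l$annotation <- lapply(l$annotation, function(tx) {
      tx$exons <- as.list(tx$exons)
      tx
    })
    l$isoforms <- lapply(l$isoforms, function(iso) {
      iso$exons <- as.list(iso$exons)
      iso
    })
    if (!is.null(l$cds_start)) l$cds_start <- as.list(l$cds_start)
    l
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(scenario)
}

#' Read a scenario from a JSON config file
#'
#' @param path Config path written by [write_scenario()].
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path)
  to_df <- function(e) {
    data.frame(chrom = unlist(e$chrom), start = as.integer(unlist(e$start)),
               end = as.integer(unlist(e$end)),
               strand = unlist(e$strand), stringsAsFactors = FALSE)
  }
  loci <- lapply(x$loci, function(l) {
    ann <- lapply(l$annotation, function(tx) {
      list(id = tx$id, exons = to_df(tx$exons))
    })
    isoforms <- lapply(l$isoforms, function(iso) {
      list(id = iso$id, exons = to_df(iso$exons),
           weight_ctrl = iso$weight_ctrl, weight_kd = iso$weight_kd,
           nmd = isTRUE(iso$nmd))
    })
    cds <- if (!is.null(l$cds_start)) {
      setNames(as.integer(unlist(l$cds_start)), names(l$cds_start))
    } else NULL
    make_sim_locus(l$id, l$type, l$category, l$psi_ctrl, l$psi_kd,
                   l$depth, ann, isoforms,
                   nmd_depletion = l$nmd_depletion, cds_start = cds,
                   seq = if (is.null(l$seq)) NULL else l$seq)
  })
  build_scenario(loci = loci, read_length = x$read_length,
                 junction_span_frac = x$junction_span_frac,
                 noise = x$noise,
                 nb_size = if (is.null(x$nb_size)) NULL else x$nb_size,
                 chx = isTRUE(x$chx))
}
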