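---
title: "Junction-read differential splicing with psijunc: models and design choices"
author: "psijunc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-read differential splicing with psijunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psijunc)
```

# The problem

Depletion of a spliceosomal factor — the motivating case is knockdown of
the U1 snRNP-specific protein U1C in HeLa cells — changes how 5' splice
sites are recognised, and the downstream readout is a genome-wide shift
in alternative splicing: cassette exons that are skipped more (or less),
and shifts between competing 5' or 3' splice sites. With single-end
RNA-seq and one library per condition, the cleanest observable of splice
site choice is the junction read: an alignment that crosses an exon-exon
boundary and therefore unambiguously witnesses one splicing decision.
psijunc implements the whole junction-read workflow: catalog, counting,
event discovery, PSI quantification, differential calling, NMD
annotation of non-productive isoforms, donor-site strength scoring, and
a truth-bearing simulator used to validate every stage.

# Quantities and models

## PSI from junction counts

For an event with inclusion-supporting junction counts $I$ and
exclusion-supporting counts $S$, percent spliced in is

$$\Psi = \frac{I}{I + S}$$

for alternative 5'/3' splice-site events ($I$ = proximal junction, $S$ =
distal junction), and

$$\Psi = \frac{i_1 + i_2}{i_1 + i_2 + 2s}$$

for cassette exons, where $i_1, i_2$ are the two inclusion junctions and
$s$ the skipping junction. The factor 2 reflects that an included
molecule presents two junctions where a skipping molecule presents one;
with per-junction coverage proportional to molecule abundance this
estimator is unbiased for the inclusion fraction. When no supporting
read exists in either class the estimate is flagged undefined rather
than raised as an error, because absent support is a data property, not
a usage error.

## The differential test

Each event is tested with a two-by-two exact test on pooled junction
supports, (inclusion, exclusion) by (control, knockdown), and q values
are Benjamini–Hochberg adjusted across all tested events of all types
jointly. The exact test is implemented in the package by direct
hypergeometric enumeration (two-sided: the sum of all tables at the
observed margins whose probability does not exceed the observed one, with
the conventional $1 + 10^{-7}$ relative guard against floating-point
ties); `stats::fisher.test` serves as an independent cross-check in the
test suite, never as the implementation. This choice — exact test, BH at
0.05, $|\Delta\Psi| \ge 0.1$, and at least 10 supporting reads per
condition — is the package's own fixed operationalisation of a
"significant splicing change" for a design with one library per
condition; all four thresholds are exposed in `call_differential()` and
ties at a threshold count as significant ($\ge$/$\le$ semantics).
A replicate-aware dispersion model would be preferable when replicates
exist, and is deliberately out of scope.

## Event taxonomy and the six categories

Events are discovered structurally from the annotated junction catalog:

* cassette — junctions $(u,a)$, $(b,d)$ and the bridge $(u,d)$;
* alt5 — two donors sharing one acceptor; the *proximal* donor is the
  downstream one (shorter intron, nearer the acceptor);
* alt3 — one donor with two acceptors; the *proximal* acceptor is the
  upstream, intron-internal one (shorter intron, nearer the donor).

A junction triple that forms a cassette is reported as a cassette only;
its constituent shared-end pairs are not additionally reported as
alt5/alt3 events, so a locus contributes one event and category tallies
add up. Each significant call lands in one of six directional
categories (`skip_up`, `inclusion_up`, `proximal5_up`, `distal5_up`,
`proximal3_up`, `distal3_up`) determined purely by the event type and
the sign of $\Delta\Psi = \Psi_{kd} - \Psi_{ctrl}$; everything else is
`unchanged`.

## NMD annotation

Non-productive isoforms are recognised by the canonical
exon-junction-complex rule: a transcript is NMD-sensitive when its first
in-frame stop codon ends at least 50 nt (configurable) upstream of the
last exon-exon junction. The motivating case is an intron-internal
alternative acceptor that adds a PTC-bearing alternative exon ("exon
7a") between two constitutive exons: the fully spliced inclusion isoform
places the PTC far upstream of the final junction and is degraded, while
the normal two-exon product ends downstream of its only junction and is
stable. Two conventions to note: distance is measured from the *last*
base of the stop codon to the junction position (the last base of the
upstream exon, mRNA coordinates), and when several isoform models are
compatible with an event side, the maximally spliced one (most
junctions) is annotated, because EJC deposition happens on the spliced
product. The partially spliced product that retains the intron tail
downstream of the alternative exon has no junction downstream of its
stop and is therefore *not* flagged by the rule, even though such
transcripts may be unstable for other reasons — a known limitation of
any junction-based rule. Cycloheximide is modelled solely as a simulator
flag that disables NMD-dependent count depletion; no decay kinetics are
modelled.

## Donor-site scoring

5' splice sites are scored as 9-mers (3 exonic + 6 intronic bases).
Two model kinds are supported behind one interface: table-backed models
(a two-column 9-mer/score TSV, or factorized component tables combined
by summation as declared in a small manifest — the layout in which
published maximum-entropy 5'ss models are distributed) and a log2-odds
position weight matrix trained from annotated donors,
$\log_2\!\big((c_{jb} + p)/(n + 4p)\big) - \log_2 b_b$ with pseudocount
$p = 0.5$ by default. Scores are reported in the model's native
log2-odds units, unscaled. With `require_gt` (the default), sites
lacking GT at intron positions +1/+2 score $-\infty$ with a flag — the
scoring-side mirror of inactivating a donor by GT→AC mutagenesis in a
minigene. The package does not train or ship a maximum-entropy model;
when external tables are supplied the loader reproduces their scores
bit-for-bit, and the PWM is the self-contained fallback.

# Coordinates

All coordinates are 1-based inclusive, matching GTF/GFF3 and the
IRanges/GenomicRanges containers R users already reason in; we
deliberately did not introduce a 0-based internal convention, trading
one fewer conversion layer for care at the handful of `±1` sites
(junction donor/acceptor, intron offsets), each of which is pinned by a
unit test. A junction is (donor = last exonic base of the upstream exon,
acceptor = first exonic base of the downstream exon), in transcript
orientation, so `acceptor − donor − 1` is the intron length on the plus
strand. Intron-relative offsets count from the first intronic base
(= +1): an alternative acceptor whose last intronic base is at +642 puts
the first exonic base of its alternative exon at +643. Minigene
construction keeps an explicit bijective map between construct and
genomic positions, verified by round-trip property tests, and mutations
are applied only after the reference base is checked.

# The simulator: what it emulates, and what it does not

`build_scenario()` ships two presets chosen to match the emulated study
design: 105-nt single-end reads, a 30% junction-spanning read fraction,
multinomial counting noise (one library per condition, no biological
replicates), and NMD modelled as post-hoc thinning of observations from
NMD-sensitive isoforms (default factor 0.95).

* `u1_70k` — one alternative-3'ss locus with three isoforms: the
  productive two-exon product, a non-productive product using an
  acceptor 642 nt into the intron, and a low-abundance NMD-sensitive
  inclusion isoform spliced through a cryptic donor that is *absent from
  the annotation* (as cryptic sites are in real annotation sets). Truth
  PSI is 0.2175 versus 0.00554 — the 107/492 and 4/722 junction-read
  ratios of the emulated locus. The preset's depletion factor is 0.98,
  chosen so the cryptic inclusion junction is essentially undetectable
  without the CHX flag, mirroring the observation that the inclusion
  product appears only under translation block; default per-locus depth
  is 2000 junction observations. The truth-PSI convergence check in the
  test suite runs with the CHX flag on, since with depletion active the
  observable PSI sits necessarily below the configured truth.
* `fig1b_mix` — 363 signal loci in the six-category composition
  169 : 37 : 111 : 12 : 17 : 17 with $|\Delta\Psi| = 0.3$ (pairs
  $0.5 \pm 0.15$) at depth 500 by default, plus optional null loci at
  PSI 0.5/0.5 for error-rate checks.

Counts are drawn multinomially over (isoform, junction) cells with
probability proportional to isoform weight — each junction of a molecule
is covered in proportion to that molecule's abundance — which makes the
junction-ratio PSI estimators consistent for the configured isoform
fractions. Read-level simulation places reads uniformly within
junction-spanning windows (spanning with the configured probability) or
junction-free stretches, emits gapped N-CIGAR SAM, and matches the
counts model in expectation, so the extractor/simulator round trip is a
genuine two-implementation consistency check. Per-locus random streams
are derived from the master seed and the locus id, so results do not
depend on locus order.

What the simulator does *not* model: sequencing errors and quality
scores, positional/fragmentation bias, aligner artefacts, multimapping,
paired ends, overdispersion beyond the optional negative-binomial depth
mode, intron retention as an event class, and any real effect-size
distribution. Passing recovery tests therefore demonstrate that the
caller is correct *under the stated generative model* at realistic
depths and effect sizes — not that real libraries, with their mapping
biases and unannotated junctions, would be called at the same rates.

# Numerical and procedural choices

* Minimum intron length 20 nt in the catalog (configurable), rejecting
  micro-gaps that are almost always alignment noise.
* "Uniquely mapped" is operationalised as MAPQ ≥ 255, the unique-read
  sentinel of STAR-style mappers; the threshold is configurable since
  mappers differ.
* Annotated-only counting is the pipeline default; unannotated junctions
  are never silently dropped but reported as novel with per-condition
  counts. Junction strand comes from the annotation where available.
* Undefined PSI in both conditions skips an event with a logged reason;
  in one condition, the event is still tested (the exact test uses raw
  supports) but cannot pass the $\Delta\Psi$ threshold.
* BH is applied across all tested events jointly, not per event type.
* Problem sizes in the shipped checks — depth 500–5000, 363 + 2000
  loci, ~21,000 simulated reads, exhaustive exact-test sweeps to table
  total 40 plus 2000 sampled tables to total 200 — were chosen as the
  smallest sizes at which the binomial/hypergeometric error bands in the
  assertions are decisive.
* Reports carry no timestamps, so identical config + seed reruns are
  byte-identical; determinism is asserted in the suite.

# Known limitations

Single-sample-per-condition design throughout (no dispersion
estimation); no intron-retention or mutually-exclusive-exon event
types; 3' splice sites are not scored (no 23-mer acceptor model); the
NMD rule is positional only (no uORFs, no long-3'UTR triggers); GFF3
ingestion expects exon features with `Parent` attributes and ignores
everything else.
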