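# Gene models, junction catalogs, and coordinate engineering.
#
# All coordinates are 1-based inclusive, the convention of GTF/GFF3 and of
# the IRanges/GenomicRanges containers this package sits next to. Intron-
# relative offsets count from the first intronic base (= +1), so an acceptor
# whose last intronic base sits at +642 places the first exonic base of the
# downstream exon at +643.

#' Construct a genomic interval
#'
#' @param chrom Sequence (chromosome) identifier.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row data frame with class `genomic_interval` columns.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  if (!all(strand %in% c("+", "-"))) .fail("strand must be '+' or '-'")
  if (!.is_count(start) || !.is_count(end) || any(start < 1)) {
    .fail("start/end must be positive integers")
  }
  if (any(start > end)) .fail("interval start exceeds end")
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# Extract sequence from a genome accessor (named character vector or
# DNAStringSet), always on the + strand; callers reverse-complement.
.get_seq <- function(genome, chrom, start, end) {
  if (is.null(genome)) .fail("no genome sequence accessor available")
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) .fail("chromosome '%s' not in genome", chrom)
    len <- Biostrings::width(genome[chrom])
    if (start < 1 || end > len) {
      .fail("range %d-%d outside chromosome '%s' (length %d)",
            start, end, chrom, len)
    }
    return(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
  }
  if (!chrom %in% names(genome)) .fail("chromosome '%s' not in genome", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 1 || end > len) {
    .fail("range %d-%d outside chromosome '%s' (length %d)", start, end,
          chrom, len)
  }
  substr(genome[[chrom]], start, end)
}

#' Construct a gene model from an exon table
#'
#' @param exons Data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (one row per exon). Exons are re-ordered
#'   5' to 3' in transcript orientation.
#' @param genome Optional genome accessor: a named character vector or a
#'   [Biostrings::DNAStringSet] keyed by chromosome.
#' @param cds_start Optional named integer vector: mRNA-coordinate position
#'   of the translation start per transcript id.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(exons, genome = NULL, cds_start = NULL) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(exons))) {
    .fail("exon table must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(exons) == 0) .fail("gene model has no exons")
  if (any(exons$start > exons$end)) .fail("exon start exceeds end")
  exons$chrom <- as.character(exons$chrom)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  ord <- order(exons$transcript_id,
               ifelse(exons$strand == "+", 1L, -1L) * exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    if (length(unique(e$strand)) != 1L || length(unique(e$chrom)) != 1L) {
      .fail("transcript '%s' mixes chromosomes or strands", tx)
    }
    gs <- e[order(e$start), ]
    if (nrow(gs) > 1 && any(gs$start[-1] <= gs$end[-nrow(gs)])) {
      .fail("transcript '%s' has overlapping exons", tx)
    }
  }
  structure(list(exons = exons, genome = genome, cds_start = cds_start),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d transcripts, %d genes, %d exons%s\n",
              length(unique(x$exons$transcript_id)),
              length(unique(x$exons$gene_id)),
              nrow(x$exons),
              if (is.null(x$genome)) "" else ", with genome sequence"))
  invisible(x)
}

#' Load a gene annotation (GTF or GFF3)
#'
#' Exon features are grouped into transcripts; other feature types are
#' ignored. Both GTF 2.2 (`transcript_id`/`gene_id` attributes) and GFF3
#' (`Parent` attribute) dialects are accepted and yield identical models.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param genome Optional genome accessor (see [gene_model()]).
#' @return A `gene_model`.
#' @export
load_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) .fail("annotation file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) .fail("failed to parse '%s': %s",
                                           path, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0) .fail("no exon features in '%s'", path)
  if ("transcript_id" %in% names(md) && !all(is.na(md$transcript_id))) {
    tx <- as.character(md$transcript_id)
  } else if ("Parent" %in% names(md)) {
    pl <- md$Parent
    if (any(lengths(pl) != 1L)) .fail("exon with zero or multiple parents")
    tx <- sub("^transcript:", "", unlist(pl))
  } else {
    .fail("exon features carry no transcript grouping attribute")
  }
  gene <- if ("gene_id" %in% names(md) && !all(is.na(md$gene_id))) {
    as.character(md$gene_id)
  } else tx
  exons <- data.frame(transcript_id = tx, gene_id = gene,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  if (any(!exons$strand %in% c("+", "-"))) {
    .fail("exon without a defined strand in '%s'", path)
  }
  gene_model(exons, genome = genome)
}

#' Derive the splice junction catalog of a gene model
#'
#' One junction per adjacent exon pair per transcript, deduplicated across
#' transcripts. `donor` is the last exonic base of the upstream exon and
#' `acceptor` the first exonic base of the downstream exon, both in
#' transcript orientation (so `donor < acceptor` on `+`, `donor > acceptor`
#' on `-`).
#'
#' @param model A `gene_model`.
#' @param min_intron Minimum intron length in nt (default 20); shorter
#'   gaps are treated as spurious micro-introns and dropped.
#' @return Data frame with columns `chrom`, `donor`, `acceptor`, `strand`.
#' @export
junction_catalog <- function(model, min_intron = 20) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    if (nrow(e) < 2) next
    if (e$strand[1] == "+") {
      donor <- e$end[-nrow(e)]
      acceptor <- e$start[-1]
    } else {
      donor <- e$start[-nrow(e)]
      acceptor <- e$end[-1]
    }
    out[[tx]] <- data.frame(chrom = e$chrom[1], donor = donor,
                            acceptor = acceptor, strand = e$strand[1],
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  j <- do.call(rbind, out)
  j <- j[abs(j$acceptor - j$donor) - 1L >= min_intron, , drop = FALSE]
  j <- unique(j)
  j <- j[order(j$chrom, pmin(j$donor, j$acceptor),
               pmax(j$donor, j$acceptor), j$strand), , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Gap lengths between ordered retained blocks
#'
#' For minigene engineering: given the ordered, non-overlapping blocks kept
#' in a construct, returns the lengths of the deleted sequence between
#' consecutive blocks (`start[i+1] - end[i] - 1`).
#'
#' @param blocks Data frame of intervals (see [genomic_interval()]), sorted
#'   by position, all on one chromosome and strand.
#' @return Integer vector of length `nrow(blocks) - 1`.
#' @export
interval_gaps <- function(blocks) {
  if (nrow(blocks) <= 1) return(integer(0))
  if (length(unique(blocks$chrom)) != 1L ||
      length(unique(blocks$strand)) != 1L) {
    .fail("blocks must share one chromosome and strand")
  }
  if (is.unsorted(blocks$start, strictly = TRUE)) {
    .fail("blocks must be sorted by start position")
  }
  gaps <- blocks$start[-1] - blocks$end[-nrow(blocks)] - 1L
  if (any(gaps < 0)) .fail("blocks overlap")
  as.integer(gaps)
}

#' Convert a genomic position to an intron-relative offset
#'
#' Offsets are 1-based from the first intronic base in transcript
#' orientation: the first intronic base is +1 and the last intronic base is
#' the intron length.
#'
#' @param pos Genomic position inside the intron.
#' @param intron A one-row interval (see [genomic_interval()]).
#' @return Integer offset.
#' @seealso [intron_offset_to_genome()] for the inverse.
#' @export
genome_to_intron_offset <- function(pos, intron) {
  if (any(pos < intron$start | pos > intron$end)) {
    .fail("position outside intron %d-%d", intron$start, intron$end)
  }
  if (intron$strand == "+") {
    as.integer(pos - intron$start + 1L)
  } else {
    as.integer(intron$end - pos + 1L)
  }
}

#' Convert an intron-relative offset back to a genomic position
#'
#' @param offset 1-based offset from the first intronic base.
#' @param intron A one-row interval.
#' @return Genomic position.
#' @export
intron_offset_to_genome <- function(offset, intron) {
  len <- intron$end - intron$start + 1L
  if (any(offset < 1 | offset > len)) {
    .fail("offset outside intron of length %d", len)
  }
  if (intron$strand == "+") {
    as.integer(intron$start + offset - 1L)
  } else {
    as.integer(intron$end - offset + 1L)
  }
}

#' Build a minigene construct by fusing retained blocks
#'
#' Concatenates the sequences of the retained genomic blocks (in transcript
#' orientation), keeps an exact bijective map between construct positions
#' and retained genomic positions, and applies point mutations with
#' reference-base verification.
#'
#' @param model A `gene_model` with a genome accessor, or a genome accessor
#'   itself (named character vector / `DNAStringSet`).
#' @param retained Data frame of retained blocks (sorted, non-overlapping,
#'   one chromosome/strand).
#' @param mutations Optional data frame with columns `pos` (genomic), `ref`,
#'   `alt` (single bases).
#' @param name Construct name.
#' @return Object of class `minigene` with elements `name`, `blocks`,
#'   `sequence`, `map` (data frame `construct_pos`, `chrom`, `genomic_pos`),
#'   and `mutations`.
#' @export
build_minigene <- function(model, retained, mutations = NULL,
                           name = "minigene") {
  genome <- if (inherits(model, "gene_model")) model$genome else model
  interval_gaps(retained)  # validates ordering/overlap
  strand <- retained$strand[1]
  chrom <- retained$chrom[1]
  segs <- vapply(seq_len(nrow(retained)), function(i) {
    .get_seq(genome, chrom, retained$start[i], retained$end[i])
  }, character(1))
  gpos <- unlist(lapply(seq_len(nrow(retained)), function(i) {
    seq.int(retained$start[i], retained$end[i])
  }))
  if (strand == "-") {
    segs <- rev(revcomp(segs))
    gpos <- rev(gpos)
  }
  seqs <- paste(segs, collapse = "")
  map <- data.frame(construct_pos = seq_along(gpos), chrom = chrom,
                    genomic_pos = gpos, stringsAsFactors = FALSE)
  if (!is.null(mutations) && nrow(mutations) > 0) {
    ch <- strsplit(seqs, "")[[1]]
    for (i in seq_len(nrow(mutations))) {
      cp <- map$construct_pos[match(mutations$pos[i], map$genomic_pos)]
      if (is.na(cp)) .fail("mutation position %d not retained",
                           mutations$pos[i])
      have <- ch[cp]
      want <- if (strand == "-") revcomp(mutations$ref[i]) else mutations$ref[i]
      if (have != want) {
        .fail("reference mismatch at genomic position %d: construct has %s, mutation expects %s",
              mutations$pos[i], have, mutations$ref[i])
      }
      ch[cp] <- if (strand == "-") revcomp(mutations$alt[i]) else mutations$alt[i]
    }
    seqs <- paste(ch, collapse = "")
  }
  structure(list(name = name, blocks = retained, sequence = seqs, map = map,
                 mutations = mutations),
            class = "minigene")
}

#' @export
print.minigene <- function(x, ...) {
  cat(sprintf("minigene '%s': %d blocks, fused length %d nt, %d mutation(s)\n",
              x$name, nrow(x$blocks), nchar(x$sequence),
              if (is.null(x$mutations)) 0L else nrow(x$mutations)))
  invisible(x)
}

#' Map construct positions to genomic positions (and back)
#'
#' @param mg A `minigene`.
#' @param construct_pos,genomic_pos Positions to convert (give exactly one).
#' @return Integer vector of mapped positions.
#' @export
minigene_map <- function(mg, construct_pos = NULL, genomic_pos = NULL) {
  if (!is.null(construct_pos)) {
    idx <- match(construct_pos, mg$map$construct_pos)
    if (anyNA(idx)) .fail("construct position outside construct")
    return(mg$map$genomic_pos[idx])
  }
  idx <- match(genomic_pos, mg$map$genomic_pos)
  if (anyNA(idx)) .fail("genomic position not retained in construct")
  mg$map$construct_pos[idx]
}

#' Inactivate 5' splice sites by GT to AC substitution
#'
#' @param seqs Nucleotide string.
#' @param donor_positions Positions of the first intronic base (the G of the
#'   GT dinucleotide) of each donor to inactivate.
#' @return The mutated sequence; length unchanged, exactly two substitutions
#'   per site.
#' @export
apply_donor_mutations <- function(seqs, donor_positions) {
  if (length(donor_positions) == 0) return(seqs)
  ch <- strsplit(seqs, "")[[1]]
  for (p in donor_positions) {
    if (p < 1 || p + 1 > length(ch)) .fail("donor position %d out of range", p)
    if (ch[p] != "G" || ch[p + 1] != "T") {
      .fail("no GT dinucleotide at position %d (found %s%s)",
            p, ch[p], ch[p + 1])
    }
    ch[p] <- "A"
    ch[p + 1] <- "C"
  }
  paste(ch, collapse = "")
}

#' Write a minigene as FASTA plus a coordinate-map sidecar
#'
#' @param mg A `minigene`.
#' @param fasta_path Output FASTA path.
#' @param map_path Output TSV path (`construct_pos`, `chrom`, `genomic_pos`).
#' @export
write_minigene <- function(mg, fasta_path, map_path) {
  dna <- Biostrings::DNAStringSet(setNames(mg$sequence, mg$name))
  Biostrings::writeXStringSet(dna, fasta_path)
  write.table(mg$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mg)
}
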