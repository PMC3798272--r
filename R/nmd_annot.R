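# Mature isoform assembly, ORF stop scanning, and NMD-sensitivity
# classification under the 50-nt rule: a transcript is predicted to be
# degraded by nonsense-mediated decay when its first in-frame stop codon
# ends at least `threshold` nt (default 50) upstream of the last exon-exon
# junction, the canonical exon-junction-complex model of PTC recognition.

#' Construct a mature transcript
#'
#' @param sequence Spliced mRNA sequence (A/C/G/T).
#' @param junctions mRNA-coordinate positions of exon-exon junctions (the
#'   last base of each upstream exon), strictly increasing.
#' @param cds_start mRNA position of the translation start (the A of ATG),
#'   or `NA` when unknown.
#' @param id Isoform identifier.
#' @return Object of class `mature_transcript`.
#' @export
mature_transcript <- function(sequence, junctions = integer(0),
                              cds_start = NA_integer_, id = "isoform") {
  n <- nchar(sequence)
  if (length(junctions)) {
    if (is.unsorted(junctions, strictly = TRUE)) {
      .fail("junction positions must be strictly increasing")
    }
    if (any(junctions < 1 | junctions >= n)) {
      .fail("junction positions must lie inside the sequence")
    }
  }
  if (!is.na(cds_start) && (cds_start < 1 || cds_start > n)) {
    .fail("cds_start outside sequence")
  }
  structure(list(id = id, sequence = sequence,
                 junctions = as.integer(junctions),
                 cds_start = as.integer(cds_start)),
            class = "mature_transcript")
}

#' @export
print.mature_transcript <- function(x, ...) {
  cat(sprintf("mature_transcript '%s': %d nt, %d junction(s), cds_start %s\n",
              x$id, nchar(x$sequence), length(x$junctions),
              format(x$cds_start)))
  invisible(x)
}

# Exons (genomic, transcript orientation) -> mature transcript.
.mature_from_exons <- function(exons, genome, cds_start = NA_integer_,
                               id = "isoform") {
  segs <- vapply(seq_len(nrow(exons)), function(i) {
    s <- .get_seq(genome, exons$chrom[i], exons$start[i], exons$end[i])
    if (exons$strand[i] == "-") revcomp(s) else s
  }, character(1))
  lens <- nchar(segs)
  juncs <- if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer(0)
  mature_transcript(paste(segs, collapse = ""), juncs, cds_start, id = id)
}

#' Assemble the mature sequence of an event isoform
#'
#' For `choice = "inclusion"` the transcript's exon structure is used as
#' given (it must contain the event's inclusion junctions). For
#' `choice = "exclusion"` the exons internal to the exclusion (distal)
#' junction's intron are removed, so that e.g. a cassette exon or an
#' alternative-acceptor exon is spliced out.
#'
#' @param transcript Transcript exon table (columns `chrom`, `start`,
#'   `end`, `strand`, ordered 5' to 3'), or a `gene_model` plus
#'   `transcript_id`.
#' @param event A `splice_event`.
#' @param choice `"inclusion"` or `"exclusion"`.
#' @param genome Genome accessor.
#' @param cds_start mRNA position of the translation start in the
#'   *inclusion* transcript; re-mapped for the exclusion isoform.
#' @param transcript_id Transcript to take from a `gene_model`.
#' @return A `mature_transcript`.
#' @export
splice_isoform_seq <- function(transcript, event,
                               choice = c("inclusion", "exclusion"),
                               genome = NULL, cds_start = NA_integer_,
                               transcript_id = NULL) {
  choice <- match.arg(choice)
  if (inherits(transcript, "gene_model")) {
    model <- transcript
    if (is.null(genome)) genome <- model$genome
    if (is.null(transcript_id)) .fail("transcript_id required with a gene_model")
    transcript <- model$exons[model$exons$transcript_id == transcript_id, ]
    if (is.na(cds_start) && !is.null(model$cds_start) &&
        transcript_id %in% names(model$cds_start)) {
      cds_start <- model$cds_start[[transcript_id]]
    }
  }
  if (nrow(transcript) == 0) .fail("transcript has no exons")
  tx_j <- .transcript_junctions(transcript)
  has_j <- function(j) {
    any(tx_j$donor == j$donor & tx_j$acceptor == j$acceptor)
  }
  if (choice == "inclusion") {
    ok <- all(vapply(seq_len(nrow(event$inclusion)), function(i) {
      has_j(event$inclusion[i, ])
    }, logical(1)))
    if (!ok) .fail("transcript lacks the event's inclusion junction(s)")
    return(.mature_from_exons(transcript, genome, cds_start,
                              id = paste0(event$type, ":inclusion")))
  }
  excl <- event$exclusion[1, ]
  lo <- min(excl$donor, excl$acceptor)
  hi <- max(excl$donor, excl$acceptor)
  inside <- transcript$start > lo & transcript$end < hi
  if (!any(inside)) .fail("exclusion choice incompatible: no exon inside the exclusion junction's intron")
  kept <- transcript[!inside, , drop = FALSE]
  kept_j <- .transcript_junctions(kept)
  if (!any(kept_j$donor == excl$donor & kept_j$acceptor == excl$acceptor)) {
    .fail("exclusion choice incompatible with transcript structure")
  }
  removed <- sum(transcript$end[inside] - transcript$start[inside] + 1L)
  new_cds <- cds_start
  if (!is.na(cds_start)) {
    # mRNA offset of the removed block within the inclusion isoform
    lens <- transcript$end - transcript$start + 1L
    offs <- cumsum(c(0L, lens[-length(lens)]))
    first_removed <- which(inside)[1]
    if (cds_start > offs[first_removed]) {
      if (cds_start <= offs[first_removed] + removed) {
        .fail("translation start lies inside the excluded exon(s)")
      }
      new_cds <- cds_start - removed
    }
  }
  .mature_from_exons(kept, genome, new_cds,
                     id = paste0(event$type, ":exclusion"))
}

.transcript_junctions <- function(exons) {
  if (nrow(exons) < 2) {
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  }
  if (exons$strand[1] == "+") {
    data.frame(donor = exons$end[-nrow(exons)], acceptor = exons$start[-1])
  } else {
    data.frame(donor = exons$start[-nrow(exons)], acceptor = exons$end[-1])
  }
}

#' First in-frame stop codon of a mature transcript
#'
#' Scans codons from `cds_start`; returns the 1-based mRNA position of the
#' first base of the first TAA/TAG/TGA encountered in frame, or `NA` when
#' the open reading frame runs off the end of the sequence.
#'
#' @param mt A `mature_transcript` with `cds_start` set.
#' @return Integer position or `NA`.
#' @export
scan_orf_stop <- function(mt) {
  if (is.na(mt$cds_start)) .fail("cds_start not set")
  s <- mt$sequence
  n <- nchar(s)
  if (mt$cds_start < 1 || mt$cds_start > n) .fail("cds_start outside sequence")
  pos <- mt$cds_start
  while (pos + 2 <= n) {
    codon <- substr(s, pos, pos + 2)
    if (codon %in% c("TAA", "TAG", "TGA")) return(pos)
    pos <- pos + 3L
  }
  NA_integer_
}

#' Classify a mature transcript for NMD sensitivity (50-nt rule)
#'
#' @param mt A `mature_transcript`.
#' @param threshold Minimum distance (nt) from the last base of the stop
#'   codon to the last exon-exon junction for NMD targeting (default 50).
#' @return List of class `ptc_annotation`: `id`, `stop_pos` (first base of
#'   the stop codon or `NA`), `last_junction`, `distance` (junction minus
#'   stop-codon end), `nmd_sensitive`, `threshold`.
#' @export
classify_nmd <- function(mt, threshold = 50) {
  stop_pos <- scan_orf_stop(mt)
  last_j <- if (length(mt$junctions)) max(mt$junctions) else NA_integer_
  distance <- if (!is.na(stop_pos) && !is.na(last_j)) {
    last_j - (stop_pos + 2L)
  } else NA_integer_
  sensitive <- !is.na(distance) && distance >= threshold
  structure(list(id = mt$id, stop_pos = stop_pos, last_junction = last_j,
                 distance = distance, nmd_sensitive = sensitive,
                 threshold = threshold),
            class = "ptc_annotation")
}

#' @export
print.ptc_annotation <- function(x, ...) {
  cat(sprintf("ptc_annotation '%s': stop at %s, last junction %s, distance %s nt -> %s (rule: >= %g nt)\n",
              x$id, format(x$stop_pos), format(x$last_junction),
              format(x$distance),
              if (x$nmd_sensitive) "NMD-sensitive" else "productive",
              x$threshold))
  invisible(x)
}

#' Write PTC annotations as TSV
#'
#' @param annotations List of `ptc_annotation`s.
#' @param path Output path.
#' @export
write_nmd_annotations <- function(annotations, path) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(isoform = a$id, stop_pos = a$stop_pos,
               last_junction = a$last_junction, distance = a$distance,
               nmd_sensitive = a$nmd_sensitive, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
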