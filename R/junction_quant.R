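# Junction read counting from spliced SAM alignments and junction tables.
#
# A "junction read" is an alignment whose CIGAR carries one or more N
# (reference skip) operations; each N contributes one junction observation
# with donor = last aligned reference base before the skip and acceptor =
# first aligned reference base after it. Only uniquely mapped reads are
# counted, following the convention of junction-based splicing studies;
# uniqueness is operationalised as a mapping-quality threshold (STAR and
# kin flag unique alignments with MAPQ 255).

#' Construct a junction-counts container
#'
#' @param counts Data frame with columns `chrom`, `donor`, `acceptor`,
#'   `strand`, `count` (non-negative integers).
#' @param sample Sample identifier.
#' @param total_unique,total_junction Totals of uniquely mapped and
#'   junction-spanning reads (may be `NA` when unknown, e.g. for tables).
#' @return Object of class `junction_counts`.
#' @export
junction_counts <- function(counts, sample = "sample",
                            total_unique = NA_real_,
                            total_junction = NA_real_) {
  need <- c("chrom", "donor", "acceptor", "strand", "count")
  if (!all(need %in% names(counts))) {
    .fail("counts must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(counts) > 0 && !.is_count(counts$count)) {
    .fail("junction counts must be non-negative integers")
  }
  if (!is.na(total_unique) && !is.na(total_junction) &&
      total_junction > total_unique) {
    .fail("junction-spanning reads exceed uniquely mapped reads")
  }
  counts <- counts[order(counts$chrom, pmin(counts$donor, counts$acceptor),
                         pmax(counts$donor, counts$acceptor)), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(sample = sample, counts = counts,
                 total_unique = total_unique,
                 total_junction = total_junction),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts '%s': %d junctions, %s observations (unique reads: %s, junction-spanning: %s)\n",
              x$sample, nrow(x$counts),
              format(sum(x$counts$count)),
              format(x$total_unique), format(x$total_junction)))
  invisible(x)
}

# Parse plain-text SAM into a data frame of primary fields. Accepts a file
# path, a connection, or a character vector of SAM lines.
read_sam <- function(path) {
  lines <- if (inherits(path, "connection")) {
    readLines(path)
  } else if (length(path) == 1 && !grepl("\t", path) && file.exists(path)) {
    readLines(path)
  } else {
    path
  }
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(data.frame(qname = character(), flag = integer(),
                      chrom = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 11L
  if (any(short)) .fail("malformed SAM record at line %d",
                        which(short)[1])
  data.frame(qname = vapply(f, `[`, "", 1L),
             flag = as.integer(vapply(f, `[`, "", 2L)),
             chrom = vapply(f, `[`, "", 3L),
             pos = as.integer(vapply(f, `[`, "", 4L)),
             mapq = as.integer(vapply(f, `[`, "", 5L)),
             cigar = vapply(f, `[`, "", 6L),
             stringsAsFactors = FALSE)
}

# Split a CIGAR string into (length, op) pairs.
.parse_cigar <- function(cigar) {
  ops <- gsub("[0-9]+", "", cigar)
  lens <- suppressWarnings(
    as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " ")[[1]]))
  ops <- strsplit(ops, "")[[1]]
  if (length(ops) == 0 || length(ops) != length(lens) || anyNA(lens) ||
      !all(ops %in% c("M", "I", "D", "N", "S", "H", "=", "X"))) {
    .fail("invalid CIGAR '%s'", cigar)
  }
  list(ops = ops, lens = lens)
}

#' Extract junction counts from spliced SAM alignments
#'
#' @param sam Path to a plain-text SAM file, or a data frame as returned by
#'   the internal reader (columns `flag`, `chrom`, `pos`, `mapq`, `cigar`).
#' @param sample Sample identifier.
#' @param min_mapq Mapping-quality threshold defining "uniquely mapped"
#'   (default 255, the unique-alignment sentinel used by STAR-style
#'   mappers).
#' @param catalog Optional junction catalog (see [junction_catalog()]);
#'   when given, junction strands are taken from matching annotated
#'   junctions (unannotated junctions are recorded unstranded).
#' @return A `junction_counts` object. Records with invalid CIGAR strings
#'   are skipped with a warning and reported in the `skipped` element.
#' @export
junctions_from_sam <- function(sam, sample = "sample", min_mapq = 255,
                               catalog = NULL) {
  if (is.character(sam)) sam <- read_sam(sam)
  mapped <- bitwAnd(sam$flag, 4L) == 0L
  unique_ok <- mapped & !is.na(sam$mapq) & sam$mapq >= min_mapq
  recs <- sam[unique_ok, , drop = FALSE]
  skipped <- 0L
  obs <- vector("list", nrow(recs))
  n_span <- 0L
  for (i in seq_len(nrow(recs))) {
    cig <- tryCatch(.parse_cigar(recs$cigar[i]), error = function(e) NULL)
    if (is.null(cig)) {
      skipped <- skipped + 1L
      next
    }
    ref <- recs$pos[i]
    jl <- list()
    for (k in seq_along(cig$ops)) {
      op <- cig$ops[k]
      len <- cig$lens[k]
      if (op %in% c("M", "D", "=", "X")) {
        ref <- ref + len
      } else if (op == "N") {
        jl[[length(jl) + 1L]] <- c(ref - 1L, ref + len)
        ref <- ref + len
      }
      # I, S, H, P consume no reference bases
    }
    if (length(jl) > 0) {
      n_span <- n_span + 1L
      obs[[i]] <- data.frame(chrom = recs$chrom[i],
                             donor = vapply(jl, `[`, 0, 1L),
                             acceptor = vapply(jl, `[`, 0, 2L),
                             stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) {
    warning(sprintf("%d record(s) with invalid CIGAR skipped", skipped))
  }
  obs <- do.call(rbind, obs)
  if (is.null(obs) || nrow(obs) == 0) {
    counts <- data.frame(chrom = character(), donor = integer(),
                         acceptor = integer(), strand = character(),
                         count = integer(), stringsAsFactors = FALSE)
  } else {
    key <- paste(obs$chrom, obs$donor, obs$acceptor, sep = ":")
    agg <- table(key)
    first <- obs[!duplicated(key), , drop = FALSE]
    first <- first[match(names(agg), paste(first$chrom, first$donor,
                                           first$acceptor, sep = ":")), ]
    counts <- data.frame(chrom = first$chrom, donor = first$donor,
                         acceptor = first$acceptor, strand = "*",
                         count = as.integer(agg), stringsAsFactors = FALSE)
  }
  if (!is.null(catalog) && nrow(counts) > 0) {
    counts$strand <- .assign_strand(counts, catalog)
  }
  out <- junction_counts(counts, sample = sample,
                         total_unique = sum(unique_ok) - skipped,
                         total_junction = n_span)
  out$skipped <- skipped
  out
}

# Strand from annotation where the (chrom, donor, acceptor) pair matches in
# either orientation; "*" otherwise.
.assign_strand <- function(counts, catalog) {
  key_fwd <- paste(catalog$chrom, catalog$donor, catalog$acceptor)
  key_rev <- paste(catalog$chrom, catalog$acceptor, catalog$donor)
  k1 <- paste(counts$chrom, counts$donor, counts$acceptor)
  s <- catalog$strand[match(k1, key_fwd)]
  s2 <- catalog$strand[match(k1, key_rev)]
  s[is.na(s)] <- s2[is.na(s)]
  s[is.na(s)] <- "*"
  s
}

#' Restrict junction counts to annotated junctions
#'
#' @param jc A `junction_counts` object.
#' @param catalog Annotated junction catalog.
#' @return List with elements `annotated` (a `junction_counts` restricted to
#'   catalog junctions, with strands assigned and donor/acceptor oriented as
#'   annotated) and `novel` (data frame of the remaining junctions).
#' @export
filter_annotated <- function(jc, catalog) {
  cts <- jc$counts
  key_fwd <- paste(catalog$chrom, catalog$donor, catalog$acceptor)
  key_rev <- paste(catalog$chrom, catalog$acceptor, catalog$donor)
  k <- paste(cts$chrom, cts$donor, cts$acceptor)
  hit_fwd <- match(k, key_fwd)
  hit_rev <- match(k, key_rev)
  is_ann <- !is.na(hit_fwd) | !is.na(hit_rev)
  ann <- cts[is_ann, , drop = FALSE]
  if (nrow(ann) > 0) {
    hf <- hit_fwd[is_ann]
    hr <- hit_rev[is_ann]
    flip <- is.na(hf)
    idx <- ifelse(flip, hr, hf)
    ann$strand <- catalog$strand[idx]
    tmp <- ann$donor[flip]
    ann$donor[flip] <- ann$acceptor[flip]
    ann$acceptor[flip] <- tmp
  }
  res <- junction_counts(ann, sample = jc$sample,
                         total_unique = jc$total_unique,
                         total_junction = jc$total_junction)
  list(annotated = res, novel = cts[!is_ann, , drop = FALSE])
}

#' Load a junction-count table
#'
#' Two dialects are accepted: the STAR `SJ.out.tab` layout (chrom, first and
#' last intronic base, strand code 0/1/2 or `+`/`-`, intron motif,
#' annotation flag, unique-read count, multi-read count, overhang) and the
#' package's native 5-column TSV (chrom, donor, acceptor, strand, count).
#' STAR intron coordinates are converted to the donor/acceptor convention
#' (donor = last exonic base, acceptor = first exonic base).
#'
#' @param path Table path.
#' @param format `"auto"` (default; by column count), `"star"`, or
#'   `"native"`.
#' @param sample Sample identifier.
#' @return A `junction_counts` object (totals are `NA` unless recorded in
#'   `#total_unique=`/`#total_junction=` comment lines).
#' @export
load_junction_counts <- function(path, format = c("auto", "star", "native"),
                                 sample = "sample") {
  format <- match.arg(format)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*=", "", hit[1])) else NA_real_
  }
  tu <- get_meta("total_unique")
  tj <- get_meta("total_junction")
  if (length(body) > 0 && startsWith(body[1], "chrom\t")) body <- body[-1]
  if (length(body) == 0) {
    return(junction_counts(data.frame(chrom = character(), donor = integer(),
                                      acceptor = integer(),
                                      strand = character(), count = integer(),
                                      stringsAsFactors = FALSE),
                           sample = sample, total_unique = tu,
                           total_junction = tj))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  ncol <- unique(lengths(f))
  if (length(ncol) != 1) {
    .fail("ragged junction table at line %d of %s",
          which(lengths(f) != lengths(f)[1L])[1L], path)
  }
  if (format == "auto") format <- if (ncol >= 9) "star" else "native"
  parse_num <- function(x, what, col) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v))
    if (length(bad)) .fail("malformed %s at line %d of %s", what, bad[1], path)
    v
  }
  if (format == "star") {
    chrom <- vapply(f, `[`, "", 1L)
    istart <- parse_num(vapply(f, `[`, "", 2L), "intron start", 2)
    iend <- parse_num(vapply(f, `[`, "", 3L), "intron end", 3)
    scode <- vapply(f, `[`, "", 4L)
    count <- parse_num(vapply(f, `[`, "", 7L), "count", 7)
    strand <- ifelse(scode %in% c("1", "+"), "+",
                     ifelse(scode %in% c("2", "-"), "-", "*"))
    donor <- ifelse(strand == "-", iend + 1L, istart - 1L)
    acceptor <- ifelse(strand == "-", istart - 1L, iend + 1L)
  } else {
    if (ncol != 5) .fail("native junction table must have 5 columns")
    chrom <- vapply(f, `[`, "", 1L)
    donor <- parse_num(vapply(f, `[`, "", 2L), "donor", 2)
    acceptor <- parse_num(vapply(f, `[`, "", 3L), "acceptor", 3)
    strand <- vapply(f, `[`, "", 4L)
    count <- parse_num(vapply(f, `[`, "", 5L), "count", 5)
  }
  if (any(count < 0)) {
    .fail("negative count at line %d of %s", which(count < 0)[1], path)
  }
  junction_counts(data.frame(chrom = chrom, donor = as.integer(donor),
                             acceptor = as.integer(acceptor),
                             strand = strand, count = count,
                             stringsAsFactors = FALSE),
                  sample = sample, total_unique = tu, total_junction = tj)
}

#' Write junction counts as the native 5-column TSV
#'
#' Totals are preserved in `#total_unique=` / `#total_junction=` comment
#' lines so that a write/read round trip is lossless.
#'
#' @param jc A `junction_counts` object.
#' @param path Output path.
#' @export
write_junction_counts <- function(jc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(jc$total_unique)) {
    writeLines(sprintf("#total_unique=%s", format(jc$total_unique,
                                                  scientific = FALSE)), con)
  }
  if (!is.na(jc$total_junction)) {
    writeLines(sprintf("#total_junction=%s", format(jc$total_junction,
                                                    scientific = FALSE)), con)
  }
  writeLines("chrom\tdonor\tacceptor\tstrand\tcount", con)
  if (nrow(jc$counts) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d", jc$counts$chrom,
                       jc$counts$donor, jc$counts$acceptor,
                       jc$counts$strand, jc$counts$count), con)
  }
  invisible(jc)
}

#' Fraction of uniquely mapped reads that span a splice junction
#'
#' @param jc A `junction_counts` object with recorded totals.
#' @return Numeric fraction in `[0, 1]`.
#' @export
spliced_read_fraction <- function(jc) {
  if (is.na(jc$total_unique) || is.na(jc$total_junction)) {
    .fail("totals not recorded for sample '%s'", jc$sample)
  }
  if (jc$total_unique == 0) .fail("zero uniquely mapped reads")
  jc$total_junction / jc$total_unique
}

#' Per-base read coverage over a region
#'
#' Depth counts aligned (M/=/X) bases only; N gaps and clipped bases
#' contribute nothing.
#'
#' @param sam SAM path or data frame (see [junctions_from_sam()]).
#' @param region One-row interval (see [genomic_interval()]).
#' @param min_mapq Mapping-quality filter (default 0: all mapped reads).
#' @return Object of class `coverage_track`: list with `region` and `depth`
#'   (integer vector of length `end - start + 1`).
#' @export
region_coverage <- function(sam, region, min_mapq = 0) {
  if (is.character(sam)) sam <- read_sam(sam)
  if (region$start < 1) .fail("region start below 1")
  n <- region$end - region$start + 1L
  depth <- integer(n)
  keep <- bitwAnd(sam$flag, 4L) == 0L & sam$chrom == region$chrom &
    !is.na(sam$mapq) & sam$mapq >= min_mapq
  recs <- sam[keep, , drop = FALSE]
  for (i in seq_len(nrow(recs))) {
    cig <- .parse_cigar(recs$cigar[i])
    ref <- recs$pos[i]
    for (k in seq_along(cig$ops)) {
      op <- cig$ops[k]
      len <- cig$lens[k]
      if (op %in% c("M", "=", "X")) {
        a <- max(ref, region$start)
        b <- min(ref + len - 1L, region$end)
        if (a <= b) {
          idx <- (a - region$start + 1L):(b - region$start + 1L)
          depth[idx] <- depth[idx] + 1L
        }
        ref <- ref + len
      } else if (op %in% c("D", "N")) {
        ref <- ref + len
      }
    }
  }
  structure(list(region = region, depth = depth), class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' @param cov A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  d <- cov$depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g0 <- cov$region$start - 1L  # bedGraph is 0-based half-open
  lines <- sprintf("%s\t%d\t%d\t%d", cov$region$chrom,
                   g0 + starts - 1L, g0 + ends, r$values)
  writeLines(lines, path)
  invisible(cov)
}
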