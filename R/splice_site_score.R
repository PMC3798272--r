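# 5' splice-site (donor) scoring. A donor site is the 9-mer spanning the
# exon/intron boundary: 3 exonic + 6 intronic nt (positions -3..-1, +1..+6),
# with the canonical GT at intron positions +1/+2. Scoring models are
# either table-backed (9-mer -> score, optionally factorized into component
# tables composed by summation, the dialect of published maximum-entropy
# 5'ss models) or position weight matrices of log2-odds trained from
# annotated donors. Scores are reported in the model's native log2-odds
# units.

DNA_BASES <- c("A", "C", "G", "T")

#' Extract the 9-mer donor site of a junction
#'
#' @param genome Genome accessor (named character vector / `DNAStringSet`).
#' @param junction One-row junction data frame (`chrom`, `donor`,
#'   `acceptor`, `strand`); `donor` is the last exonic base.
#' @param label Site label.
#' @param strict In strict mode (default) ambiguity characters are an
#'   error; otherwise `NULL` is returned for ambiguous windows.
#' @return Object of class `donor_site`: `ninemer` (transcript
#'   orientation), `boundary` (genomic position of the last exonic base),
#'   `strand`, `label`.
#' @export
extract_donor_site <- function(genome, junction, label = NULL,
                               strict = TRUE) {
  d <- junction$donor
  chrom <- junction$chrom
  if (junction$strand == "+") {
    ninemer <- .get_seq(genome, chrom, d - 2L, d + 6L)
  } else {
    ninemer <- revcomp(.get_seq(genome, chrom, d - 6L, d + 2L))
  }
  if (!grepl("^[ACGT]{9}$", ninemer)) {
    if (strict) .fail("ambiguous base in donor window at %s:%d", chrom, d)
    return(NULL)
  }
  structure(list(ninemer = ninemer, boundary = d, chrom = chrom,
                 strand = junction$strand,
                 label = if (is.null(label)) sprintf("%s:%d", chrom, d)
                         else label),
            class = "donor_site")
}

#' @export
print.donor_site <- function(x, ...) {
  cat(sprintf("donor_site '%s': %s|%s (%s:%d, %s strand)\n", x$label,
              substr(x$ninemer, 1, 3), substr(x$ninemer, 4, 9),
              x$chrom, x$boundary, x$strand))
  invisible(x)
}

.donor_model <- function(kind, table = NULL, components = NULL, pwm = NULL,
                         background = NULL, require_gt = TRUE) {
  structure(list(kind = kind, table = table, components = components,
                 pwm = pwm, background = background,
                 require_gt = require_gt),
            class = "donor_model")
}

#' @export
print.donor_model <- function(x, ...) {
  desc <- switch(x$kind,
                 table = sprintf("table (%d 9-mers)", length(x$table)),
                 composite = sprintf("factorized table (%d components)",
                                     length(x$components)),
                 pwm = "position weight matrix (9 x 4 log2-odds)")
  cat(sprintf("donor_model: %s, require_gt = %s\n", desc, x$require_gt))
  invisible(x)
}

#' Load a donor scoring model from disk
#'
#' Three on-disk dialects:
#' \itemize{
#'   \item two-column TSV `ninemer<TAB>score` (strict table model: querying
#'     a 9-mer absent from the table is an error);
#'   \item a manifest TSV with header `file<TAB>positions` naming component
#'     tables (each two-column `kmer<TAB>score` over the sub-positions
#'     given as e.g. `1-3`); the composed score is the sum of the component
#'     scores, the composition rule of factorized maximum-entropy models;
#'   \item a PWM file written by [write_donor_model()] (marker line
#'     `#pwm`).
#' }
#'
#' @param path Model (or manifest) path.
#' @param format `"auto"`, `"table"`, `"manifest"`, or `"pwm"`.
#' @param require_gt Require GT at intron positions +1/+2 when scoring.
#' @return A `donor_model`.
#' @export
load_donor_model <- function(path, format = c("auto", "table", "manifest",
                                              "pwm"),
                             require_gt = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (length(lines) && lines[1] == "#pwm") {
      "pwm"
    } else if (length(lines) && startsWith(lines[1], "file\t")) {
      "manifest"
    } else "table"
  }
  if (format == "pwm") {
    return(.read_pwm_model(lines, require_gt))
  }
  if (format == "table") {
    tab <- .read_score_table(lines, path, kmer_len = 9)
    return(.donor_model("table", table = tab, require_gt = require_gt))
  }
  # manifest
  if (!length(lines) || !startsWith(lines[1], "file\t")) {
    .fail("malformed manifest '%s': expected header 'file<TAB>positions'",
          path)
  }
  rows <- strsplit(lines[-1][nzchar(lines[-1])], "\t", fixed = TRUE)
  if (any(lengths(rows) != 2)) .fail("malformed manifest row in '%s'", path)
  comps <- lapply(rows, function(r) {
    rng <- as.integer(strsplit(r[2], "-", fixed = TRUE)[[1]])
    if (anyNA(rng)) .fail("malformed positions '%s' in manifest", r[2])
    pos <- if (length(rng) == 2) rng[1]:rng[2] else rng
    if (any(pos < 1 | pos > 9)) .fail("component positions outside 1..9")
    fp <- file.path(dirname(path), r[1])
    list(positions = pos,
         table = .read_score_table(readLines(fp), fp,
                                   kmer_len = length(pos)))
  })
  .donor_model("composite", components = comps, require_gt = require_gt)
}

.read_score_table <- function(lines, path, kmer_len) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 2)) {
    .fail("malformed score table at line %d of %s",
          which(lengths(f) != 2)[1], path)
  }
  kmers <- vapply(f, `[`, "", 1L)
  scores <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  if (anyNA(scores)) {
    .fail("non-numeric score at line %d of %s", which(is.na(scores))[1], path)
  }
  if (any(nchar(kmers) != kmer_len)) {
    .fail("k-mer of wrong length at line %d of %s",
          which(nchar(kmers) != kmer_len)[1], path)
  }
  setNames(scores, kmers)
}

.read_pwm_model <- function(lines, require_gt) {
  lines <- lines[nzchar(lines)]
  bg_line <- grep("^#background\t", lines, value = TRUE)
  if (!length(bg_line)) .fail("pwm model lacks a #background line")
  background <- as.numeric(strsplit(bg_line, "\t")[[1]][-1])
  body <- lines[!startsWith(lines, "#")]
  mat <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (nrow(mat) != 9 || ncol(mat) != 4) .fail("pwm must be 9 x 4")
  colnames(mat) <- DNA_BASES
  .donor_model("pwm", pwm = mat, background = background,
               require_gt = require_gt)
}

#' Write a donor model to disk
#'
#' Table models are written as two-column TSV; PWM models with a `#pwm`
#' marker, `#background` line, and the 9x4 log2-odds matrix.
#'
#' @param model A `donor_model` (table or pwm kind).
#' @param path Output path.
#' @export
write_donor_model <- function(model, path) {
  if (model$kind == "table") {
    writeLines(sprintf("%s\t%.10g", names(model$table), model$table), path)
  } else if (model$kind == "pwm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#pwm", con)
    writeLines(paste(c("#background", sprintf("%.10g", model$background)),
                     collapse = "\t"), con)
    writeLines(apply(model$pwm, 1, function(r) {
      paste(sprintf("%.10g", r), collapse = "\t")
    }), con)
  } else {
    .fail("only table and pwm models can be serialized directly")
  }
  invisible(model)
}

#' Score a donor site
#'
#' @param model A `donor_model`.
#' @param site A `donor_site` or a 9-mer character string.
#' @return List with `score` (log2-odds; `-Inf` when `require_gt` is set
#'   and the site lacks GT at +1/+2) and `gt_ok`.
#' @export
score_donor <- function(model, site) {
  ninemer <- if (inherits(site, "donor_site")) site$ninemer else site
  if (!grepl("^[ACGT]{9}$", ninemer)) .fail("site must be an A/C/G/T 9-mer")
  gt_ok <- substr(ninemer, 4, 5) == "GT"
  if (model$require_gt && !gt_ok) {
    return(list(score = -Inf, gt_ok = FALSE))
  }
  score <- switch(model$kind,
    table = {
      if (!ninemer %in% names(model$table)) {
        .fail("9-mer '%s' missing from score table", ninemer)
      }
      unname(model$table[ninemer])
    },
    composite = {
      sum(vapply(model$components, function(cp) {
        km <- paste(strsplit(ninemer, "")[[1]][cp$positions], collapse = "")
        if (!km %in% names(cp$table)) {
          .fail("k-mer '%s' missing from component table", km)
        }
        unname(cp$table[km])
      }, numeric(1)))
    },
    pwm = {
      ch <- strsplit(ninemer, "")[[1]]
      sum(model$pwm[cbind(1:9, match(ch, DNA_BASES))])
    },
    .fail("unknown model kind '%s'", model$kind))
  list(score = score, gt_ok = gt_ok)
}

#' Score several donor sites into a table
#'
#' @param model A `donor_model`.
#' @param sites List of `donor_site`s (or 9-mer strings).
#' @return Data frame with `label`, `ninemer`, `score`, `gt_ok`.
#' @export
score_donors <- function(model, sites) {
  rows <- lapply(sites, function(s) {
    r <- score_donor(model, s)
    data.frame(label = if (inherits(s, "donor_site")) s$label else s,
               ninemer = if (inherits(s, "donor_site")) s$ninemer else s,
               score = r$score, gt_ok = r$gt_ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train a log2-odds PWM donor model from annotated sites
#'
#' Column-wise `log2((freq + pseudo-adjusted) / background)` with
#' frequencies `(count + pseudocount) / (n + 4 * pseudocount)`.
#' Deterministic and invariant to the order of the training set.
#'
#' @param sites List of `donor_site`s or 9-mer strings (at least 2).
#' @param pseudocount Additive pseudocount per base (default 0.5; must be
#'   positive).
#' @param background Background base frequencies (A, C, G, T; must sum
#'   to 1). Default uniform.
#' @param require_gt Require GT when scoring (default `TRUE`).
#' @return A `donor_model` of kind `pwm`.
#' @export
train_pwm_donor <- function(sites, pseudocount = 0.5,
                            background = rep(0.25, 4), require_gt = TRUE) {
  seqs <- vapply(sites, function(s) {
    if (inherits(s, "donor_site")) s$ninemer else s
  }, character(1))
  if (length(seqs) < 2) .fail("at least 2 training sites required")
  if (pseudocount <= 0) .fail("pseudocount must be positive")
  if (abs(sum(background) - 1) > 1e-8) .fail("background must sum to 1")
  if (any(nchar(seqs) != 9) || any(!grepl("^[ACGT]{9}$", seqs))) {
    .fail("training sites must be A/C/G/T 9-mers")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  pwm <- t(vapply(1:9, function(j) {
    cnt <- vapply(DNA_BASES, function(b) sum(mat[, j] == b), numeric(1))
    freq <- (unname(cnt) + pseudocount) / (n + 4 * pseudocount)
    log2(freq / background)
  }, numeric(4)))
  colnames(pwm) <- DNA_BASES
  .donor_model("pwm", pwm = pwm, background = background,
               require_gt = require_gt)
}
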