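# Alternative-splicing event discovery, PSI quantification, and
# differential calling between two conditions.
#
# Event taxonomy (junction patterns, per chromosome and strand):
#   cassette - inclusion junctions (u->a) and (b->d) plus the skipping
#              junction (u->d) over the alternative exon [a, b];
#   alt5     - two donors competing for one acceptor; the proximal donor is
#              the downstream one (shorter intron, nearer the acceptor);
#   alt3     - one donor with two acceptors; the proximal acceptor is the
#              upstream, intron-internal one (shorter intron, nearer the
#              donor).
# A junction triple that forms a cassette is reported as a cassette only;
# its constituent shared-end pairs are not additionally reported as
# alt5/alt3 events.

EVENT_CATEGORIES <- c("skip_up", "inclusion_up", "proximal5_up",
                      "distal5_up", "proximal3_up", "distal3_up",
                      "unchanged")

#' Discover alternative-splicing events from a junction catalog
#'
#' @param catalog Junction catalog data frame (see [junction_catalog()]).
#' @return List of `splice_event` objects in a deterministic order. Each
#'   event carries `type` (`cassette`, `alt5`, `alt3`), `chrom`, `strand`,
#'   `inclusion` and `exclusion` junction data frames, and an `event_id`.
#' @export
discover_events <- function(catalog) {
  events <- list()
  if (nrow(catalog) == 0) return(events)
  catalog$intron_len <- abs(catalog$acceptor - catalog$donor) - 1L
  for (grp in split(catalog,
                    paste(catalog$chrom, catalog$strand, sep = "\r"))) {
    chrom <- grp$chrom[1]
    strand <- grp$strand[1]
    key <- function(d, a) paste(d, a, sep = ":")
    jkey <- key(grp$donor, grp$acceptor)
    in_cassette <- character(0)
    # cassette: skip junction (u,d) bridged by (u,a) and (b,d)
    for (s in seq_len(nrow(grp))) {
      u <- grp$donor[s]
      d <- grp$acceptor[s]
      j1 <- grp[grp$donor == u & grp$acceptor != d &
                  .between(grp$acceptor, u, d, strand), , drop = FALSE]
      j2 <- grp[grp$acceptor == d & grp$donor != u &
                  .between(grp$donor, u, d, strand), , drop = FALSE]
      if (nrow(j1) == 0 || nrow(j2) == 0) next
      for (i1 in seq_len(nrow(j1))) {
        for (i2 in seq_len(nrow(j2))) {
          a <- j1$acceptor[i1]
          b <- j2$donor[i2]
          ok <- if (strand == "+") a <= b else a >= b
          if (!ok) next
          inc <- data.frame(chrom = chrom,
                            donor = c(u, b), acceptor = c(a, d),
                            strand = strand, stringsAsFactors = FALSE)
          exc <- data.frame(chrom = chrom, donor = u, acceptor = d,
                            strand = strand, stringsAsFactors = FALSE)
          events[[length(events) + 1L]] <- .splice_event(
            "cassette", chrom, strand, inc, exc,
            exon = c(min(a, b), max(a, b)))
          in_cassette <- c(in_cassette,
                           paste(key(u, a), key(u, d)),
                           paste(key(b, d), key(u, d)))
        }
      }
    }
    # alt3: shared donor, two acceptors (proximal = shorter intron)
    for (dn in unique(grp$donor[duplicated(grp$donor)])) {
      cand <- grp[grp$donor == dn, , drop = FALSE]
      cand <- cand[order(cand$intron_len), , drop = FALSE]
      for (i in seq_len(nrow(cand) - 1L)) {
        for (k in seq(i + 1L, nrow(cand))) {
          prox <- cand[i, , drop = FALSE]
          dist <- cand[k, , drop = FALSE]
          pair_id <- paste(key(prox$donor, prox$acceptor),
                           key(dist$donor, dist$acceptor))
          if (pair_id %in% in_cassette) next
          events[[length(events) + 1L]] <- .splice_event(
            "alt3", chrom, strand,
            prox[, c("chrom", "donor", "acceptor", "strand")],
            dist[, c("chrom", "donor", "acceptor", "strand")])
        }
      }
    }
    # alt5: shared acceptor, two donors (proximal = shorter intron)
    for (ac in unique(grp$acceptor[duplicated(grp$acceptor)])) {
      cand <- grp[grp$acceptor == ac, , drop = FALSE]
      cand <- cand[order(cand$intron_len), , drop = FALSE]
      for (i in seq_len(nrow(cand) - 1L)) {
        for (k in seq(i + 1L, nrow(cand))) {
          prox <- cand[i, , drop = FALSE]
          dist <- cand[k, , drop = FALSE]
          pair_id <- paste(key(prox$donor, prox$acceptor),
                           key(dist$donor, dist$acceptor))
          if (pair_id %in% in_cassette) next
          events[[length(events) + 1L]] <- .splice_event(
            "alt5", chrom, strand,
            prox[, c("chrom", "donor", "acceptor", "strand")],
            dist[, c("chrom", "donor", "acceptor", "strand")])
        }
      }
    }
  }
  ids <- vapply(events, `[[`, "", "event_id")
  events[order(ids)]
}

.between <- function(x, u, d, strand) {
  if (strand == "+") x > u & x < d else x < u & x > d
}

.splice_event <- function(type, chrom, strand, inclusion, exclusion,
                          exon = NULL) {
  rownames(inclusion) <- NULL
  rownames(exclusion) <- NULL
  id <- sprintf("%s:%s:%s:%s", type, chrom,
                paste(sprintf("%d-%d", inclusion$donor, inclusion$acceptor),
                      collapse = ","),
                paste(sprintf("%d-%d", exclusion$donor, exclusion$acceptor),
                      collapse = ","))
  structure(list(type = type, chrom = chrom, strand = strand,
                 inclusion = inclusion, exclusion = exclusion,
                 exon = exon, event_id = id),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("splice_event [%s] %s (%s strand)\n", x$type, x$event_id,
              x$strand))
  invisible(x)
}

.lookup_count <- function(event_junctions, jc) {
  cts <- jc$counts
  k <- paste(cts$chrom, pmin(cts$donor, cts$acceptor),
             pmax(cts$donor, cts$acceptor))
  q <- paste(event_junctions$chrom,
             pmin(event_junctions$donor, event_junctions$acceptor),
             pmax(event_junctions$donor, event_junctions$acceptor))
  hit <- match(q, k)
  out <- ifelse(is.na(hit), 0L, cts$count[hit])
  as.integer(out)
}

#' Percent spliced in (PSI) of an event from junction counts
#'
#' Cassette PSI uses the two-inclusion-junction estimator
#' `(inc1 + inc2) / (inc1 + inc2 + 2 * skip)`; alternative splice-site PSI
#' is `proximal / (proximal + distal)`. Junctions absent from the counts
#' contribute zero. When no supporting read exists the estimate is flagged
#' undefined (`psi = NA`) rather than raising an error.
#'
#' @param event A `splice_event`.
#' @param counts A `junction_counts` object.
#' @return List with `psi`, `inclusion_support`, `exclusion_support`,
#'   `defined`.
#' @export
compute_psi <- function(event, counts) {
  inc <- .lookup_count(event$inclusion, counts)
  exc <- .lookup_count(event$exclusion, counts)
  inc_total <- sum(inc)
  exc_total <- sum(exc)
  if (event$type == "cassette") {
    den <- inc_total + 2 * exc_total
  } else {
    den <- inc_total + exc_total
  }
  psi <- if (den == 0) NA_real_ else inc_total / den
  list(psi = psi, inclusion_support = inc_total,
       exclusion_support = exc_total, defined = den > 0)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p value by hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (up to a relative error of
#' 1e-7 in the comparison, the usual guard against floating-point ties).
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integer counts with at least one positive margin.
#' @return Two-sided p value.
#' @export
fisher_2x2 <- function(tab) {
  x <- as.vector(tab)
  if (length(x) != 4) .fail("table must be 2x2")
  if (!.is_count(x)) .fail("table entries must be non-negative integers")
  a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4]
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  k <- a + c_         # column 1 margin
  if (m + n == 0) .fail("all margins are zero")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Call differential splicing for a set of events
#'
#' For each event, a 2x2 exact test compares inclusion versus exclusion
#' junction supports between the two conditions; q values are
#' Benjamini-Hochberg adjusted across the whole call set (all event types
#' jointly). An event is assigned a directional category when it meets all
#' thresholds (`>=`/`<=` semantics, so ties at a threshold are called);
#' otherwise it is `unchanged`. Events with PSI undefined in both
#' conditions are skipped and logged in the `skipped` attribute.
#'
#' @param events List of `splice_event`s.
#' @param counts_ctrl,counts_kd `junction_counts` for the control and
#'   knockdown conditions.
#' @param thresholds List with `min_support` (minimum total event support
#'   per condition, default 10), `min_delta` (minimum |delta PSI|, default
#'   0.1), `max_q` (FDR level, default 0.05).
#' @return A data frame of class `splice_calls` with one row per event:
#'   id, type, coordinates, psi_ctrl, psi_kd, delta_psi (kd - ctrl),
#'   supports, p, q, category.
#' @export
call_differential <- function(events, counts_ctrl, counts_kd,
                              thresholds = list()) {
  th <- utils::modifyList(list(min_support = 10, min_delta = 0.1,
                               max_q = 0.05), thresholds)
  rows <- list()
  skipped <- character(0)
  for (ev in events) {
    pc <- compute_psi(ev, counts_ctrl)
    pk <- compute_psi(ev, counts_kd)
    if (!pc$defined && !pk$defined) {
      skipped <- c(skipped, sprintf("%s: no junction support in either condition",
                                    ev$event_id))
      next
    }
    p <- fisher_2x2(matrix(c(pc$inclusion_support, pk$inclusion_support,
                             pc$exclusion_support, pk$exclusion_support),
                           nrow = 2))
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = ev$event_id, type = ev$type, chrom = ev$chrom,
      strand = ev$strand,
      psi_ctrl = pc$psi, psi_kd = pk$psi,
      delta_psi = pk$psi - pc$psi,
      support_ctrl = pc$inclusion_support + pc$exclusion_support,
      support_kd = pk$inclusion_support + pk$exclusion_support,
      p = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    calls <- data.frame(event_id = character(), type = character(),
                        chrom = character(), strand = character(),
                        psi_ctrl = numeric(), psi_kd = numeric(),
                        delta_psi = numeric(), support_ctrl = integer(),
                        support_kd = integer(), p = numeric(),
                        q = numeric(), category = character(),
                        stringsAsFactors = FALSE)
  } else {
    calls <- do.call(rbind, rows)
    calls$q <- p.adjust(calls$p, method = "BH")
    calls$category <- mapply(classify_call, calls$type, calls$delta_psi,
                             MoreArgs = list(th = th), calls$support_ctrl,
                             calls$support_kd, calls$q)
  }
  attr(calls, "thresholds") <- th
  attr(calls, "skipped") <- skipped
  class(calls) <- c("splice_calls", "data.frame")
  calls
}

#' Category of a single differential call
#'
#' Pure function of the event type, the sign of delta PSI, and whether the
#' thresholds are met.
#'
#' @param type Event type.
#' @param delta_psi PSI difference (knockdown minus control).
#' @param support_ctrl,support_kd Total event junction support per
#'   condition.
#' @param q BH-adjusted p value.
#' @param th Threshold list (see [call_differential()]).
#' @return One of the six directional categories or `"unchanged"`.
#' @export
classify_call <- function(type, delta_psi, support_ctrl, support_kd, q,
                          th = list(min_support = 10, min_delta = 0.1,
                                    max_q = 0.05)) {
  passes <- !is.na(delta_psi) && !is.na(q) &&
    support_ctrl >= th$min_support && support_kd >= th$min_support &&
    abs(delta_psi) >= th$min_delta && q <= th$max_q
  if (!passes) return("unchanged")
  switch(type,
         cassette = if (delta_psi > 0) "inclusion_up" else "skip_up",
         alt5 = if (delta_psi > 0) "proximal5_up" else "distal5_up",
         alt3 = if (delta_psi > 0) "proximal3_up" else "distal3_up",
         .fail("unknown event type '%s'", type))
}

#' @export
print.splice_calls <- function(x, ...) {
  cat(sprintf("splice_calls: %d events tested\n", nrow(x)))
  print(tally_categories(x))
  invisible(x)
}

#' @export
summary.splice_calls <- function(object, ...) {
  th <- attr(object, "thresholds")
  cat(sprintf("Differential splicing calls (%d events)\n", nrow(object)))
  cat(sprintf("thresholds: min support %g per condition, |dPSI| >= %g, q <= %g\n",
              th$min_support, th$min_delta, th$max_q))
  print(tally_categories(object))
  sk <- attr(object, "skipped")
  if (length(sk)) cat(sprintf("%d event(s) skipped (no support)\n",
                              length(sk)))
  invisible(object)
}

#' Tally calls by category
#'
#' @param calls A `splice_calls` data frame.
#' @return Named integer vector of class `category_tally` over the six
#'   directional categories plus `unchanged`, in fixed report order.
#' @export
tally_categories <- function(calls) {
  t <- table(factor(calls$category, levels = EVENT_CATEGORIES))
  structure(setNames(as.integer(t), names(t)), class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  df <- data.frame(category = names(x), n = as.integer(x))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write calls as TSV
#'
#' @param calls A `splice_calls` data frame.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(calls)
}

#' Write a category tally as TSV
#'
#' @param tally A `category_tally`.
#' @param path Output path.
#' @export
write_tally <- function(tally, path) {
  write.table(data.frame(category = names(tally), n = as.integer(tally)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tally)
}
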