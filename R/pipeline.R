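# End-to-end orchestration: inputs (simulated or from files) -> junction
# catalog -> event discovery -> differential calls -> NMD annotation ->
# report. Single-threaded and deterministic: identical config and seed
# give identical outputs (no timestamps in the report body).

#' Build and validate a pipeline configuration
#'
#' Either a simulation scenario or a set of input files must be given.
#' File inputs: a GTF/GFF3 annotation and one junction source per
#' condition (native/STAR count table, or a plain-text SAM file, detected
#' by the `.sam` extension).
#'
#' @param scenario A `sim_scenario`, a preset name (`"u1_70k"`,
#'   `"fig1b_mix"`), or a scenario config path.
#' @param annotation Annotation path (file mode).
#' @param counts_ctrl,counts_kd Junction-count tables or SAM paths (file
#'   mode).
#' @param genome Optional FASTA path with locus sequence (enables NMD
#'   annotation and donor extraction in file mode).
#' @param thresholds Caller thresholds (see [call_differential()]).
#' @param nmd_threshold NMD rule distance in nt (default 50).
#' @param chx Cycloheximide flag forwarded to the simulator.
#' @param donor_model Optional donor model path; when given, annotated
#'   donor sites are scored.
#' @param annotated_only Restrict counting to annotated junctions (default
#'   `TRUE`); unannotated junctions are reported separately as novel.
#' @param min_mapq Uniqueness threshold for SAM inputs.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, annotation = NULL,
                            counts_ctrl = NULL, counts_kd = NULL,
                            genome = NULL, thresholds = list(),
                            nmd_threshold = 50, chx = FALSE,
                            donor_model = NULL, annotated_only = TRUE,
                            min_mapq = 255, seed = 1, out_dir = NULL) {
  if (is.character(scenario)) {
    scenario <- if (scenario %in% c("u1_70k", "fig1b_mix")) {
      build_scenario(scenario, chx = chx)
    } else {
      read_scenario(scenario)
    }
  }
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "sim_scenario"))
    scenario$chx <- chx
  } else {
    if (is.null(annotation) || is.null(counts_ctrl) || is.null(counts_kd)) {
      .fail("either a scenario or annotation + counts for both conditions must be given")
    }
    for (p in c(annotation, counts_ctrl, counts_kd, genome, donor_model)) {
      if (!is.null(p) && !file.exists(p)) .fail("input not found: %s", p)
    }
  }
  if (nmd_threshold < 0) .fail("nmd_threshold must be non-negative")
  structure(list(scenario = scenario, annotation = annotation,
                 counts_ctrl = counts_ctrl, counts_kd = counts_kd,
                 genome = genome, thresholds = thresholds,
                 nmd_threshold = nmd_threshold, chx = chx,
                 donor_model = donor_model,
                 annotated_only = annotated_only, min_mapq = min_mapq,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

.load_condition_counts <- function(path, sample, min_mapq) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    junctions_from_sam(path, sample = sample, min_mapq = min_mapq)
  } else {
    load_junction_counts(path, sample = sample)
  }
}

# Isoform models available for NMD annotation: scenario isoforms (with
# cds_start) in simulation mode, annotation transcripts otherwise.
.isoform_models <- function(config, model) {
  if (!is.null(config$scenario)) {
    out <- list()
    for (l in config$scenario$loci) {
      for (iso in l$isoforms) {
        cds <- if (!is.null(l$cds_start) && iso$id %in% names(l$cds_start)) {
          l$cds_start[[iso$id]]
        } else NA_integer_
        out[[paste(l$id, iso$id, sep = ":")]] <-
          list(id = paste(l$id, iso$id, sep = ":"), exons = iso$exons,
               cds_start = cds)
      }
    }
    out
  } else {
    out <- list()
    for (tx in unique(model$exons$transcript_id)) {
      cds <- if (!is.null(model$cds_start) && tx %in% names(model$cds_start)) {
        model$cds_start[[tx]]
      } else NA_integer_
      out[[tx]] <- list(id = tx,
                        exons = model$exons[model$exons$transcript_id == tx,
                                            c("chrom", "start", "end",
                                              "strand")],
                        cds_start = cds)
    }
    out
  }
}

.model_has_junctions <- function(iso, junctions) {
  jx <- .iso_junctions(iso)
  all(vapply(seq_len(nrow(junctions)), function(i) {
    any(jx$donor == junctions$donor[i] &
          jx$acceptor == junctions$acceptor[i])
  }, logical(1)))
}

# NMD annotation of the inclusion and exclusion isoforms of one event.
.annotate_event_nmd <- function(event, iso_models, genome, threshold) {
  res <- list(inclusion = NULL, exclusion = NULL)
  for (side in c("inclusion", "exclusion")) {
    need <- event[[side]]
    hit <- NULL
    for (im in iso_models) {
      if (im$exons$chrom[1] != event$chrom) next
      if (is.na(im$cds_start)) next
      if (.model_has_junctions(im, need)) {
        # the EJC-based rule applies to the spliced mRNA, so prefer the
        # maximally spliced compatible model (most junctions)
        if (is.null(hit) ||
            nrow(.iso_junctions(im)) > nrow(.iso_junctions(hit))) {
          hit <- im
        }
      }
    }
    if (is.null(hit)) next
    mt <- .mature_from_exons(hit$exons, genome, hit$cds_start, id = hit$id)
    res[[side]] <- classify_nmd(mt, threshold)
  }
  res
}

#' Run the full differential-splicing pipeline
#'
#' Stages, in fixed order: load or simulate junction counts; derive the
#' annotated junction catalog; (optionally) restrict counts to annotated
#' junctions, keeping the rest as novel; discover events; call
#' differential splicing; tally categories; annotate event isoforms for
#' NMD where isoform models with translation starts and sequence are
#' available; score annotated donor sites when a donor model is supplied.
#'
#' @param config A `pipeline_config`.
#' @return Object of class `run_report`. When `config$out_dir` is set,
#'   also writes `calls.tsv`, `tally.tsv`, `novel_junctions.tsv`,
#'   `nmd.tsv`, `donor_scores.tsv`, `report.tsv` and `summary.txt`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .fail("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- inputs
  genome <- NULL
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_counts(config$scenario, config$seed))
    cc <- sim$ctrl
    ck <- sim$kd
    model <- stage("annotation",
                   scenario_gene_model(config$scenario, genome = TRUE,
                                       seed = config$seed))
    genome <- model$genome
  } else {
    genome <- if (!is.null(config$genome)) {
      g <- Biostrings::readDNAStringSet(config$genome)
      names(g) <- sub("\\s.*", "", names(g))
      g
    } else NULL
    model <- stage("annotation",
                   load_annotation(config$annotation, genome = genome))
    cc <- stage("counts", .load_condition_counts(config$counts_ctrl, "ctrl",
                                                 config$min_mapq))
    ck <- stage("counts", .load_condition_counts(config$counts_kd, "kd",
                                                 config$min_mapq))
  }

  # -- catalog and annotated-only restriction
  catalog <- stage("catalog", junction_catalog(model))
  novel <- data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), count_ctrl = integer(),
                      count_kd = integer(), stringsAsFactors = FALSE)
  if (config$annotated_only) {
    fc <- filter_annotated(cc, catalog)
    fk <- filter_annotated(ck, catalog)
    novel <- merge(
      setNames(fc$novel[, c("chrom", "donor", "acceptor", "count")],
               c("chrom", "donor", "acceptor", "count_ctrl")),
      setNames(fk$novel[, c("chrom", "donor", "acceptor", "count")],
               c("chrom", "donor", "acceptor", "count_kd")),
      by = c("chrom", "donor", "acceptor"), all = TRUE)
    novel$count_ctrl[is.na(novel$count_ctrl)] <- 0L
    novel$count_kd[is.na(novel$count_kd)] <- 0L
    novel <- novel[order(novel$chrom, novel$donor, novel$acceptor), ,
                   drop = FALSE]
    rownames(novel) <- NULL
    cc <- fc$annotated
    ck <- fk$annotated
  }

  # -- events and calls
  events <- stage("discover", discover_events(catalog))
  calls <- stage("call", call_differential(events, cc, ck,
                                           config$thresholds))
  if (length(attr(calls, "skipped"))) {
    note(sprintf("%d event(s) skipped by the caller (no support)",
                 length(attr(calls, "skipped"))))
  }
  tally <- tally_categories(calls)

  # -- NMD annotation of event isoforms
  nmd <- data.frame(event_id = character(), isoform = character(),
                    side = character(), stop_pos = integer(),
                    last_junction = integer(), distance = integer(),
                    nmd_sensitive = logical(), stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    iso_models <- .isoform_models(config, model)
    rows <- list()
    for (ev in events) {
      ann <- tryCatch(
        .annotate_event_nmd(ev, iso_models, genome,
                            config$nmd_threshold),
        error = function(e) {
          note(sprintf("NMD annotation failed for %s: %s", ev$event_id,
                       conditionMessage(e)))
          NULL
        })
      if (is.null(ann)) next
      for (side in c("inclusion", "exclusion")) {
        a <- ann[[side]]
        if (is.null(a)) next
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = ev$event_id, isoform = a$id, side = side,
          stop_pos = a$stop_pos, last_junction = a$last_junction,
          distance = a$distance, nmd_sensitive = a$nmd_sensitive,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) nmd <- do.call(rbind, rows)
  }

  # -- donor scoring
  donor_scores <- NULL
  if (!is.null(config$donor_model) && !is.null(genome)) {
    dm <- stage("score-donors", load_donor_model(config$donor_model))
    sites <- list()
    for (i in seq_len(nrow(catalog))) {
      s <- tryCatch(extract_donor_site(genome, catalog[i, ],
                                       strict = FALSE),
                    error = function(e) NULL)
      if (!is.null(s)) sites[[length(sites) + 1L]] <- s
    }
    donor_scores <- if (length(sites)) score_donors(dm, sites) else NULL
  }

  report <- structure(list(
    version = as.character(packageVersion("psijunc")),
    config = .config_echo(config),
    stage_counts = c(
      junction_obs_ctrl = sum(cc$counts$count),
      junction_obs_kd = sum(ck$counts$count),
      catalog_junctions = nrow(catalog),
      novel_junctions = nrow(novel),
      events = length(events),
      calls = nrow(calls),
      significant = sum(calls$category != "unchanged"),
      nmd_annotated = nrow(nmd),
      nmd_sensitive = sum(nmd$nmd_sensitive)),
    tally = tally, calls = calls, novel_junctions = novel, nmd = nmd,
    donor_scores = donor_scores, warnings = warnings),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

.config_echo <- function(config) {
  c(mode = if (is.null(config$scenario)) "files" else "scenario",
    scenario = if (is.null(config$scenario)) "" else config$scenario$name,
    annotation = if (is.null(config$annotation)) "" else config$annotation,
    counts_ctrl = if (is.null(config$counts_ctrl)) "" else config$counts_ctrl,
    counts_kd = if (is.null(config$counts_kd)) "" else config$counts_kd,
    chx = as.character(config$chx),
    annotated_only = as.character(config$annotated_only),
    nmd_threshold = as.character(config$nmd_threshold),
    seed = as.character(config$seed))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (psijunc %s)\n", x$version))
  for (k in names(x$stage_counts)) {
    cat(sprintf("  %-20s %d\n", k, x$stage_counts[[k]]))
  }
  cat("category tally:\n")
  print(x$tally)
  if (length(x$warnings)) {
    cat("warnings:\n")
    cat(paste0("  ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a run report
#'
#' Writes the machine-readable `report.tsv` (stage counts, tally, and
#' config echo as key-value rows in stable order), the human-readable
#' `summary.txt`, and the per-stage tables (`calls.tsv`, `tally.tsv`,
#' `novel_junctions.tsv`, `nmd.tsv`, `donor_scores.tsv`). The report body
#' contains no timestamps, so reruns with identical inputs are
#' byte-identical.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return The report, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kv <- rbind(
    data.frame(key = paste0("config.", names(report$config)),
               value = unname(report$config), stringsAsFactors = FALSE),
    data.frame(key = paste0("stage.", names(report$stage_counts)),
               value = as.character(report$stage_counts),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("tally.", names(report$tally)),
               value = as.character(as.integer(report$tally)),
               stringsAsFactors = FALSE))
  write.table(kv, file.path(dir, "report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_calls(report$calls, file.path(dir, "calls.tsv"))
  write_tally(report$tally, file.path(dir, "tally.tsv"))
  write.table(report$novel_junctions, file.path(dir, "novel_junctions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$nmd, file.path(dir, "nmd.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$donor_scores)) {
    write.table(report$donor_scores, file.path(dir, "donor_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(sprintf("psijunc run report (version %s)", report$version), con)
  writeLines("", con)
  writeLines("stage counts:", con)
  for (k in names(report$stage_counts)) {
    writeLines(sprintf("  %-20s %d", k, report$stage_counts[[k]]), con)
  }
  writeLines("", con)
  writeLines("category tally:", con)
  for (k in names(report$tally)) {
    writeLines(sprintf("  %-14s %d", k, report$tally[[k]]), con)
  }
  if (length(report$warnings)) {
    writeLines("", con)
    writeLines("warnings:", con)
    writeLines(paste0("  ", report$warnings), con)
  }
  invisible(report)
}
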