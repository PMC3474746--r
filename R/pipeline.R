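# Project layer: flat key=value configuration, per-sample step execution
# with dependency checking, per-step TSV summaries and an SQLite mirror.

default_config <- function() list(
  input_dir = ".", output_dir = "mgpipe_out", samples = character(),
  readtrimfilter.method = "solexaqa", readtrimfilter.length_cutoff = 30,
  readtrimfilter.quality_cutoff = 20, readtrimfilter.five_prime = "yes",
  readtrimfilter.five_prime_sd = 2,
  screen.db = "", screen.mode = "remove", screen.length_cutoff = 30,
  screen.identity = 90, screen.paired_end_filtering = "yes",
  screenfastafile.adapters = "", screenfastafile.min_score = 16,
  coverage.genome_map = "", coverage.taxon_map = "",
  assemblyprep.ref = "", assemblyprep.min_pairs = 100,
  revision.scaftigs = "", revision.min_depth = 3, revision.majority = 0.5,
  revision.max_indel = 10, revision.span_window = 100, revision.min_scaftig = 60)

#' Read a project configuration file
#'
#' Flat `key = value` lines (`#` comments allowed); keys use step-name
#' prefixes, e.g. `readtrimfilter.length_cutoff = 30`.  A `samples` key
#' names a file with one sample id per line (or a comma-separated list).
#' Unset keys take package defaults.
#'
#' @param path configuration file path, or `NULL` for pure defaults.
#' @param ... named overrides applied after the file.
#' @return A list of class `mg_config`.
#' @export
read_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (length(cfg$samples) == 1 && is.character(cfg$samples)) {
    cfg$samples <- if (file.exists(cfg$samples)) {
      s <- trimws(readLines(cfg$samples)); s[nzchar(s)]
    } else trimws(strsplit(cfg$samples, ",")[[1]])
  }
  structure(cfg, class = c("mg_config", "list"))
}

step_dir <- function(cfg, sample, step) file.path(cfg$output_dir, sample, step)

step_done <- function(cfg, sample, step)
  file.exists(file.path(step_dir(cfg, sample, step), ".done"))

mark_done <- function(dir) { writeLines(character(), file.path(dir, ".done")) }

hq_input_step <- function(cfg, sample) {
  for (s in c("screen", "screen_fastafile", "read_trim_filter"))
    if (step_done(cfg, sample, s)) return(s)
  NULL
}

read_step_reads <- function(cfg, sample, step) {
  d <- step_dir(cfg, sample, step)
  rd <- function(f, mate) {
    p <- file.path(d, f)
    if (file.exists(p)) read_fastq(p, offset = 33L, mate = mate) else
      mg_reads(character(), character(), character(), mate)
  }
  list(pair1 = rd("pair.1.fq", 1L), pair2 = rd("pair.2.fq", 2L),
       single = rd("single.fq", 0L))
}

write_step_reads <- function(d, pair1, pair2, single) {
  write_fastq(pair1, file.path(d, "pair.1.fq"))
  write_fastq(pair2, file.path(d, "pair.2.fq"))
  write_fastq(single, file.path(d, "single.fq"))
}

require_step <- function(cfg, sample, step, needed_by) {
  if (!step_done(cfg, sample, step))
    stop(needed_by, ": ", step, " output missing for sample ", sample,
         " (run that step first)")
}

#' Run one pipeline step over every sample
#'
#' Processes samples serially and deterministically, writing step outputs
#' under `<output_dir>/<sample>/<step>/` and appending the per-sample
#' summary to `<output_dir>/summaries/<step>.tsv`.  A per-sample failure is
#' recorded in the summary and does not stop the remaining samples; a
#' missing prerequisite step raises an error naming it.
#'
#' @param cfg an [read_config()] configuration.
#' @param step one of `"read_trim_filter"`, `"screen_fastafile"`,
#'   `"screen"`, `"filter"`, `"calculate_coverage"`, `"assembly_prep"`,
#'   `"assembly_revision"`.
#' @return The step summary data.frame (one row per sample), invisibly.
#' @export
run_step <- function(cfg, step = c("read_trim_filter", "screen_fastafile",
                                   "screen", "filter", "calculate_coverage",
                                   "assembly_prep", "assembly_revision")) {
  step <- match.arg(step)
  stopifnot(length(cfg$samples) >= 1)
  rows <- list()
  for (sample in cfg$samples) {
    row <- tryCatch(run_step_sample(cfg, sample, step),
                    error = function(e) {
                      if (grepl("output missing", conditionMessage(e))) stop(e)
                      data.frame(sample = sample, error = conditionMessage(e))
                    })
    rows[[sample]] <- row
  }
  smry <- do.call(rbind_fill, rows)
  sd <- file.path(cfg$output_dir, "summaries")
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  write_tsv(smry, file.path(sd, paste0(step, ".tsv")))
  invisible(smry)
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

run_step_sample <- function(cfg, sample, step) {
  d <- step_dir(cfg, sample, step)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  fp <- filter_params(cfg$screen.length_cutoff, cfg$screen.identity,
                      identical(cfg$screen.paired_end_filtering, "yes"))
  row <- switch(step,
    read_trim_filter = {
      raw <- file.path(cfg$input_dir, sample, "raw")
      f1 <- list.files(raw, "\\.1\\.fq(\\.gz)?$", full.names = TRUE)
      f2 <- list.files(raw, "\\.2\\.fq(\\.gz)?$", full.names = TRUE)
      fs <- list.files(raw, "\\.single\\.fq(\\.gz)?$", full.names = TRUE)
      if (!length(f1) && !length(fs))
        stop("no FASTQ input under ", raw)
      cat_reads <- function(files, mate) {
        if (!length(files)) return(mg_reads(character(), character(), character(), mate))
        out <- do.call(rbind, lapply(files, read_fastq, mate = mate))
        class(out) <- c("mg_reads", "data.frame"); out
      }
      qc <- read_trim_filter(
        pair1 = if (length(f1)) cat_reads(f1, 1L) else NULL,
        pair2 = if (length(f2)) cat_reads(f2, 2L) else NULL,
        single = if (length(fs)) cat_reads(fs, 0L) else NULL,
        params = qc_params(cfg$readtrimfilter.quality_cutoff,
                           cfg$readtrimfilter.length_cutoff,
                           cfg$readtrimfilter.method,
                           identical(cfg$readtrimfilter.five_prime, "yes"),
                           cfg$readtrimfilter.five_prime_sd))
      write_step_reads(d, qc$pair1, qc$pair2, qc$single)
      write_tsv(qc$stats, file.path(d, "qc_stats.tsv"))
      cbind(data.frame(sample = sample), qc$stats)
    },
    screen_fastafile = {
      require_step(cfg, sample, "read_trim_filter", step)
      if (!nzchar(cfg$screenfastafile.adapters)) stop("screenfastafile.adapters not set")
      adapters <- read_fasta(cfg$screenfastafile.adapters)
      inp <- read_step_reads(cfg, sample, "read_trim_filter")
      res1 <- screen_fastafile(inp$pair1, adapters, cfg$screenfastafile.min_score)
      res2 <- screen_fastafile(inp$pair2, adapters, cfg$screenfastafile.min_score)
      ress <- screen_fastafile(inp$single, adapters, cfg$screenfastafile.min_score)
      flagged <- unique(c(res1$flagged$id, res2$flagged$id))
      keep <- !(inp$pair1$id %in% flagged)
      p1 <- inp$pair1[keep, , drop = FALSE]; p2 <- inp$pair2[keep, , drop = FALSE]
      class(p1) <- class(p2) <- c("mg_reads", "data.frame")
      write_step_reads(d, p1, p2, ress$clean)
      data.frame(sample = sample,
                 reads_in = nrow(inp$pair1) + nrow(inp$pair2) + nrow(inp$single),
                 reads_flagged = 2L * sum(!keep) + nrow(ress$flagged),
                 reads_clean = 2L * sum(keep) + nrow(ress$clean))
    },
    screen = {
      require_step(cfg, sample, "read_trim_filter", step)
      if (!nzchar(cfg$screen.db)) stop("screen.db not set")
      refs <- read_fasta(cfg$screen.db)
      src <- if (step_done(cfg, sample, "screen_fastafile")) "screen_fastafile"
             else "read_trim_filter"
      inp <- read_step_reads(cfg, sample, src)
      reads <- rbind(inp$pair1, inp$pair2, inp$single)
      class(reads) <- c("mg_reads", "data.frame")
      res <- screen(reads, refs, fp, cfg$screen.mode)
      out <- res$retained
      write_step_reads(d, out[out$mate == 1L, , drop = FALSE],
                       out[out$mate == 2L, , drop = FALSE],
                       out[out$mate == 0L, , drop = FALSE])
      write_sam(res$alignments, refs, file.path(d, "alignments.sam"), reads)
      write_tsv(res$per_ref_counts, file.path(d, "per_ref_counts.tsv"))
      smry <- data.frame(sample = sample, reads_in = nrow(reads),
                         reads_mapped = sum(res$alignments$mapped),
                         reads_matched = nrow(res$matched),
                         reads_retained = nrow(res$retained))
      write_tsv(smry, file.path(d, "screen_stats.tsv"))
      smry
    },
    filter = {
      require_step(cfg, sample, "screen", step)
      aln <- read_sam(file.path(step_dir(cfg, sample, "screen"), "alignments.sam"))
      kept <- filter_alignments(aln, fp)
      fa <- filter_apply(aln, kept)
      refs <- read_fasta(cfg$screen.db)
      write_sam(fa, refs, file.path(d, "filtered.sam"))
      data.frame(sample = sample, alignments_in = nrow(aln),
                 alignments_kept = nrow(fa))
    },
    calculate_coverage = {
      require_step(cfg, sample, "screen", step)
      aln <- read_sam(file.path(step_dir(cfg, sample, "screen"), "alignments.sam"))
      refs <- read_fasta(cfg$screen.db)
      kept <- filter_alignments(aln, fp)
      cov <- calculate_coverage(filter_apply(aln, kept), refs)
      gm <- if (nzchar(cfg$coverage.genome_map)) read_tsv(cfg$coverage.genome_map) else NULL
      ab_base <- genome_normalize(cov, gm, "base")
      ab_read <- genome_normalize(cov, gm, "read")
      ab_insert <- genome_normalize(cov, gm, "insert")
      write_tsv(cov, file.path(d, "coverage.tsv"))
      write_tsv(ab_base, file.path(d, "abundance.base.tsv"))
      write_tsv(ab_read, file.path(d, "abundance.read.tsv"))
      write_tsv(ab_insert, file.path(d, "abundance.insert.tsv"))
      if (nzchar(cfg$coverage.taxon_map)) {
        tm <- read_tsv(cfg$coverage.taxon_map)
        write_tsv(aggregate_by_taxon(ab_base, tm), file.path(d, "abundance.taxon.tsv"))
      }
      data.frame(sample = sample, refs = nrow(cov),
                 total_bases = sum(cov$base_count),
                 total_reads = sum(cov$read_count),
                 total_inserts = sum(cov$insert_count))
    },
    assembly_prep = {
      require_step(cfg, sample, "read_trim_filter", step)
      src <- hq_input_step(cfg, sample)
      inp <- read_step_reads(cfg, sample, src)
      reads <- rbind(inp$pair1, inp$pair2, inp$single)
      class(reads) <- c("mg_reads", "data.frame")
      aln <- NULL
      if (nzchar(cfg$assemblyprep.ref) && nrow(inp$pair1)) {
        idx <- build_index(read_fasta(cfg$assemblyprep.ref))
        pr <- rbind(inp$pair1, inp$pair2)
        class(pr) <- c("mg_reads", "data.frame")
        aln <- map_reads(pr, idx)
      }
      prep <- assembly_prep(reads, aln, cfg$assemblyprep.min_pairs)
      smry <- data.frame(sample = sample,
                         avg_read_length = prep$avg_read_length,
                         kmer = prep$kmer,
                         insert_size = prep$insert_size_estimate,
                         insert_spread = prep$insert_size_spread)
      write_tsv(smry, file.path(d, "assembly_prep.tsv"))
      smry
    },
    assembly_revision = {
      require_step(cfg, sample, "read_trim_filter", step)
      scf_path <- if (nzchar(cfg$revision.scaftigs)) cfg$revision.scaftigs else
        file.path(cfg$input_dir, sample, "assembly", "scaftigs.fasta")
      if (!file.exists(scf_path)) stop("scaftigs FASTA not found: ", scf_path)
      scaftigs <- read_fasta(scf_path)
      src <- hq_input_step(cfg, sample)
      inp <- read_step_reads(cfg, sample, src)
      reads <- rbind(inp$pair1, inp$pair2, inp$single)
      class(reads) <- c("mg_reads", "data.frame")
      idx <- build_index(scaftigs)
      aln <- map_reads(reads, idx)
      kept <- filter_alignments(aln, filter_params(cfg$screen.length_cutoff,
                                                   cfg$screen.identity, FALSE))
      fa <- align_with_seq(filter_apply(aln, kept), reads)
      rp <- revision_params(cfg$revision.min_depth, cfg$revision.majority,
                            cfg$revision.max_indel, cfg$revision.span_window,
                            cfg$revision.min_scaftig)
      res <- revise_assembly(scaftigs, fa, rp)
      write_fasta(res$scaftigs, file.path(d, "revised.fasta"))
      write_tsv(res$events, file.path(d, "revision_events.tsv"))
      smry <- cbind(data.frame(sample = sample), as.data.frame(res$stats))
      write_tsv(smry, file.path(d, "revision_stats.tsv"))
      smry
    })
  mark_done(d)
  row
}

#' Gene prediction quality metrics
#'
#' @param genes a gene table from [read_gff()].
#' @param assembly_total_bp total assembled bp the genes were predicted on.
#' @return List with `n_complete`, `complete_per_Mbp`,
#'   `mean_complete_length`.
#' @export
gene_metrics <- function(genes, assembly_total_bp) {
  stopifnot(assembly_total_bp > 0)
  comp <- genes[genes$completeness == "complete", , drop = FALSE]
  n <- nrow(comp)
  list(n_complete = n,
       complete_per_Mbp = n / (assembly_total_bp / 1e6),
       mean_complete_length = if (n) mean(comp$end - comp$start + 1) else 0)
}

#' Summarize a project into TSV tables and an SQLite database
#'
#' Collects the per-step summary tables under `<output_dir>/summaries/` and
#' mirrors them into `summaries/project.sqlite` (one table per step, equal
#' row for row) when the RSQLite package is available.
#'
#' @param cfg an [read_config()] configuration.
#' @return Named list of the summary data.frames, invisibly.
#' @export
summarize_project <- function(cfg) {
  sd <- file.path(cfg$output_dir, "summaries")
  files <- list.files(sd, "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no completed steps to summarize")
  tabs <- lapply(files, read_tsv)
  names(tabs) <- sub("\\.tsv$", "", basename(files))
  if (requireNamespace("RSQLite", quietly = TRUE) &&
      requireNamespace("DBI", quietly = TRUE)) {
    db <- DBI::dbConnect(RSQLite::SQLite(), file.path(sd, "project.sqlite"))
    on.exit(DBI::dbDisconnect(db))
    for (nm in names(tabs))
      DBI::dbWriteTable(db, nm, tabs[[nm]], overwrite = TRUE)
  }
  invisible(tabs)
}
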