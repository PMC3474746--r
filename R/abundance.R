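# Coverage counting and genome-size-normalized relative abundance.

#' Per-reference coverage from filtered alignments
#'
#' For every reference: `base_count` (sum of aligned query lengths, M+I, so
#' sequenced bases assigned to the reference; deletions contribute nothing),
#' `read_count` (primary mapped records), `insert_count` (one per sequenced
#' fragment: a pair with >= 1 mapped mate on the reference counts once, a
#' mapped singleton counts once), and `base_coverage = base_count /
#' ref_length`.  References without alignments get zero rows.
#'
#' @param aln an [mg_alignments] table that already passed
#'   [filter_alignments()] (mapped primary records).
#' @param refs an [mg_refs] object naming every reference.
#' @param base_ops `"MI"` (default) counts insertion bases toward
#'   `base_count`; `"M"` counts match/mismatch columns only.
#' @return A data.frame of class `coverage_table`, one row per reference.
#' @export
calculate_coverage <- function(aln, refs, base_ops = c("MI", "M")) {
  base_ops <- match.arg(base_ops)
  refs <- mg_refs(refs)
  aln <- aln[aln$mapped & aln$is_primary, , drop = FALSE]
  unknown <- setdiff(unique(aln$ref_id), names(refs))
  if (length(unknown))
    stop("alignments reference unknown sequence(s): ",
         paste(unknown, collapse = ", "))
  lev <- names(refs)
  f <- factor(aln$ref_id, levels = lev)
  cs <- cigar_stats(aln$cigar)
  blen <- if (base_ops == "MI") cs[, "aligned_q"] else cs[, "ref_span"] - deletion_len(aln$cigar)
  base_count <- as.numeric(tapply(blen, f, sum, default = 0))
  read_count <- as.integer(table(f))
  ins <- !duplicated(paste(aln$qname, aln$ref_id))
  insert_count <- as.integer(table(factor(aln$ref_id[ins], levels = lev)))
  out <- data.frame(ref_id = lev, ref_length = as.integer(nchar(refs)),
                    base_count = base_count, read_count = read_count,
                    insert_count = insert_count,
                    base_coverage = base_count / nchar(refs),
                    row.names = NULL)
  class(out) <- c("coverage_table", "data.frame")
  if (sum(read_count) == 0)
    attr(out, "empty") <- TRUE
  out
}

deletion_len <- function(cigars) {
  vapply(cigars, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op == "D"])
  }, 1L, USE.NAMES = FALSE)
}

#' Genome-size-normalized abundance table
#'
#' Aggregates per-reference counts to genomes (a genome's length is the sum
#' of its replicon lengths), divides by genome length, and renormalizes to
#' relative fractions.
#'
#' @param cov a [calculate_coverage()] table.
#' @param genome_map data.frame with columns `ref_id`, `genome_id` covering
#'   every reference, or `NULL` to treat each reference as its own genome.
#' @param count one of `"base"`, `"read"`, `"insert"`: which raw count to
#'   normalize.
#' @return A data.frame of class `abundance_table` with columns `group`,
#'   `raw_count`, `length`, `normalized`, `relative`; zero-count genomes are
#'   retained with abundance 0.  Relative fractions sum to 1 when any count
#'   is nonzero.
#' @export
genome_normalize <- function(cov, genome_map = NULL,
                             count = c("base", "read", "insert")) {
  count <- match.arg(count)
  if (is.null(genome_map))
    genome_map <- data.frame(ref_id = cov$ref_id, genome_id = cov$ref_id)
  miss <- setdiff(cov$ref_id, genome_map$ref_id)
  if (length(miss))
    stop("reference(s) missing from the genome map: ", paste(miss, collapse = ", "))
  g <- genome_map$genome_id[match(cov$ref_id, genome_map$ref_id)]
  raw <- cov[[paste0(count, "_count")]]
  agg_count <- tapply(as.numeric(raw), g, sum)
  agg_len <- tapply(as.numeric(cov$ref_length), g, sum)
  normalized <- agg_count / agg_len
  total <- sum(normalized)
  relative <- if (total > 0) normalized / total else normalized * 0
  out <- data.frame(group = names(agg_count), raw_count = as.numeric(agg_count),
                    length = as.numeric(agg_len), normalized = as.numeric(normalized),
                    relative = as.numeric(relative), row.names = NULL)
  class(out) <- c("abundance_table", "data.frame")
  if (total == 0) attr(out, "empty") <- TRUE
  out
}

#' Aggregate an abundance table by taxon
#'
#' @param ab an [genome_normalize()] table.
#' @param taxon_map data.frame with columns `genome_id`, `taxon` covering
#'   every group of `ab`.
#' @return An `abundance_table` over taxa (relative fractions still sum
#'   to 1).
#' @export
aggregate_by_taxon <- function(ab, taxon_map) {
  miss <- setdiff(ab$group, taxon_map$genome_id)
  if (length(miss))
    stop("group(s) missing from the taxon map: ", paste(miss, collapse = ", "))
  tx <- taxon_map$taxon[match(ab$group, taxon_map$genome_id)]
  out <- data.frame(group = names(tapply(ab$relative, tx, sum)),
                    raw_count = as.numeric(tapply(ab$raw_count, tx, sum)),
                    length = as.numeric(tapply(ab$length, tx, sum)),
                    normalized = as.numeric(tapply(ab$normalized, tx, sum)),
                    relative = as.numeric(tapply(ab$relative, tx, sum)),
                    row.names = NULL)
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Correlation between observed and expected abundance
#'
#' @param observed,expected `abundance_table`s (or data.frames with `group`
#'   and `relative` columns) over the same group set.
#' @return Named numeric vector `c(pearson_r = ..., spearman_rho = ...)`.
#' @export
compare_to_truth <- function(observed, expected) {
  if (!setequal(observed$group, expected$group))
    stop("observed and expected tables cover different groups")
  if (length(observed$group) < 3)
    stop("need at least 3 shared groups for a correlation")
  o <- observed$relative[order(observed$group)]
  e <- expected$relative[order(expected$group)]
  c(pearson_r = cor(o, e, method = "pearson"),
    spearman_rho = cor(o, e, method = "spearman"))
}
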