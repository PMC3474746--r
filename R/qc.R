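# Read quality control: per-read trimming (two algorithms), sample-wide 5'
# base-composition-bias trimming, and the combined trim/filter step.

#' Quality-control parameters
#'
#' @param quality_cutoff Phred threshold (default 20).
#' @param length_cutoff minimum retained read length in bp (default 30).
#' @param method `"solexaqa"` (longest all-passing segment) or `"fastx"`
#'   (3' threshold trimming).
#' @param five_prime_enabled apply sample-wide 5' composition-bias trimming.
#' @param five_prime_sd deviation multiplier for the 5' rule (default 2).
#' @param five_prime_cap maximum fraction of read positions the 5' rule may
#'   remove (guards degenerate samples).
#' @param inclusive if `TRUE` (default) a base at exactly the cutoff passes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(quality_cutoff = 20L, length_cutoff = 30L,
                      method = c("solexaqa", "fastx"),
                      five_prime_enabled = TRUE, five_prime_sd = 2,
                      five_prime_cap = 0.15, inclusive = TRUE) {
  method <- match.arg(method)
  stopifnot(quality_cutoff >= 0, length_cutoff >= 1, five_prime_sd > 0)
  structure(list(quality_cutoff = as.integer(quality_cutoff),
                 length_cutoff = as.integer(length_cutoff), method = method,
                 five_prime_enabled = five_prime_enabled,
                 five_prime_sd = five_prime_sd, five_prime_cap = five_prime_cap,
                 inclusive = inclusive),
            class = "qc_params")
}

trim_by_bounds <- function(reads, bounds) {
  keep <- bounds[, 2] >= bounds[, 1]
  seq <- character(nrow(reads)); qual <- character(nrow(reads))
  seq[keep] <- substr(reads$seq[keep], bounds[keep, 1], bounds[keep, 2])
  qual[keep] <- substr(reads$qual[keep], bounds[keep, 1], bounds[keep, 2])
  out <- reads
  out$seq <- seq; out$qual <- qual
  out
}

#' Trim a read to its longest all-passing segment
#'
#' Keeps the longest contiguous segment in which every quality score passes
#' the threshold (ties resolved in favour of the 5'-most segment); returns an
#' empty read when no base passes.
#'
#' @param reads an [mg_reads] object.
#' @param q Phred threshold.
#' @param inclusive if `TRUE`, quality exactly `q` passes.
#' @return A trimmed [mg_reads] object (same number of rows; empty sequences
#'   where nothing passed).
#' @export
dynamic_trim <- function(reads, q = 20L, inclusive = TRUE) {
  b <- .mg_trim_bounds(reads$qual, 33L, as.integer(q), 0L, inclusive)
  trim_by_bounds(reads, b)
}

#' Trim low-quality bases from the 3' end
#'
#' Removes trailing bases while the terminal base fails the threshold;
#' interior low-quality bases are retained.
#'
#' @inheritParams dynamic_trim
#' @return A trimmed [mg_reads] object.
#' @export
fastx_trim <- function(reads, q = 20L, inclusive = TRUE) {
  b <- .mg_trim_bounds(reads$qual, 33L, as.integer(q), 1L, inclusive)
  trim_by_bounds(reads, b)
}

#' Positional base-composition profile of a read set
#'
#' For every read position the frequency of each base among non-N calls,
#' plus the mean and sample standard deviation of each base's frequency
#' across positions.
#'
#' @param reads an [mg_reads] object with at least one read.
#' @return A list of class `base_composition_profile` with elements `freq`
#'   (positions x A/C/G/T matrix), `n_reads_at_position`, `per_base_mean`,
#'   `per_base_sd`.
#' @export
base_composition_profile <- function(reads) {
  if (nrow(reads) == 0) stop("no reads: cannot profile base composition")
  bc <- .mg_base_counts(reads$seq)
  counts <- bc$counts
  nonN <- rowSums(counts[, 1:4, drop = FALSE])
  freq <- counts[, 1:4, drop = FALSE] / pmax(nonN, 1L)
  colnames(freq) <- c("A", "C", "G", "T")
  per_base_mean <- colMeans(freq)
  per_base_sd <- if (nrow(freq) > 1) apply(freq, 2, sd) else setNames(rep(0, 4), colnames(freq))
  structure(list(freq = freq, n_reads_at_position = bc$n_at_position,
                 per_base_mean = per_base_mean, per_base_sd = per_base_sd),
            class = "base_composition_profile")
}

#' 5' composition-bias trim length
#'
#' Length of the maximal contiguous prefix of positions, starting at
#' position 1, in which at least one base's frequency deviates from that
#' base's across-position mean by more than `n_sd` standard deviations.
#' Interior biased positions (after a compliant one) are never trimmed.
#'
#' @param profile a [base_composition_profile()].
#' @param n_sd deviation multiplier (default 2).
#' @param cap maximum fraction of positions that may be trimmed.
#' @return Integer trim length `t >= 0`.
#' @export
five_prime_trim_length <- function(profile, n_sd = 2, cap = 0.15) {
  freq <- profile$freq
  if (nrow(freq) < 2) return(0L)
  dev <- abs(sweep(freq, 2, profile$per_base_mean))
  lim <- n_sd * profile$per_base_sd
  biased <- apply(sweep(dev, 2, lim, ">"), 1, any)
  t <- 0L
  while (t < nrow(freq) && biased[t + 1L]) t <- t + 1L
  min(t, as.integer(floor(cap * nrow(freq))))
}

drop_prefix <- function(reads, t) {
  if (t <= 0L) return(reads)
  reads$seq <- substring(reads$seq, t + 1L)
  reads$qual <- substring(reads$qual, t + 1L)
  reads
}

#' Quality trimming and filtering of a sample
#'
#' Applies, in order: (1) sample-wide 5' composition-bias trimming of `t`
#' positions from every read (`t` estimated from the raw reads), (2) quality
#' trimming by the selected method, (3) the minimum-length filter.  For
#' paired input, when one mate fails the length filter the surviving mate is
#' moved to the singleton output.
#'
#' @param pair1,pair2 paired [mg_reads] (equal row counts), or `NULL`.
#' @param single unpaired [mg_reads], or `NULL`.
#' @param params a [qc_params()] list.
#' @return A list of class `qc_result`: `pair1`, `pair2`, `single`
#'   ([mg_reads]), `stats` (one-row data.frame of raw/high-quality read and
#'   base counts and retention percentages) and `five_prime_trim_length`.
#' @export
read_trim_filter <- function(pair1 = NULL, pair2 = NULL, single = NULL,
                             params = qc_params()) {
  if (xor(is.null(pair1), is.null(pair2)))
    stop("paired input requires both mate files")
  if (!is.null(pair1) && nrow(pair1) != nrow(pair2))
    stop("mismatched pair files: ", nrow(pair1), " vs ", nrow(pair2), " reads")
  empty <- mg_reads(character(), character(), character())
  if (is.null(pair1)) { pair1 <- empty; pair2 <- empty }
  if (is.null(single)) single <- empty
  pair1$mate <- rep_len(1L, nrow(pair1)); pair2$mate <- rep_len(2L, nrow(pair2))
  single$mate <- rep_len(0L, nrow(single))
  all_raw <- rbind(pair1, pair2, single)
  raw_reads <- nrow(all_raw); raw_bases <- sum(nchar(all_raw$seq))
  if (raw_reads == 0) stop("no reads")

  t <- 0L
  if (params$five_prime_enabled) {
    prof <- base_composition_profile(all_raw)
    t <- five_prime_trim_length(prof, params$five_prime_sd, params$five_prime_cap)
  }
  trim1 <- function(r) {
    r <- drop_prefix(r, t)
    if (params$method == "solexaqa")
      dynamic_trim(r, params$quality_cutoff, params$inclusive)
    else fastx_trim(r, params$quality_cutoff, params$inclusive)
  }
  p1 <- trim1(pair1); p2 <- trim1(pair2); sg <- trim1(single)

  ok1 <- nchar(p1$seq) >= params$length_cutoff
  ok2 <- nchar(p2$seq) >= params$length_cutoff
  oks <- nchar(sg$seq) >= params$length_cutoff
  out_pair1 <- p1[ok1 & ok2, , drop = FALSE]
  out_pair2 <- p2[ok1 & ok2, , drop = FALSE]
  orphan1 <- p1[ok1 & !ok2, , drop = FALSE]
  orphan2 <- p2[!ok1 & ok2, , drop = FALSE]
  orphan1$mate <- rep_len(0L, nrow(orphan1))
  orphan2$mate <- rep_len(0L, nrow(orphan2))
  out_single <- rbind(sg[oks, , drop = FALSE], orphan1, orphan2)
  class(out_pair1) <- class(out_pair2) <- class(out_single) <- c("mg_reads", "data.frame")

  hq_reads <- nrow(out_pair1) + nrow(out_pair2) + nrow(out_single)
  hq_bases <- sum(nchar(out_pair1$seq)) + sum(nchar(out_pair2$seq)) +
    sum(nchar(out_single$seq))
  stats <- data.frame(raw_reads = raw_reads, raw_bases = raw_bases,
                      hq_reads = hq_reads, hq_bases = hq_bases,
                      pct_reads_retained = 100 * hq_reads / raw_reads,
                      pct_bases_retained = 100 * hq_bases / raw_bases,
                      five_prime_trim_length = t)
  structure(list(pair1 = out_pair1, pair2 = out_pair2, single = out_single,
                 stats = stats, five_prime_trim_length = t),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", x$stats$hq_reads, "/", x$stats$raw_reads,
      " reads retained (", round(x$stats$pct_reads_retained, 1), "%), 5' trim ",
      x$five_prime_trim_length, " bp\n", sep = "")
  invisible(x)
}
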