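# Synthetic community simulator: random genomes, strain derivation, paired
# read simulation with ground truth, and assembly corruption fixtures with a
# truth log of the revisions needed to repair them.

rand_dna <- function(n, gc = 0.5)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Generate a random genome sequence
#'
#' I.i.d. bases with the requested GC content; deterministic given the seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param seed integer RNG seed.
#' @param id reference id.
#' @return An [mg_refs] object with one sequence.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, id = "genome1") {
  stopifnot(length >= 1000)
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0, 1)")
  set.seed(seed)
  mg_refs(setNames(rand_dna(length, gc), id))
}

#' Derive a strain by random substitution
#'
#' Substitutes each position independently with the given probability
#' (uniform over the three alternative bases).
#'
#' @param genome an [mg_refs] object (first sequence used).
#' @param divergence per-site substitution probability in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @param id id of the derived strain.
#' @return An [mg_refs] object with attribute `realized_divergence`.
#' @export
mutate_genome <- function(genome, divergence, seed = 1L,
                          id = paste0(names(genome)[1], "_strain")) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  set.seed(seed)
  s <- strsplit(genome[[1]], "")[[1]]
  hit <- which(runif(length(s)) < divergence)
  if (length(hit)) {
    alt <- vapply(s[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  "", USE.NAMES = FALSE)
    s[hit] <- alt
  }
  out <- mg_refs(setNames(paste(s, collapse = ""), id))
  attr(out, "realized_divergence") <- length(hit) / length(s)
  out
}

#' Define a synthetic community
#'
#' Draws independent random genomes (pairwise divergence of independent
#' i.i.d. sequences is ~75%) and a relative abundance vector.
#'
#' @param n_genomes number of genomes.
#' @param genome_length bp per genome.
#' @param abundances `"loguniform"` (log10-uniform over `log_range` decades,
#'   then normalized), `"even"`, or a numeric vector summing to 1.
#' @param log_range decades spanned by the log-uniform draw (default 2).
#' @param gc GC fraction of the genomes.
#' @param seed integer RNG seed.
#' @return A list of class `community_truth`: `genomes` ([mg_refs]),
#'   `abundance` (named, sums to 1), `genome_map` (replicon -> genome),
#'   `seed`.
#' @export
simulate_community <- function(n_genomes = 10L, genome_length = 100000L,
                               abundances = "loguniform", log_range = 2,
                               gc = 0.5, seed = 42L) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n_genomes))
  genomes <- mg_refs(setNames(
    vapply(seq_len(n_genomes), function(i) rand_dna(genome_length, gc), ""), ids))
  ab <- if (is.numeric(abundances)) {
    stopifnot(length(abundances) == n_genomes, abs(sum(abundances) - 1) < 1e-8)
    abundances
  } else if (identical(abundances, "even")) {
    rep(1 / n_genomes, n_genomes)
  } else {
    x <- 10^runif(n_genomes, 0, log_range)
    x / sum(x)
  }
  structure(list(genomes = genomes, abundance = setNames(ab, ids),
                 genome_map = data.frame(ref_id = ids, genome_id = ids),
                 seed = seed),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat("<community_truth> ", length(x$genomes), " genomes, ",
      sum(nchar(x$genomes)), " bp total\n", sep = "")
  invisible(x)
}

ramp_quality <- function(read_len, q_high = 35L, q_low = 20L) {
  ramp_start <- ceiling(0.8 * read_len)
  q <- rep(q_high, read_len)
  if (ramp_start < read_len) {
    k <- seq(ramp_start, read_len)
    q[k] <- round(q_high - (q_high - q_low) * (k - ramp_start) / (read_len - ramp_start))
  }
  phred_encode(as.integer(q))
}

add_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(list(seqs = seqs, n_errors = 0L))
  n <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = n)
  hit <- which(matrix(runif(length(mat)) < error_rate, nrow = n))
  if (length(hit)) {
    alt <- vapply(mat[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  "", USE.NAMES = FALSE)
    mat[hit] <- alt
  }
  list(seqs = apply(mat, 2, paste, collapse = ""), n_errors = length(hit))
}

#' Simulate paired-end reads from a community
#'
#' Fragments are drawn from genomes with probability proportional to
#' `abundance * genome_length` (a genome's share of sequenced fragments), at
#' uniform start positions, with insert length ~ Normal(`insert_mean`,
#' `insert_sd`) (resampled while it exceeds the replicon or falls below
#' `2 * read_len`).  Mate 1 is the fragment 5' end; mate 2 the reverse
#' complement of its 3' end.  Substitution errors are applied at
#' `error_rate`; qualities follow a constant-Q35 model with a linear ramp
#' to Q20 over the last 20% of the read.
#'
#' @param community a [simulate_community()] result.
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (outer distance).
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return A list of class `sim_reads`: `pair1`, `pair2` ([mg_reads]),
#'   `truth` (data.frame read_id, genome_id, ref_id, position, strand,
#'   insert), and `n_errors`.
#' @export
simulate_reads <- function(community, n_pairs = 1000L, read_len = 100L,
                           insert_mean = 300, insert_sd = 30,
                           error_rate = 0, seed = 1L) {
  stopifnot(insert_mean >= 2 * read_len)
  set.seed(seed)
  genomes <- community$genomes
  glen <- nchar(genomes)
  w <- community$abundance[names(genomes)] * glen
  origin <- sample(seq_along(genomes), n_pairs, replace = TRUE, prob = w / sum(w))
  ins <- round(rnorm(n_pairs, insert_mean, insert_sd))
  bad <- which(ins < 2 * read_len | ins > glen[origin])
  tries <- 0L
  while (length(bad)) {
    if ((tries <- tries + 1L) > 1000L)
      stop("cannot draw an insert fitting the replicon after 1000 attempts")
    ins[bad] <- round(rnorm(length(bad), insert_mean, insert_sd))
    bad <- bad[ins[bad] < 2 * read_len | ins[bad] > glen[origin[bad]]]
  }
  start <- floor(runif(n_pairs, 1, glen[origin] - ins + 2))
  frag_end <- start + ins - 1L
  gseq <- as.character(unclass(genomes))
  m1 <- substring(gseq[origin], start, start + read_len - 1L)
  m2 <- revcomp_chr(substring(gseq[origin], frag_end - read_len + 1L, frag_end))
  e1 <- add_errors(m1, error_rate); e2 <- add_errors(m2, error_rate)
  ids <- sprintf("p%07d", seq_len(n_pairs))
  qual <- ramp_quality(read_len)
  pair1 <- mg_reads(ids, e1$seqs, rep(qual, n_pairs), mate = 1L)
  pair2 <- mg_reads(ids, e2$seqs, rep(qual, n_pairs), mate = 2L)
  truth <- data.frame(read_id = ids, genome_id = names(genomes)[origin],
                      ref_id = names(genomes)[origin], position = start,
                      strand = "+", insert = ins)
  structure(list(pair1 = pair1, pair2 = pair2, truth = truth,
                 n_errors = e1$n_errors + e2$n_errors),
            class = "sim_reads")
}

#' Corrupt genome segments into an assembly fixture
#'
#' Cuts segments out of the supplied genomes as "scaftigs", then injects the
#' requested substitutions, 1-5 bp indels, and chimeric fusions (a scaftig
#' concatenating segments of two different genomes).  Returns both the
#' corrupted scaftigs and the pristine source pieces, plus a truth log of
#' the revision events needed to repair the corruption, with positions on
#' the corrupted scaftigs (format matching [revise_assembly()] events).
#'
#' @param genomes an [mg_refs] object with >= 2 sequences when chimeras are
#'   requested.
#' @param n_subs,n_indels,n_chimeras number of events to inject.
#' @param segment_length scaftig segment length in bp.
#' @param margin minimum distance between events and from segment ends.
#' @param seed integer RNG seed.
#' @return A list of class `corrupt_assembly`: `scaftigs` (corrupted,
#'   [mg_refs]), `sources` (pristine pieces; chimera parts are separate
#'   sequences), `truth` (event data.frame: kind, scaftig_id, position,
#'   before, after), `junctions` (data.frame of chimeric junction positions).
#' @export
corrupt_assembly <- function(genomes, n_subs = 20L, n_indels = 10L,
                             n_chimeras = 2L, segment_length = 5000L,
                             margin = 200L, seed = 1L) {
  set.seed(seed)
  genomes <- mg_refs(genomes)
  if (n_chimeras > 0 && length(genomes) < 2)
    stop("chimeras require at least two genomes")
  gseq <- as.character(unclass(genomes))
  glen <- nchar(gseq)
  if (any(glen < segment_length))
    stop("all genomes must be at least segment_length bp")
  # segments are sampled without overlap within a genome so that no locus is
  # duplicated across scaftigs (duplicates would shadow read placement)
  used <- lapply(seq_along(genomes), function(i) matrix(integer(0), ncol = 2))
  take_segment <- function(g) {
    for (try in 1:1000) {
      s <- sample.int(glen[g] - segment_length + 1L, 1)
      e <- s + segment_length - 1L
      iv <- used[[g]]
      if (!nrow(iv) || all(e < iv[, 1] | s > iv[, 2])) {
        used[[g]] <<- rbind(iv, c(s, e))
        return(substr(gseq[g], s, e))
      }
    }
    stop("cannot place a non-overlapping segment after 1000 attempts; ",
         "genomes too short for the requested scaftigs")
  }
  # plain scaftigs: one segment per genome (recycled as needed)
  n_plain <- max(2L, length(genomes))
  plain_src <- rep_len(seq_along(genomes), n_plain)
  scaftigs <- character(0); sources <- character(0)
  src_ids <- character(0); sc_ids <- character(0)
  junctions <- list()
  for (i in seq_len(n_plain)) {
    seg <- take_segment(plain_src[i])
    id <- sprintf("scaftig%02d", i)
    sc_ids <- c(sc_ids, id); scaftigs <- c(scaftigs, seg)
    src_ids <- c(src_ids, id); sources <- c(sources, seg)
  }
  for (j in seq_len(n_chimeras)) {
    gs <- sample(seq_along(genomes), 2)
    a <- take_segment(gs[1]); b <- take_segment(gs[2])
    id <- sprintf("chimera%02d", j)
    sc_ids <- c(sc_ids, id); scaftigs <- c(scaftigs, paste0(a, b))
    src_ids <- c(src_ids, paste0(id, "_partA"), paste0(id, "_partB"))
    sources <- c(sources, a, b)
    junctions[[j]] <- data.frame(scaftig_id = id, position = nchar(a))
  }
  names(scaftigs) <- sc_ids; names(sources) <- src_ids
  # place substitutions and indels on the plain scaftigs, pairwise-separated
  truth <- list()
  n_events <- n_subs + n_indels
  if (n_events > 0) {
    placed <- data.frame(sc = integer(), pos = integer())
    tries <- 0L
    while (nrow(placed) < n_events) {
      if ((tries <- tries + 1L) > 1000L * n_events)
        stop("cannot place non-overlapping events after 1000 attempts each")
      sc <- sample.int(n_plain, 1)
      pos <- sample(seq(margin, segment_length - margin), 1)
      if (any(placed$sc == sc & abs(placed$pos - pos) < margin)) next
      placed <- rbind(placed, data.frame(sc = sc, pos = pos))
    }
    kinds <- sample(c(rep("sub", n_subs), rep("indel", n_indels)))
    # plan all events against the pristine segments (loci are >= margin
    # apart so planning order is irrelevant), then apply per scaftig in
    # descending position order so earlier loci keep their coordinates
    plan <- data.frame(sc = placed$sc, pos = placed$pos, kind = kinds,
                       len = 0L, payload = "", orig = "", new = "",
                       stringsAsFactors = FALSE)
    for (k in seq_len(n_events)) {
      if (plan$kind[k] == "sub") {
        plan$orig[k] <- substr(scaftigs[plan$sc[k]], plan$pos[k], plan$pos[k])
        plan$new[k] <- sample(setdiff(c("A", "C", "G", "T"), plan$orig[k]), 1)
      } else {
        plan$len[k] <- sample(1:5, 1)
        if (runif(1) < 0.5) {  # inject extra bases; repair = delete
          plan$kind[k] <- "inject"
          plan$payload[k] <- rand_dna(plan$len[k])
        } else {               # remove bases; repair = insert back
          plan$kind[k] <- "excise"
          plan$payload[k] <- substr(scaftigs[plan$sc[k]], plan$pos[k] + 1L,
                                    plan$pos[k] + plan$len[k])
        }
      }
    }
    for (sc in unique(plan$sc)) {
      rows <- which(plan$sc == sc)
      for (k in rows[order(-plan$pos[rows])]) {
        pos <- plan$pos[k]
        if (plan$kind[k] == "sub") {
          substr(scaftigs[sc], pos, pos) <- plan$new[k]
        } else if (plan$kind[k] == "inject") {
          scaftigs[sc] <- paste0(substr(scaftigs[sc], 1, pos), plan$payload[k],
                                 substring(scaftigs[sc], pos + 1L))
        } else {
          scaftigs[sc] <- paste0(substr(scaftigs[sc], 1, pos),
                                 substring(scaftigs[sc], pos + plan$len[k] + 1L))
        }
      }
    }
    # truth positions on the CORRUPTED scaftig: shift by the net indel
    # balance of events to the left
    for (sc in unique(plan$sc)) {
      rows <- which(plan$sc == sc)
      shift <- 0L
      for (k in rows[order(plan$pos[rows])]) {
        pos <- plan$pos[k] + shift
        id <- sc_ids[sc]
        if (plan$kind[k] == "sub") {
          truth[[length(truth) + 1L]] <-
            data.frame(kind = "substitution", scaftig_id = id, position = pos,
                       before = plan$new[k], after = plan$orig[k])
        } else if (plan$kind[k] == "inject") {
          truth[[length(truth) + 1L]] <-
            data.frame(kind = "deletion", scaftig_id = id, position = pos + 1L,
                       before = plan$payload[k], after = "")
          shift <- shift + plan$len[k]
        } else {
          truth[[length(truth) + 1L]] <-
            data.frame(kind = "insertion", scaftig_id = id, position = pos,
                       before = "", after = plan$payload[k])
          shift <- shift - plan$len[k]
        }
      }
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE)) else
    data.frame(kind = character(), scaftig_id = character(), position = integer(),
               before = character(), after = character())
  structure(list(scaftigs = mg_refs(scaftigs), sources = mg_refs(sources),
                 truth = truth_df,
                 junctions = if (length(junctions)) do.call(rbind, junctions)
                             else data.frame(scaftig_id = character(), position = integer())),
            class = "corrupt_assembly")
}

#' Simulate paired reads tiling a set of source pieces
#'
#' Helper for assembly-revision fixtures: draws error-free (or noisy) pairs
#' from every source piece at the requested coverage.  Pair starts are
#' uniform, so both ends of each piece are covered by construction.
#'
#' @param sources an [mg_refs] object of pristine pieces.
#' @param coverage mean per-base read coverage (default 30).
#' @param read_len,insert_mean,insert_sd,error_rate,seed as in
#'   [simulate_reads()].
#' @return A `sim_reads` list (`pair1`, `pair2`, `truth`).
#' @export
simulate_coverage_reads <- function(sources, coverage = 30, read_len = 100L,
                                    insert_mean = 300, insert_sd = 30,
                                    error_rate = 0, seed = 1L) {
  set.seed(seed)
  p1 <- list(); p2 <- list(); truth <- list()
  qual <- ramp_quality(read_len)
  for (id in names(sources)) {
    s <- sources[[id]]
    L <- nchar(s)
    n_pairs <- max(1L, ceiling(coverage * L / (2 * read_len)))
    ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)), 2 * read_len), L)
    start <- floor(runif(n_pairs, 1, L - ins + 2))
    # anchor a few fragments flush with each end so terminal bases are
    # always covered (uniform sampling alone leaves the last few bp bare)
    n_anchor <- min(2L, n_pairs %/% 2L)
    if (n_anchor > 0) {
      start[seq_len(n_anchor)] <- 1L
      tail_idx <- n_pairs - seq_len(n_anchor) + 1L
      start[tail_idx] <- L - ins[tail_idx] + 1L
    }
    m1 <- substring(s, start, start + read_len - 1L)
    m2 <- revcomp_chr(substring(s, start + ins - read_len, start + ins - 1L))
    e1 <- add_errors(m1, error_rate); e2 <- add_errors(m2, error_rate)
    ids <- sprintf("%s_p%06d", id, seq_len(n_pairs))
    p1[[id]] <- mg_reads(ids, e1$seqs, rep(qual, n_pairs), mate = 1L)
    p2[[id]] <- mg_reads(ids, e2$seqs, rep(qual, n_pairs), mate = 2L)
    truth[[id]] <- data.frame(read_id = ids, ref_id = id, position = start,
                              insert = ins)
  }
  pair1 <- do.call(rbind, c(p1, make.row.names = FALSE))
  pair2 <- do.call(rbind, c(p2, make.row.names = FALSE))
  class(pair1) <- class(pair2) <- c("mg_reads", "data.frame")
  structure(list(pair1 = pair1, pair2 = pair2,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 n_errors = NA_integer_),
            class = "sim_reads")
}
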