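# Readers and writers for the standard text formats.  FASTA goes through
# Biostrings; FASTQ and SAM are line-oriented formats read with base tools so
# that malformed records can be reported with file and line numbers and
# Phred+64 input round-trips losslessly.  GFF3 is consumed (never produced)
# and only seqid/start/end/strand plus the ID/partial/completeness attributes
# are used.

#' Read a FASTQ file
#'
#' Four-line FASTQ only.  The quality encoding is auto-detected
#' ([detect_quality_offset()]) unless `offset` is given; qualities are
#' re-encoded to Phred+33 internally.
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @param offset 33, 64 or `NULL` (auto-detect).
#' @param mate mate role to assign (0 single, 1, 2).
#' @return An [mg_reads] object.
#' @export
read_fastq <- function(path, offset = NULL, mate = 0L) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop(path, ": truncated FASTQ, ", length(lines), " lines is not a multiple of 4")
  if (length(lines) == 0)
    return(mg_reads(character(), character(), character(), mate))
  idx <- seq(1, length(lines), by = 4)
  hdr <- lines[idx]; seq <- lines[idx + 1]; plus <- lines[idx + 2]; qual <- lines[idx + 3]
  bad <- which(substring(hdr, 1, 1) != "@")
  if (length(bad))
    stop(path, " line ", idx[bad[1]], ": header does not start with '@'")
  bad <- which(substring(plus, 1, 1) != "+")
  if (length(bad))
    stop(path, " line ", idx[bad[1]] + 2, ": separator line does not start with '+'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(path, " line ", idx[bad[1]] + 1, ": sequence length ", nchar(seq[bad[1]]),
         " != quality length ", nchar(qual[bad[1]]))
  if (is.null(offset)) offset <- detect_quality_offset(qual)
  if (offset == 64L)
    qual <- vapply(qual, function(q)
      if (nzchar(q)) intToUtf8(utf8ToInt(q) - 31L) else q, "", USE.NAMES = FALSE)
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  mg_reads(ids, seq, qual, mate)
}

#' Write a FASTQ file
#'
#' @param reads an [mg_reads] object.
#' @param path output path.
#' @param offset quality encoding of the output (33 or 64).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  qual <- reads$qual
  if (offset == 64L)
    qual <- vapply(qual, function(q)
      if (nzchar(q)) intToUtf8(utf8ToInt(q) + 31L) else q, "", USE.NAMES = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)), con)
  invisible(path)
}

#' Process a FASTQ file in fixed-size chunks
#'
#' Streams a FASTQ file, invoking `fun` on successive [mg_reads] chunks so
#' that memory stays bounded by the chunk size.
#'
#' @param path FASTQ path.
#' @param fun function of one argument (an [mg_reads] chunk).
#' @param chunk_size records per chunk.
#' @inheritParams read_fastq
#' @return List of the values returned by `fun`, invisibly.
#' @export
fastq_chunk_apply <- function(path, fun, chunk_size = 10000L, offset = NULL,
                              mate = 0L) {
  con <- file(path, "r")
  on.exit(close(con))
  out <- list()
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0) break
    tf <- tempfile(fileext = ".fq")
    writeLines(lines, tf)
    chunk <- read_fastq(tf, offset = offset, mate = mate)
    unlink(tf)
    out[[length(out) + 1L]] <- fun(chunk)
    if (length(lines) < 4L * chunk_size) break
  }
  invisible(out)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting [mg_refs] (named
#' character vectors).  Output is wrapped at 80 columns.
#'
#' @param path FASTA path.
#' @return `read_fasta`: an [mg_refs] object.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  mg_refs(x)
}

#' @param refs an [mg_refs] object (or named character vector).
#' @rdname read_fasta
#' @export
write_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(setNames(as.character(unclass(refs)), names(refs)))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# --- SAM ------------------------------------------------------------------

sam_flag <- function(aln) {
  paired <- aln$mate > 0L
  flag <- ifelse(paired, 1L, 0L)
  flag <- flag + ifelse(!aln$mapped, 4L, 0L)
  flag <- flag + ifelse(paired & !aln$mate_mapped, 8L, 0L)
  flag <- flag + ifelse(aln$mapped & !is.na(aln$strand) & aln$strand == "-", 16L, 0L)
  flag <- flag + ifelse(aln$mate == 1L, 64L, ifelse(aln$mate == 2L, 128L, 0L))
  flag + ifelse(!aln$is_primary, 256L, 0L)
}

#' Write alignments as SAM text
#'
#' Emits a headerful SAM file with `@SQ` lines for every reference.  `SEQ`
#' and `QUAL` columns are filled from `reads` when supplied, else `*`.
#'
#' @param aln an [mg_alignments] table.
#' @param refs an [mg_refs] object (for `@SQ` lines).
#' @param path output path.
#' @param reads optional [mg_reads] supplying SEQ/QUAL (matched on id+mate).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, refs, path, reads = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs)))
  seqs <- rep("*", nrow(aln)); quals <- rep("*", nrow(aln))
  if (!is.null(reads)) {
    key <- paste(reads$id, reads$mate); akey <- paste(aln$qname, aln$mate)
    m <- match(akey, key)
    seqs <- ifelse(is.na(m), "*", reads$seq[m])
    quals <- ifelse(is.na(m), "*", reads$qual[m])
    rc <- which(aln$mapped & aln$strand == "-" & seqs != "*")
    if (length(rc)) {
      seqs[rc] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
      quals[rc] <- vapply(quals[rc], function(q) intToUtf8(rev(utf8ToInt(q))), "")
    }
  }
  body <- paste(aln$qname, sam_flag(aln),
                ifelse(aln$mapped, aln$ref_id, "*"),
                ifelse(aln$mapped, aln$pos, 0L),
                ifelse(aln$mapped, 60L, 0L),
                ifelse(aln$mapped, aln$cigar, "*"),
                "*", 0L, aln$tlen, seqs, quals,
                ifelse(aln$mapped, paste0("NM:i:", aln$nm), ""),
                sep = "\t")
  body <- sub("\t$", "", body)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text
#'
#' Parses headerful or headerless SAM.  Secondary/supplementary records are
#' kept but flagged `is_primary = FALSE`; downstream operations use primary
#' records only.
#'
#' @param path SAM path.
#' @return An [mg_alignments] table with attribute `refs` (named integer
#'   vector of `@SQ` lengths, when present).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lens <- NULL
  if (length(sq)) {
    sn <- sub(".*\\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\\tLN:([0-9]+).*", "\\1", sq))
    ref_lens <- setNames(ln, sn)
  }
  if (length(body) == 0) {
    out <- mg_alignments(character())
    attr(out, "refs") <- ref_lens
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    stop(path, " line ", length(hdr) + which(nf < 11)[1],
         ": SAM record has fewer than 11 fields")
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, 1L)
  mapped <- bitwAnd(flag, 4L) == 0L
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L))
  out <- mg_alignments(
    qname = get(1), mate = mate, mapped = mapped,
    ref_id = ifelse(mapped, get(3), NA_character_),
    pos = ifelse(mapped, suppressWarnings(as.integer(get(4))), NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"), NA_character_),
    cigar = ifelse(mapped, get(6), NA_character_),
    nm = ifelse(mapped & !is.na(nm), nm, ifelse(mapped, 0L, NA_integer_)),
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    mate_mapped = bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 8L) == 0L,
    tlen = as.integer(get(9)))
  attr(out, "refs") <- ref_lens
  out
}

# --- GFF ------------------------------------------------------------------

#' Read gene records from a GFF3 file
#'
#' Consumes `gene`/`CDS` features.  Completeness comes from a
#' `completeness=` attribute when present, else from the Prodigal-style
#' `partial=` attribute (`00` complete, `10` missing start, `01` missing
#' end, `11` fragment); features without either are taken as complete.
#'
#' @param path GFF3 path.
#' @return A data.frame with columns `gene_id`, `scaftig_id`, `start`,
#'   `end`, `strand`, `completeness`.
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene_id = character(), scaftig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      completeness = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9)) stop(path, ": GFF line with fewer than 9 fields")
  get <- function(i) vapply(f, `[[`, "", i)
  type <- get(3)
  keep <- type %in% c("gene", "CDS")
  f <- f[keep]
  if (!length(f))
    return(read_gff_empty())
  get <- function(i) vapply(f, `[[`, "", i)
  attrs <- get(9)
  attr_val <- function(key) {
    vapply(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs)),
           function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[1]) else NA_character_, "")
  }
  start <- as.integer(get(4)); end <- as.integer(get(5))
  if (any(start > end)) stop(path, ": GFF feature with start > end")
  comp <- attr_val("completeness")
  partial <- attr_val("partial")
  comp[is.na(comp)] <- c("00" = "complete", "10" = "missing_start",
                         "01" = "missing_end", "11" = "fragment")[partial[is.na(comp)]]
  comp[is.na(comp)] <- "complete"
  id <- attr_val("ID")
  id[is.na(id)] <- paste0("gene_", seq_along(id))[is.na(id)]
  data.frame(gene_id = id, scaftig_id = get(1), start = start, end = end,
             strand = get(7), completeness = comp)
}

read_gff_empty <- function()
  data.frame(gene_id = character(), scaftig_id = character(), start = integer(),
             end = integer(), strand = character(), completeness = character())

# --- TSV ------------------------------------------------------------------

#' Write / read a tab-separated table
#'
#' Header row always present; missing values written as `.`.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path)
  read.delim(path, sep = "\t", na.strings = ".", stringsAsFactors = FALSE,
             check.names = FALSE)
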