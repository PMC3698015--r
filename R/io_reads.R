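# FASTQ and alignment-record I/O.
#
# Reads are plain data.frames (read_id, sequence, qualities) with
# qualities as Phred+33 strings; alignments are long-format data.frames
# with one row per candidate locus (read_id, chrom, start, strand,
# n_loci, is_unique) so a multi-read is one logical record spread over
# its loci.

#' Read a 4-line FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame(read_id, sequence, qualities).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      qualities = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) stop("read_fastq: truncated FASTQ (line count not a multiple of 4)")
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("read_fastq: sequence/quality length mismatch in record '%s'", ids[bad[1]]))
  }
  data.frame(read_id = ids, sequence = seqs, qualities = quals,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33)
#'
#' Round-trips byte-identically with [read_fastq()].
#' @param reads data.frame as from [read_fastq()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", reads$qualities)), con)
  invisible(path)
}

# Decode a Phred+33 quality string to integer scores.
phred_decode <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

#' Read alignment records from minimal SAM or BED
#'
#' Only the ungapped single-end subset is parsed from SAM: QNAME, the
#' FLAG strand bit, RNAME and POS (1-based, converted to 0-based); MAPQ
#' and CIGAR are ignored. BED input uses the name column as read id.
#' Multiple lines with the same read id are collapsed into one
#' multi-mapping record; a read with more than `max_loci` loci keeps the
#' first `max_loci` with a warning.
#'
#' @param path SAM or BED file.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @param max_loci multi-mapping cap (default 20).
#' @return data.frame(read_id, chrom, start, strand, n_loci, is_unique),
#'   one row per retained locus, sorted by read_id.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bed"), max_loci = 20L) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "sam"
  if (format == "sam") {
    lines <- readLines(path)
    lines <- lines[!grepl("^@", lines) & nzchar(lines)]
    if (!length(lines)) return(empty_alignments())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(parts, length, integer(1))
    if (any(nf < 4)) stop(sprintf("read_alignments: malformed SAM line %d", which(nf < 4)[1]))
    m <- t(vapply(parts, function(p) p[1:4], character(4)))
    flag <- as.integer(m[, 2])
    aln <- data.frame(read_id = m[, 1], chrom = m[, 3],
                      start = as.integer(m[, 4]) - 1L,
                      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                      stringsAsFactors = FALSE)
    aln <- aln[aln$chrom != "*", , drop = FALSE]
  } else {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 6) stop("read_alignments: BED input needs 6 columns (strand required)")
    aln <- data.frame(read_id = tab[[4]], chrom = tab[[1]],
                      start = as.integer(tab[[2]]), strand = tab[[6]],
                      stringsAsFactors = FALSE)
  }
  collapse_alignments(aln, max_loci)
}

collapse_alignments <- function(aln, max_loci = 20L) {
  if (!nrow(aln)) return(empty_alignments())
  aln <- aln[order(aln$read_id), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(aln)), aln$read_id, FUN = seq_along)
  over <- idx > max_loci
  if (any(over)) {
    warning(sprintf("read_alignments: %d read(s) exceeded the %d-locus cap; extra loci dropped",
                    length(unique(aln$read_id[over])), max_loci))
    aln <- aln[!over, , drop = FALSE]
  }
  n <- table(aln$read_id)
  aln$n_loci <- as.integer(n[aln$read_id])
  aln$is_unique <- aln$n_loci == 1L
  rownames(aln) <- NULL
  aln
}

empty_alignments <- function() {
  data.frame(read_id = character(0), chrom = character(0), start = integer(0),
             strand = character(0), n_loci = integer(0), is_unique = logical(0),
             stringsAsFactors = FALSE)
}

#' Write alignment loci as minimal SAM or BED6
#'
#' @param aln alignment data.frame as from [read_alignments()].
#' @param path output file.
#' @param format `"sam"` or `"bed"`.
#' @param read_len read length used for the BED end column.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, format = c("sam", "bed"), read_len = 36L) {
  format <- match.arg(format)
  if (format == "sam") {
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       aln$read_id, ifelse(aln$strand == "-", 16L, 0L),
                       aln$chrom, aln$start + 1L, read_len), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", aln$chrom, aln$start,
                       aln$start + read_len, aln$read_id, aln$strand), path)
  }
  invisible(path)
}
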