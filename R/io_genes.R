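# Gene annotation I/O and the TSS-relative coordinate axis.
#
# Internal convention: 0-based coordinates; `tss` is the first transcribed
# base and `tts` the last, so tss > tts on the minus strand. The
# TSS-relative axis has 0 at the TSS and upstream negative on both strands.

#' Read gene models from BED6 or GFF3
#'
#' BED input is taken as 0-based half-open (native); GFF3 (1-based,
#' inclusive) is converted on read. Minus-strand genes get TSS/TTS in
#' transcription orientation. For BED, the anticodon family is derived by
#' stripping the trailing copy tag from the gene name
#' (`tP(UGG)-3` -> `tP(UGG)`) and records named `ps-*` are flagged
#' pseudogenes; GFF3 carries both in `family=` / `pseudo=` attributes.
#'
#' @param path BED6 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff"`.
#' @return data.frame with columns gene_id, chrom, strand, tss, tts,
#'   family, is_pseudo, length.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff" else "bed"
  }
  if (format == "bed") read_genes_bed(path) else read_genes_gff(path)
}

read_genes_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 6L)
  if (length(bad)) {
    nostrand <- bad[vapply(parts[bad], length, integer(1)) >= 4L]
    if (length(nostrand)) {
      warning(sprintf("read_genes: %d record(s) without a strand column rejected (first at line %d)",
                      length(nostrand), nostrand[1]))
      parts <- parts[-nostrand]
      bad <- which(vapply(parts, length, integer(1)) < 6L)
    }
    if (length(bad)) stop(sprintf("read_genes: malformed BED line %d", bad[1]))
  }
  if (!length(parts)) return(empty_genes())
  m <- do.call(rbind, parts)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  if (any(is.na(start) | is.na(end))) {
    stop(sprintf("read_genes: malformed BED line %d", which(is.na(start) | is.na(end))[1]))
  }
  strand <- m[, 6]
  ok <- strand %in% c("+", "-")
  if (any(!ok)) {
    warning(sprintf("read_genes: %d record(s) with missing/unknown strand rejected", sum(!ok)))
    m <- m[ok, , drop = FALSE]; start <- start[ok]; end <- end[ok]; strand <- strand[ok]
  }
  if (!nrow(m)) return(empty_genes())
  name <- m[, 4]
  genes_frame(gene_id = name, chrom = m[, 1], strand = strand,
              tss = ifelse(strand == "+", start, end - 1L),
              tts = ifelse(strand == "+", end - 1L, start),
              family = sub("-[0-9]+$", "", sub("^ps-", "", name)),
              is_pseudo = grepl("^ps-", name))
}

read_genes_gff <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  strand <- as.character(md$strand)
  ok <- strand %in% c("+", "-")
  if (any(!ok)) {
    warning(sprintf("read_genes: %d GFF record(s) without strand rejected", sum(!ok)))
    md <- md[ok, , drop = FALSE]; strand <- strand[ok]
  }
  if (!nrow(md)) return(empty_genes())
  start0 <- md$start - 1L; end0 <- md$end  # to 0-based half-open
  id <- md$ID %||% md$Name %||% sprintf("gene%d", seq_len(nrow(md)))
  fam <- md$family %||% sub("-[0-9]+$", "", id)
  pseudo <- if (!is.null(md$pseudo)) tolower(as.character(md$pseudo)) %in% c("true", "1", "yes")
            else rep(FALSE, nrow(md))
  genes_frame(gene_id = as.character(id), chrom = as.character(md$seqnames),
              strand = strand,
              tss = ifelse(strand == "+", start0, end0 - 1L),
              tts = ifelse(strand == "+", end0 - 1L, start0),
              family = as.character(fam), is_pseudo = pseudo)
}

genes_frame <- function(gene_id, chrom, strand, tss, tts, family, is_pseudo) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = as.integer(tss), tts = as.integer(tts),
                   family = family, is_pseudo = is_pseudo,
                   stringsAsFactors = FALSE)
  df$length <- abs(df$tts - df$tss) + 1L
  if (any(!nzchar(df$family))) stop("read_genes: empty family name")
  rownames(df) <- NULL
  df
}

empty_genes <- function() {
  genes_frame(character(0), character(0), character(0), integer(0),
              integer(0), character(0), logical(0))
}

#' Write gene models
#'
#' @param genes gene data.frame as from [read_genes()].
#' @param path output file.
#' @param format `"bed"` (BED6) or `"gff"` (GFF3 with family/pseudo
#'   attributes).
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, format = c("bed", "gff")) {
  format <- match.arg(format)
  start <- pmin(genes$tss, genes$tts)
  end <- pmax(genes$tss, genes$tts) + 1L
  if (format == "bed") {
    nm <- ifelse(genes$is_pseudo & !grepl("^ps-", genes$gene_id),
                 paste0("ps-", genes$gene_id), genes$gene_id)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       genes$chrom, start, end, nm, genes$strand), path)
  } else {
    attrs <- sprintf("ID=%s;family=%s;pseudo=%s", genes$gene_id, genes$family,
                     ifelse(genes$is_pseudo, "true", "false"))
    writeLines(c("##gff-version 3",
                 sprintf("%s\tnucleoscope\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         genes$chrom, start + 1L, end, genes$strand, attrs)),
               path)
  }
  invisible(path)
}

#' Genomic to TSS-relative coordinates
#'
#' Position 0 is the TSS base; upstream is negative on either strand.
#'
#' @param gene one-row gene data.frame (or list with tss, strand).
#' @param pos genomic positions (0-based).
#' @return TSS-relative positions.
#' @export
rel_pos <- function(gene, pos) {
  if (gene$strand == "+") pos - gene$tss else gene$tss - pos
}

#' TSS-relative to genomic coordinates
#'
#' Inverse of [rel_pos()].
#' @param gene one-row gene data.frame.
#' @param rel TSS-relative positions.
#' @return genomic positions (0-based).
#' @export
abs_pos <- function(gene, rel) {
  if (gene$strand == "+") gene$tss + rel else gene$tss - rel
}

# TTS-relative coordinate (positive = downstream of the terminator).
rel_pos_tts <- function(gene, pos) {
  if (gene$strand == "+") pos - gene$tts else gene$tts - pos
}
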