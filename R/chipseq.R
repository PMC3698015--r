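# Pol III ChIP-seq quantification: read filtering, exact multi-mapping
# alignment, unique-coverage-guided reallocation of multi-reads,
# per-million scaling and windowed gene enrichment.

#' Quality-filter reads
#'
#' Keeps a read iff at least `min_frac` of its bases have Phred quality
#' >= `min_q` (boundary inclusive on both thresholds).
#'
#' @param reads data.frame from [read_fastq()].
#' @param min_q Phred threshold.
#' @param min_frac minimum passing-base fraction.
#' @return filtered reads, with attribute `filter_counts`
#'   (kept/dropped).
#' @export
quality_filter <- function(reads, min_q = 20L, min_frac = 0.8) {
  if (!nrow(reads)) {
    attr(reads, "filter_counts") <- c(kept = 0L, dropped = 0L)
    return(reads)
  }
  frac <- vapply(phred_decode(reads$qualities),
                 function(q) mean(q >= min_q), numeric(1))
  keep <- frac >= min_frac
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Exact multi-mapping alignment against a small genome
#'
#' Reports every exact full-length match of each read on either strand,
#' up to `max_loci` per read (extra loci dropped with a warning, as in
#' [read_alignments()]). Reads containing N or with no exact match are
#' dropped; the dropped count is attached as an attribute. Matching uses
#' a preprocessed dictionary ([Biostrings::PDict]).
#'
#' @param reads data.frame from [read_fastq()] (equal-length reads).
#' @param genome named [Biostrings::DNAStringSet].
#' @param max_loci multi-mapping cap.
#' @return alignment data.frame (see [read_alignments()]) with
#'   attribute `unaligned` (count of dropped reads).
#' @export
align_exact <- function(reads, genome, max_loci = 20L) {
  if (!nrow(reads)) {
    out <- empty_alignments(); attr(out, "unaligned") <- 0L; return(out)
  }
  has_n <- grepl("[^ACGT]", reads$sequence)
  clean <- reads[!has_n, , drop = FALSE]
  if (!nrow(clean)) {
    out <- empty_alignments(); attr(out, "unaligned") <- nrow(reads); return(out)
  }
  rs <- Biostrings::DNAStringSet(clean$sequence)
  pd_f <- Biostrings::PDict(rs)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(rs))
  hits <- list()
  for (ch in names(genome)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r, genome[[ch]])
      st <- Biostrings::startIndex(m)
      n_hit <- lengths(st)
      idx <- which(n_hit > 0)
      if (!length(idx)) next
      hits[[length(hits) + 1]] <- data.frame(
        read_id = rep(clean$read_id[idx], n_hit[idx]),
        chrom = ch,
        start = unlist(st[idx]) - 1L,
        strand = str, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    out <- empty_alignments(); attr(out, "unaligned") <- nrow(reads); return(out)
  }
  aln <- do.call(rbind, hits)
  out <- collapse_alignments(aln, max_loci)
  attr(out, "unaligned") <- nrow(reads) - length(unique(out$read_id))
  out
}

#' Reallocate multi-mapping reads by local unique coverage
#'
#' Builds the start-position coverage of uniquely mapped reads, weights
#' every candidate locus of a multi-read by the unique-read count in a
#' +-`window` bp neighbourhood plus a pseudocount `alpha`, and draws the
#' chosen locus with probability proportional to those weights (a
#' single pass; all-zero neighbourhoods fall back to a uniform draw via
#' the pseudocount). Every multi-read ends up assigned to exactly one
#' locus.
#'
#' @param aln alignment data.frame from [align_exact()] /
#'   [read_alignments()].
#' @param seed seed for the categorical draws.
#' @param window half-width (bp) of the unique-coverage neighbourhood.
#' @param alpha pseudocount.
#' @return `aln` with a logical `chosen` column: one chosen locus per
#'   read.
#' @export
reallocate_multireads <- function(aln, seed = 1L, window = 200L, alpha = 0.1) {
  aln$chosen <- aln$is_unique
  multi_ids <- unique(aln$read_id[!aln$is_unique])
  if (!length(multi_ids)) return(aln)
  uniq <- aln[aln$is_unique, , drop = FALSE]
  starts_by_chrom <- lapply(split(uniq$start, uniq$chrom), sort)
  count_near <- function(chrom, pos) {
    s <- starts_by_chrom[[chrom]]
    if (is.null(s)) return(numeric(length(pos)))
    findInterval(pos + window, s) - findInterval(pos - window - 1L, s)
  }
  midx <- which(!aln$is_unique)
  w <- numeric(nrow(aln))
  for (ch in unique(aln$chrom[midx])) {
    i <- midx[aln$chrom[midx] == ch]
    w[i] <- count_near(ch, aln$start[i])
  }
  groups <- split(midx, aln$read_id[midx])
  with_seed(substream(seed, "realloc"), {
    for (rows in groups) {
      p <- w[rows] + alpha
      aln$chosen[rows[sample.int(length(rows), 1, prob = p)]] <- TRUE
    }
  })
  aln
}

#' Scale coverage to a one-million-read library
#'
#' Multiplies every value by `1e6 / n_reads`, making tracks comparable
#' across libraries of different depth.
#'
#' @param tracks a [coverage_track()] or list of them.
#' @param n_reads library size (> 0).
#' @return scaled track(s).
#' @export
scale_per_million <- function(tracks, n_reads) {
  stopifnot(n_reads > 0)
  one <- function(t) { t$values <- t$values * 1e6 / n_reads; t }
  if (inherits(tracks, "coverage_track")) return(one(tracks))
  lapply(tracks, one)
}

#' Windowed pol III enrichment per gene
#'
#' Mean per-million-scaled coverage in a TSS-centred window for IP and
#' mock, and the mock-relative fold enrichment with a symmetric
#' pseudocount. Windows extending past a chromosome end are clipped with
#' a warning. Pseudogenes are flagged so they can be reported
#' separately.
#'
#' @param ip_tracks,mock_tracks per-million-scaled coverage (lists of
#'   step-1 tracks).
#' @param genes gene data.frame.
#' @param window TSS-relative window `c(from, to)` (bp).
#' @param eps pseudocount (scaled units).
#' @return data.frame(gene_id, family, is_pseudo, ip_mean, mock_mean,
#'   fold).
#' @export
gene_enrichment <- function(ip_tracks, mock_tracks, genes,
                            window = c(-100, 100), eps = 0.5) {
  clipped <- 0L
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    pos <- sort(abs_pos(g, window))
    ipt <- track_for(ip_tracks, g$chrom)
    mot <- track_for(mock_tracks, g$chrom)
    if (is.null(ipt) || is.null(mot)) return(NULL)
    if (pos[1] < ipt$origin || pos[2] + 1 > track_end(ipt)) clipped <<- clipped + 1L
    data.frame(gene_id = g$gene_id, family = g$family, is_pseudo = g$is_pseudo,
               ip_mean = track_mean(ipt, pos[1], pos[2] + 1),
               mock_mean = track_mean(mot, pos[1], pos[2] + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (clipped > 0) warning(sprintf("gene_enrichment: %d gene window(s) clipped at a chromosome end", clipped))
  out$fold <- (out$ip_mean + eps) / (out$mock_mean + eps)
  rownames(out) <- NULL
  out
}
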