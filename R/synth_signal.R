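# MNase readout simulators: tiling-array log2-ratio tracks (array mode)
# and mononucleosome fragments (seq mode).

chrom_lengths_from <- function(truth, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(chrom_lengths)
  g <- truth$genes
  ends <- tapply(pmax(g$tss, g$tts), g$chrom, max)
  stats::setNames(as.integer(ends + 2000L), names(ends))
}

#' Simulate MNase tiling-array log2-ratio tracks
#'
#' Expected probe signal is `log2((background + sum of footprint
#' kernels) / background)` — the nucleosomal/genomic log ratio — plus
#' i.i.d. Gaussian probe noise. Probes tile every `step` bp (4 bp, the
#' array design); the probe coordinate refers to the probe midpoint.
#'
#' @param truth a `synthetic_truth`.
#' @param noise_sd probe noise sd (log2 units).
#' @param step probe spacing (bp).
#' @param seed seed for the noise stream.
#' @param chrom_lengths named chromosome lengths; derived from the gene
#'   table (+2 kb) when omitted.
#' @return list of [coverage_track()]s (kind `"log2ratio"`), one per
#'   chromosome.
#' @export
simulate_mnase_array <- function(truth, noise_sd = 0.3, step = 4L, seed = 1L,
                                 chrom_lengths = NULL) {
  arch <- truth$arch
  cl <- chrom_lengths_from(truth, chrom_lengths)
  half <- arch$footprint / 2
  with_seed(substream(seed, "mnase-array"), {
    lapply(names(cl), function(ch) {
      n_probes <- cl[[ch]] %/% step + 1L
      occ <- rep(arch$background, n_probes)
      nucs <- truth$nucleosomes[truth$nucleosomes$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(nucs))) {
        d <- nucs$dyad[j]
        i0 <- max(1L, ceiling((d - half) / step) + 1L)
        i1 <- min(n_probes, floor((d + half) / step) + 1L)
        if (i0 > i1) next
        pos <- (i0:i1 - 1L) * step
        occ[i0:i1] <- occ[i0:i1] + nucs$occupancy[j] *
          footprint_kernel(pos - d, arch$footprint, arch$taper)
      }
      # sub-nucleosomal upstream encroachment, per gene
      genes <- truth$genes[truth$genes$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(genes))) {
        g <- genes[k, ]
        enc <- truth$gene_truth$encroach[match(g$gene_id, truth$gene_truth$gene_id)]
        lo <- min(abs_pos(g, arch$nfr_start + 1), abs_pos(g, 0))
        hi <- max(abs_pos(g, arch$nfr_start + 1), abs_pos(g, 0))
        i0 <- max(1L, ceiling(lo / step) + 1L); i1 <- min(n_probes, floor(hi / step) + 1L)
        if (i0 <= i1) occ[i0:i1] <- occ[i0:i1] + enc
      }
      coverage_track(ch, log2(occ / arch$background) + rnorm(n_probes, 0, noise_sd),
                     origin = 0L, step = step, kind = "log2ratio")
    })
  })
}

#' Simulate mononucleosome fragments (seq mode)
#'
#' Fragment midpoints are drawn from a mixture over the planted dyads
#' (weights proportional to occupancy, Gaussian positional scatter) with
#' a uniform genomic background component; lengths are Gaussian around
#' `frag_len`. Exactly `n_fragments` fragments are emitted.
#'
#' @param truth a `synthetic_truth`.
#' @param n_fragments number of fragments.
#' @param frag_len nominal fragment length (bp).
#' @param frag_len_jitter fragment-length sd (bp).
#' @param background_frac fraction of fragments from uniform background.
#' @param midpoint_sd scatter of midpoints around the dyad (bp).
#' @param seed seed.
#' @param chrom_lengths named chromosome lengths (see
#'   [simulate_mnase_array()]).
#' @return data.frame(chrom, start, end, strand), 0-based half-open.
#' @export
simulate_mnase_fragments <- function(truth, n_fragments, frag_len = 150L,
                                     frag_len_jitter = 10, background_frac = 0.1,
                                     midpoint_sd = 15, seed = 1L,
                                     chrom_lengths = NULL) {
  stopifnot(n_fragments > 0)
  cl <- chrom_lengths_from(truth, chrom_lengths)
  nucs <- truth$nucleosomes
  with_seed(substream(seed, "mnase-frags"), {
    is_bg <- runif(n_fragments) < background_frac
    n_bg <- sum(is_bg); n_sig <- n_fragments - n_bg
    chrom <- character(n_fragments); mid <- numeric(n_fragments)
    if (n_sig > 0 && nrow(nucs) > 0) {
      pick <- sample(nrow(nucs), n_sig, replace = TRUE, prob = nucs$occupancy)
      chrom[!is_bg] <- nucs$chrom[pick]
      mid[!is_bg] <- nucs$dyad[pick] + rnorm(n_sig, 0, midpoint_sd)
    } else {
      is_bg[] <- TRUE; n_bg <- n_fragments
    }
    if (n_bg > 0) {
      ch <- sample(names(cl), n_bg, replace = TRUE, prob = as.numeric(cl))
      chrom[is_bg] <- ch
      mid[is_bg] <- floor(runif(n_bg) * cl[ch])
    }
    len <- pmax(50L, round(frag_len + rnorm(n_fragments, 0, frag_len_jitter)))
    start <- round(mid - len / 2)
    end <- start + len
    maxlen <- as.numeric(cl[chrom])
    start <- pmax(0, pmin(start, maxlen - 1))
    end <- pmax(start + 1, pmin(end, maxlen))
    data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
               strand = sample(c("+", "-"), n_fragments, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Fragment midpoint counts track
#'
#' @param frags fragment data.frame from [simulate_mnase_fragments()].
#' @param chrom chromosome to tabulate.
#' @param chrom_length its length (bp).
#' @return step-1 counts [coverage_track()] of fragment midpoints.
#' @export
midpoint_track <- function(frags, chrom, chrom_length) {
  f <- frags[frags$chrom == chrom, , drop = FALSE]
  mids <- pmin(chrom_length - 1L, pmax(0L, (f$start + f$end) %/% 2L))
  counts <- tabulate(mids + 1L, nbins = chrom_length)
  coverage_track(chrom, counts, origin = 0L, step = 1L, kind = "counts")
}

#' Turn fragments into 36-bp single-end reads
#'
#' Reads are taken from the fragment 5' end on the fragment's strand,
#' with sequences looked up in `genome` and uniform maximal qualities.
#'
#' @param frags fragment data.frame.
#' @param genome named [Biostrings::DNAStringSet].
#' @param read_len read length (bp).
#' @param prefix read-id prefix.
#' @return data.frame(read_id, sequence, qualities).
#' @export
fragments_to_reads <- function(frags, genome, read_len = 36L, prefix = "frag") {
  w <- stats::setNames(Biostrings::width(genome), names(genome))
  start <- ifelse(frags$strand == "+", frags$start, frags$end - read_len)
  start <- pmax(0L, pmin(as.integer(start), w[frags$chrom] - read_len))
  seqs <- character(nrow(frags))
  for (ch in unique(frags$chrom)) {
    i <- frags$chrom == ch
    v <- Biostrings::Views(genome[[ch]], start = start[i] + 1L,
                           width = read_len)
    s <- as.character(v)
    minus <- frags$strand[i] == "-"
    if (any(minus)) {
      s[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[minus])))
    }
    seqs[i] <- s
  }
  data.frame(read_id = sprintf("%s%06d", prefix, seq_len(nrow(frags))),
             sequence = seqs,
             qualities = strrep("I", read_len), stringsAsFactors = FALSE)
}
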