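# Pol III ChIP-seq simulation and the exact-correlation pair
# construction used for the family-correlation worked example.

#' Construct (occupancy, tag count) pairs with an exact Pearson r
#'
#' Gram-Schmidt construction: a noise vector is orthogonalized against
#' the occupancy vector and the two are mixed so that the *sample*
#' correlation equals `r` exactly (up to floating point), before any
#' read sampling. Used to carry a configured family correlation into
#' [family_correlations()].
#'
#' @param n number of isogenes (>= 3).
#' @param r target sample correlation in `[-1, 0]`.
#' @param seed seed for the occupancy and noise draws.
#' @param family family label for the output rows.
#' @return data.frame(gene_id, family, occupancy, tag_count).
#' @export
make_correlated_pairs <- function(n = 10L, r = -0.6544, seed = 7L,
                                  family = "tP(UGG)") {
  stopifnot(n >= 3, r >= -1, r <= 0)
  with_seed(substream(seed, "pairs"), {
    occ <- runif(n, 0.2, 1.2)
    noise <- rnorm(n)
    x <- if (r == -1) -scale_unit(occ) else correlated_vector(occ, noise, r)
    data.frame(gene_id = paste0(family, "-", seq_len(n)), family = family,
               occupancy = occ, tag_count = 500 + 120 * x,
               stringsAsFactors = FALSE)
  })
}

#' Simulate pol III ChIP-seq reads (IP and mock)
#'
#' IP fragments are centred on gene bodies with per-gene rates
#' proportional to the truth's planted pol III intensities (pseudogenes
#' have intensity 0 and receive background only) plus a uniform genomic
#' background; the mock sample is uniform background. Reads are 36 bp
#' from fragment 5' ends.
#'
#' @param truth a `synthetic_truth` (carries per-gene intensities with
#'   the within-family occupancy anticorrelation planted by
#'   [simulate_nucleosome_truth()]).
#' @param genome named [Biostrings::DNAStringSet].
#' @param n_reads_ip,n_reads_mock library sizes.
#' @param background_frac uniform background fraction of the IP library.
#' @param frag_len ChIP fragment size (bp; sonication average ~180).
#' @param read_len read length (bp).
#' @param seed seed.
#' @return list with `ip` and `mock` read data.frames (see
#'   [fragments_to_reads()]) and the fragment tables `ip_frags`,
#'   `mock_frags`.
#' @export
simulate_pol3_chip <- function(truth, genome, n_reads_ip = 100000L,
                               n_reads_mock = 50000L, background_frac = 0.15,
                               frag_len = 180L, read_len = 36L, seed = 1L) {
  genes <- truth$genes
  gt <- truth$gene_truth
  cl <- stats::setNames(Biostrings::width(genome), names(genome))
  intens <- pmax(0, gt$pol3_intensity)
  intens[gt$is_pseudo] <- 0
  with_seed(substream(seed, "pol3-chip"), {
    ip_frags <- chip_fragments(genes, intens, cl, n_reads_ip, background_frac, frag_len)
    mock_frags <- chip_fragments(genes, intens, cl, n_reads_mock, 1, frag_len)
    list(ip = fragments_to_reads(ip_frags, genome, read_len, prefix = "ip"),
         mock = fragments_to_reads(mock_frags, genome, read_len, prefix = "mock"),
         ip_frags = ip_frags, mock_frags = mock_frags)
  })
}

chip_fragments <- function(genes, intens, chrom_lengths, n, background_frac, frag_len) {
  is_bg <- runif(n) < background_frac
  n_sig <- sum(!is_bg)
  chrom <- character(n); mid <- numeric(n)
  if (n_sig > 0 && sum(intens) > 0) {
    pick <- sample(nrow(genes), n_sig, replace = TRUE, prob = intens)
    g <- genes[pick, ]
    centre <- (g$tss + g$tts) / 2
    chrom[!is_bg] <- g$chrom
    mid[!is_bg] <- round(centre + runif(n_sig, -frag_len / 2, frag_len / 2))
  } else {
    is_bg[] <- TRUE
  }
  n_bg <- sum(is_bg)
  if (n_bg > 0) {
    ch <- sample(names(chrom_lengths), n_bg, replace = TRUE,
                 prob = as.numeric(chrom_lengths))
    chrom[is_bg] <- ch
    mid[is_bg] <- floor(runif(n_bg) * chrom_lengths[ch])
  }
  start <- round(mid - frag_len / 2)
  maxlen <- as.numeric(chrom_lengths[chrom])
  start <- pmax(0, pmin(start, maxlen - frag_len))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + frag_len),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
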