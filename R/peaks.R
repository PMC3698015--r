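# Seq-mode nucleosome calling: fragment extension to coverage and
# Gaussian-kernel peak calling with an exclusion zone.

#' Extend aligned reads/fragment 5' ends into coverage
#'
#' Each record contributes +1 over `frag_len` bp in its strand
#' orientation: plus-strand records cover `[start, start + frag_len)`;
#' minus-strand records cover the `frag_len` bp ending at their 5' end
#' (`[start + read_len - frag_len, start + read_len)`). Extension past
#' a chromosome end is clipped and the clipped mass counted.
#'
#' @param aln data.frame(chrom, start, strand) of alignment starts
#'   (leftmost base, 0-based).
#' @param chrom_lengths named chromosome lengths.
#' @param frag_len extension length (bp): ~180 for ChIP fragments,
#'   150 for MNase.
#' @param read_len aligned read length (bp).
#' @return list of step-1 counts [coverage_track()]s with attribute
#'   `clipped_bases`.
#' @export
extend_fragments <- function(aln, chrom_lengths, frag_len = 150L, read_len = 36L) {
  clipped <- 0
  tracks <- lapply(names(chrom_lengths), function(ch) {
    n <- as.integer(chrom_lengths[[ch]])
    a <- aln[aln$chrom == ch, , drop = FALSE]
    d <- numeric(n + 1L)
    if (nrow(a)) {
      s <- ifelse(a$strand == "+", a$start, a$start + read_len - frag_len)
      e <- s + frag_len
      cs <- pmax(0L, pmin(as.integer(s), n))
      ce <- pmax(0L, pmin(as.integer(e), n))
      clipped <<- clipped + sum((e - s) - (ce - cs))
      inc <- tabulate(cs + 1L, nbins = n + 1L)
      dec <- tabulate(ce + 1L, nbins = n + 1L)
      d <- inc - dec
    }
    coverage_track(ch, cumsum(d)[seq_len(n)], origin = 0L, step = 1L,
                   kind = "counts")
  })
  attr(tracks, "clipped_bases") <- clipped
  tracks
}

#' Gaussian-kernel nucleosome peak calling
#'
#' Midpoint counts are smoothed with a Gaussian kernel (sd `sigma`);
#' local maxima are accepted greedily in order of decreasing height
#' (leftmost first on ties), and any maximum within `exclusion` bp of an
#' accepted dyad is suppressed. The call footprint is
#' dyad +- `exclusion`/2.
#'
#' @param track step-1 counts [coverage_track()] of fragment midpoints.
#' @param sigma kernel sd (bp).
#' @param exclusion minimum distance between accepted dyads (bp).
#' @return call data.frame (source `"seq_kernel"`).
#' @export
call_peaks_kernel <- function(track, sigma = 20, exclusion = 147) {
  stopifnot(track$step == 1L, track$kind == "counts")
  x <- track$values
  if (!length(x) || all(x == 0)) return(empty_calls())
  h <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k <- k / sum(k)
  s <- as.numeric(stats::filter(x, k, sides = 2))
  s[is.na(s)] <- 0
  n <- length(s)
  left <- c(-Inf, s[-n]); right <- c(s[-1], -Inf)
  peaks <- which(s > 0 & s > left & s >= right)
  if (!length(peaks)) return(empty_calls())
  peaks <- peaks[order(-s[peaks], peaks)]
  accepted <- integer(0)
  for (p in peaks) {
    if (!length(accepted) || all(abs(accepted - p) >= exclusion)) {
      accepted <- c(accepted, p)
    }
  }
  accepted <- sort(accepted)
  dyad <- track$origin + accepted - 1L
  half <- floor(exclusion / 2)
  data.frame(chrom = track$chrom, start = dyad - half, end = dyad + half + 1L,
             dyad = dyad, occupancy = s[accepted], positioned = TRUE,
             source = "seq_kernel", stringsAsFactors = FALSE)
}
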