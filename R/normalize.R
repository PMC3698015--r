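# Two-channel array normalization and probe smoothing.

#' Normalize a two-channel array against blanks, then Lowess
#'
#' Each channel is divided by the median intensity of its blank spots;
#' the log2 ratio M = log2(Cy5/Cy3) is then detrended for
#' intensity-dependent dye bias by locally weighted regression of M on
#' A = 0.5*log2(Cy5*Cy3) (span 0.3, 2 robustness iterations), and the
#' fitted trend subtracted.
#'
#' @param raw data.frame with columns probe_id, chrom, pos, cy5, cy3.
#' @param blank_ids probe_ids of blank spots (>= 10 required).
#' @param span Lowess span.
#' @param iter Lowess robustness iterations.
#' @return list of [coverage_track()]s (kind `"log2ratio"`), one per
#'   chromosome, probe step inferred from positions.
#' @export
normalize_two_channel <- function(raw, blank_ids, span = 0.3, iter = 2) {
  stopifnot(all(c("probe_id", "chrom", "pos", "cy5", "cy3") %in% names(raw)))
  if (sum(raw$probe_id %in% blank_ids) < 10) {
    stop("normalize_two_channel: need at least 10 blank probes")
  }
  bad <- raw$cy5 <= 0 | raw$cy3 <= 0
  if (any(bad)) {
    warning(sprintf("normalize_two_channel: dropping %d probe(s) with nonpositive intensities",
                    sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  blanks <- raw[raw$probe_id %in% blank_ids, ]
  cy5 <- raw$cy5 / median(blanks$cy5)
  cy3 <- raw$cy3 / median(blanks$cy3)
  keep <- !raw$probe_id %in% blank_ids
  m <- log2(cy5 / cy3)[keep]
  a <- 0.5 * log2(cy5 * cy3)[keep]
  fit <- lowess(a, m, f = span, iter = iter)
  m <- m - stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
  probes <- raw[keep, , drop = FALSE]
  probes$m <- m
  lapply(split(probes, probes$chrom), function(p) {
    p <- p[order(p$pos), ]
    step <- if (nrow(p) > 1) min(diff(p$pos)) else 1L
    coverage_track(p$chrom[1], p$m, origin = p$pos[1], step = step,
                   kind = "log2ratio")
  })
}

#' Moving-average smoothing of a track
#'
#' `window`-probe centred moving average (the 3-point smoothing used
#' ahead of segmentation); edges use a shrinking window so track length
#' is preserved and a constant track is unchanged.
#'
#' @param track a [coverage_track()].
#' @param window odd window size in probes.
#' @return smoothed [coverage_track()].
#' @export
smooth_track <- function(track, window = 3L) {
  stopifnot(window %% 2 == 1)
  n <- length(track$values)
  if (window > n) stop("smooth_track: window larger than track")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, track$values))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  track$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  track
}
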