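# CoverageTrack: per-base or per-probe numeric signal on one chromosome.
# Positions are 0-based; values[i] is the signal at origin + (i-1)*step.

#' Construct a coverage track
#'
#' A track holds an ordered vector of finite signal values sampled every
#' `step` bp along one chromosome, starting at `origin` (0-based). `kind`
#' distinguishes read-count tracks (seq mode, step 1) from log2-ratio
#' tracks (tiling-array mode, step 4).
#'
#' @param chrom chromosome name.
#' @param values numeric vector of finite values.
#' @param origin 0-based coordinate of the first value.
#' @param step spacing in bp between consecutive values (>= 1).
#' @param kind one of `"counts"`, `"log2ratio"`.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, values, origin = 0L, step = 1L,
                           kind = c("counts", "log2ratio")) {
  kind <- match.arg(kind)
  stopifnot(length(chrom) == 1L, length(values) >= 1L, step >= 1L)
  if (!all(is.finite(values))) stop("coverage_track: all values must be finite")
  structure(
    list(chrom = as.character(chrom), origin = as.integer(origin),
         step = as.integer(step), values = as.numeric(values), kind = kind),
    class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:%d-%d step %d (%s), %d values\n",
              x$chrom, x$origin, track_end(x), x$step, x$kind,
              length(x$values)))
  invisible(x)
}

# One past the last covered base.
track_end <- function(track) track$origin + (length(track$values) - 1L) * track$step + 1L

# Genomic positions sampled by the track.
track_positions <- function(track) {
  track$origin + (seq_along(track$values) - 1L) * track$step
}

#' Signal values over a genomic interval
#'
#' Returns the track values whose sampled positions fall in
#' `[start, end)` (0-based half-open). Positions outside the track are
#' dropped; an empty result means the interval is uncovered.
#'
#' @param track a `coverage_track`.
#' @param start,end 0-based half-open interval.
#' @return numeric vector (possibly empty).
#' @export
track_slice <- function(track, start, end) {
  i0 <- ceiling((start - track$origin) / track$step) + 1
  i1 <- floor((end - 1 - track$origin) / track$step) + 1
  i0 <- max(1, i0); i1 <- min(length(track$values), i1)
  if (i0 > i1) return(numeric(0))
  track$values[i0:i1]
}

# Mean signal over [start, end); NA when uncovered.
track_mean <- function(track, start, end) {
  v <- track_slice(track, start, end)
  if (length(v) == 0) NA_real_ else mean(v)
}

# Look up the track for a chromosome in a list of tracks.
track_for <- function(tracks, chrom) {
  if (inherits(tracks, "coverage_track")) {
    if (tracks$chrom == chrom) return(tracks) else return(NULL)
  }
  for (t in tracks) if (t$chrom == chrom) return(t)
  NULL
}
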