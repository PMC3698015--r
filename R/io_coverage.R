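# bedGraph / fixed-step WIG writers and readers for coverage tracks.

#' Write a coverage track as bedGraph or fixed-step WIG
#'
#' bedGraph output merges runs of equal adjacent values into single
#' intervals (step-1 tracks only); tracks with step > 1 are written as
#' fixed-step WIG. Round-tripping through [read_coverage()] recovers the
#' values at every sampled position.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @param format `"bedGraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "bedGraph" && track$step > 1L) {
    stop("write_coverage: step > 1 tracks are written as fixed-step wig only")
  }
  if (format == "bedGraph") {
    r <- rle(track$values)
    end <- track$origin + cumsum(r$lengths)
    start <- c(track$origin, head(end, -1))
    writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, start, end,
                       format_sig(r$values)), path)
  } else {
    # WIG is 1-based; span marks the step footprint of each value.
    writeLines(c(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         track$chrom, track$origin + 1L, track$step, track$step),
                 format_sig(track$values)), path)
  }
  invisible(path)
}

format_sig <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  trimws(out)
}

#' Read a coverage track from bedGraph or fixed-step WIG
#'
#' @param path input file written by [write_coverage()] (or equivalent).
#' @param kind value kind to stamp on the track.
#' @return a [coverage_track()] (bedGraph input is expanded to step 1).
#' @export
read_coverage <- function(path, kind = c("counts", "log2ratio")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) stop("read_coverage: empty file")
  if (grepl("^fixedStep", lines[1])) {
    hdr <- lines[1]
    get <- function(k) sub(sprintf(".*%s=([^ ]+).*", k), "\\1", hdr)
    vals <- as.numeric(lines[-1])
    coverage_track(get("chrom"), vals,
                   origin = as.integer(get("start")) - 1L,
                   step = as.integer(get("step")), kind = kind)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    m <- do.call(rbind, parts)
    start <- as.integer(m[, 2]); end <- as.integer(m[, 3]); v <- as.numeric(m[, 4])
    if (any(diff(start) < 0)) stop("read_coverage: bedGraph intervals must be sorted")
    # zero-fill gaps between intervals so positions stay aligned
    gap <- c(0L, pmax(0L, start[-1] - end[-length(end)]))
    pieces <- vector("list", 2L * length(v))
    pieces[seq(1, by = 2, length.out = length(v))] <- lapply(gap, function(g) rep(0, g))
    pieces[seq(2, by = 2, length.out = length(v))] <-
      lapply(seq_along(v), function(i) rep(v[i], end[i] - start[i]))
    coverage_track(m[1, 1], unlist(pieces), origin = start[1], step = 1L, kind = kind)
  }
}
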