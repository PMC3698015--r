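# Strand-aware meta-gene binning, averaged profiles, periodicity and
# heat-map export.

#' Bin signal around gene anchors into a meta-gene matrix
#'
#' For every gene, track values in a +-`window` bp region around the
#' anchor (TSS or TTS) are averaged in `bin`-bp bins on the
#' transcription-oriented axis: minus-strand rows are flipped so column
#' order always runs upstream -> downstream, and upstream bin centres
#' are negative. Bins not covered by the track are missing (`NA`), never
#' zero; a gene on a chromosome without a track gets an all-missing row
#' with a warning.
#'
#' @param tracks [coverage_track()] or list of them.
#' @param genes gene data.frame (pseudogenes are excluded by default).
#' @param anchor `"tss"` or `"tts"`.
#' @param window half-width (bp).
#' @param bin bin width (bp).
#' @param include_pseudo include pseudogenes as rows.
#' @return `meta_matrix`: genes x bins numeric matrix; column names are
#'   bin centres (bp relative to the anchor), attributes `anchor`,
#'   `bin`, `window`.
#' @export
bin_around <- function(tracks, genes, anchor = c("tss", "tts"),
                       window = 1000L, bin = 20L, include_pseudo = FALSE) {
  anchor <- match.arg(anchor)
  if (!include_pseudo) genes <- genes[!genes$is_pseudo, , drop = FALSE]
  centers <- seq(-window + bin / 2, window - bin / 2, by = bin)
  lo <- centers - bin / 2
  m <- matrix(NA_real_, nrow(genes), length(centers),
              dimnames = list(genes$gene_id, centers))
  missing_chrom <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tr <- track_for(tracks, g$chrom)
    if (is.null(tr)) { missing_chrom <- c(missing_chrom, g$gene_id); next }
    a <- if (anchor == "tss") g$tss else g$tts
    gene0 <- g; gene0$tss <- a   # rel axis anchored at `a`
    for (j in seq_along(centers)) {
      r0 <- lo[j]; r1 <- lo[j] + bin
      gpos <- sort(abs_pos(gene0, c(r0, r1 - 1)))
      m[i, j] <- track_mean(tr, gpos[1], gpos[2] + 1)
    }
  }
  if (length(missing_chrom)) {
    warning(sprintf("bin_around: %d gene(s) on chromosomes without a track (all-missing rows)",
                    length(missing_chrom)))
  }
  structure(m, anchor = anchor, bin = bin, window = window,
            kind = if (inherits(tracks, "coverage_track")) tracks$kind
                   else tracks[[1]]$kind,
            class = c("meta_matrix", "matrix"))
}

#' Column-average a meta-gene matrix into a profile
#'
#' Missing bins are excluded from the averages; the per-column count of
#' contributing genes is returned alongside.
#'
#' @param mm a `meta_matrix` from [bin_around()].
#' @return `meta_profile` data.frame(pos, mean, sd, n).
#' @export
average_profile <- function(mm) {
  pos <- as.numeric(colnames(mm))
  n <- colSums(!is.na(mm))
  structure(data.frame(pos = pos, mean = colMeans(mm, na.rm = TRUE),
                       sd = apply(mm, 2, sd, na.rm = TRUE), n = n),
            anchor = attr(mm, "anchor"), bin = attr(mm, "bin"),
            class = c("meta_profile", "data.frame"))
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$pos, x$mean, type = "l",
                 xlab = sprintf("distance from %s (bp)", toupper(attr(x, "anchor") %||% "anchor")),
                 ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Meta-gene density profile of called dyads
#'
#' Bins the TSS-relative dyads of assigned nucleosome calls (the
#' called peaks, not the raw signal) into a per-gene average count
#' profile. The modal dyad of a positioned nucleosome class shows up as
#' a sharp peak; use [architecture_from_profile()] with
#' `linearize = FALSE` to read peak positions off it.
#'
#' @param assigned assigned calls (see [assign_calls_to_genes()]).
#' @param genes gene data.frame.
#' @param window half-width (bp).
#' @param bin bin width (bp).
#' @param positioned_only drop delocalized calls first.
#' @param include_pseudo include pseudogenes.
#' @return `meta_profile` data.frame(pos, mean, n): mean dyads per gene
#'   per bin.
#' @export
dyad_profile <- function(assigned, genes, window = 1000L, bin = 20L,
                         positioned_only = FALSE, include_pseudo = FALSE) {
  if (!include_pseudo) {
    keep <- genes$gene_id[!genes$is_pseudo]
    assigned <- assigned[assigned$gene_id %in% keep, , drop = FALSE]
    n_genes <- length(keep)
  } else n_genes <- nrow(genes)
  if (positioned_only) assigned <- assigned[assigned$positioned, , drop = FALSE]
  centers <- seq(-window + bin / 2, window - bin / 2, by = bin)
  d <- assigned$dyad_rel
  d <- d[d >= -window & d < window]
  counts <- tabulate(floor((d + window) / bin) + 1L, nbins = length(centers))
  structure(data.frame(pos = centers, mean = counts / n_genes, n = n_genes),
            anchor = "tss", bin = bin,
            class = c("meta_profile", "data.frame"))
}

#' Upstream nucleosome repeat length from a profile
#'
#' Autocorrelation of the mean-subtracted upstream portion
#' (-1000..-200 bp) of an averaged profile; the repeat length is the lag
#' of the first local autocorrelation maximum inside `search_range`,
#' refined by parabolic interpolation. A weak maximum (below
#' `min_acf`) is reported as low-confidence; none in range gives
#' `NA`.
#'
#' @param profile a `meta_profile` (TSS-anchored, covering -1000..-200).
#' @param search_range repeat-length search window (bp).
#' @param min_acf confidence floor on the autocorrelation peak.
#' @return list(period, acf_peak, confident).
#' @export
upstream_periodicity <- function(profile, search_range = c(120, 220), min_acf = 0.2) {
  up <- profile[profile$pos >= -1000 & profile$pos <= -200 & is.finite(profile$mean), ]
  bin <- attr(profile, "bin") %||% diff(profile$pos[1:2])
  if (nrow(up) < 10) return(list(period = NA_real_, acf_peak = NA_real_, confident = FALSE))
  x <- up$mean - mean(up$mean)
  max_lag <- min(nrow(up) - 1, ceiling(search_range[2] / bin) + 1)
  ac <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)
  lags <- (seq_along(ac) - 1) * bin
  cand <- which(lags >= search_range[1] & lags <= search_range[2])
  cand <- cand[cand > 1 & cand < length(ac)]
  is_max <- cand[ac[cand] > ac[cand - 1] & ac[cand] >= ac[cand + 1]]
  if (!length(is_max)) return(list(period = NA_real_, acf_peak = NA_real_, confident = FALSE))
  k <- is_max[1]
  denom <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
  off <- if (abs(denom) > 1e-12) 0.5 * (ac[k - 1] - ac[k + 1]) / denom else 0
  list(period = lags[k] + off * bin, acf_peak = ac[k],
       confident = ac[k] >= min_acf)
}

#' Export a meta-gene matrix as TSV and heat-map image
#'
#' Rows can be sorted by downstream-nucleosome distance from the TTS
#' (ties broken by family, then input order; the sort is stable) or by
#' family alone.
#'
#' @param mm a `meta_matrix`.
#' @param path_prefix output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.png`.
#' @param sort_key `"none"`, `"family"`, or `"ds_distance_then_family"`.
#' @param genes gene data.frame (needed for family sorting).
#' @param architecture per-gene architecture (needed for ds_distance
#'   sorting; see [extract_architecture()]).
#' @return the row-sorted matrix, invisibly.
#' @export
heatmap_export <- function(mm, path_prefix, sort_key = c("none", "family",
                                                         "ds_distance_then_family"),
                           genes = NULL, architecture = NULL) {
  sort_key <- match.arg(sort_key)
  ord <- seq_len(nrow(mm))
  if (sort_key != "none") {
    fam <- genes$family[match(rownames(mm), genes$gene_id)]
    ord <- if (sort_key == "family") order(fam) else {
      if (is.null(architecture)) stop("heatmap_export: ds_distance sort needs the architecture table")
      ds <- architecture$ds_dyad_tts[match(rownames(mm), architecture$gene_id)]
      order(ds, fam, na.last = TRUE)
    }
  }
  out <- mm[ord, , drop = FALSE]
  write.table(data.frame(gene_id = rownames(out), out, check.names = FALSE),
              paste0(path_prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  grDevices::png(paste0(path_prefix, ".png"), width = 800, height = 600)
  op <- graphics::par(mar = c(4, 4, 1, 1)); on.exit({ graphics::par(op); grDevices::dev.off() })
  z <- t(out[rev(seq_len(nrow(out))), , drop = FALSE])
  graphics::image(x = as.numeric(colnames(mm)), y = seq_len(nrow(out)), z = z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "distance from anchor (bp)", ylab = "genes", useRaster = TRUE)
  invisible(out)
}
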