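# tDNA architecture extraction: upstream/downstream nucleosome, NFR
# boundaries, positioned/fuzzy classification — from per-gene calls or
# from an averaged profile.

#' Assign nucleosome calls to genes in TSS-relative coordinates
#'
#' Calls whose dyad lies within `window` bp of a gene's span are
#' attached to that gene, with dyad and footprint re-expressed on the
#' transcription-oriented TSS-relative axis (and the dyad also relative
#' to the TTS).
#'
#' @param calls genomic call data.frame (from [call_nucleosomes()] or
#'   [call_peaks_kernel()]).
#' @param genes gene data.frame.
#' @param window assignment half-width (bp) around the gene span.
#' @return calls with gene_id, dyad_rel, start_rel, end_rel,
#'   dyad_rel_tts columns (a call can appear under several genes).
#' @export
assign_calls_to_genes <- function(calls, genes, window = 1000L) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    lo <- min(g$tss, g$tts) - window
    hi <- max(g$tss, g$tts) + window
    k <- calls$chrom == g$chrom & calls$dyad >= lo & calls$dyad <= hi
    if (!any(k)) return(NULL)
    cc <- calls[k, , drop = FALSE]
    r1 <- rel_pos(g, cc$start); r2 <- rel_pos(g, cc$end - 1L)
    cc$gene_id <- g$gene_id
    cc$dyad_rel <- rel_pos(g, cc$dyad)
    cc$start_rel <- pmin(r1, r2)
    cc$end_rel <- pmax(r1, r2) + 1L
    cc$dyad_rel_tts <- cc$dyad_rel - (g$length - 1L)
    cc
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- cbind(empty_calls(),
                 data.frame(gene_id = character(0), dyad_rel = numeric(0),
                            start_rel = numeric(0), end_rel = numeric(0),
                            dyad_rel_tts = numeric(0)))
  }
  rownames(res) <- NULL
  res
}

#' Extract tDNA architecture
#'
#' Dispatches on input: a `meta_profile` gives one architecture for the
#' averaged profile ([architecture_from_profile()]); an assigned call
#' table gives a per-gene architecture ([architecture_from_calls()]).
#'
#' @param x `meta_profile` or assigned calls (see
#'   [assign_calls_to_genes()]).
#' @param ... passed on.
#' @return see the respective worker.
#' @export
extract_architecture <- function(x, ...) {
  if (inherits(x, "meta_profile")) architecture_from_profile(x, ...)
  else architecture_from_calls(x, ...)
}

#' Architecture of an averaged meta-gene profile
#'
#' Works on the linearized signal (`2^value` for log2-ratio profiles).
#' The upstream (-1) peak is the maximum in `us_window`; the downstream
#' (+1) peak the maximum in `ds_window`; both positions are refined by
#' parabolic interpolation. The NFR is the maximal interval around the
#' inter-peak minimum where the linearized signal stays below
#' `baseline + nfr_threshold_frac * (mean flanking-peak height -
#' baseline)`; boundaries are reported at the (interpolated) crossing
#' positions. Raising the threshold can only widen the reported NFR.
#'
#' @param profile TSS-anchored `meta_profile`.
#' @param nfr_threshold_frac crossing threshold as a fraction of the
#'   baseline-to-peak height.
#' @param us_window,ds_window search windows (bp relative to TSS).
#' @param linearize undo the log2 before thresholding (set `FALSE` for
#'   linear-scale profiles).
#' @return list of class `tdna_architecture`: us_dyad, us_height,
#'   ds_dyad, ds_height, nfr_start, nfr_end, nfr_length,
#'   nfr_threshold.
#' @export
architecture_from_profile <- function(profile, nfr_threshold_frac = 0.5,
                                      us_window = c(-300, -40),
                                      ds_window = c(60, 400),
                                      linearize = TRUE) {
  pos <- profile$pos
  v <- if (linearize) 2^profile$mean else profile$mean
  # The -1/+1 nucleosome is the flanking peak *bordering* the NFR: among
  # qualifying local maxima in the window (>= 50% of the window maximum)
  # take the one nearest the gene, refined by parabolic interpolation.
  peak <- function(win, side) {
    i <- which(pos >= win[1] & pos <= win[2] & is.finite(v))
    if (!length(i)) return(NULL)
    locmax <- i[v[i] >= c(-Inf, v)[i] & v[i] >= c(v, -Inf)[i + 1] &
                  v[i] >= 0.5 * max(v[i])]
    k <- if (length(locmax)) {
      if (side == "us") max(locmax) else min(locmax)
    } else i[which.max(v[i])]
    off <- 0
    if (k > 1 && k < length(v)) {
      den <- v[k - 1] - 2 * v[k] + v[k + 1]
      if (abs(den) > 1e-12) off <- 0.5 * (v[k - 1] - v[k + 1]) / den
      off <- max(-1, min(1, off))
    }
    list(pos = pos[k] + off * (pos[2] - pos[1]), height = v[k], idx = k)
  }
  us <- peak(us_window, "us"); ds <- peak(ds_window, "ds")
  if (is.null(us) || is.null(ds)) {
    return(structure(list(us_dyad = us$pos %||% NA_real_, us_height = us$height %||% NA_real_,
                          ds_dyad = ds$pos %||% NA_real_, ds_height = ds$height %||% NA_real_,
                          nfr_start = NA_real_, nfr_end = NA_real_,
                          nfr_length = NA_real_, nfr_threshold = NA_real_),
                     class = "tdna_architecture"))
  }
  between <- us$idx:ds$idx
  vmin_idx <- between[which.min(v[between])]
  baseline <- v[vmin_idx]
  thr <- baseline + nfr_threshold_frac * (mean(c(us$height, ds$height)) - baseline)
  cross <- function(dir) {
    i <- vmin_idx
    while (i + dir >= 1 && i + dir <= length(v) && v[i + dir] < thr) i <- i + dir
    j <- i + dir
    if (j < 1 || j > length(v) || !is.finite(v[j])) return(pos[i])
    # linear interpolation between the last sub-threshold and first
    # super-threshold bin centres
    pos[i] + dir * (thr - v[i]) / (v[j] - v[i]) * abs(pos[j] - pos[i])
  }
  nfr_start <- cross(-1L); nfr_end <- cross(1L)
  structure(list(us_dyad = us$pos, us_height = us$height,
                 ds_dyad = ds$pos, ds_height = ds$height,
                 nfr_start = nfr_start, nfr_end = nfr_end,
                 nfr_length = nfr_end - nfr_start, nfr_threshold = thr),
            class = "tdna_architecture")
}

#' @export
print.tdna_architecture <- function(x, ...) {
  cat(sprintf("<tdna_architecture> US dyad %.1f bp, NFR %.1f..%.1f bp (len %.1f), DS peak %.1f bp\n",
              x$us_dyad, x$nfr_start, x$nfr_end, x$nfr_length, x$ds_dyad))
  invisible(x)
}

#' Per-gene architecture from assigned nucleosome calls
#'
#' The upstream (-1) nucleosome is the call with dyad in `us_window`
#' nearest the TSS; the downstream (+1) the call with dyad (relative to
#' the TTS) in `ds_window` nearest the TTS. A gene's upstream nucleosome
#' is *positioned* when a call exists, its footprint is at most
#' `max_positioned_len` bp, and its dyad lies within `positioned_tol` bp
#' of the family's modal upstream dyad (families with fewer than 3
#' upstream calls use the global mode); genes without an upstream call
#' count as not positioned. Calls overlapping the gene body set the
#' `nuc_plus` flag. Per-gene NFR boundaries are the upstream-call
#' footprint end and downstream-call footprint start.
#'
#' @param calls assigned calls (see [assign_calls_to_genes()]).
#' @param genes gene data.frame.
#' @param us_window,ds_window dyad search windows (bp, TSS- and
#'   TTS-relative).
#' @param positioned_tol dyad tolerance around the family modal dyad.
#' @param max_positioned_len footprint bound for a positioned call.
#' @param mode_bin bin width for the modal-dyad estimate.
#' @return data.frame, one row per gene: us_dyad, us_len,
#'   us_positioned, us_occupancy, ds_dyad_tts, nfr_start, nfr_end,
#'   nuc_plus.
#' @export
architecture_from_calls <- function(calls, genes, us_window = c(-300, -40),
                                    ds_window = c(-40, 300),
                                    positioned_tol = 40,
                                    max_positioned_len = 250,
                                    mode_bin = 20) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cc <- calls[calls$gene_id == g$gene_id, , drop = FALSE]
    us <- cc[cc$dyad_rel >= us_window[1] & cc$dyad_rel <= us_window[2], , drop = FALSE]
    us <- if (nrow(us)) us[which.max(us$dyad_rel), ] else NULL
    ds <- cc[cc$dyad_rel_tts >= ds_window[1] & cc$dyad_rel_tts <= ds_window[2], , drop = FALSE]
    ds <- if (nrow(ds)) ds[which.min(ds$dyad_rel_tts), ] else NULL
    body_hit <- any(cc$start_rel < g$length & cc$end_rel > 0)
    data.frame(
      gene_id = g$gene_id, family = g$family, is_pseudo = g$is_pseudo,
      us_dyad = if (is.null(us)) NA_real_ else us$dyad_rel,
      us_len = if (is.null(us)) NA_real_ else us$end_rel - us$start_rel,
      us_call_positioned = if (is.null(us)) NA else us$positioned,
      us_occupancy = if (is.null(us)) NA_real_ else us$occupancy,
      ds_dyad_tts = if (is.null(ds)) NA_real_ else ds$dyad_rel_tts,
      nfr_start = if (is.null(us)) NA_real_ else us$end_rel,
      nfr_end = if (is.null(ds)) NA_real_ else ds$start_rel,
      nuc_plus = body_hit, stringsAsFactors = FALSE)
  })
  arch <- do.call(rbind, rows)
  # positioned = small footprint + dyad near the family's modal dyad
  global_mode <- modal_value(arch$us_dyad, mode_bin)
  fam_mode <- vapply(arch$family, function(f) {
    d <- arch$us_dyad[arch$family == f]
    d <- d[is.finite(d)]
    if (length(d) >= 3) modal_value(d, mode_bin) else global_mode
  }, numeric(1))
  arch$us_positioned <- !is.na(arch$us_dyad) &
    arch$us_len <= max_positioned_len &
    !is.na(arch$us_call_positioned) & arch$us_call_positioned &
    abs(arch$us_dyad - fam_mode) <= positioned_tol
  rownames(arch) <- NULL
  arch
}

# Mode of a numeric vector by binning: weighted mean of the values in
# the modal bin and its neighbours.
modal_value <- function(x, bin = 20) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  b <- floor(x / bin)
  tab <- table(b)
  mb <- as.numeric(names(tab)[which.max(tab)])
  mean(x[b >= mb - 1 & b <= mb + 1])
}

#' Fraction of genes with a positioned upstream nucleosome
#'
#' @param arch per-gene architecture from [architecture_from_calls()].
#' @param include_pseudo count pseudogenes too.
#' @return fraction in `[0, 1]`.
#' @export
positioned_fraction <- function(arch, include_pseudo = FALSE) {
  if (!include_pseudo) arch <- arch[!arch$is_pseudo, , drop = FALSE]
  mean(arch$us_positioned)
}
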