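# Occupancy/pol III quantification: windowed means, family-wise
# correlations, and ddCt relative qPCR quantification.

# Mean track signal over a TSS-relative region, transcription oriented;
# clipped at track edges with a warning.
region_mean <- function(gene, tracks, region) {
  tr <- track_for(tracks, gene$chrom)
  if (is.null(tr)) return(NA_real_)
  gpos <- sort(abs_pos(gene, region))
  lo <- gpos[1]; hi <- gpos[2] + 1
  if (lo < tr$origin || hi > track_end(tr)) {
    warning(sprintf("region clipped at a chromosome end for gene %s", gene$gene_id))
  }
  track_mean(tr, lo, hi)
}

#' Mean nucleosome occupancy upstream of the TSS
#'
#' Average signal over the TFIIIB-binding region (-60 bp to the TSS by
#' default), in transcription orientation.
#'
#' @param gene one-row gene data.frame.
#' @param tracks nucleosome signal track(s).
#' @param region TSS-relative region `c(from, to)`.
#' @return mean signal (NA when uncovered).
#' @export
upstream_occupancy <- function(gene, tracks, region = c(-60, 0)) {
  region_mean(gene, tracks, region)
}

#' Mean pol III tag count over the gene region
#'
#' Average per-million-scaled tag coverage in a TSS-centred window
#' (-100..+100 bp by default).
#'
#' @param gene one-row gene data.frame.
#' @param tracks per-million-scaled coverage track(s).
#' @param region TSS-relative region `c(from, to)`.
#' @return mean scaled tags (NA when uncovered).
#' @export
pol3_window_count <- function(gene, tracks, region = c(-100, 100)) {
  region_mean(gene, tracks, region)
}

#' Family-wise Pearson correlation of occupancy and pol III level
#'
#' For each anticodon family with at least `min_isogenes` members the
#' sample Pearson correlation between per-gene upstream occupancy and
#' pol III tag count is computed; smaller families, or families with a
#' zero-variance vector, are reported without an r (with a reason).
#' Optionally a leave-one-out diagnostic reports, per family, the most
#' negative r achievable by dropping a single gene — an upper bound on
#' the effect of one outlier, clearly separated from the primary r.
#'
#' @param pairs data.frame(gene_id, family, occupancy, tag_count).
#' @param min_isogenes minimum family size for an r.
#' @param leave_one_out add the `loo_best_r` diagnostic column.
#' @return data.frame(family, n_isogenes, pearson_r, reason
#'   \[, loo_best_r\]).
#' @export
family_correlations <- function(pairs, min_isogenes = 3L, leave_one_out = FALSE) {
  stopifnot(all(c("family", "occupancy", "tag_count") %in% names(pairs)))
  rows <- lapply(split(pairs, pairs$family), function(p) {
    n <- nrow(p)
    r <- NA_real_; reason <- ""
    if (n < min_isogenes) {
      reason <- sprintf("fewer than %d isogenes", min_isogenes)
    } else if (sd(p$occupancy) == 0 || sd(p$tag_count) == 0) {
      reason <- "zero variance"
    } else {
      r <- cor(p$occupancy, p$tag_count)
    }
    out <- data.frame(family = p$family[1], n_isogenes = n, pearson_r = r,
                      reason = reason, stringsAsFactors = FALSE)
    if (leave_one_out) {
      out$loo_best_r <- if (n >= min_isogenes + 1) {
        min(vapply(seq_len(n), function(i)
          suppressWarnings(cor(p$occupancy[-i], p$tag_count[-i])), numeric(1)),
          na.rm = TRUE)
      } else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Relative quantification by the ddCt method
#'
#' `relative_level = 2^-[(Ct_target - Ct_reference)_sample -
#' (Ct_target - Ct_reference)_calibrator]`. With a genomic-DNA
#' calibrator this normalizes gene copy number away, so levels are
#' comparable between families. Any Ct of 40 cycles or more flags the
#' row unreliable (still reported).
#'
#' @param m data.frame with columns ct_target, ct_reference,
#'   ct_target_cal, ct_reference_cal (e.g. from [simulate_qpcr()]).
#' @return `m` with `relative_level` and `unreliable` columns.
#' @export
delta_delta_ct <- function(m) {
  need <- c("ct_target", "ct_reference", "ct_target_cal", "ct_reference_cal")
  stopifnot(all(need %in% names(m)))
  ddct <- (m$ct_target - m$ct_reference) - (m$ct_target_cal - m$ct_reference_cal)
  m$relative_level <- 2^(-ddct)
  m$unreliable <- apply(m[need] >= 40, 1, any)
  m
}
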