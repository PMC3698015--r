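# qPCR simulation: Ct tables for the ddCt relative quantification,
# with a genomic-DNA calibrator encoding gene copy number and a fixed
# pol II reference transcript (U4-like).

#' Simulate a qPCR Ct table
#'
#' Each primer set measures the pooled abundance of all genes it covers
#' (primers are generally not isogene-specific): the sample target Ct is
#' `offset - log2(pooled abundance)` plus optional cycle noise; doubling
#' a family's abundance therefore lowers its expected Ct by one cycle.
#' The calibrator reaction runs on genomic DNA, so its target Ct encodes
#' the covered copy number, which is how ddCt normalizes family copy
#' number away. The reference primer measures a fixed single-copy pol II
#' transcript.
#'
#' @param truth a `synthetic_truth`; planted pol III intensities are
#'   taken as transcript abundances.
#' @param primer_map named list family -> character vector of gene ids
#'   covered; defaults to one primer per family covering all its
#'   (non-pseudo) members.
#' @param ct_noise_sd cycle noise sd on the sample reactions.
#' @param seed seed.
#' @param ref_abundance reference-transcript abundance.
#' @param sample_offset,calibrator_offset Ct at unit template.
#' @return data.frame(target, n_genes, ct_target, ct_reference,
#'   ct_target_cal, ct_reference_cal).
#' @export
simulate_qpcr <- function(truth, primer_map = NULL, ct_noise_sd = 0,
                          seed = 1L, ref_abundance = 1000,
                          sample_offset = 38, calibrator_offset = 34) {
  gt <- truth$gene_truth[!truth$gene_truth$is_pseudo, ]
  if (is.null(primer_map)) {
    primer_map <- split(gt$gene_id, gt$family)
  }
  stopifnot(all(lengths(primer_map) >= 1))
  with_seed(substream(seed, "qpcr"), {
    rows <- lapply(names(primer_map), function(fam) {
      ids <- primer_map[[fam]]
      ab <- sum(gt$pol3_intensity[gt$gene_id %in% ids])
      copies <- length(ids)
      data.frame(
        target = fam, n_genes = copies,
        ct_target = sample_offset - log2(max(ab, 1e-6)) + rnorm(1, 0, ct_noise_sd),
        ct_reference = sample_offset - log2(ref_abundance) + rnorm(1, 0, ct_noise_sd),
        ct_target_cal = calibrator_offset - log2(copies),
        ct_reference_cal = calibrator_offset - log2(1),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
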