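# High-level recovery runs: one call from synthetic truth to recovered
# quantity, under the default study conditions. These are the package's
# replication surface (used by scripts/acceptance.R and the test suite)
# and a convenient entry point for exploring parameter recovery.

# One condition run: genome-independent truth + array signal + calls.
simulate_and_call <- function(genes, chrom_lengths, preset = "wild_type",
                              seed = 1L, arch = architecture_config(),
                              noise_sd = 0.3) {
  truth <- simulate_nucleosome_truth(genes, arch, condition_preset(preset), seed = seed)
  tracks <- simulate_mnase_array(truth, noise_sd = noise_sd, seed = seed,
                                 chrom_lengths = chrom_lengths)
  calls <- call_nucleosomes(tracks)
  list(truth = truth, tracks = tracks, calls = calls,
       assigned = assign_calls_to_genes(calls, genes))
}

#' Recover the wild-type tDNA architecture from a default simulation
#'
#' Simulates `n_genes` tDNAs with the default wild-type architecture,
#' calls nucleosomes by HMM segmentation, and reads the headline
#' architecture off the meta-gene summaries: the modal upstream dyad
#' from the called-dyad density profile and the NFR boundaries from the
#' averaged log2-ratio signal profile.
#'
#' @param n_genes number of genes.
#' @param seed run seed.
#' @param arch an [architecture_config()].
#' @return list: us_dyad (bp rel. TSS), nfr_start, nfr_end (bp rel.
#'   TSS), plus the underlying `profile`, `dyad_profile` and run.
#' @export
recover_wild_type_architecture <- function(n_genes = 200L, seed = 1L,
                                           arch = architecture_config()) {
  gen <- generate_genome(n_genes = n_genes, seed = seed)
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  run <- simulate_and_call(gen$genes, cl, "wild_type", seed = substream(seed, "wt"),
                           arch = arch)
  prof <- average_profile(bin_around(run$tracks, gen$genes, "tss"))
  dens <- dyad_profile(run$assigned, gen$genes)
  ar_sig <- architecture_from_profile(prof)
  ar_dyad <- architecture_from_profile(dens, linearize = FALSE)
  list(us_dyad = ar_dyad$us_dyad, nfr_start = ar_sig$nfr_start,
       nfr_end = ar_sig$nfr_end, profile = prof, dyad_profile = dens,
       run = run, genes = gen$genes)
}

#' Recover the positioned upstream-nucleosome fraction
#'
#' Simulates `n_genes` tDNAs at the default planted positioned fraction,
#' calls nucleosomes per gene and classifies each upstream nucleosome
#' positioned vs fuzzy via the per-gene architecture.
#'
#' @param n_genes number of genes.
#' @param seed run seed.
#' @param arch an [architecture_config()].
#' @return list: percent (recovered, 0-100), planted_percent, and the
#'   per-gene architecture table.
#' @export
recover_positioned_fraction <- function(n_genes = 273L, seed = 2L,
                                        arch = architecture_config()) {
  gen <- generate_genome(n_genes = n_genes, seed = seed)
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  run <- simulate_and_call(gen$genes, cl, "wild_type", seed = substream(seed, "wt"),
                           arch = arch)
  ag <- architecture_from_calls(run$assigned, gen$genes)
  gt <- run$truth$gene_truth
  list(percent = 100 * positioned_fraction(ag),
       planted_percent = 100 * mean(gt$positioned[!gt$is_pseudo]),
       architecture = ag, run = run)
}

#' Recover changed-gene counts for a condition preset
#'
#' Simulates a shared gene set under wild type and under a perturbation
#' preset (separate measurement seeds), matches calls around the gene
#' ends and classifies differential events.
#'
#' @param preset preset name (see [condition_preset()]).
#' @param n_genes number of genes.
#' @param seed_wt,seed_mut measurement seeds of the two runs.
#' @param flank gene-end window (bp).
#' @param arch an [architecture_config()].
#' @return list: changed (genes with any event), gain_loss (genes with a
#'   gain or loss event), shift (genes with a shift event), planted
#'   (truth changed-gene count), and the event table.
#' @export
recover_changed_genes <- function(preset, n_genes = 273L, seed_wt = 3L,
                                  seed_mut = 4L, flank = 100L,
                                  arch = architecture_config()) {
  gen <- generate_genome(n_genes = n_genes, seed = seed_wt)
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  wt <- simulate_and_call(gen$genes, cl, "wild_type", seed = seed_wt, arch = arch)
  mu <- simulate_and_call(gen$genes, cl, preset, seed = seed_mut, arch = arch)
  ev <- classify_changes(match_calls(wt$assigned, mu$assigned, gen$genes,
                                     flank = flank), gen$genes)
  list(changed = changed_gene_count(ev),
       gain_loss = changed_gene_count(ev, c("gain", "loss")),
       shift = changed_gene_count(ev, "shift"),
       planted = sum(mu$truth$gene_truth$changed),
       events = ev, wt = wt, mutant = mu, genes = gen$genes)
}

#' Worked example: family correlation carried through the pipeline ops
#'
#' Builds the 10-isogene (occupancy, pol III tag) fixture with the
#' default target correlation via the exact Gram-Schmidt construction
#' and recomputes the family Pearson r with [family_correlations()].
#'
#' @param n isogenes in the family.
#' @param r target sample correlation.
#' @param seed fixture seed.
#' @return the recovered Pearson r.
#' @export
worked_example_correlation <- function(n = 10L, r = -0.6544, seed = 7L) {
  pairs <- make_correlated_pairs(n = n, r = r, seed = seed)
  fc <- family_correlations(pairs, min_isogenes = 3L)
  fc$pearson_r[1]
}
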