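# Generator configuration: planted architecture and condition presets.

#' Planted tDNA chromatin architecture
#'
#' Defaults encode the canonical arrangement around a budding-yeast tRNA
#' gene: a strongly positioned upstream (-1) nucleosome with its dyad at
#' -140 bp from the TSS, a nucleosome-free region from -70 to +180 bp, a
#' downstream (+1) nucleosome at variable distance from the terminator,
#' a regularly phased upstream array and a sloppier downstream array.
#' 82% of genes carry a positioned upstream nucleosome; the rest are
#' fuzzy, modelled as a strongly inflated per-gene dyad variance.
#'
#' The 147 bp footprint kernel is a tapered boxcar (flat core with
#' `taper` bp cosine edges), so an isolated nucleosome's half-height
#' points sit at the footprint edges; with the default geometry the
#' upstream footprint edge falls at -140 + (147 - 10)/2 = -71.5 ~ -70,
#' and the default `ds_center_range` places the mean downstream edge at
#' +180 for a mean gene length of 95 bp, making `nfr_start`/`nfr_end`
#' and the planted nucleosome geometry mutually consistent.
#'
#' @param us_center upstream (-1) dyad, bp relative to TSS.
#' @param us_sd positional sd of a positioned upstream dyad (bp).
#' @param nfr_start,nfr_end planted NFR boundaries, bp relative to TSS.
#' @param ds_center_range range (bp relative to TTS) of the per-gene
#'   uniform draw of the downstream (+1) dyad.
#' @param upstream_period nucleosome repeat length of the upstream
#'   (-2, -3, ...) array (bp).
#' @param downstream_period spacing of the downstream (+2, ...) array (bp).
#' @param n_upstream,n_downstream nucleosomes planted on each side
#'   (counting -1/+1).
#' @param positioned_fraction fraction of genes with a positioned (vs
#'   fuzzy) upstream nucleosome.
#' @param fuzzy_sd_multiplier dyad-sd inflation for fuzzy genes (> 1).
#' @param upstream_jitter_sd,downstream_jitter_sd positional sd of array
#'   nucleosomes beyond -1/+1 (upstream array more regular).
#' @param footprint nucleosome footprint (bp).
#' @param taper cosine edge taper of the footprint kernel (bp per edge).
#' @param background free-DNA background occupancy (occupancy units).
#' @param occupancy_range per-nucleosome occupancy, uniform draw.
#' @param nfr_encroach_max per-gene sub-nucleosomal occupancy planted
#'   over (nfr_start, TSS], uniform in (0, nfr_encroach_max); makes
#'   upstream occupancy vary across isogenes.
#' @return list of class `architecture_config`.
#' @export
architecture_config <- function(us_center = -140, us_sd = 10,
                                nfr_start = -70, nfr_end = 180,
                                ds_center_range = c(125, 185),
                                upstream_period = 165,
                                downstream_period = 190,
                                n_upstream = 3, n_downstream = 2,
                                positioned_fraction = 0.82,
                                fuzzy_sd_multiplier = 20,
                                upstream_jitter_sd = 5,
                                downstream_jitter_sd = 20,
                                footprint = 147, taper = 10,
                                background = 0.25,
                                occupancy_range = c(0.85, 1.0),
                                nfr_encroach_max = 0.15) {
  stopifnot(nfr_start < 0, nfr_end > 0, us_center < nfr_start,
            positioned_fraction > 0, positioned_fraction <= 1,
            fuzzy_sd_multiplier > 1, length(ds_center_range) == 2,
            ds_center_range[1] <= ds_center_range[2])
  structure(as.list(environment()), class = "architecture_config")
}

#' Condition presets for the perturbation experiments
#'
#' Four presets mirror the studied conditions. `wild_type` plants the
#' base architecture. `starvation` raises upstream/downstream (-1/+1)
#' nucleosome occupancy on a set of changed genes, slightly lowers
#' -2/+2, moves the +1 nucleosome toward the terminator and scales pol
#' III down sharply. `isw1d2d` plants nucleosome gain on the gene body
#' for one gene set, loss of the upstream nucleosome for a disjoint set,
#' and disorders the upstream array. `rsc4d4` shifts the +1 nucleosome
#' toward the gene for a set of genes so it encroaches the NFR.
#'
#' Perturbed-set sizes default to the changed-gene counts of the
#' corresponding experiments (52 starvation; 77 gain + 35 loss; 120
#' shifts). Set membership and per-gene magnitudes are keyed on gene
#' identity, so paired runs under different seeds perturb the same genes.
#'
#' @param name preset name.
#' @param ... override any preset field (n_changed, gain_set, loss_set,
#'   shift_set, ds_shift_mean, ds_shift_sd, occupancy_delta_flank,
#'   occupancy_delta_array, gain_occupancy, array_disorder_sd,
#'   pol3_scale).
#' @return list of class `condition_preset`.
#' @export
condition_preset <- function(name = c("wild_type", "starvation", "isw1d2d", "rsc4d4"),
                             ...) {
  name <- match.arg(name)
  p <- switch(name,
    wild_type = list(n_changed = 0L, gain_set = 0L, loss_set = 0L, shift_set = 0L,
                     ds_shift_mean = 0, ds_shift_sd = 0,
                     occupancy_delta_flank = 0, occupancy_delta_array = 0,
                     gain_occupancy = 0, array_disorder_sd = 0, pol3_scale = 1),
    starvation = list(n_changed = 52L, gain_set = 0L, loss_set = 0L, shift_set = 52L,
                      ds_shift_mean = 40, ds_shift_sd = 5,
                      occupancy_delta_flank = 0.5, occupancy_delta_array = -0.2,
                      gain_occupancy = 0, array_disorder_sd = 0, pol3_scale = 0.15),
    isw1d2d = list(n_changed = 112L, gain_set = 77L, loss_set = 35L, shift_set = 0L,
                   ds_shift_mean = 0, ds_shift_sd = 0,
                   occupancy_delta_flank = 0, occupancy_delta_array = 0,
                   gain_occupancy = 0.9, array_disorder_sd = 30, pol3_scale = 1),
    rsc4d4 = list(n_changed = 120L, gain_set = 0L, loss_set = 0L, shift_set = 120L,
                  ds_shift_mean = 60, ds_shift_sd = 10,
                  occupancy_delta_flank = -0.1, occupancy_delta_array = 0,
                  gain_occupancy = 0, array_disorder_sd = 0, pol3_scale = 1))
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  p$name <- name
  structure(p, class = "condition_preset")
}
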