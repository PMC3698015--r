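# nucleoscope

Nucleosome architecture around RNA polymerase III genes: a simulation and
analysis pipeline for R.

## What it is for

Budding-yeast tRNA genes (tDNAs) are short (70–120 bp), pol III-transcribed
genes embedded in a stereotyped chromatin arrangement: a strongly positioned
upstream (−1) nucleosome with its dyad near **−140 bp** from the TSS, a
nucleosome-free region (**NFR**) from about **−70 to +180 bp** covering the
gene body, a downstream (+1) nucleosome at variable distance from the
terminator, and a phased upstream array. About **82%** of genes carry the
positioned −1 nucleosome. The arrangement reacts to perturbations —
starvation, loss of the ISWI remodelers (*isw1∆2∆*), the *rsc4-∆4* RSC
mutation — and pol III occupancy on isogenes anticorrelates with nucleosome
occupancy in the TFIIIB-binding region just upstream of the TSS.

`nucleoscope` is aimed at chromatin/regulatory genomics analysts who want a
fully testable version of this analysis. Because the underlying raw data are
not redistributable, the package pairs every analysis step with a
synthetic-data generator that plants the architecture with a recorded
ground truth, so parameter recovery can be verified end to end:

* **Generator** — isogene families with identical gene bodies (forcing
  multi-mapping reads), pseudogenes, planted nucleosome geometry with
  positioned/fuzzy classes, condition presets (`wild_type`, `starvation`,
  `isw1d2d`, `rsc4d4`), MNase tiling-array and MNase-seq readouts, pol III
  ChIP-seq with an exact within-family occupancy/intensity correlation,
  qPCR Ct tables.
* **Array calling** — blank-median + Lowess two-channel normalization,
  3-probe smoothing, two-state Gaussian-emission hidden Markov model
  segmentation (Viterbi, EM-fit emissions, dwell-length-mapped
  transitions), delocalized-run handling.
* **Seq calling** — fragment extension to per-base coverage and
  Gaussian-kernel peak calling (sigma 20 bp, 147-bp exclusion zone).
* **ChIP quantification** — quality filtering (Q ≥ 20 on ≥ 80% of bases),
  exact multi-mapping alignment (up to 20 loci), probabilistic multi-read
  reallocation by local unique coverage, per-million scaling, windowed
  (−100..+100) gene enrichment over mock.
* **Meta-gene analysis** — strand-aware 20-bp binning around TSS/TTS,
  averaged and dyad-density profiles, NFR boundary extraction,
  positioned-fraction classification, upstream periodicity, heat-map
  export.
* **Differential chromatin** — call matching between conditions and
  gain / loss / shift classification within 100 bp of the gene ends.
* **Quantification** — family-wise Pearson correlation of upstream
  occupancy vs pol III tags, and ddCt relative qPCR quantification
  `2^-[(Ct_t - Ct_ref)_sample - (Ct_t - Ct_ref)_calibrator]`.

The methods vignette (`vignettes/nucleosome-architecture.Rmd`) documents the
model, every default and the design decisions.

## Worked example

Simulate a 60-gene cohort, call nucleosomes, and read the architecture
back:

```r
library(nucleoscope)

gen <- generate_genome(n_genes = 60, n_families = 12, n_pseudo = 2,
                       n_chrom = 4, seed = 42)
cl  <- setNames(Biostrings::width(gen$genome), names(gen$genome))
truth  <- simulate_nucleosome_truth(gen$genes, seed = 1)
tracks <- simulate_mnase_array(truth, seed = 1, chrom_lengths = cl)

calls    <- call_nucleosomes(tracks)
assigned <- assign_calls_to_genes(calls, gen$genes)
profile  <- average_profile(bin_around(tracks, gen$genes, "tss"))
architecture_from_profile(profile)
#> <tdna_architecture> US dyad -111.9 bp, NFR -77.1..190.5 bp (len 267.6), DS peak 248.9 bp

ag <- architecture_from_calls(assigned, gen$genes)
round(100 * positioned_fraction(ag), 1)
#> [1] 80
round(architecture_from_profile(dyad_profile(assigned, gen$genes),
                                linearize = FALSE)$us_dyad, 1)
#> [1] -142.9
```

The NFR boundaries (−77, +190) come back within one 20-bp bin of the
planted −70/+180, and the modal upstream dyad from the called-dyad density
(−142.9) sits on the planted −140; the recovered positioned fraction (80%)
matches the planted 82% of this 60-gene draw. (The *signal*-profile US peak
prints −112 because the averaged log2 footprint is flat-topped — peak
positions are read from the dyad density, as in the example.)

A differential comparison against an *rsc4-∆4*-style perturbation of 20
genes on the same gene set:

```r
mut <- simulate_nucleosome_truth(gen$genes,
         preset = condition_preset("rsc4d4", n_changed = 20L, shift_set = 20L),
         seed = 2)
mtracks   <- simulate_mnase_array(mut, seed = 2, chrom_lengths = cl)
massigned <- assign_calls_to_genes(call_nucleosomes(mtracks), gen$genes)
ev <- classify_changes(match_calls(assigned, massigned, gen$genes), gen$genes)
changed_gene_count(ev, "shift")
#> [1] 19
summary(ev$displacement[ev$event == "shift"])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   44.00   51.00   58.00   58.32   64.00   82.00
```

19 of the 20 planted shifts are recovered, with positive displacements
(toward the terminator) around the planted 60 bp mean. Finally, the
worked-example family correlation, built by the exact Gram–Schmidt
construction and recomputed through `family_correlations()`:

```r
worked_example_correlation(n = 10, r = -0.6544, seed = 7)
#> [1] -0.6544
```

`run_full(pipeline_config(...), out_dir)` chains all stages (genome →
truth → tracks → calls → meta-gene → differential → optional ChIP/qPCR)
into plain-text TSV outputs plus a `report.tsv` of headline numbers.

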