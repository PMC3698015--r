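---
title: "Nucleosome architecture around pol III genes: model, generator and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome architecture around pol III genes: model, generator and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological picture

Budding-yeast tRNA genes (tDNAs) are short (70–120 bp), highly transcribed
RNA polymerase III genes with intragenic promoter elements. Their chromatin
shows a stereotyped arrangement: a strongly positioned upstream (−1)
nucleosome with its dyad near −140 bp from the TSS, a nucleosome-free region
(NFR) spanning roughly −70 to +180 bp that contains the entire gene body, a
downstream (+1) nucleosome at variable distance from the terminator, a
regularly phased array further upstream and a sloppier array downstream.
About 82% of genes carry the positioned −1 nucleosome; the rest show a fuzzy
(delocalized) upstream signal. This arrangement responds to perturbations:
nutrient starvation raises −1/+1 occupancy and lets the +1 nucleosome
encroach on the terminator; loss of the ISWI remodelers (*isw1∆2∆*) causes
nucleosome gain on gene bodies, loss near gene ends and disorder of the
upstream array; the *rsc4-∆4* RSC mutation shifts the +1 nucleosome into the
NFR. Pol III occupancy on isogenes anticorrelates with nucleosome occupancy
immediately upstream of the TSS (−60 bp to the TSS), where TFIIIB binds.

Real raw data for this system are not redistributable here, so `nucleoscope`
is built around a synthetic-data generator that plants this architecture
with a recorded ground truth, plus the analysis pipeline that recovers it:
tiling-array normalization and HMM nucleosome calling, seq-mode kernel peak
calling, pol III ChIP-seq quantification with multi-read reallocation,
strand-aware meta-gene profiling, differential chromatin classification and
occupancy/transcription correlation. Every analysis operation is exercised
against the planted truth.

## The planted architecture and its parameters

`architecture_config()` holds the generator defaults (units are bp and
occupancy units; occupancy 1 is one fully occupied nucleosome):

* `us_center = -140`, `us_sd = 10`: the −1 dyad, drawn per gene.
* `positioned_fraction = 0.82`, `fuzzy_sd_multiplier = 20`: the fuzzy subset
  draws its dyad with sd 200 bp, i.e. essentially delocalized across the
  mapped window. The positioned set is planted as an *exact* count
  (`round(0.82 n)` genes, chosen by a deterministic gene-keyed ordering):
  the fraction is a population parameter of the design, and planting it
  exactly keeps recovery comparisons free of binomial sampling noise.
* `nfr_start = -70`, `nfr_end = +180`: the planted NFR boundaries.
* `ds_center_range = c(125, 185)` relative to the TTS: the variable +1
  dyad. With the 147-bp footprint below, the mean downstream footprint edge
  for a 95-bp gene falls at +180 from the TSS — consistent with `nfr_end`.
* `upstream_period = 165` with 5 bp jitter (regular −2/−3 array);
  `downstream_period = 190` with 20 bp jitter (sloppier +2).
* `footprint = 147`, `taper = 10`: the occupancy kernel is a tapered boxcar
  (flat core, 10-bp cosine edges). A nucleosome protects its whole footprint
  from MNase, so the kernel's half-height points must sit at the footprint
  edges (±68.5 bp); a peaked kernel (e.g. a raised cosine over the full
  footprint) would put the half-height ~37 bp from the dyad and make the
  planted −140 dyad inconsistent with a −70 NFR boundary under any
  fractional threshold rule.
* `background = 0.25`: free-DNA background occupancy.
* `nfr_encroach_max = 0.15`: each gene carries a sub-nucleosomal occupancy
  level, uniform in (0, 0.15), over (−70, 0]. This is the biologically
  load-bearing variance: upstream occupancy must differ between isogenes for
  an occupancy/pol III correlation to exist at all, and partial nucleosome
  encroachment over the TFIIIB site is the proposed mechanism.

Pol III intensities are planted per family by an exact Gram–Schmidt
construction: within every family of three or more isogenes the *sample*
Pearson correlation between upstream occupancy (−60..TSS) and intensity
equals the target (−0.6544 by default) before any read sampling. Families
sit on lognormal base levels so totals differ across families. Pseudogenes
get zero intensity and therefore only background reads.

### Randomness is split into two kinds

Architecture draws (dyads, positioned labels, perturbation-set membership,
shift magnitudes, encroachment) are keyed on *gene identity* via string-hash
substreams; the run seed drives only measurement noise, probe noise and read
sampling. A gene's chromatin state is a stable property of the cell — two
measurements of the same strain should disagree only by measurement noise —
and the differential analysis depends on this: wild-type and mutant runs
use different seeds yet must share the same base truth per gene. Outputs
remain pure functions of (configuration, seed): the gene identities
themselves derive from the genome seed.

### Condition presets

`condition_preset()` encodes the perturbations, with set sizes defaulting to
the changed-gene counts of the corresponding experiments:

* `starvation`: 52 genes get −1/+1 occupancy +0.5, −2/+2 occupancy −0.2 and
  a +1 shift of 40 bp toward the terminator; pol III is scaled to 0.15.
* `isw1d2d`: 77 genes gain a gene-body nucleosome (occupancy 0.9), a
  disjoint 35 lose the −1 nucleosome, and the upstream array is disordered
  (30 bp sd) genome-wide.
* `rsc4d4`: 120 genes have the +1 dyad shifted toward the gene by
  N(60, 10) bp (clamped to ±25 of the mean), so it encroaches the NFR.

Perturbation sets are drawn from positioned genes first. The published
counts are counts of genes *showing* changes in heat maps; a perturbation
planted on an already-delocalized upstream nucleosome cannot produce a
visible, classifiable change, so planting it would make the truth count
unrecoverable by any method.

## The measurement models

**Array mode.** Probes tile every 4 bp; the expected probe value is
`log2((background + sum of kernels)/background)` — the nucleosomal/genomic
log ratio — plus Gaussian probe noise (`noise_sd = 0.3` log2 units, a
typical replicate-averaged tiling-array noise level). **Seq mode** draws
fragment midpoints from an occupancy-weighted mixture over planted dyads
(15 bp scatter) plus a uniform background fraction, with 150-bp nominal
fragments, and can emit 36-bp reads from fragment 5′ ends. **ChIP mode**
centres ~180-bp fragments on gene bodies at rates proportional to planted
intensity plus uniform background; the mock library is background only.

## Nucleosome calling

Array tracks are smoothed with a 3-probe moving average (shrinking windows
at the edges) and segmented with a two-state (linker/nucleosome) Gaussian
HMM. Emission parameters are fit by one EM pass (initialized from a
quantile split at the 35th/95th percentiles, tolerance 1e-6 on the
log-likelihood, at most 200 iterations, sd floor 1e-3); state dwell lengths
(147 bp nucleosome, 500 bp linker) are mapped to self-transitions as
`p = 1 − step/dwell` and held fixed — fitting transitions as well is
unidentifiable at this SNR and adds nothing. Viterbi ties break toward the
linker state. Maximal nucleosome-state runs become calls: runs under 100 bp
are dropped; runs over 250 bp are delocalized. A delocalized run whose
interior dips below the midpoint of the two state means is recursively
split at the valley: with a 165-bp repeat length the −2/−1 linker is only
~18 bp and falls below the 4-bp-probe resolution for a few percent of
genes, and without the split such neighbours fuse into one blob whose dyad
is meaningless. A long run with no interior valley (a genuinely fuzzy
region) stays one delocalized call.

Seq-mode fragment midpoints are called with a Gaussian kernel smoother
(sd 20 bp): local maxima are accepted greedily by height (leftmost on
ties) with a 147-bp exclusion zone, and the call footprint is the dyad
±73 bp.

## Meta-gene summaries and architecture extraction

Signal is binned in 20-bp bins over ±1 kb around the TSS (or TTS), with
minus-strand rows flipped so upstream is always negative; missing bins
propagate as missing, never zero. Two profiles matter downstream: the
bin-wise average of the log2 signal, and the *called-dyad density* profile
(calls binned the same way). The modal upstream dyad is read off the dyad
density — the log2 average of near-boxcar footprints has a flat top on
which an argmax is unstable, while the dyad density is sharply peaked.

`architecture_from_profile()` linearizes the averaged log2 profile and
takes, within the upstream window (−300..−40) and downstream window
(+60..+400), the qualifying local maximum (≥ 50% of the window maximum)
*nearest the gene* — the −1/+1 nucleosome is by definition the peak
bordering the NFR, and the window argmax would otherwise pick the sharper
−2 array peak. The NFR is the maximal interval around the inter-peak
minimum where the linearized signal stays below
`baseline + 0.5 × (mean flanking-peak height − baseline)`; boundaries are
linearly interpolated at the crossings, and raising the threshold can only
widen the NFR. With the tapered-boxcar kernel this rule recovers the
planted −70/+180 from the planted −140 dyad and +1 placement — the
geometry, kernel and rule are designed to be mutually consistent.

Per gene, the upstream nucleosome is the call with dyad in (−300..−40)
nearest the TSS, the downstream one the call nearest the TTS within
(−40..+300) of it. A gene counts as *positioned* when its upstream call
exists, has a footprint of at most 250 bp, and lies within ±40 bp of the
family's modal upstream dyad (families with fewer than three upstream calls
fall back to the global mode); genes without an upstream call count as not
positioned. Calls overlapping the gene body set a `nuc_plus` flag. The
upstream repeat length is the lag of the first autocorrelation maximum
(120–220 bp) of the mean-subtracted −1000..−200 profile, with parabolic
refinement; peaks below 0.2 autocorrelation are flagged low-confidence.

## Differential classification

Calls from two conditions are paired per gene, greedily by nearest dyad
with a 100-bp pairing ceiling, over a window 250 bp around the gene span —
wide enough that a nucleosome moving *into* the ±100 bp gene-end window
still finds its partner. Events are then classified with the gene-end
window applied where it belongs: a singleton is a gain (condition B only)
or loss (A only) when the call is within 100 bp + half a footprint of the
gene span, i.e. when the nucleosome as a 147-bp object lies within 100 bp
of the gene ends; a matched pair is an occupancy gain/loss when the mean
call signal changes by ≥ 0.25 log2 units, and a positional shift when the
dyads differ by ≥ 30 bp — provided both calls are positioned (a
delocalized call has no meaningful dyad) and at least one side is near the
gene ends. Shift displacement is signed positive toward (and past) the
terminator, so both the starvation and the *rsc4-∆4* +1 encroachment are
positive. The 30-bp shift threshold (1.5 bins) separates the planted
40–60 bp displacements from the few-bp measurement jitter at default
noise; 0.25 log2 units is ~3 standard errors of a call-mean difference at
default noise, putting the false-event rate at a few genes per 273 while
keeping the planted +0.5-occupancy changes essentially always detected.

## Pol III quantification

Reads are kept when ≥ 80% of bases have Phred ≥ 20. Alignment against the
synthetic genome is exact full-length matching on both strands (a
preprocessed dictionary over equal-length reads), reporting up to 20 loci
per read; reads with N or no match are dropped with counts. Real data
aligned elsewhere enters through the minimal-SAM/BED import instead —
mismatch-tolerant alignment is deliberately out of scope. Multi-reads are
reallocated in a single pass: each candidate locus is weighted by the
number of uniquely-mapped read starts within ±200 bp plus a pseudocount of
0.1, and the chosen locus is drawn proportionally (all-zero neighbourhoods
therefore fall back to uniform). Coverage is fragment-extended (180 bp for
ChIP, 150 bp for MNase-seq), scaled to one million reads, and summarized
per gene as the mean over −100..+100 around the TSS; fold enrichment is
`(IP + 0.5)/(mock + 0.5)` with pseudogenes reported separately. On a
genome without duplicated sequence every read is unique and reallocation
is exactly a no-op.

Family correlations use the sample Pearson r on per-gene (mean upstream
occupancy, mean window tag count) pairs for families with ≥ 3 isogenes
(below three an r is meaningless); zero-variance vectors are reported
without an r. The published analysis excluded one or two visually
identified outliers per family; that is not replicated automatically — an
optional leave-one-out diagnostic reports the most negative r achievable
by dropping a single gene, in a clearly separate column. qPCR
quantification is the ddCt rule
`2^{-[(Ct_t - Ct_ref)_sample - (Ct_t - Ct_ref)_calibrator]}` with a
genomic-DNA calibrator (normalizing copy number away) and a fixed pol II
reference transcript; primers measure the pooled abundance of all genes
they cover. Ct values of ≥ 40 cycles flag a row unreliable.

## What the generator does and does not emulate

It emulates: isogene families with identical bodies and unique flanks
(forcing multi-mapping), pseudogenes, the planted chromatin geometry and
its condition-specific perturbations, probe-level array noise, fragment
sampling, and copy-number-aware qPCR. It does not emulate: sequence-
dependent nucleosome energetics (the system's NFR is specifically *not*
sequence-directed), MNase sequence bias, mismatch/indel sequencing errors,
paired-end reads, replicate structure, or the higher nucleosome densities
of other genomes. Passing recovery tests therefore demonstrates that the
pipeline's inference is correct *for this measurement model*, not that it
is robust to every artefact of real arrays or libraries.

## Problem sizes and numerical choices

The bundled checks run the generator at its study scale — 200 genes for
architecture recovery, 273 (the mapped tDNA count) for the positioned
fraction and the differential comparisons, ~10^5 reads for ChIP recovery —
which keeps the full suite in the minutes range on one core. Smaller gene
sets (20–120) are used for unit tests; preset set sizes scale down through
`condition_preset(...)` overrides. Remaining numerical conventions:
coordinates are 0-based half-open internally (BED native; GFF and SAM
converted on read); the TSS-relative axis has 0 at the TSS and upstream
negative on both strands; probe coordinates refer to the probe midpoint
(exposed as a reader option); array WIG output is fixed-step; bedGraph
output merges equal-valued runs; Lowess normalization uses span 0.3 with
2 robustness iterations after blank-median scaling per channel.

## Known limitations

* The +1/+2 spacing occasionally falls below footprint separation, fusing
  the two into a delocalized call on both sides of a comparison; a planted
  shift on such a gene is (correctly) not scored as a positional shift.
  This costs a few of the 120 planted *rsc4-∆4* shifts.
* Architecture extraction from the averaged profile reports boundaries
  with a systematic few-bp outward offset (log-averaging across genes with
  jittered edges); it stays well within one 20-bp bin of the planted
  values.
* The HMM assumes homoskedastic Gaussian emissions per state; heavy-tailed
  probe artefacts would need a robust emission model.
* Exact alignment is correct only for the synthetic genome; real reads
  must be aligned externally and imported.
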