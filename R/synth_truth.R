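# Planted nucleosome truth: the ground-truth ledger every recovery test
# reads. Architecture draws are keyed on gene identity (not the run
# seed) so paired condition runs perturb the same genes on top of the
# same base state; the run seed drives only measurement noise and read
# sampling.

#' Tapered-boxcar nucleosome footprint kernel
#'
#' Occupancy contributed at signed dyad offsets `x`: 1 over the flat
#' core, cosine-tapered to 0 over the outer `taper` bp of the
#' `footprint`. The half-height points sit `(footprint - taper)/2` bp
#' from the dyad, i.e. essentially at the footprint edge.
#'
#' @param x signed offsets from the dyad (bp).
#' @param footprint footprint width (bp).
#' @param taper edge taper width (bp).
#' @return occupancy values in `[0, 1]`.
#' @export
footprint_kernel <- function(x, footprint = 147, taper = 10) {
  half <- footprint / 2
  a <- abs(x)
  out <- numeric(length(x))
  out[a <= half - taper] <- 1
  edge <- a > half - taper & a <= half
  out[edge] <- 0.5 * (1 + cos(pi * (a[edge] - (half - taper)) / taper))
  out
}

# Exact positioned set: the planted positioned fraction is a population
# parameter, so it is hit as an exact count over a deterministic
# gene-keyed ordering (shared across condition runs).
positioned_ids <- function(genes, positioned_fraction) {
  ord <- order(str_hash(paste0(genes$gene_id, "::positioned-order")), genes$gene_id)
  genes$gene_id[ord][seq_len(round(positioned_fraction * nrow(genes)))]
}

# Deterministic gene-keyed ordering used to pick perturbed gene sets.
# Genes with a positioned upstream nucleosome come first: the planted
# changed-gene counts mirror counts of *visible* changes, and a
# perturbation on a delocalized nucleosome is invisible by definition.
perturb_order <- function(genes, preset_name, pos_ids) {
  real <- genes[!genes$is_pseudo, , drop = FALSE]
  h <- str_hash(paste0(real$gene_id, "::perturb::", preset_name))
  real$gene_id[order(!(real$gene_id %in% pos_ids), h, real$gene_id)]
}

#' Simulate the planted nucleosome truth for a gene set
#'
#' Plants, per gene: an upstream (-1) dyad drawn around
#' `arch$us_center` (sd inflated `arch$fuzzy_sd_multiplier`-fold for the
#' fuzzy subset), a downstream (+1) dyad uniform in
#' `arch$ds_center_range` relative to the TTS, a phased upstream array
#' and a sloppier downstream array, per-nucleosome occupancies, a
#' sub-nucleosomal upstream-encroachment level, and a pol III intensity
#' anticorrelated with upstream occupancy within each family. The
#' condition preset then perturbs its designated gene subsets (gain,
#' loss, shift, occupancy deltas, array disorder) and the perturbations
#' are recorded as labels.
#'
#' @param genes gene data.frame from [read_genes()]/[generate_genome()].
#' @param arch an [architecture_config()].
#' @param preset a [condition_preset()].
#' @param seed run seed (recorded; base architecture draws are
#'   gene-keyed and shared across runs).
#' @param pol3_r target within-family Pearson correlation between
#'   upstream occupancy and pol III intensity (families with >= 3
#'   members get it exactly).
#' @return list of class `synthetic_truth` with elements `genes`,
#'   `nucleosomes` (one row per planted dyad), `gene_truth` (per-gene
#'   labels and intensities), `arch`, `preset`, `seed`.
#' @export
simulate_nucleosome_truth <- function(genes, arch = architecture_config(),
                                      preset = condition_preset("wild_type"),
                                      seed = 1L, pol3_r = -0.6544) {
  n_real <- sum(!genes$is_pseudo)
  if (preset$gain_set + preset$loss_set + preset$shift_set > n_real) {
    stop("simulate_nucleosome_truth: preset perturbation sets exceed the gene count")
  }
  pos_ids <- positioned_ids(genes, arch$positioned_fraction)
  ord <- perturb_order(genes, preset$name, pos_ids)
  gain_ids <- head(ord, preset$gain_set)
  loss_ids <- head(setdiff(ord, gain_ids), preset$loss_set)
  shift_ids <- head(setdiff(ord, c(gain_ids, loss_ids)), preset$shift_set)
  perturbed <- c(gain_ids, loss_ids, shift_ids)

  nuc_list <- vector("list", nrow(genes))
  gt <- genes[, c("gene_id", "family", "is_pseudo")]
  gt$positioned <- NA; gt$us_dyad_rel <- NA_real_; gt$ds_dyad_rel_tts <- NA_real_
  gt$encroach <- NA_real_; gt$event <- "none"; gt$shift_bp <- 0

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    id <- g$gene_id
    positioned <- id %in% pos_ids
    us_sd <- arch$us_sd * if (positioned) 1 else arch$fuzzy_sd_multiplier
    us_rel <- gene_draw(id, "us-dyad", function() rnorm(1, arch$us_center, us_sd))
    ds_rel_tts <- gene_draw(id, "ds-dyad",
                            function() runif(1, arch$ds_center_range[1], arch$ds_center_range[2]))
    encroach <- gene_draw(id, "encroach", function() runif(1, 0, arch$nfr_encroach_max))

    roles <- c("us", "ds")
    rel_tss <- c(us_rel, NA)
    rel_tts <- c(NA, ds_rel_tts)
    if (arch$n_upstream > 1) {
      for (k in seq_len(arch$n_upstream - 1)) {
        jit <- gene_draw(id, paste0("array-m", k + 1),
                         function() rnorm(1, 0, arch$upstream_jitter_sd))
        roles <- c(roles, paste0("m", k + 1))
        rel_tss <- c(rel_tss, arch$us_center - k * arch$upstream_period + jit)
        rel_tts <- c(rel_tts, NA)
      }
    }
    if (arch$n_downstream > 1) {
      for (k in seq_len(arch$n_downstream - 1)) {
        jit <- gene_draw(id, paste0("array-p", k + 1),
                         function() rnorm(1, 0, arch$downstream_jitter_sd))
        roles <- c(roles, paste0("p", k + 1))
        rel_tss <- c(rel_tss, NA)
        rel_tts <- c(rel_tts, ds_rel_tts + k * arch$downstream_period + jit)
      }
    }
    occ <- vapply(roles, function(r) {
      gene_draw(id, paste0("occ-", r),
                function() runif(1, arch$occupancy_range[1], arch$occupancy_range[2]))
    }, numeric(1))

    # --- preset perturbations -------------------------------------------
    event <- "none"; shift_bp <- 0
    if (id %in% loss_ids) {
      keep <- roles != "us"
      roles <- roles[keep]; rel_tss <- rel_tss[keep]; rel_tts <- rel_tts[keep]; occ <- occ[keep]
      event <- "loss"
    }
    if (id %in% gain_ids) {
      jit <- gene_draw(id, paste0("gain-", preset$name), function() rnorm(1, 0, 5))
      roles <- c(roles, "body_gain")
      rel_tss <- c(rel_tss, floor((g$length - 1) / 2) + jit)
      rel_tts <- c(rel_tts, NA)
      occ <- c(occ, preset$gain_occupancy)
      event <- "gain"
    }
    if (id %in% shift_ids && "ds" %in% roles) {
      delta <- gene_draw(id, paste0("shift-", preset$name),
                         function() rnorm(1, preset$ds_shift_mean, preset$ds_shift_sd))
      delta <- min(max(delta, preset$ds_shift_mean - 25), preset$ds_shift_mean + 25)
      rel_tts[roles == "ds"] <- rel_tts[roles == "ds"] - delta  # toward the terminator
      event <- if (event == "none") "shift" else event
      shift_bp <- delta
    }
    if (id %in% perturbed) {
      occ[roles %in% c("us", "ds")] <- pmax(0.1, occ[roles %in% c("us", "ds")] +
                                              preset$occupancy_delta_flank)
      occ[grepl("^(m|p)[0-9]", roles)] <- pmax(0.05, occ[grepl("^(m|p)[0-9]", roles)] +
                                                 preset$occupancy_delta_array)
    }
    if (preset$array_disorder_sd > 0) {
      for (r in roles[grepl("^m[0-9]", roles)]) {
        rel_tss[roles == r] <- rel_tss[roles == r] +
          gene_draw(id, paste0("disorder-", preset$name, "-", r),
                    function() rnorm(1, 0, preset$array_disorder_sd))
      }
    }

    # resolve TTS-anchored dyads to the TSS axis, then to genomic coords
    rel_resolved <- ifelse(is.na(rel_tss), (g$length - 1) + rel_tts, rel_tss)
    nuc_list[[i]] <- data.frame(
      gene_id = id, chrom = g$chrom, role = roles,
      dyad = round(abs_pos(g, rel_resolved)),
      dyad_rel = round(rel_resolved), occupancy = occ,
      stringsAsFactors = FALSE)

    gt$positioned[i] <- positioned
    gt$us_dyad_rel[i] <- if ("us" %in% roles) round(rel_resolved[roles == "us"]) else NA_real_
    gt$ds_dyad_rel_tts[i] <- if ("ds" %in% roles) rel_tts[roles == "ds"] else NA_real_
    gt$encroach[i] <- encroach
    gt$event[i] <- event
    gt$shift_bp[i] <- shift_bp
  }
  nucs <- do.call(rbind, nuc_list)
  rownames(nucs) <- NULL
  gt$changed <- gt$event != "none"

  truth <- structure(list(genes = genes, nucleosomes = nucs, gene_truth = gt,
                          arch = arch, preset = preset, seed = seed),
                     class = "synthetic_truth")
  truth$gene_truth$upstream_occ <- vapply(seq_len(nrow(genes)), function(i) {
    expected_upstream_occupancy(truth, genes[i, ])
  }, numeric(1))
  truth$gene_truth$pol3_intensity <- plant_pol3_intensity(truth, pol3_r)
  truth
}

# Expected occupancy (occupancy units) at TSS-relative positions.
expected_occupancy_rel <- function(truth, gene, rel) {
  arch <- truth$arch
  nucs <- truth$nucleosomes[truth$nucleosomes$gene_id == gene$gene_id, ]
  o <- rep(arch$background, length(rel))
  for (j in seq_len(nrow(nucs))) {
    o <- o + nucs$occupancy[j] *
      footprint_kernel(rel - nucs$dyad_rel[j], arch$footprint, arch$taper)
  }
  enc <- truth$gene_truth$encroach[match(gene$gene_id, truth$gene_truth$gene_id)]
  if (length(enc) == 1 && is.finite(enc)) {
    o[rel > arch$nfr_start & rel <= 0] <- o[rel > arch$nfr_start & rel <= 0] + enc
  }
  o
}

# Planted mean occupancy over the TFIIIB-binding window (-60..TSS].
expected_upstream_occupancy <- function(truth, gene, from = -60, to = 0) {
  mean(expected_occupancy_rel(truth, gene, seq(from, to)))
}

# Within-family construction of pol III intensities with an exact sample
# correlation against upstream occupancy (families >= 3; smaller
# families get a decreasing affine map of occupancy). Each family sits
# on its own base expression level (family-keyed lognormal draw), so
# family totals differ the way codon-usage-matched tRNA pools do;
# per-family shift/scale leaves the planted correlation exact.
plant_pol3_intensity <- function(truth, pol3_r) {
  gt <- truth$gene_truth
  intensity <- numeric(nrow(gt))
  for (fam in unique(gt$family[!gt$is_pseudo])) {
    idx <- which(gt$family == fam & !gt$is_pseudo)
    o <- gt$upstream_occ[idx]
    if (length(idx) >= 3 && sd(o) > 0) {
      noise <- vapply(gt$gene_id[idx], function(id) {
        gene_draw(id, "pol3-noise", function() rnorm(1))
      }, numeric(1))
      x <- correlated_vector(o, noise, pol3_r)
    } else {
      x <- -scale_unit(o)
    }
    base <- gene_draw(fam, "family-level", function() exp(rnorm(1, log(500), 0.5)))
    s <- 0.3 * base
    if (max(abs(x)) > 0) s <- min(s, 0.95 * base / max(abs(x)))
    intensity[idx] <- base + s * x
  }
  intensity * truth$preset$pol3_scale
}

scale_unit <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# Gram-Schmidt: unit-variance vector with exact sample correlation r
# against o, built from o and an arbitrary noise vector.
correlated_vector <- function(o, noise, r) {
  z1 <- scale_unit(o)
  e <- noise - mean(noise)
  e <- e - sum(e * z1) / sum(z1 * z1) * z1
  if (sd(e) == 0) stop("correlated_vector: degenerate noise vector")
  z2 <- scale_unit(e)
  r * z1 + sqrt(1 - r^2) * z2
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d genes (%d pseudo), %d planted nucleosomes, preset %s, seed %d\n",
              nrow(x$genes), sum(x$genes$is_pseudo), nrow(x$nucleosomes),
              x$preset$name, x$seed))
  invisible(x)
}

#' Write the truth ledger as tab-separated tables
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory; writes `truth_nucleosomes.tsv` and
#'   `truth_genes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truth$nucleosomes, file.path(dir, "truth_nucleosomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$gene_truth, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
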