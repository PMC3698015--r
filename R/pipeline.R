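# End-to-end orchestration: simulate -> call -> metagene -> differential
# -> correlate, with plain-text TSV intermediates and a summary report.

#' Pipeline configuration
#'
#' Bundles the generator, calling and analysis parameters with their
#' documented defaults; round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param n_genes,n_families,n_pseudo,n_chrom genome layout.
#' @param presets condition presets to simulate besides wild type.
#' @param noise_sd array probe noise (log2 units).
#' @param seed global seed; stage substreams are derived from it.
#' @param arch architecture overrides (named list of
#'   [architecture_config()] arguments).
#' @param with_chip also simulate and quantify pol III ChIP-seq.
#' @param n_reads_ip,n_reads_mock ChIP library sizes.
#' @param window,bin meta-gene geometry (bp).
#' @param flank,shift_min,occ_min_delta differential parameters.
#' @param preset_params named list of per-preset overrides passed to
#'   [condition_preset()] (e.g. scaled-down perturbation-set sizes for
#'   small gene sets).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genes = 273L, n_families = 42L, n_pseudo = 8L,
                            n_chrom = 8L,
                            presets = c("starvation", "isw1d2d", "rsc4d4"),
                            noise_sd = 0.3, seed = 1L, arch = list(),
                            with_chip = FALSE, n_reads_ip = 100000L,
                            n_reads_mock = 50000L, window = 1000L, bin = 20L,
                            flank = 100L, shift_min = 30, occ_min_delta = 0.25,
                            preset_params = list()) {
  stopifnot(n_genes >= n_families,
            all(presets %in% c("wild_type", "starvation", "isw1d2d", "rsc4d4")))
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config seed. Stages: genome generation;
#' per-condition truth + array simulation + HMM calling; meta-gene
#' matrices, averaged profile and architecture; differential
#' classification of each mutant preset against wild type; optional pol
#' III ChIP quantification with family correlations and qPCR. All
#' intermediates are written as plain-text tables under `out_dir`,
#' along with `report.tsv` (the headline numbers) and `manifest.tsv`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory results and the report.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    ns_log("stage ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  arch <- do.call(architecture_config, config$arch)
  gen <- stage("genome", {
    g <- generate_genome(n_genes = config$n_genes, n_families = config$n_families,
                         n_pseudo = config$n_pseudo, n_chrom = config$n_chrom,
                         seed = config$seed)
    write_genome(g$genome, file.path(out_dir, "genome.fa"))
    write_genes(g$genes, file.path(out_dir, "genes.gff3"), format = "gff")
    g
  })
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))

  conds <- c("wild_type", setdiff(config$presets, "wild_type"))
  res <- list()
  for (k in seq_along(conds)) {
    cond <- conds[k]
    res[[cond]] <- stage(cond, {
      preset <- do.call(condition_preset,
                        c(list(name = cond), config$preset_params[[cond]]))
      truth <- simulate_nucleosome_truth(gen$genes, arch, preset,
                                         seed = substream(config$seed, cond))
      write_truth(truth, file.path(out_dir, cond))
      tracks <- simulate_mnase_array(truth, noise_sd = config$noise_sd,
                                     seed = substream(config$seed, paste0(cond, "-array")),
                                     chrom_lengths = cl)
      calls <- call_nucleosomes(tracks)
      write.table(calls, file.path(out_dir, cond, "calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      assigned <- assign_calls_to_genes(calls, gen$genes)
      mm <- bin_around(tracks, gen$genes, "tss", window = config$window, bin = config$bin)
      prof <- average_profile(mm)
      write.table(prof, file.path(out_dir, cond, "profile_tss.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      arch_prof <- architecture_from_profile(prof)
      arch_genes <- architecture_from_calls(assigned, gen$genes)
      write.table(arch_genes, file.path(out_dir, cond, "architecture.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(truth = truth, tracks = tracks, calls = calls, assigned = assigned,
           matrix = mm, profile = prof, arch_profile = arch_prof,
           arch_genes = arch_genes)
    })
  }

  events <- list()
  for (cond in setdiff(conds, "wild_type")) {
    events[[cond]] <- stage(paste0("diff-", cond), {
      pairs <- match_calls(res$wild_type$assigned, res[[cond]]$assigned,
                           gen$genes, flank = config$flank)
      ev <- classify_changes(pairs, gen$genes, shift_min = config$shift_min,
                             occ_min_delta = config$occ_min_delta)
      write.table(ev, file.path(out_dir, cond, "events.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ev
    })
  }

  fam_corr <- NULL
  if (isTRUE(config$with_chip)) {
    fam_corr <- stage("chip", {
      wt <- res$wild_type
      chip <- simulate_pol3_chip(wt$truth, gen$genome,
                                 n_reads_ip = config$n_reads_ip,
                                 n_reads_mock = config$n_reads_mock,
                                 seed = substream(config$seed, "chip"))
      quantify_pol3(chip, gen, wt, config, out_dir)
    })
  }

  wtp <- res$wild_type$arch_profile
  report <- data.frame(
    quantity = c("us_dyad_modal", "nfr_start", "nfr_end", "positioned_pct",
                 if (length(events)) paste0("changed_genes_", names(events))),
    value = c(wtp$us_dyad, wtp$nfr_start, wtp$nfr_end,
              100 * positioned_fraction(res$wild_type$arch_genes),
              vapply(events, changed_gene_count, numeric(1))),
    stringsAsFactors = FALSE)
  if (!is.null(fam_corr)) {
    ok <- is.finite(fam_corr$pearson_r)
    report <- rbind(report, data.frame(
      quantity = "family_r_median", value = median(fam_corr$pearson_r[ok])))
  }
  write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- data.frame(file = list.files(out_dir, recursive = TRUE))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(conditions = res, events = events, family_correlations = fam_corr,
                 report = report, out_dir = out_dir))
}

# ChIP branch of run_full: align, reallocate, scale, enrich, correlate,
# qPCR.
quantify_pol3 <- function(chip, gen, wt, config, out_dir) {
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  quantify_sample <- function(reads, tag) {
    reads <- quality_filter(reads)
    aln <- align_exact(reads, gen$genome)
    aln <- reallocate_multireads(aln, seed = substream(config$seed, paste0("realloc-", tag)))
    chosen <- aln[aln$chosen, , drop = FALSE]
    tracks <- extend_fragments(chosen, cl, frag_len = 180L)
    scale_per_million(tracks, length(unique(chosen$read_id)))
  }
  ip <- quantify_sample(chip$ip, "ip")
  mock <- quantify_sample(chip$mock, "mock")
  enr <- gene_enrichment(ip, mock, gen$genes)
  write.table(enr, file.path(out_dir, "pol3_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  genes <- gen$genes[!gen$genes$is_pseudo, , drop = FALSE]
  pairs <- data.frame(
    gene_id = genes$gene_id, family = genes$family,
    occupancy = vapply(seq_len(nrow(genes)), function(i)
      upstream_occupancy(genes[i, ], wt$tracks), numeric(1)),
    tag_count = vapply(seq_len(nrow(genes)), function(i)
      pol3_window_count(genes[i, ], ip), numeric(1)),
    stringsAsFactors = FALSE)
  fam_corr <- family_correlations(pairs)
  write.table(fam_corr, file.path(out_dir, "family_correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qpcr <- delta_delta_ct(simulate_qpcr(wt$truth, seed = substream(config$seed, "qpcr")))
  write.table(qpcr, file.path(out_dir, "qpcr_levels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fam_corr
}
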