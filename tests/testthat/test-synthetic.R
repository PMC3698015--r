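# Synthetic-data generator: genome construction, planted truth,
# simulated readouts, and their determinism/conservation contracts.

test_that("isogenes share a body sequence and the genome is deterministic", {
  gen <- generate_genome(n_genes = 4, n_families = 1, n_pseudo = 0,
                         n_chrom = 2, seed = 3)
  expect_equal(nrow(gen$genes), 4L)
  expect_equal(length(unique(gen$genes$family)), 1L)
  bodies <- vapply(seq_len(4), function(i) {
    g <- gen$genes[i, ]
    s <- Biostrings::subseq(gen$genome[[g$chrom]],
                            min(g$tss, g$tts) + 1, max(g$tss, g$tts) + 1)
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  expect_equal(length(unique(bodies)), 1L)

  gen2 <- generate_genome(n_genes = 4, n_families = 1, n_pseudo = 0,
                          n_chrom = 2, seed = 3)
  expect_identical(as.character(gen$genome), as.character(gen2$genome))
  expect_identical(gen$genes, gen2$genes)

  # a read from the shared body multi-maps across the 4 copies
  body_read <- substr(bodies[1], 1, 36)
  aln <- align_exact(data.frame(read_id = "r", sequence = body_read,
                                qualities = strrep("I", 36)), gen$genome)
  expect_gte(nrow(aln), 2L)
  expect_false(aln$is_unique[1])
})

test_that("planted truth honours labels, presets and the CLT", {
  gen <- medium_genome()
  arch1 <- architecture_config(positioned_fraction = 1)
  tr1 <- simulate_nucleosome_truth(gen$genes, arch1, seed = 1)
  expect_true(all(tr1$gene_truth$positioned))

  pre <- condition_preset("rsc4d4", n_changed = 30L, shift_set = 30L)
  tr2 <- simulate_nucleosome_truth(gen$genes, preset = pre, seed = 1)
  expect_equal(sum(tr2$gene_truth$event == "shift"), 30L)
  shifted <- tr2$gene_truth$shift_bp[tr2$gene_truth$event == "shift"]
  expect_true(all(shifted > 0))
  expect_equal(mean(shifted), 60, tolerance = 0.1)

  wt <- simulate_nucleosome_truth(gen$genes, seed = 5)
  us <- wt$gene_truth$us_dyad_rel[wt$gene_truth$positioned]
  arch <- architecture_config()
  expect_lt(abs(mean(us) - arch$us_center), 3 * arch$us_sd / sqrt(length(us)))
  # shared base truth: a different run seed re-plants the same dyads
  wt2 <- simulate_nucleosome_truth(gen$genes, seed = 6)
  expect_equal(wt$nucleosomes$dyad, wt2$nucleosomes$dyad)
})

test_that("preset perturbation sets larger than the gene set are rejected", {
  gen <- generate_genome(n_genes = 10, n_families = 3, n_pseudo = 0,
                         n_chrom = 1, seed = 1)
  expect_error(simulate_nucleosome_truth(
    gen$genes, preset = condition_preset("isw1d2d")), "exceed")
})

test_that("array signal follows the planted occupancy model", {
  gen <- generate_genome(n_genes = 6, n_families = 2, n_pseudo = 0,
                         n_chrom = 1, seed = 11)
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)

  # empty truth: background-only signal is ~ Normal(0, noise_sd)
  t0 <- truth
  t0$nucleosomes <- t0$nucleosomes[0, ]
  t0$gene_truth$encroach <- 0
  tr0 <- simulate_mnase_array(t0, noise_sd = 0.3, seed = 2, chrom_lengths = cl)[[1]]
  expect_lt(abs(mean(tr0$values)), 0.02)
  expect_equal(sd(tr0$values), 0.3, tolerance = 0.02)

  # single planted dyad: expected signal is maximal at the dyad probe
  t1 <- truth
  t1$nucleosomes <- t1$nucleosomes[1, ]
  t1$gene_truth$encroach <- 0
  tr1 <- simulate_mnase_array(t1, noise_sd = 0, seed = 2, chrom_lengths = cl)[[1]]
  d <- t1$nucleosomes$dyad[1]
  pos <- track_positions(tr1)
  expect_equal(tr1$values[which.min(abs(pos - d))], max(tr1$values))
  expect_true(all(abs(pos[tr1$values == max(tr1$values)] - d) <= 74))

  # replicate tracks at low noise correlate strongly
  ra <- simulate_mnase_array(truth, noise_sd = 0.1, seed = 31, chrom_lengths = cl)[[1]]
  rb <- simulate_mnase_array(truth, noise_sd = 0.1, seed = 32, chrom_lengths = cl)[[1]]
  expect_gt(cor(ra$values, rb$values), 0.9)
})

test_that("fragment simulation: uniform background, dyad modes, conservation", {
  gen <- generate_genome(n_genes = 4, n_families = 2, n_pseudo = 0,
                         n_chrom = 1, seed = 21)
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)

  fr_bg <- simulate_mnase_fragments(truth, 5000, background_frac = 1,
                                    seed = 3, chrom_lengths = cl)
  expect_equal(nrow(fr_bg), 5000L)
  mids <- (fr_bg$start + fr_bg$end) / 2
  ks <- suppressWarnings(ks.test(mids, "punif", 0, cl[[1]]))
  expect_gt(ks$p.value, 0.01)

  t1 <- truth
  t1$nucleosomes <- t1$nucleosomes[3, ]
  fr1 <- simulate_mnase_fragments(t1, 2000, background_frac = 0, midpoint_sd = 10,
                                  seed = 4, chrom_lengths = cl)
  m1 <- (fr1$start + fr1$end) %/% 2
  h <- table(round(m1 / 20))
  expect_lt(abs(as.numeric(names(h)[which.max(h)]) * 20 - t1$nucleosomes$dyad), 30)
})

test_that("pol III intensities carry the requested correlation exactly", {
  gen <- medium_genome()
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1, pol3_r = -0.6544)
  gt <- truth$gene_truth[!truth$gene_truth$is_pseudo, ]
  for (fam in unique(gt$family)) {
    p <- gt[gt$family == fam, ]
    if (nrow(p) >= 3 && sd(p$upstream_occ) > 0) {
      expect_equal(cor(p$upstream_occ, p$pol3_intensity), -0.6544,
                   tolerance = 1e-9)
    }
  }
  # r = -1 is an exact decreasing affine map
  x <- correlated_vector(1:8, rnorm(8), -1 + 1e-12)
  expect_equal(cor(1:8, x), -1, tolerance = 1e-6)

  # starvation preset scales intensities down by pol3_scale
  st <- simulate_nucleosome_truth(gen$genes,
                                  preset = condition_preset("starvation"), seed = 1)
  ratio <- st$gene_truth$pol3_intensity / truth$gene_truth$pol3_intensity
  expect_equal(unname(ratio[!truth$gene_truth$is_pseudo][1:10]),
               rep(0.15, 10), tolerance = 0.05)
})

test_that("chip reads: conservation, pseudo background, determinism", {
  gen <- generate_genome(n_genes = 12, n_families = 3, n_pseudo = 2,
                         n_chrom = 2, seed = 31)
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)
  chip <- simulate_pol3_chip(truth, gen$genome, n_reads_ip = 3000,
                             n_reads_mock = 1000, seed = 5)
  expect_equal(nrow(chip$ip), 3000L)
  expect_equal(nrow(chip$mock), 1000L)
  chip2 <- simulate_pol3_chip(truth, gen$genome, n_reads_ip = 3000,
                              n_reads_mock = 1000, seed = 5)
  expect_identical(chip$ip, chip2$ip)
})

test_that("qPCR tables follow the log2 law and are deterministic", {
  gen <- medium_genome()
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)
  q1 <- simulate_qpcr(truth, ct_noise_sd = 0, seed = 9)
  # doubling a family's abundance lowers its target Ct by one cycle
  t2 <- truth
  t2$gene_truth$pol3_intensity <- 2 * t2$gene_truth$pol3_intensity
  q2 <- simulate_qpcr(t2, ct_noise_sd = 0, seed = 9)
  expect_equal(q1$ct_target - q2$ct_target, rep(1, nrow(q1)), tolerance = 1e-9)
  expect_identical(q1, simulate_qpcr(truth, ct_noise_sd = 0, seed = 9))
})
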