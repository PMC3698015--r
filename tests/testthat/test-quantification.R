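# Windowed quantification, family correlations, ddCt.

test_that("windowed means are constant-correct, mirrored, and clip-warned", {
  g_plus <- data.frame(gene_id = "p", chrom = "chrI", strand = "+", tss = 500L,
                       tts = 589L, family = "f", is_pseudo = FALSE, length = 90L)
  tr <- list(make_track(rep(3.5, 1000), kind = "log2ratio"))
  expect_equal(upstream_occupancy(g_plus, tr), 3.5)
  expect_equal(pol3_window_count(g_plus, tr), 3.5)

  v <- seq_len(1000) / 100
  g_minus <- data.frame(gene_id = "m", chrom = "chrI", strand = "-", tss = 499L,
                        tts = 410L, family = "f", is_pseudo = FALSE, length = 90L)
  fwd <- upstream_occupancy(g_plus, list(make_track(v, kind = "log2ratio")))
  rev_tr <- list(make_track(rev(v), kind = "log2ratio"))
  mir <- upstream_occupancy(g_minus, rev_tr)
  expect_equal(mir, fwd)

  g_edge <- g_plus; g_edge$tss <- 30L; g_edge$tts <- 119L
  expect_warning(upstream_occupancy(g_edge, tr), "clipped")
})

test_that("the 10-isogene fixture reproduces the configured family r", {
  pairs <- make_correlated_pairs(n = 10, r = -0.6544, seed = 7)
  fc <- family_correlations(pairs, min_isogenes = 3)
  expect_equal(fc$pearson_r, -0.6544, tolerance = 1e-9)
  expect_equal(fc$n_isogenes, 10L)

  expect_equal(worked_example_correlation(), -0.6544, tolerance = 1e-9)
})

test_that("degenerate and small families are reported without an r", {
  pairs <- data.frame(gene_id = letters[1:5],
                      family = c("big", "big", "big", "small", "small"),
                      occupancy = c(1, 1, 1, 1, 2),
                      tag_count = c(5, 6, 7, 8, 9))
  fc <- family_correlations(pairs)
  expect_true(is.na(fc$pearson_r[fc$family == "big"]))     # zero variance
  expect_match(fc$reason[fc$family == "big"], "variance")
  expect_true(is.na(fc$pearson_r[fc$family == "small"]))   # < 3 isogenes
  perfect <- data.frame(gene_id = letters[1:4], family = "f",
                        occupancy = 1:4, tag_count = c(8, 6, 4, 2))
  expect_equal(family_correlations(perfect)$pearson_r, -1)
})

test_that("Pearson agrees with the direct covariance formula", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    manual <- sum((x - mean(x)) * (y - mean(y))) / (19 * sd(x) * sd(y))
    fc <- family_correlations(data.frame(gene_id = 1:20, family = "f",
                                         occupancy = x, tag_count = y))
    expect_equal(fc$pearson_r, manual, tolerance = 1e-12)
  }
})

test_that("Gram-Schmidt construction hits any requested r exactly", {
  for (r in c(-0.93, -0.6544, -0.5, -0.1, 0)) {
    p <- make_correlated_pairs(n = 8, r = r, seed = 3)
    expect_equal(cor(p$occupancy, p$tag_count), r, tolerance = 1e-9)
  }
})

test_that("leave-one-out diagnostic is labeled and at least as negative", {
  p <- make_correlated_pairs(n = 10, r = -0.5, seed = 2)
  fc <- family_correlations(p, leave_one_out = TRUE)
  expect_true("loo_best_r" %in% names(fc))
  expect_lte(fc$loo_best_r, fc$pearson_r)
})

test_that("ddCt arithmetic, invariance, and reliability flag", {
  m <- data.frame(ct_target = c(20, 20, 20, 42),
                  ct_reference = c(20, 18, 18, 20),
                  ct_target_cal = c(20, 22, 22, 20),
                  ct_reference_cal = c(20, 18, 18, 20))
  out <- delta_delta_ct(m)
  expect_equal(out$relative_level[1], 1)
  expect_equal(out$relative_level[2], 4)      # ddCt = -2
  expect_true(out$unreliable[4])
  # adding a constant to all four Cts changes nothing
  m2 <- m[2, ] + 3
  expect_equal(delta_delta_ct(m2)$relative_level, 4)
})

test_that("ddCt inverts the simulated Ct table exactly at zero noise", {
  gen <- medium_genome()
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)
  q <- delta_delta_ct(simulate_qpcr(truth, ct_noise_sd = 0, seed = 2,
                                    ref_abundance = 1000))
  gt <- truth$gene_truth[!truth$gene_truth$is_pseudo, ]
  per_copy <- tapply(gt$pol3_intensity, gt$family, mean)
  expect_equal(q$relative_level, as.numeric(per_copy[q$target]) / 1000,
               tolerance = 1e-9)
})

test_that("family r is recovered through the measurement pipeline", {
  gen <- medium_genome()
  run <- medium_run("wild_type", 7)
  chip <- simulate_pol3_chip(run$truth, gen$genome, n_reads_ip = 80000,
                             n_reads_mock = 20000, seed = 3)
  aln <- reallocate_multireads(align_exact(chip$ip, gen$genome), seed = 4)
  ch <- aln[aln$chosen, ]
  ip <- scale_per_million(extend_fragments(ch, gen$chrom_lengths, frag_len = 180L),
                          length(unique(ch$read_id)))
  genes <- gen$genes[!gen$genes$is_pseudo, ]
  pairs <- data.frame(
    gene_id = genes$gene_id, family = genes$family,
    occupancy = vapply(seq_len(nrow(genes)), function(i)
      upstream_occupancy(genes[i, ], run$tracks), numeric(1)),
    tag_count = vapply(seq_len(nrow(genes)), function(i)
      pol3_window_count(genes[i, ], ip), numeric(1)))
  fc <- family_correlations(pairs)
  big <- fc[fc$n_isogenes >= 5 & is.finite(fc$pearson_r), ]
  expect_gte(nrow(big), 4)
  expect_lt(abs(mean(big$pearson_r) - (-0.6544)), 0.1)
})
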