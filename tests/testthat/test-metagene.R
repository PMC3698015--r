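# Meta-gene binning, profiles, periodicity, architecture extraction.

test_that("binning geometry: column count, constant tracks, strand flip", {
  L <- 12000L
  v <- rnorm(L)
  genes <- data.frame(
    gene_id = c("plus", "minus"), chrom = c("chrI", "chrII"),
    strand = c("+", "-"), tss = c(5000L, L - 1L - 5000L),
    tts = c(5089L, L - 1L - 5089L), family = "f", is_pseudo = FALSE,
    length = 90L, stringsAsFactors = FALSE)
  tracks <- list(make_track(v, "chrI", kind = "log2ratio"),
                 make_track(rev(v), "chrII", kind = "log2ratio"))
  mm <- bin_around(tracks, genes, "tss", window = 1000, bin = 20)
  expect_equal(ncol(mm), 100L)
  # the mirrored minus-strand gene sees the identical oriented signal
  expect_equal(unname(mm["plus", ]), unname(mm["minus", ]), tolerance = 1e-12)

  const <- list(make_track(rep(1.5, L), "chrI", kind = "log2ratio"))
  mc <- bin_around(const, genes[1, ], "tss")
  expect_true(all(mc == 1.5))
})

test_that("genes without a track give all-missing rows, not zeros", {
  genes <- data.frame(gene_id = "lost", chrom = "chrX", strand = "+",
                      tss = 5000L, tts = 5089L, family = "f",
                      is_pseudo = FALSE, length = 90L, stringsAsFactors = FALSE)
  expect_warning(mm <- bin_around(list(make_track(rnorm(100), "chrI")), genes, "tss"),
                 "without a track")
  expect_true(all(is.na(mm)))
})

test_that("average profile is the row mean and ignores missing bins", {
  m <- matrix(c(1, 3, NA, 5), 2, 2, dimnames = list(c("a", "b"), c(-10, 10)))
  attr(m, "anchor") <- "tss"; attr(m, "bin") <- 20
  class(m) <- c("meta_matrix", "matrix")
  p <- average_profile(m)
  expect_equal(p$mean, c(2, 5))
  expect_equal(p$n, c(2L, 1L), ignore_attr = TRUE)
  p1 <- average_profile(m[1, , drop = FALSE])
  expect_equal(p1$mean, c(1, NA))
})

test_that("wild-type simulation shows the planted meta-gene anatomy", {
  run <- medium_run("wild_type", 7)
  gen <- medium_genome()
  mm <- bin_around(run$tracks, gen$genes, "tss")
  prof <- average_profile(mm)
  # gene-body occupancy sits at background level, far below the flanks
  at <- function(lo, hi) mean(prof$mean[prof$pos > lo & prof$pos < hi])
  expect_lt(at(0, 120), at(-200, -80) - 1)
  expect_lt(at(0, 120), at(200, 300) - 1)
  expect_lt(at(0, 120), 0.3)
  ar <- architecture_from_profile(prof)
  expect_lt(abs(ar$nfr_start - (-70)), 25)
  expect_lt(abs(ar$nfr_end - 180), 25)
  # called-dyad density peaks at the planted upstream dyad
  dens <- dyad_profile(run$assigned, gen$genes)
  ar2 <- architecture_from_profile(dens, linearize = FALSE)
  expect_lt(abs(ar2$us_dyad - (-140)), 20)
})

test_that("plus- and minus-strand gene subsets give matching architecture", {
  run <- medium_run("wild_type", 7)
  gen <- medium_genome()
  genes <- gen$genes[!gen$genes$is_pseudo, ]
  a <- architecture_from_profile(average_profile(
    bin_around(run$tracks, genes[genes$strand == "+", ], "tss")))
  b <- architecture_from_profile(average_profile(
    bin_around(run$tracks, genes[genes$strand == "-", ], "tss")))
  expect_lt(abs(a$nfr_start - b$nfr_start), 20)
  expect_lt(abs(a$nfr_end - b$nfr_end), 20)
})

test_that("raising the NFR threshold never shrinks the NFR", {
  run <- medium_run("wild_type", 7)
  gen <- medium_genome()
  prof <- average_profile(bin_around(run$tracks, gen$genes, "tss"))
  lens <- vapply(c(0.3, 0.5, 0.7), function(f)
    architecture_from_profile(prof, nfr_threshold_frac = f)$nfr_length, numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("upstream periodicity: sinusoid, white noise, preset disorder", {
  pos <- seq(-990, 990, by = 20)
  sine <- structure(data.frame(pos = pos, mean = sin(2 * pi * pos / 165), n = 50),
                    anchor = "tss", bin = 20, class = c("meta_profile", "data.frame"))
  p <- upstream_periodicity(sine)
  expect_lt(abs(p$period - 165), 20)
  expect_true(p$confident)

  set.seed(8)
  noise <- structure(data.frame(pos = pos, mean = rnorm(length(pos)), n = 50),
                     anchor = "tss", bin = 20, class = c("meta_profile", "data.frame"))
  pn <- upstream_periodicity(noise)
  expect_true(is.na(pn$period) || !pn$confident)

  gen <- medium_genome()
  wt <- medium_run("wild_type", 7)
  mu <- medium_run("isw1d2d", 8)
  p_wt <- upstream_periodicity(average_profile(bin_around(wt$tracks, gen$genes, "tss")))
  p_mu <- upstream_periodicity(average_profile(bin_around(mu$tracks, gen$genes, "tss")))
  # array disorder weakens (or abolishes) the phasing signal
  expect_true(p_wt$confident)
  expect_true(is.na(p_mu$acf_peak) || p_mu$acf_peak < p_wt$acf_peak)
})

test_that("per-gene architecture rules on hand-built calls", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrI", strand = "+",
                      tss = c(1000L, 9000L), tts = c(1089L, 9089L),
                      family = c("fam", "fam"), is_pseudo = FALSE, length = 90L,
                      stringsAsFactors = FALSE)
  mk <- function(gene_id, dyad_rel, len = 148, positioned = TRUE, tts_off = 89L) {
    data.frame(chrom = "chrI", start = 0L, end = 0L, dyad = 0L, occupancy = 2,
               positioned = positioned, source = "array_hmm", gene_id = gene_id,
               dyad_rel = dyad_rel, start_rel = dyad_rel - len / 2,
               end_rel = dyad_rel + len / 2, dyad_rel_tts = dyad_rel - tts_off,
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk("g1", -140), mk("g1", 129),       # US at -140, DS at +40 rel TTS
                 mk("g2", -150), mk("g2", 300))
  ar <- architecture_from_calls(calls, genes)
  expect_equal(ar$us_dyad[ar$gene_id == "g1"], -140)
  expect_equal(ar$ds_dyad_tts[ar$gene_id == "g1"], 40)
  expect_true(ar$us_positioned[ar$gene_id == "g1"])
  # no upstream call inside [-300, -40]: counted as not positioned
  calls2 <- rbind(mk("g1", -350), mk("g1", 129 + 40))
  ar2 <- architecture_from_calls(calls2, genes)
  expect_true(is.na(ar2$us_dyad[1]))
  expect_false(ar2$us_positioned[1])
  # a gene-body call sets the Nuc-plus flag
  calls3 <- rbind(mk("g1", 45), mk("g2", -150))
  ar3 <- architecture_from_calls(calls3, genes)
  expect_true(ar3$nuc_plus[ar3$gene_id == "g1"])
})

test_that("heat-map export sorts rows as documented", {
  gen <- medium_genome()
  run <- medium_run("wild_type", 7)
  mm <- bin_around(run$tracks, gen$genes, "tss")[1:10, ]
  class(mm) <- c("meta_matrix", "matrix"); attr(mm, "anchor") <- "tss"
  arch <- architecture_from_calls(run$assigned, gen$genes)
  pre <- withr::local_tempfile()
  out_none <- heatmap_export(mm, pre, "none")
  expect_identical(rownames(out_none), rownames(mm))
  out_ds <- heatmap_export(mm, pre, "ds_distance_then_family",
                           genes = gen$genes, architecture = arch)
  ds <- arch$ds_dyad_tts[match(rownames(out_ds), arch$gene_id)]
  expect_true(!is.unsorted(ds[!is.na(ds)]))
  expect_true(file.exists(paste0(pre, ".tsv")))
  expect_true(file.exists(paste0(pre, ".png")))
})
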