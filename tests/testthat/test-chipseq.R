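# ChIP-seq quantification: filtering, exact alignment, reallocation,
# scaling and enrichment.

test_that("quality filter applies both thresholds inclusively", {
  q_of <- function(scores) intToUtf8(scores + 33)
  reads <- data.frame(
    read_id = c("all20", "q28of36", "empty_ok"),
    sequence = rep(strrep("A", 36), 3),
    qualities = c(q_of(rep(20, 36)),
                  q_of(c(rep(20, 28), rep(10, 8))),
                  q_of(rep(40, 36))),
    stringsAsFactors = FALSE)
  kept <- quality_filter(reads, min_q = 20, min_frac = 0.8)
  expect_true("all20" %in% kept$read_id)          # boundary inclusive
  expect_false("q28of36" %in% kept$read_id)       # 28/36 = 0.778 < 0.8
  expect_equal(attr(kept, "filter_counts")[["dropped"]], 1L)

  empty <- quality_filter(reads[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("exact alignment finds unique, multi-mapped and reverse hits", {
  gen <- generate_genome(n_genes = 4, n_families = 1, n_pseudo = 0,
                         n_chrom = 2, seed = 17)
  g1 <- gen$genes[1, ]
  flank_start <- min(g1$tss, g1$tts) - 500L
  flank_read <- as.character(Biostrings::subseq(gen$genome[[g1$chrom]],
                                                flank_start + 1, flank_start + 36))
  body <- as.character(Biostrings::subseq(gen$genome[[g1$chrom]],
                                          min(g1$tss, g1$tts) + 1,
                                          min(g1$tss, g1$tts) + 36))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(flank_read)))
  reads <- data.frame(read_id = c("flank", "body", "rc", "withN"),
                      sequence = c(flank_read, body, rc,
                                   paste0("N", substr(flank_read, 2, 36))),
                      qualities = strrep("I", 36), stringsAsFactors = FALSE)
  aln <- align_exact(reads, gen$genome)
  expect_true(all(aln$is_unique[aln$read_id == "flank"]))
  expect_equal(unique(aln$n_loci[aln$read_id == "body"]), 4L)
  expect_false("withN" %in% aln$read_id)
  rcrow <- aln[aln$read_id == "rc", ]
  expect_equal(rcrow$start, flank_start)
  expect_equal(rcrow$strand, "-")
})

test_that("reallocation follows unique-coverage weights and conserves reads", {
  # two candidate loci; unique starts 9:1 in the two neighbourhoods
  uniq <- data.frame(
    read_id = sprintf("u%d", 1:10),
    chrom = "chrI",
    start = c(seq(1000, 1160, length.out = 9), 5000),
    strand = "+", n_loci = 1L, is_unique = TRUE, stringsAsFactors = FALSE)
  multi <- data.frame(read_id = rep(sprintf("m%05d", 1:10000), each = 2),
                      chrom = "chrI", start = rep(c(1080L, 5000L), 10000),
                      strand = "+", n_loci = 2L, is_unique = FALSE,
                      stringsAsFactors = FALSE)
  aln <- rbind(uniq, multi)
  out <- reallocate_multireads(aln, seed = 11, window = 200, alpha = 1e-9)
  expect_equal(sum(out$chosen), 10L + 10000L)          # conservation
  chosen_multi <- out[out$chosen & !out$is_unique, ]
  expect_equal(nrow(chosen_multi), 10000L)
  frac_a <- mean(chosen_multi$start == 1080L)
  expect_gt(frac_a, 0.88)                              # binomial CI around 0.9
  expect_lt(frac_a, 0.92)

  # no unique reads anywhere: pseudocount gives a uniform draw
  out0 <- reallocate_multireads(multi, seed = 12, alpha = 0.1)
  f0 <- mean(out0$start[out0$chosen] == 1080L)
  expect_gt(f0, 0.47); expect_lt(f0, 0.53)
})

test_that("per-million scaling is an identity at 1e6 reads and preserves mass", {
  tr <- make_track(c(1, 2, 3, 4))
  expect_equal(scale_per_million(tr, 1e6)$values, tr$values)
  sc <- scale_per_million(tr, 2500)
  expect_equal(sum(sc$values) * 2500 / 1e6, sum(tr$values))
})

test_that("duplication-free genomes make reallocation a no-op", {
  gen <- generate_genome(n_genes = 6, n_families = 6, n_pseudo = 0,
                         n_chrom = 2, seed = 23)   # every family single-copy
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)
  chip <- simulate_pol3_chip(truth, gen$genome, n_reads_ip = 4000,
                             n_reads_mock = 1000, seed = 2)
  aln <- align_exact(chip$ip, gen$genome)
  expect_true(all(aln$is_unique))
  out <- reallocate_multireads(aln, seed = 3)
  expect_true(all(out$chosen))
  expect_equal(out[, names(aln)], aln, ignore_attr = TRUE)
})

test_that("gene enrichment: identity fold, pseudo background, recovery", {
  tr <- list(make_track(rep(4, 4000)))
  genes <- data.frame(gene_id = "g1", chrom = "chrI", strand = "+",
                      tss = 2000L, tts = 2089L, family = "f", is_pseudo = FALSE,
                      length = 90L, stringsAsFactors = FALSE)
  enr <- gene_enrichment(tr, tr, genes)
  expect_equal(enr$fold, 1)

  gen <- generate_genome(n_genes = 20, n_families = 5, n_pseudo = 3,
                         n_chrom = 2, seed = 29)
  cl <- stats::setNames(Biostrings::width(gen$genome), names(gen$genome))
  truth <- simulate_nucleosome_truth(gen$genes, seed = 1)
  chip <- simulate_pol3_chip(truth, gen$genome, n_reads_ip = 30000,
                             n_reads_mock = 15000, seed = 2)
  quant <- function(reads, tag) {
    aln <- reallocate_multireads(align_exact(reads, gen$genome), seed = tag)
    ch <- aln[aln$chosen, ]
    scale_per_million(extend_fragments(ch, cl, frag_len = 180L),
                      length(unique(ch$read_id)))
  }
  ip <- quant(chip$ip, 1); mock <- quant(chip$mock, 2)
  enr2 <- gene_enrichment(ip, mock, gen$genes)
  expect_gt(median(enr2$fold[!enr2$is_pseudo]), 3)
  expect_lt(median(enr2$fold[enr2$is_pseudo]), 1.5)

  # estimated per-gene tag counts track the planted intensities
  genes_real <- gen$genes[!gen$genes$is_pseudo, ]
  tags <- vapply(seq_len(nrow(genes_real)), function(i)
    pol3_window_count(genes_real[i, ], ip), numeric(1))
  planted <- truth$gene_truth$pol3_intensity[
    match(genes_real$gene_id, truth$gene_truth$gene_id)]
  expect_gte(cor(planted, tags, method = "spearman"), 0.9)
})
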