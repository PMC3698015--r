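# Differential classification: matching, event rules, symmetry,
# preset recovery at reduced scale.

fake_genes <- function() {
  data.frame(gene_id = "g1", chrom = "chrI", strand = "+", tss = 1000L,
             tts = 1089L, family = "f", is_pseudo = FALSE, length = 90L,
             stringsAsFactors = FALSE)
}

fake_call <- function(dyad_rel, occ = 2, len = 148, positioned = TRUE) {
  data.frame(chrom = "chrI", start = 0L, end = 0L, dyad = 0L, occupancy = occ,
             positioned = positioned, source = "array_hmm", gene_id = "g1",
             dyad_rel = dyad_rel, start_rel = dyad_rel - len / 2,
             end_rel = dyad_rel + len / 2, dyad_rel_tts = dyad_rel - 89L,
             stringsAsFactors = FALSE)
}

test_that("identical call sets match completely and yield no events", {
  a <- rbind(fake_call(-140), fake_call(150))
  p <- match_calls(a, a, fake_genes())
  expect_equal(nrow(p), 2L)
  expect_true(all(is.finite(p$dyad_a) & is.finite(p$dyad_b)))
  expect_equal(nrow(classify_changes(p, fake_genes())), 0L)
})

test_that("singletons become gains/losses; nearest pairing wins", {
  a <- rbind(fake_call(-140), fake_call(-20))
  b <- fake_call(-130)
  p <- match_calls(a, b, fake_genes())
  ev <- classify_changes(p, fake_genes())
  # nearest pair (-140 vs -130) matches; the -20 call is a loss
  expect_equal(sort(ev$event), "loss")
  expect_equal(ev$region, "upstream")

  p2 <- match_calls(fake_call(-140), rbind(fake_call(-140), fake_call(45)), fake_genes())
  ev2 <- classify_changes(p2, fake_genes())
  expect_equal(ev2$event, "gain")
  expect_equal(ev2$region, "body")
})

test_that("shift threshold and the toward-TTS sign convention", {
  # upstream call moving 50 bp downstream: positive displacement
  p <- match_calls(fake_call(-140), fake_call(-90), fake_genes())
  ev <- classify_changes(p, fake_genes())
  expect_equal(ev$event, "shift")
  expect_equal(ev$displacement, 50)

  # downstream call moving 50 bp toward the gene: also positive
  p2 <- match_calls(fake_call(240), fake_call(190), fake_genes())
  ev2 <- classify_changes(p2, fake_genes())
  expect_equal(ev2$displacement, 50)

  # sub-threshold displacement: no event
  p3 <- match_calls(fake_call(-140), fake_call(-130), fake_genes())
  expect_equal(nrow(classify_changes(p3, fake_genes())), 0L)

  # a delocalized side never makes a positional shift
  p4 <- match_calls(fake_call(-140), fake_call(-60, len = 300, positioned = FALSE),
                    fake_genes())
  ev4 <- classify_changes(p4, fake_genes())
  expect_false("shift" %in% ev4$event)
})

test_that("occupancy change on a matched pair is a gain/loss event", {
  p <- match_calls(fake_call(-140, occ = 2), fake_call(-140, occ = 2.5), fake_genes())
  ev <- classify_changes(p, fake_genes())
  expect_equal(ev$event, "gain")
  expect_equal(ev$delta_occupancy, 0.5)
  p2 <- match_calls(fake_call(-140, occ = 2), fake_call(-140, occ = 2.1), fake_genes())
  expect_equal(nrow(classify_changes(p2, fake_genes())), 0L)
})

test_that("swapping conditions maps gain<->loss and negates displacements", {
  run_a <- medium_run("wild_type", 7)
  run_b <- medium_run("rsc4d4", 8)
  gen <- medium_genome()
  ev_ab <- classify_changes(match_calls(run_a$assigned, run_b$assigned, gen$genes),
                            gen$genes)
  ev_ba <- classify_changes(match_calls(run_b$assigned, run_a$assigned, gen$genes),
                            gen$genes)
  expect_equal(sum(ev_ab$event == "gain"), sum(ev_ba$event == "loss"))
  expect_equal(sum(ev_ab$event == "loss"), sum(ev_ba$event == "gain"))
  sa <- sort(ev_ab$displacement[ev_ab$event == "shift"])
  sb <- sort(-ev_ba$displacement[ev_ba$event == "shift"])
  expect_equal(sa, sb)
})

test_that("raising shift_min never increases the shift count", {
  run_a <- medium_run("wild_type", 7)
  run_b <- medium_run("rsc4d4", 8)
  gen <- medium_genome()
  p <- match_calls(run_a$assigned, run_b$assigned, gen$genes)
  n <- vapply(c(20, 30, 45, 70), function(s)
    changed_gene_count(classify_changes(p, gen$genes, shift_min = s), "shift"),
    numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("preset recovery at reduced scale matches planted counts", {
  gen <- medium_genome()
  wt <- medium_run("wild_type", 7)
  # scaled-down presets on the 120-gene set
  for (cfg in list(list(name = "isw1d2d", over = list(n_changed = 40L, gain_set = 28L,
                                                      loss_set = 12L), type = c("gain", "loss")),
                   list(name = "rsc4d4", over = list(n_changed = 45L, shift_set = 45L),
                        type = "shift"))) {
    pre <- do.call(condition_preset, c(list(name = cfg$name), cfg$over))
    truth <- simulate_nucleosome_truth(gen$genes, preset = pre, seed = 15)
    tracks <- simulate_mnase_array(truth, seed = 15, chrom_lengths = gen$chrom_lengths)
    assigned <- assign_calls_to_genes(call_nucleosomes(tracks), gen$genes)
    ev <- classify_changes(match_calls(wt$assigned, assigned, gen$genes), gen$genes)
    got <- changed_gene_count(ev, cfg$type)
    expect_lt(abs(got - pre$n_changed), 0.12 * pre$n_changed + 1)
  }
})

test_that("occupancy deltas: zeros, constants, starvation sign pattern", {
  gen <- medium_genome()
  wt <- medium_run("wild_type", 7)
  mm <- bin_around(wt$tracks, gen$genes, "tss")
  d0 <- occupancy_delta(mm, mm)
  expect_true(all(d0$delta == 0, na.rm = TRUE))
  mm1 <- mm; mm1[] <- mm1 + 1
  d1 <- occupancy_delta(mm, mm1)
  expect_true(all(abs(d1$delta - 1) < 1e-12, na.rm = TRUE))

  st <- medium_run("starvation", 9)
  mm_st <- bin_around(st$tracks, gen$genes, "tss")
  changed <- st$truth$gene_truth$gene_id[st$truth$gene_truth$changed]
  d <- occupancy_delta(mm[changed, ], mm_st[changed, ])
  at <- function(p) d$per_bin$mean_delta[which.min(abs(d$per_bin$pos - p))]
  expect_gt(at(-140), 0)            # US occupancy up
  expect_gt(at(240), 0)             # DS occupancy up
  expect_lt(at(-305), 0)            # -2 down
  expect_lt(at(430), 0)             # +2 down
})
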