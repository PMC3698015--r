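# Shared fixtures: small cached simulations so several test files can
# reuse the same runs without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_env)) assign(key, make(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Medium genome (120 genes) shared across metagene/differential tests.
medium_genome <- function() {
  cached("medium_genome", function() {
    gen <- generate_genome(n_genes = 120L, n_families = 20L, n_pseudo = 4L,
                           n_chrom = 4L, seed = 42L)
    gen$chrom_lengths <- stats::setNames(Biostrings::width(gen$genome),
                                         names(gen$genome))
    gen
  })
}

# A wild-type (or preset) simulation + calls on the medium genome.
medium_run <- function(preset = "wild_type", seed = 7L) {
  key <- sprintf("run_%s_%d", preset, seed)
  cached(key, function() {
    gen <- medium_genome()
    truth <- simulate_nucleosome_truth(gen$genes,
                                       preset = condition_preset(preset),
                                       seed = seed)
    tracks <- simulate_mnase_array(truth, seed = seed,
                                   chrom_lengths = gen$chrom_lengths)
    calls <- call_nucleosomes(tracks)
    list(truth = truth, tracks = tracks, calls = calls,
         assigned = assign_calls_to_genes(calls, gen$genes))
  })
}

# Tiny single-chromosome track helper.
make_track <- function(values, chrom = "chrI", origin = 0L, step = 1L,
                       kind = "counts") {
  coverage_track(chrom, values, origin = origin, step = step, kind = kind)
}

# Brute-force Viterbi oracle: enumerate every state path of a 2-state
# Gaussian HMM and return the maximum-probability path.
brute_force_viterbi <- function(x, mu, sd, trans, init) {
  T <- length(x)
  paths <- as.matrix(expand.grid(rep(list(0:1), T)))[, T:1, drop = FALSE]
  lt <- log(trans); li <- log(init)
  score <- apply(paths, 1, function(p) {
    s <- li[p[1] + 1] + dnorm(x[1], mu[p[1] + 1], sd[p[1] + 1], log = TRUE)
    for (t in seq_len(T - 1)) {
      s <- s + lt[p[t] + 1, p[t + 1] + 1] +
        dnorm(x[t + 1], mu[p[t + 1] + 1], sd[p[t + 1] + 1], log = TRUE)
    }
    s
  })
  paths[which.max(score), ]
}
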