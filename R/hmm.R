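# Two-state (linker/nucleosome) Gaussian HMM segmentation of log2-ratio
# tracks. Emission parameters are fit by a single EM pass initialized
# from a two-component quantile split; state dwell lengths are mapped to
# self-transition probabilities given the probe step and held fixed.

#' Specification of the segmentation HMM
#'
#' @param track a [coverage_track()] used to pick the step; emissions
#'   are fit from data unless given.
#' @param nuc_dwell,linker_dwell expected state dwell lengths (bp);
#'   mapped to self-transitions as `p = 1 - step/dwell`.
#' @param smooth_window probe smoothing window applied before
#'   segmentation (odd; 1 disables).
#' @param means,sds optional fixed per-state Gaussian emissions,
#'   `c(linker, nucleosome)`; fit by EM when `NULL`.
#' @param min_len,max_len run-length bounds (bp): shorter runs are
#'   dropped, longer ones flagged delocalized (`positioned = FALSE`).
#' @param em_tol,em_max_iter EM stopping rule on the log-likelihood.
#' @return list of class `hmm_spec`.
#' @export
hmm_spec <- function(track, nuc_dwell = 147, linker_dwell = 500,
                     smooth_window = 3L, means = NULL, sds = NULL,
                     min_len = 100, max_len = 250,
                     em_tol = 1e-6, em_max_iter = 200L) {
  step <- track$step
  p_nn <- 1 - step / nuc_dwell
  p_ll <- 1 - step / linker_dwell
  trans <- matrix(c(p_ll, 1 - p_ll, 1 - p_nn, p_nn), 2, 2, byrow = TRUE)
  init <- c(linker_dwell, nuc_dwell) / (linker_dwell + nuc_dwell)
  structure(list(trans = trans, init = init, smooth_window = smooth_window,
                 means = means, sds = sds, min_len = min_len, max_len = max_len,
                 em_tol = em_tol, em_max_iter = em_max_iter, step = step),
            class = "hmm_spec")
}

# Single EM pass over one track: emissions only, transitions fixed.
fit_hmm_emissions <- function(x, spec) {
  q <- quantile(x, c(0.35, 0.95), names = FALSE)
  mu <- q
  if (diff(mu) < 1e-8) mu <- mu + c(-1e-3, 1e-3)
  s <- rep(max(sd(x) / 2, 1e-3), 2)
  ll_old <- -Inf
  for (it in seq_len(spec$em_max_iter)) {
    fb <- hmm_forward_backward_cpp(x, mu, s, spec$trans, spec$init)
    g <- fb$gamma
    w <- colSums(g)
    mu_new <- c(sum(g[, 1] * x), sum(g[, 2] * x)) / w
    s_new <- sqrt(c(sum(g[, 1] * (x - mu_new[1])^2),
                    sum(g[, 2] * (x - mu_new[2])^2)) / w)
    s_new <- pmax(s_new, 1e-3)
    mu <- mu_new; s <- s_new
    if (abs(fb$loglik - ll_old) < spec$em_tol) break
    ll_old <- fb$loglik
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); s <- rev(s) }  # state 2 = nucleosome
  list(means = mu, sds = s)
}

#' Segment a log2-ratio track into nucleosome calls (Viterbi)
#'
#' Smooths the track, fits the two Gaussian emissions by EM (unless the
#' spec fixes them), decodes the maximum-probability state path, and
#' turns maximal nucleosome-state runs into calls: runs shorter than
#' `min_len` bp are discarded; runs longer than `max_len` bp whose
#' interior dips below the midpoint of the two state means are split at
#' the valley (adjacent nucleosomes separated by a sub-resolution
#' linker), and long runs without such a valley are kept as single
#' delocalized calls (`positioned = FALSE`). The dyad is the run
#' midpoint and the occupancy the mean smoothed signal over the run.
#' Viterbi ties are broken toward the linker state.
#'
#' @param track a log2-ratio [coverage_track()].
#' @param spec an [hmm_spec()]; defaults are derived from the track.
#' @return call data.frame(chrom, start, end, dyad, occupancy,
#'   positioned, source).
#' @export
hmm_viterbi_segment <- function(track, spec = hmm_spec(track)) {
  if (track$kind != "log2ratio") stop("hmm_viterbi_segment: expected a log2ratio track")
  if (spec$smooth_window > 1 && length(track$values) >= spec$smooth_window) {
    track <- smooth_track(track, spec$smooth_window)
  }
  x <- track$values
  if (sd(x) < 1e-12) {
    warning("hmm_viterbi_segment: zero-variance track, no calls")
    return(empty_calls())
  }
  em <- if (is.null(spec$means)) fit_hmm_emissions(x, spec)
        else list(means = spec$means, sds = spec$sds)
  path <- hmm_viterbi_cpp(x, em$means, em$sds, log(spec$trans), log(spec$init))
  runs_to_calls(path, track, spec, em)
}

# Over-long nucleosome runs whose interior dips below the midpoint of
# the two state means are split at the valley (adjacent nucleosomes
# separated by a sub-resolution linker); long runs without such a
# valley stay single delocalized calls.
split_run <- function(i0, i1, x, spec, midpoint) {
  step <- spec$step
  len <- (i1 - i0 + 1L) * step
  if (len <= spec$max_len) return(list(c(i0, i1)))
  guard <- max(1L, spec$min_len %/% step)
  lo <- i0 + guard; hi <- i1 - guard
  if (lo > hi) return(list(c(i0, i1)))
  k <- (lo:hi)[which.min(x[lo:hi])]
  if (x[k] >= midpoint) return(list(c(i0, i1)))
  c(split_run(i0, k - 1L, x, spec, midpoint),
    split_run(k + 1L, i1, x, spec, midpoint))
}

runs_to_calls <- function(path, track, spec, em = NULL) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nuc <- which(r$values == 1L)
  if (!length(nuc)) return(empty_calls())
  step <- track$step
  midpoint <- if (is.null(em)) Inf else mean(em$means)
  segs <- unlist(lapply(nuc, function(k)
    split_run(starts[k], ends[k], track$values, spec, midpoint)), recursive = FALSE)
  out <- lapply(segs, function(s) {
    p0 <- track$origin + (s[1] - 1L) * step
    n_probes <- s[2] - s[1] + 1L
    start <- p0 - step %/% 2L            # each probe covers ~step bp around its midpoint
    end <- start + n_probes * step
    len <- end - start
    if (len < spec$min_len) return(NULL)
    data.frame(chrom = track$chrom, start = start, end = end,
               dyad = floor((start + end) / 2),
               occupancy = mean(track$values[s[1]:s[2]]),
               positioned = len <= spec$max_len, source = "array_hmm",
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             dyad = integer(0), occupancy = numeric(0), positioned = logical(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Segment a set of per-chromosome tracks
#'
#' @param tracks list of log2-ratio tracks.
#' @param ... passed to [hmm_spec()].
#' @return combined call data.frame.
#' @export
call_nucleosomes <- function(tracks, ...) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  out <- lapply(tracks, function(t) hmm_viterbi_segment(t, hmm_spec(t, ...)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
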