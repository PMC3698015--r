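# Differential chromatin: match calls between two conditions near gene
# ends and classify gains, losses and shifts.

#' Match nucleosome calls between two conditions per gene
#'
#' Candidate calls are collected from a pairing window `flank +
#' match_pad` bp around the gene span (wide enough that a nucleosome
#' moving into the `flank` window from just outside still finds its
#' partner), then paired greedily by nearest dyad with a maximum pairing
#' distance of `max_dist` bp; unmatched calls are carried as singletons.
#' Each row records whether the call(s) lie "near the gene ends" — dyad
#' within `flank` + half a footprint of the gene span — which is the
#' window on which gains and losses are counted downstream.
#'
#' @param calls_a,calls_b assigned calls (see
#'   [assign_calls_to_genes()]) for conditions A and B.
#' @param genes gene data.frame.
#' @param flank gene-end window (bp) used for event counting.
#' @param max_dist maximum dyad distance for a pair (bp).
#' @param match_pad extra pairing-window width beyond `flank` (bp).
#' @param near_pad half-footprint allowance for the near-gene-ends test
#'   (bp).
#' @param include_pseudo analyse pseudogenes too.
#' @return data.frame, one row per pair or singleton: gene_id, dyad_a,
#'   dyad_b, occ_a, occ_b, positioned_a, positioned_b, near_a, near_b
#'   (TSS-relative dyads; NA marks the absent side).
#' @export
match_calls <- function(calls_a, calls_b, genes, flank = 100L, max_dist = 100L,
                        match_pad = 150L, near_pad = 74L,
                        include_pseudo = FALSE) {
  if (!include_pseudo) genes <- genes[!genes$is_pseudo, , drop = FALSE]
  wide <- flank + match_pad
  in_window <- function(cc, g) {
    cc <- cc[cc$gene_id == g$gene_id, , drop = FALSE]
    cc[cc$end_rel > -wide & cc$start_rel < (g$length - 1L) + wide + 1L, , drop = FALSE]
  }
  near <- function(dyad, g) {
    is.finite(dyad) & dyad >= -(flank + near_pad) & dyad <= (g$length - 1L) + flank + near_pad
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    a <- in_window(calls_a, g); b <- in_window(calls_b, g)
    na <- nrow(a); nb <- nrow(b)
    if (na == 0 && nb == 0) return(NULL)
    pair_a <- integer(0); pair_b <- integer(0)
    if (na > 0 && nb > 0) {
      d <- abs(outer(a$dyad_rel, b$dyad_rel, "-"))
      repeat {
        k <- which.min(d)
        if (!length(k) || d[k] > max_dist) break
        ia <- (k - 1) %% na + 1; ib <- (k - 1) %/% na + 1
        pair_a <- c(pair_a, ia); pair_b <- c(pair_b, ib)
        d[ia, ] <- Inf; d[, ib] <- Inf
      }
    }
    sole_a <- setdiff(seq_len(na), pair_a)
    sole_b <- setdiff(seq_len(nb), pair_b)
    da <- c(a$dyad_rel[pair_a], a$dyad_rel[sole_a], rep(NA_real_, length(sole_b)))
    db <- c(b$dyad_rel[pair_b], rep(NA_real_, length(sole_a)), b$dyad_rel[sole_b])
    data.frame(
      gene_id = g$gene_id, dyad_a = da, dyad_b = db,
      occ_a = c(a$occupancy[pair_a], a$occupancy[sole_a], rep(NA_real_, length(sole_b))),
      occ_b = c(b$occupancy[pair_b], rep(NA_real_, length(sole_a)), b$occupancy[sole_b]),
      positioned_a = c(a$positioned[pair_a], a$positioned[sole_a], rep(NA, length(sole_b))),
      positioned_b = c(b$positioned[pair_b], rep(NA, length(sole_a)), b$positioned[sole_b]),
      near_a = near(da, g), near_b = near(db, g),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), dyad_a = numeric(0), dyad_b = numeric(0),
                      occ_a = numeric(0), occ_b = numeric(0),
                      positioned_a = logical(0), positioned_b = logical(0),
                      near_a = logical(0), near_b = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Classify matched call pairs into differential events
#'
#' A call present only in condition B is a *gain*, only in A a *loss*
#' (counted when the call is near the gene ends, i.e. within the
#' `flank` window of [match_calls()]); a matched pair whose occupancy
#' changes by at least `occ_min_delta` signal units is an occupancy
#' gain/loss. A matched pair whose dyads differ by at least `shift_min`
#' bp is a *shift*, provided both calls are positioned (a delocalized
#' call has no meaningful dyad) and at least one side is near the gene
#' ends. Shift displacement is signed positive toward (and past) the
#' terminator: movement of an upstream call downstream, or of a
#' downstream call back toward the gene, is positive. The event region
#' is upstream / body / downstream by the dyad position on the
#' transcription axis.
#'
#' @param pairs matched pairs from [match_calls()].
#' @param genes gene data.frame.
#' @param shift_min minimum dyad displacement for a shift (bp).
#' @param occ_min_delta minimum occupancy change (signal units).
#' @return data.frame(gene_id, event, region, displacement,
#'   delta_occupancy).
#' @export
classify_changes <- function(pairs, genes, shift_min = 30, occ_min_delta = 0.25) {
  len <- genes$length[match(pairs$gene_id, genes$gene_id)]
  events <- list()
  emit <- function(gene_id, event, dyad, len1, displacement = NA_real_, docc = NA_real_) {
    region <- if (dyad < 0) "upstream" else if (dyad <= len1 - 1) "body" else "downstream"
    events[[length(events) + 1]] <<- data.frame(
      gene_id = gene_id, event = event, region = region,
      displacement = displacement, delta_occupancy = docc,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]; l <- len[i]
    if (is.na(p$dyad_a)) {
      if (p$near_b) emit(p$gene_id, "gain", p$dyad_b, l)
    } else if (is.na(p$dyad_b)) {
      if (p$near_a) emit(p$gene_id, "loss", p$dyad_a, l)
    } else {
      disp <- p$dyad_b - p$dyad_a
      mid <- (p$dyad_a + p$dyad_b) / 2
      toward_tts <- if (mid <= l - 1) 1 else -1   # sign: positive = toward/past the TTS
      docc <- p$occ_b - p$occ_a
      if (abs(disp) >= shift_min && isTRUE(p$positioned_a) && isTRUE(p$positioned_b) &&
          (p$near_a || p$near_b)) {
        emit(p$gene_id, "shift", p$dyad_b, l, displacement = disp * toward_tts,
             docc = docc)
      }
      if (is.finite(docc) && abs(docc) >= occ_min_delta && (p$near_a || p$near_b)) {
        emit(p$gene_id, if (docc > 0) "gain" else "loss", p$dyad_b, l, docc = docc)
      }
    }
  }
  out <- do.call(rbind, events)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), event = character(0),
                      region = character(0), displacement = numeric(0),
                      delta_occupancy = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Count genes carrying differential events
#'
#' @param events event table from [classify_changes()].
#' @param types event types to count (default all).
#' @return number of distinct genes with at least one such event.
#' @export
changed_gene_count <- function(events, types = c("gain", "loss", "shift")) {
  length(unique(events$gene_id[events$event %in% types]))
}

#' Per-bin occupancy differences between two meta-gene matrices
#'
#' @param mm_a,mm_b `meta_matrix` objects sharing genes, bins and
#'   anchor.
#' @return list: `delta` (B - A matrix), `per_gene` (max |delta| and its
#'   bin per gene), `per_bin` (mean delta per bin).
#' @export
occupancy_delta <- function(mm_a, mm_b) {
  stopifnot(identical(dim(mm_a), dim(mm_b)),
            identical(rownames(mm_a), rownames(mm_b)),
            identical(attr(mm_a, "anchor"), attr(mm_b, "anchor")))
  delta <- unclass(mm_b) - unclass(mm_a)
  absd <- abs(delta)
  idx <- apply(absd, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  per_gene <- data.frame(
    gene_id = rownames(delta),
    max_abs_delta = vapply(seq_len(nrow(delta)), function(i)
      if (is.na(idx[i])) NA_real_ else absd[i, idx[i]], numeric(1)),
    at_bin = as.numeric(colnames(delta))[idx], stringsAsFactors = FALSE)
  per_bin <- data.frame(pos = as.numeric(colnames(delta)),
                        mean_delta = colMeans(delta, na.rm = TRUE))
  list(delta = delta, per_gene = per_gene, per_bin = per_bin)
}
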