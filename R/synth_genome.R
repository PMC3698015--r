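# Synthetic genome construction: families of identical-body isogenes
# scattered over several chromosomes with unique flanks, so short reads
# from gene bodies multi-map within a family while flank reads are
# unique.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

roman_chrom <- function(i) paste0("chr", as.character(utils::as.roman(i)))

#' Generate a synthetic genome with isogene families
#'
#' Genes are grouped into anticodon families; all copies of a family
#' share an identical gene-body sequence (planted so multi-mapping is
#' forced) while every flank is unique random sequence. Genes are placed
#' on `n_chrom` chromosomes with at least 2 kb between genes and 2 kb
#' chromosome margins. A configurable number of pseudogenes (single-copy
#' families, flagged `is_pseudo`) is appended.
#'
#' @param n_genes number of real genes (default mirrors the 273 mapped
#'   tRNA genes).
#' @param n_families number of anticodon families.
#' @param gene_length_range length range (bp) of the gene body.
#' @param n_pseudo number of pseudogenes.
#' @param n_chrom number of chromosomes.
#' @param spacing_range gap (bp) between consecutive genes on a
#'   chromosome, uniform draw; minimum 2 kb.
#' @param max_copies cap on isogene copies per family (kept below the
#'   20-locus multi-mapping cap).
#' @param seed seed; the same seed reproduces the genome byte for byte.
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `genes` (data.frame as from [read_genes()]).
#' @export
generate_genome <- function(n_genes = 273L, n_families = 42L,
                            gene_length_range = c(70L, 120L),
                            n_pseudo = 8L, n_chrom = 8L,
                            spacing_range = c(2000L, 3000L),
                            max_copies = 15L, seed = 1L) {
  stopifnot(n_genes >= n_families, spacing_range[1] >= 2000L)
  with_seed(substream(seed, "genome"), {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    fams <- character(0)
    while (length(fams) < n_families + n_pseudo) {
      cand <- paste0("t", sample(aa, 1), "(",
                     paste(sample(c("A", "C", "G", "U"), 3, replace = TRUE), collapse = ""), ")")
      if (!cand %in% fams) fams <- c(fams, cand)
    }
    real_fams <- fams[seq_len(n_families)]
    pseudo_fams <- fams[n_families + seq_len(n_pseudo)]

    # family sizes: at least 1, remainder spread with skewed weights
    sizes <- rep(1L, n_families)
    extra <- n_genes - n_families
    w <- runif(n_families)^2
    add <- as.vector(stats::rmultinom(1, extra, w / sum(w)))
    sizes <- sizes + add
    while (any(sizes > max_copies)) {  # redistribute overflow
      i <- which.max(sizes); j <- which.min(sizes)
      sizes[j] <- sizes[j] + (sizes[i] - max_copies)
      sizes[i] <- max_copies
    }
    fam_len <- sapply(seq_len(n_families + n_pseudo), function(i)
      sample(seq(gene_length_range[1], gene_length_range[2]), 1))
    fam_body <- vapply(fam_len, rand_dna, character(1))

    gene_id <- c(unlist(lapply(seq_len(n_families), function(i)
      paste0(real_fams[i], "-", seq_len(sizes[i])))),
      if (n_pseudo > 0) paste0("ps-", pseudo_fams, "-1"))
    family <- c(rep(real_fams, sizes), pseudo_fams)
    fam_index <- c(rep(seq_len(n_families), sizes), n_families + seq_len(n_pseudo))
    is_pseudo <- c(rep(FALSE, n_genes), rep(TRUE, n_pseudo))
    n_all <- length(gene_id)
    strand <- sample(c("+", "-"), n_all, replace = TRUE)

    # scatter copies: shuffle, deal round-robin onto chromosomes
    ord <- sample(n_all)
    chrom_of <- integer(n_all)
    chrom_of[ord] <- rep_len(seq_len(n_chrom), n_all)

    seqs <- character(n_chrom)
    out <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
      idx <- which(chrom_of == ch)
      pieces <- character(0)
      pos <- 0L
      rows <- list()
      for (i in idx) {
        gap <- sample(seq(spacing_range[1], spacing_range[2]), 1)
        pieces <- c(pieces, rand_dna(gap))
        pos <- pos + gap
        len <- fam_len[fam_index[i]]
        body <- fam_body[fam_index[i]]
        if (strand[i] == "-") {
          body <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
        }
        pieces <- c(pieces, body)
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gene_id[i], chrom = roman_chrom(ch), strand = strand[i],
          tss = if (strand[i] == "+") pos else pos + len - 1L,
          tts = if (strand[i] == "+") pos + len - 1L else pos,
          family = family[i], is_pseudo = is_pseudo[i], length = len,
          stringsAsFactors = FALSE)
        pos <- pos + len
      }
      pieces <- c(pieces, rand_dna(2000L))
      seqs[ch] <- paste(pieces, collapse = "")
      out[[ch]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    genes <- do.call(rbind, out)
    rownames(genes) <- NULL
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- roman_chrom(seq_len(n_chrom))
    list(genome = genome, genes = genes)
  })
}

#' Write a genome as FASTA
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)
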