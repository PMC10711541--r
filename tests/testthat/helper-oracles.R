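# Independent brute-force oracles. These deliberately recompute quantities
# with naive per-base / per-string loops, sharing no code with the package
# internals they check.

oracle_effective_length <- function(gr, genome) {
  total <- 0L
  for (cn in unique(as.character(GenomicRanges::seqnames(gr)))) {
    s <- strsplit(as.character(genome[[cn]]), "")[[1]]
    covered <- rep(FALSE, length(s))
    gi <- gr[as.character(GenomicRanges::seqnames(gr)) == cn]
    for (q in seq_along(gi)) {
      covered[GenomicRanges::start(gi)[q]:GenomicRanges::end(gi)[q]] <- TRUE
    }
    total <- total + sum(covered & s %in% c("A", "C", "G", "T"))
  }
  total
}

oracle_variant_count <- function(catalog, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  hits <- 0L
  for (i in seq_len(nrow(catalog))) {
    inside <- any(chrom == catalog$chrom[i] &
                    st <= catalog$pos[i] & en >= catalog$pos[i])
    hits <- hits + as.integer(inside)
  }
  hits
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (point-probability rule)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-intron octamer bin counting by explicit substring loops; returns the
# frequency matrix (with pseudocount 1) in the same layout as
# estimate_octamer_background
oracle_octamer_f <- function(intron_seqs, L, bin_width) {
  n_bins <- L %/% bin_width
  counts <- matrix(0, nrow = 4^8, ncol = n_bins)
  for (s in intron_seqs) {
    len <- nchar(s)
    if (len < 8) next
    M <- min(L, len)
    tail <- substr(s, len - M + 1, len)
    for (j in 8:M) {
      e <- M - j
      oct <- substr(tail, j - 7, j)
      if (grepl("[^ACGT]", oct)) next
      idx <- oracle_oct_index(oct)
      bin <- e %/% bin_width + 1
      counts[idx, bin] <- counts[idx, bin] + 1
    }
  }
  sweep(counts + 1, 2, colSums(counts) + 4^8, "/")
}

oracle_oct_index <- function(oct) {
  codes <- match(strsplit(oct, "")[[1]], c("A", "C", "G", "T")) - 1
  sum(codes * 4^(7:0)) + 1
}

# independent recomputation of the two-component candidate score from
# strings and the model tables
oracle_score <- function(heptamer, context, pwm, bg, q, lambda) {
  b <- strsplit(heptamer, "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  s <- 0
  for (k in 1:7) s <- s + unname(log2(unclass(pwm)[k, idx[k]] / q[idx[k]]))
  if (lambda != 0) {
    d <- nchar(context)
    if (d >= 8) {
      for (i in 8:d) {
        oct <- substr(context, i - 7, i)
        if (grepl("[^ACGT]", oct)) next
        e <- d - i
        if (e > bg$L - 8) next
        o <- oracle_oct_index(oct)
        bin <- e %/% bg$bin_width + 1
        s <- s + lambda * unname(log2(bg$f[o, bin] / bg$g[o]))
      }
    }
  }
  s
}

# per-base classifier: which bases of the chromosome fall in the union of gr
oracle_base_mask <- function(gr, chrom, len) {
  mask <- rep(FALSE, len)
  gi <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (q in seq_along(gi)) {
    mask[GenomicRanges::start(gi)[q]:GenomicRanges::end(gi)[q]] <- TRUE
  }
  mask
}
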