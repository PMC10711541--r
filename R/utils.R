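DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# the two transversion partners of each base
TV_PARTNERS <- rbind(
  A = c("C", "T"),
  C = c("A", "G"),
  G = c("C", "T"),
  T = c("A", "G")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast char -> base code (A=1,C=2,G=3,T=4, everything else NA)
.base_code_table <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

base_codes <- function(s) .base_code_table[utf8ToInt(s)]

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Genome-wide base composition
#'
#' Frequencies of A, C, G, T over all non-N bases of the assembly.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @return named numeric vector of length 4 summing to 1.
#' @export
genome_base_freq <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(genome, DNA_BASES))
  counts / sum(counts)
}

# IUPAC-style consensus from a positions x ACGT frequency matrix.
# Uppercase base when a single base reaches `upper`; lowercase 'y'/'r' when a
# pyrimidine/purine pair jointly reaches `pair` with no single base dominant;
# 'n' otherwise.
consensus_from_freq <- function(freq, upper = 0.75, pair = 0.75) {
  stopifnot(ncol(freq) == 4)
  colnames(freq) <- DNA_BASES
  out <- character(nrow(freq))
  for (i in seq_len(nrow(freq))) {
    p <- freq[i, ]
    if (max(p) >= upper) {
      out[i] <- DNA_BASES[which.max(p)]
    } else if (p["C"] + p["T"] >= pair) {
      out[i] <- "y"
    } else if (p["A"] + p["G"] >= pair) {
      out[i] <- "r"
    } else {
      out[i] <- "n"
    }
  }
  paste(out, collapse = "")
}

# positions x ACGT frequency matrix from equal-length sequences
seq_freq_matrix <- function(seqs, len) {
  stopifnot(all(nchar(seqs) == len))
  mat <- matrix(0, nrow = len, ncol = 4, dimnames = list(NULL, DNA_BASES))
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  for (k in seq_len(len)) {
    tab <- table(factor(chars[, k], levels = DNA_BASES))
    mat[k, ] <- as.numeric(tab)
  }
  mat / length(seqs)
}

# strand-aware sequence extraction from a DNAStringSet genome: minus-strand
# ranges are reverse-complemented (transcript orientation)
extract_ranges <- function(genome, gr) {
  chr <- as.character(GenomicRanges::seqnames(gr))
  out <- Biostrings::DNAStringSet(rep("", length(gr)))
  for (cn in unique(chr)) {
    i <- which(chr == cn)
    out[i] <- Biostrings::extractAt(
      genome[[cn]],
      IRanges::IRanges(GenomicRanges::start(gr)[i],
                       GenomicRanges::end(gr)[i]))
  }
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])
  out
}

# lexicographic octamer index (1-based), matching the column order of
# Biostrings::oligonucleotideFrequency; NA if any base is not A/C/G/T
oct_index <- function(s) {
  codes <- base_codes(s)
  if (length(codes) != 8 || anyNA(codes)) return(NA_integer_)
  sum((codes - 1L) * 4L^(7:0)) + 1L
}
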