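#' Train a branch-point position weight matrix
#'
#' Column-wise base frequencies over a set of heptamers with pseudocount
#' `pseudocount` added per base per position:
#' \eqn{p_{k,b} = (c_{k,b} + 1) / (n + 4)} for the default pseudocount of 1.
#' With `heptamers = NULL` the packaged default PWM is returned; its IUPAC
#' consensus is `nnyTrAy` (conserved T at position 4 and branch-point A at
#' position 6).
#'
#' @param heptamers character vector of 7-base sequences over A/C/G/T, or
#'   NULL for the shipped default.
#' @param pseudocount pseudocount per base per position.
#' @return 7 x 4 probability matrix of class `bps_pwm` (columns A, C, G, T),
#'   with attributes `pseudocount` and `provenance`.
#' @export
train_pwm <- function(heptamers = NULL, pseudocount = 1) {
  if (is.null(heptamers)) return(default_pwm())
  if (!length(heptamers)) stop("no heptamers supplied")
  if (any(nchar(heptamers) != 7))
    stop("heptamers must have length 7")
  if (any(!grepl("^[ACGT]+$", heptamers)))
    stop("heptamers must contain only A/C/G/T")
  n <- length(heptamers)
  counts <- seq_freq_matrix(heptamers, 7L) * n
  pwm <- (counts + pseudocount) / (n + 4 * pseudocount)
  structure(pwm, class = "bps_pwm", pseudocount = pseudocount,
            provenance = sprintf("trained on %d heptamers", n))
}

#' The packaged default branch-point PWM
#'
#' Loaded from `extdata/default_bps_pwm.tsv`; a degenerate matrix with
#' consensus `nnyTrAy`.
#'
#' @return a `bps_pwm`.
#' @export
default_pwm <- function() {
  path <- system.file("extdata", "default_bps_pwm.tsv", package = "bpscan")
  read_pwm(path, provenance = "bpscan default (nnyTrAy)")
}

#' Read a PWM from a 7 x 4 TSV (columns A, C, G, T)
#' @param path TSV file with header A C G T and 7 probability rows.
#' @param provenance label stored on the object.
#' @return a `bps_pwm`.
#' @export
read_pwm <- function(path, provenance = path) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t"))
  if (nrow(m) != 7 || ncol(m) != 4 || !identical(colnames(m), DNA_BASES))
    stop("PWM file must have 7 rows and columns A, C, G, T")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  if (any(m <= 0)) stop("PWM entries must be positive")
  structure(m, class = "bps_pwm", pseudocount = NA_real_,
            provenance = provenance)
}

#' Write a PWM as TSV
#' @param pwm a `bps_pwm` or 7 x 4 matrix.
#' @param path output path.
#' @export
write_pwm <- function(pwm, path) {
  write.table(format(unclass(pwm), digits = 10), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' IUPAC-style consensus of a PWM
#' @param pwm a `bps_pwm`.
#' @param upper frequency above which a single base is written uppercase.
#' @param pair joint frequency above which a purine/pyrimidine pair is
#'   written `r`/`y`.
#' @return 7-character consensus string.
#' @export
pwm_consensus <- function(pwm, upper = 0.75, pair = 0.75) {
  consensus_from_freq(unclass(pwm), upper = upper, pair = pair)
}

#' @export
print.bps_pwm <- function(x, ...) {
  cat("bps_pwm (", attr(x, "provenance"), "), consensus ",
      pwm_consensus(x), "\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Estimate the distance-binned octanucleotide background model
#'
#' For each intron, the last `min(L, intron length)` transcript-orientation
#' bases contribute sliding octamers, assigned to a distance bin by the
#' distance of the octamer's 3'-most base to the 3' splice site (bins of
#' `bin_width` bases tiling \[0, L)). Octamers containing N are skipped. A
#' pseudocount of 1 per octamer per bin is added. The genome-wide octamer
#' table g is estimated from all intronic sequence with the same
#' pseudocount.
#'
#' @param introns GRanges of introns.
#' @param genome the genome assembly.
#' @param L window length (bases upstream of the 3' splice site) used for
#'   estimation; must be a multiple of `bin_width`.
#' @param bin_width distance bin width in bases (>= 8).
#' @return list of class `octamer_bg` with elements `f` (4^8 x n_bins
#'   frequency matrix), `g` (4^8 frequencies), `lr` (log2(f/g), precomputed),
#'   `L`, `bin_width`, `n_introns`.
#' @export
estimate_octamer_background <- function(introns, genome, L = 150L,
                                        bin_width = 10L) {
  if (bin_width < 8) stop("bin_width must be >= 8")
  if (L < bin_width) stop("L must be >= bin_width")
  if (L %% bin_width != 0) stop("L must be a multiple of bin_width")
  seqs <- extract_ranges(genome, introns)
  w <- Biostrings::width(seqs)
  usable <- seqs[w >= 8]
  if (!length(usable)) stop("no usable introns (length >= 8)")

  n_oct <- 4L^8L
  n_bins <- L %/% bin_width
  counts <- matrix(0, nrow = n_oct, ncol = n_bins)
  wu <- Biostrings::width(usable)
  for (b in seq_len(n_bins) - 1L) {
    e1 <- b * bin_width
    if (e1 > L - 8L) next
    sel <- which(wu - 8L >= e1)
    if (!length(sel)) next
    # octamers must lie fully inside the last min(L, intron length) bases
    e2 <- pmin(e1 + bin_width - 1L, wu[sel] - 8L, L - 8L)
    sub <- Biostrings::subseq(usable[sel],
                              start = wu[sel] - e2 - 7L,
                              end = wu[sel] - e1)
    counts[, b + 1L] <- colSums(Biostrings::oligonucleotideFrequency(sub, 8L))
  }
  f <- sweep(counts + 1, 2, colSums(counts) + n_oct, "/")

  gc <- colSums(Biostrings::oligonucleotideFrequency(usable, 8L))
  g <- (gc + 1) / (sum(gc) + n_oct)

  out <- list(f = f, g = g, lr = log2(f / g), L = as.integer(L),
              bin_width = as.integer(bin_width), n_introns = length(usable))
  class(out) <- "octamer_bg"
  out
}

#' @export
print.octamer_bg <- function(x, ...) {
  cat("octamer_bg: L =", x$L, "bin_width =", x$bin_width,
      "bins =", ncol(x$f), "introns =", x$n_introns, "\n")
  invisible(x)
}

#' Score one branch-point candidate
#'
#' Two-component log-odds in bits:
#' the PWM component \eqn{\sum_{k=1}^{7} \log_2(PWM_{k,b_k}/q_{b_k})} plus
#' `lambda` times the octanucleotide context component
#' \eqn{\sum_o \log_2(f_{bin(d_o)}(o)/g(o))} summed over sliding octamers of
#' the context (the transcript-orientation sequence from the base after the
#' branch point to the 3' splice site), each assigned to the distance bin of
#' its 3'-most base. Octamers containing N, or beyond the background
#' window L, are skipped.
#'
#' @param heptamer 7-base candidate (branch point at position 6).
#' @param context sequence from the base after the branch point to the 3'
#'   splice site ("" for none).
#' @param pwm a `bps_pwm`.
#' @param bg an `octamer_bg` (may be NULL when `lambda = 0`).
#' @param q genome base frequencies (named A/C/G/T vector).
#' @param lambda weight of the octamer component.
#' @return score in bits, or NA if the heptamer contains N.
#' @export
score_candidate <- function(heptamer, context = "", pwm, bg = NULL, q,
                            lambda = 1) {
  if (nchar(heptamer) != 7) stop("heptamer must have 7 bases")
  codes <- base_codes(heptamer)
  if (anyNA(codes)) return(NA_real_)
  pwm_part <- sum(log2(unclass(pwm)[cbind(1:7, codes)] / q[codes]))
  if (lambda == 0) return(pwm_part)
  if (is.null(bg)) stop("octamer background required when lambda != 0")
  d <- nchar(context)
  oct_part <- 0
  if (d >= 8) {
    for (i in 8:d) {
      e <- d - i
      if (e > bg$L - 8) next
      o <- oct_index(substr(context, i - 7L, i))
      if (is.na(o)) next
      oct_part <- oct_part + bg$lr[o, e %/% bg$bin_width + 1L]
    }
  }
  pwm_part + lambda * oct_part
}
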