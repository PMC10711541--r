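#' Predict the most probable branch point per intron
#'
#' Scores every candidate branch-point offset `d` (distance from the branch
#' point to the 3' splice site, in transcript orientation) in
#' `[d_min, min(d_max, intron length - donor_guard)]` with the two-component
#' log-odds of [score_candidate()] and returns the maximum-score candidate
#' per intron. Ties are broken toward the 3' splice site (smaller `d`).
#' Candidates whose heptamer contains N are skipped; introns with no valid
#' candidate are reported as unpredicted (listed in the `"unpredicted"`
#' attribute), not errors. The heptamer's branch point is its 6th base.
#'
#' @param introns GRanges of introns (from [derive_introns()]).
#' @param genome the genome assembly.
#' @param pwm a `bps_pwm`.
#' @param bg an `octamer_bg`; required unless `lambda = 0`.
#' @param lambda weight of the octamer context component (default 1).
#' @param d_min,d_max search range of branch point to 3' splice site
#'   distances (defaults 9 and 150).
#' @param donor_guard minimum number of intron bases that must remain
#'   between the intron 5' end and the heptamer (default 8, keeping the
#'   heptamer clear of the donor dinucleotide).
#' @return data.frame of class `bps_predictions` with columns `intron_id`,
#'   `chrom`, `strand`, `intron_start`, `intron_end`, `bp_pos` (1-based
#'   genomic, forward strand), `distance`, `heptamer` (transcript
#'   orientation), `score` (bits).
#' @export
predict_branch_points <- function(introns, genome, pwm, bg = NULL,
                                  lambda = 1, d_min = 9L, d_max = 150L,
                                  donor_guard = 8L) {
  if (lambda != 0 && is.null(bg))
    stop("octamer background required when lambda != 0")
  if (d_min < 1) stop("d_min must be >= 1")
  if (d_max < d_min) stop("d_max must be >= d_min")
  if (!length(introns)) {
    out <- .empty_predictions()
    attr(out, "unpredicted") <- character(0)
    return(out)
  }

  q <- genome_base_freq(genome)
  lpwm <- log2(unclass(pwm)) -
    matrix(log2(q), nrow = 7, ncol = 4, byrow = TRUE)

  len <- GenomicRanges::width(introns)
  tails <- extract_ranges(
    genome,
    GenomicRanges::resize(introns, width = pmin(len, d_max + 6L), fix = "end"))
  tail_chr <- as.character(tails)

  chrom <- as.character(GenomicRanges::seqnames(introns))
  strand <- as.character(GenomicRanges::strand(introns))
  istart <- GenomicRanges::start(introns)
  iend <- GenomicRanges::end(introns)
  iid <- S4Vectors::mcols(introns)$intron_id %||%
    paste0(chrom, ":", istart, "-", iend, ":", strand)

  n <- length(introns)
  res_d <- integer(n); res_score <- numeric(n); res_hept <- character(n)
  ok <- logical(n)
  pow <- 4L^(7:0)

  for (i in seq_len(n)) {
    K <- nchar(tail_chr[i])
    d_hi <- min(d_max, len[i] - donor_guard)
    if (d_hi < d_min) next
    ds <- d_min:d_hi
    codes <- base_codes(tail_chr[i])

    # PWM component for every candidate: heptamer at tail positions
    # (K - d - 5) .. (K - d + 1)
    h0 <- K - ds - 5L
    sc <- numeric(length(ds))
    for (k in 0:6) {
      ck <- codes[h0 + k]
      v <- lpwm[k + 1L, ]
      sc <- sc + ifelse(is.na(ck), NA_real_, v[ifelse(is.na(ck), 1L, ck)])
    }

    # octamer context component via cumulative sums over end-distance
    if (lambda != 0 && K >= 8L) {
      cvec <- codes - 1L
      m <- K - 7L
      idx <- rep(0L, m)
      for (t in 0:7) idx <- idx + cvec[(1L + t):(m + t)] * pow[t + 1L]
      # idx[j] is the octamer ending at tail position j + 7; its distance to
      # the 3' splice site is e = K - (j + 7)
      e <- K - (seq_len(m) + 7L)
      val <- numeric(m)
      good <- !is.na(idx) & e <= bg$L - 8L
      val[good] <- bg$lr[cbind(idx[good] + 1L, e[good] %/% bg$bin_width + 1L)]
      # order by ascending e: v_e for e = 0 .. K-8
      v_e <- rev(val)
      cums <- cumsum(v_e)
      oct <- ifelse(ds >= 8L, cums[pmax(ds - 7L, 1L)], 0)
      sc <- sc + lambda * oct
    }

    if (all(is.na(sc))) next
    best <- which(sc == max(sc, na.rm = TRUE))[1]  # first = smallest d
    res_d[i] <- ds[best]
    res_score[i] <- sc[best]
    res_hept[i] <- substr(tail_chr[i], h0[best], h0[best] + 6L)
    ok[i] <- TRUE
  }

  bp_pos <- ifelse(strand == "+", iend - res_d, istart + res_d)
  out <- data.frame(
    intron_id = iid[ok], chrom = chrom[ok], strand = strand[ok],
    intron_start = istart[ok], intron_end = iend[ok],
    bp_pos = as.integer(bp_pos[ok]), distance = res_d[ok],
    heptamer = res_hept[ok], score = res_score[ok],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bps_predictions", "data.frame")
  attr(out, "unpredicted") <- iid[!ok]
  out
}

.empty_predictions <- function() {
  out <- data.frame(intron_id = character(0), chrom = character(0),
                    strand = character(0), intron_start = integer(0),
                    intron_end = integer(0), bp_pos = integer(0),
                    distance = integer(0), heptamer = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("bps_predictions", "data.frame")
  out
}

#' Genomic coordinates of heptamer positions
#'
#' Position `k` (1..7) of each predicted heptamer on the forward strand;
#' position 6 is the branch point.
#'
#' @param predictions a `bps_predictions` data.frame.
#' @param k heptamer position 1..7.
#' @return integer vector of 1-based genomic positions.
#' @export
heptamer_positions <- function(predictions, k) {
  stopifnot(k >= 1, k <= 7)
  k <- as.integer(k)
  ifelse(predictions$strand == "+",
         predictions$bp_pos + (k - 6L),
         predictions$bp_pos - (k - 6L))
}

#' Consensus sequence of predicted heptamers
#'
#' Per position: uppercase base if its frequency reaches `upper`; lowercase
#' `y` (C/T) or `r` (A/G) if the pair jointly reaches `pair` with no single
#' dominant base; `n` otherwise.
#'
#' @param x a `bps_predictions` data.frame or character vector of heptamers.
#' @param upper,pair thresholds (defaults 0.75).
#' @return 7-character consensus string.
#' @export
consensus_sequence <- function(x, upper = 0.75, pair = 0.75) {
  h <- if (is.data.frame(x)) x$heptamer else x
  if (!length(h)) stop("no predictions to summarize")
  consensus_from_freq(seq_freq_matrix(h, 7L), upper = upper, pair = pair)
}

#' Fraction of heptamers with the canonical TnA motif
#'
#' T at position 4 and A at position 6 (the branch point), any base at 5.
#'
#' @param x a `bps_predictions` data.frame or character vector of heptamers.
#' @return fraction in \[0, 1\].
#' @export
canonical_tna_fraction <- function(x) {
  h <- if (is.data.frame(x)) x$heptamer else x
  if (!length(h)) stop("no predictions to summarize")
  mean(substr(h, 4, 4) == "T" & substr(h, 6, 6) == "A")
}

#' Summary of branch point to 3' splice site distances
#'
#' @param x a `bps_predictions` data.frame or integer vector of distances.
#' @return list of class `bps_distance_summary`: `median`, `q2.5`, `q97.5`,
#'   and `histogram` (a table of counts per distance).
#' @export
distance_summary <- function(x) {
  d <- if (is.data.frame(x)) x$distance else x
  if (!length(d)) stop("no predictions to summarize")
  out <- list(median = median(d),
              q2.5 = unname(quantile(d, 0.025)),
              q97.5 = unname(quantile(d, 0.975)),
              histogram = table(d))
  class(out) <- "bps_distance_summary"
  out
}

#' @export
print.bps_distance_summary <- function(x, ...) {
  cat("branch point to 3'SS distance: median", x$median,
      " [2.5%:", x$q2.5, ", 97.5%:", x$q97.5, "]\n")
  invisible(x)
}

#' Write predictions as TSV
#' @param predictions a `bps_predictions` data.frame.
#' @param path output TSV.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
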