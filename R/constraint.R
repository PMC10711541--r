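#' Relative variability of genomic feature classes
#'
#' For each feature class, counts the variants falling in the union of its
#' intervals (each variant counted once per class, even when it overlaps two
#' intervals of the class; a variant may count in several classes), divides
#' by the class's effective (non-N) length to get a density per 100 bp, and
#' normalizes by the genome-wide density. A `genome_wide` row (relative
#' variability exactly 1) is appended. Classes with zero effective length
#' are reported with NA values rather than raising an error.
#'
#' @param catalog a `variant_catalog`.
#' @param features a `feature_catalog` (or named list of GRanges).
#' @param genome the genome assembly.
#' @param classes class names to report (default: all in `features`).
#' @return data.frame of class `variability_table`: `feature`, `n_variants`,
#'   `effective_length`, `density` (per 100 bp), `relative_variability`.
#' @export
feature_variability <- function(catalog, features, genome,
                                classes = names(features)) {
  gd <- genome_wide_density(catalog, genome)
  vgr <- catalog_granges(catalog)
  rows <- lapply(classes, function(cl) {
    r <- GenomicRanges::reduce(features[[cl]], ignore.strand = TRUE)
    eff <- effective_length(r, genome)
    if (eff == 0) {
      return(data.frame(feature = cl, n_variants = NA_integer_,
                        effective_length = 0L, density = NA_real_,
                        relative_variability = NA_real_))
    }
    nv <- sum(GenomicRanges::countOverlaps(vgr, r) > 0)
    dens <- 100 * nv / eff
    data.frame(feature = cl, n_variants = nv, effective_length = eff,
               density = dens, relative_variability = dens / gd)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    feature = "genome_wide", n_variants = nrow(catalog),
    effective_length = effective_genome_length(genome), density = gd,
    relative_variability = gd / gd))
  rownames(out) <- NULL
  class(out) <- c("variability_table", "data.frame")
  out
}

# shared site-level profile machinery: for each offset, a set of genomic
# positions (one per intron/prediction); relative variability is the
# fraction of valid sites overlapping >= 1 SNV, per 100 sites, divided by
# the genome-wide density
.profile_offsets <- function(catalog, genome, pos_by_offset, context) {
  gd <- genome_wide_density(catalog, genome)
  vkey <- unique(paste(catalog$chrom, catalog$pos))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  rows <- lapply(names(pos_by_offset), function(lab) {
    p <- pos_by_offset[[lab]]
    inb <- p$pos >= 1L & p$pos <= clen[p$chrom]
    p <- p[inb, , drop = FALSE]
    if (nrow(p)) {
      base <- character(nrow(p))
      for (cn in unique(p$chrom)) {
        i <- p$chrom == cn
        base[i] <- strsplit(as.character(genome[[cn]]), "")[[1]][p$pos[i]]
      }
      p <- p[base %in% DNA_BASES, , drop = FALSE]
    }
    n_tot <- nrow(p)
    n_var <- if (n_tot) sum(unique(paste(p$chrom, p$pos)) %in% vkey) else 0L
    # site-level: distinct genomic sites, each variable or not
    n_tot <- length(unique(paste(p$chrom, p$pos)))
    rel <- if (n_tot) (100 * n_var / n_tot) / gd else NA_real_
    data.frame(context = context, offset = lab, n_variable_sites = n_var,
               n_total_sites = n_tot, relative_variability = rel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("position_profile", "data.frame")
  out
}

#' Nucleotide-wise constraint profile around splice sites
#'
#' For each transcript-orientation offset in windows around the donor and
#' acceptor junctions (default 3 exonic + 8 intronic bases each), the
#' fraction of sites at that offset overlapping at least one SNV, per 100
#' sites, normalized by the genome-wide density. Intronic donor offsets are
#' labelled `+1..+8` (first intron bases), exonic donor offsets `-3..-1`;
#' acceptor offsets `-8..-1` (last intron bases) and `+1..+3` (first exonic
#' bases downstream). Sites falling on N or outside the chromosome are
#' excluded from that offset's denominator.
#'
#' @param catalog a `variant_catalog`.
#' @param introns GRanges of introns.
#' @param genome the genome assembly.
#' @param exonic_flank,intronic_flank window sizes in bases (>= 2 intronic).
#' @return data.frame of class `position_profile` with contexts `donor` and
#'   `acceptor`.
#' @export
splice_site_profile <- function(catalog, introns, genome, exonic_flank = 3L,
                                intronic_flank = 8L) {
  if (!length(introns)) stop("no introns supplied")
  if (intronic_flank < 2) stop("intronic_flank must be >= 2")
  chrom <- as.character(GenomicRanges::seqnames(introns))
  strand <- as.character(GenomicRanges::strand(introns))
  s <- GenomicRanges::start(introns)
  e <- GenomicRanges::end(introns)
  sgn <- ifelse(strand == "+", 1L, -1L)
  # transcript-orientation first intron base
  first <- ifelse(strand == "+", s, e)
  last <- ifelse(strand == "+", e, s)

  donor <- list()
  for (k in seq_len(exonic_flank)) {
    off <- -(exonic_flank - k + 1L)  # ... -3, -2, -1
    donor[[as.character(off)]] <-
      data.frame(chrom = chrom, pos = first + sgn * off)
  }
  for (k in seq_len(intronic_flank)) {
    donor[[paste0("+", k)]] <-
      data.frame(chrom = chrom, pos = first + sgn * (k - 1L))
  }
  acceptor <- list()
  for (k in seq_len(intronic_flank)) {
    off <- -(intronic_flank - k + 1L)  # -8 .. -1
    acceptor[[as.character(off)]] <-
      data.frame(chrom = chrom, pos = last + sgn * (off + 1L))
  }
  for (k in seq_len(exonic_flank)) {
    acceptor[[paste0("+", k)]] <-
      data.frame(chrom = chrom, pos = last + sgn * k)
  }

  rbind(.profile_offsets(catalog, genome, donor, "donor"),
        .profile_offsets(catalog, genome, acceptor, "acceptor"))
}

#' Nucleotide-wise constraint profile over predicted BPS heptamers
#'
#' For each heptamer position 1..7 (and optional flanking offsets), the
#' fraction of predictions whose genomic base at that position overlaps at
#' least one SNV, normalized as in [splice_site_profile()]. Counting is
#' site-level: a position either overlaps >= 1 SNV or it does not.
#'
#' @param catalog a `variant_catalog`.
#' @param predictions a `bps_predictions` data.frame.
#' @param genome the genome assembly.
#' @param flank number of flanking bases on each side of the heptamer
#'   (offsets labelled `-k` and `+k`), default 0.
#' @return data.frame of class `position_profile` with context `bps`.
#' @export
bps_profile <- function(catalog, predictions, genome, flank = 0L) {
  if (!nrow(predictions)) stop("no predictions supplied")
  sgn <- ifelse(predictions$strand == "+", 1L, -1L)
  offs <- list()
  if (flank > 0) {
    for (k in rev(seq_len(flank))) {
      offs[[paste0("-", k)]] <- data.frame(
        chrom = predictions$chrom,
        pos = heptamer_positions(predictions, 1) - sgn * k)
    }
  }
  for (k in 1:7) {
    offs[[as.character(k)]] <- data.frame(
      chrom = predictions$chrom, pos = heptamer_positions(predictions, k))
  }
  if (flank > 0) {
    for (k in seq_len(flank)) {
      offs[[paste0("+", k)]] <- data.frame(
        chrom = predictions$chrom,
        pos = heptamer_positions(predictions, 7) + sgn * k)
    }
  }
  .profile_offsets(catalog, genome, offs, "bps")
}

#' Fisher's exact comparison of two profile positions
#'
#' Builds the 2x2 table of variable/invariant sites at two positions of a
#' profile and applies the two-sided Fisher's exact test (point-probability
#' rule: the p-value sums the probabilities of all tables with fixed
#' margins no more probable than the observed one), together with the
#' Bonferroni-adjusted significance threshold `alpha / m_tests`.
#'
#' @param profile a `position_profile` (e.g. from [bps_profile()]).
#' @param pos_a,pos_b offset labels to compare (defaults `"4"` and `"6"`,
#'   the conserved T and the branch point A).
#' @param alpha family-wise significance level.
#' @param m_tests number of tests for the Bonferroni correction.
#' @return list of class `position_comparison`: `table`, `odds_ratio`,
#'   `p_value`, `threshold`, `significant`.
#' @export
compare_positions <- function(profile, pos_a = "4", pos_b = "6",
                              alpha = 0.05, m_tests = 1L) {
  pos_a <- as.character(pos_a); pos_b <- as.character(pos_b)
  ra <- profile[profile$offset == pos_a, ]
  rb <- profile[profile$offset == pos_b, ]
  if (nrow(ra) != 1 || nrow(rb) != 1)
    stop("positions not found in profile: ", pos_a, ", ", pos_b)
  if (ra$n_total_sites == 0 || rb$n_total_sites == 0)
    stop("zero site denominators")
  if (ra$n_total_sites != rb$n_total_sites)
    warning("unequal denominators at the two positions")
  tab <- matrix(c(ra$n_variable_sites, ra$n_total_sites - ra$n_variable_sites,
                  rb$n_variable_sites, rb$n_total_sites - rb$n_variable_sites),
                nrow = 2, byrow = TRUE,
                dimnames = list(position = c(pos_a, pos_b),
                                sites = c("variable", "invariant")))
  ft <- fisher.test(tab)
  thr <- bonferroni_threshold(alpha, m_tests)
  out <- list(positions = c(pos_a, pos_b), table = tab,
              odds_ratio = unname(ft$estimate), p_value = ft$p.value,
              alpha = alpha, m_tests = m_tests, threshold = thr,
              significant = ft$p.value < thr)
  class(out) <- "position_comparison"
  out
}

#' @export
print.position_comparison <- function(x, ...) {
  cat(sprintf(
    "positions %s vs %s: OR = %.3f, two-sided Fisher P = %.3g %s Bonferroni threshold %.3g (alpha %.3g / %d tests)\n",
    x$positions[1], x$positions[2], x$odds_ratio, x$p_value,
    if (x$significant) "<" else ">=", x$threshold, x$alpha, x$m_tests))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m_tests number of tests (>= 1).
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(alpha, m_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m_tests < 1) stop("m_tests must be >= 1")
  alpha / m_tests
}
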