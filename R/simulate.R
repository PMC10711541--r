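#' Default branch-point offset distribution
#'
#' Discrete distribution of the distance (in bases) between the branch point
#' and the 3' splice site, supported on 9..150 with its mode near 26, a
#' discretized gamma shape typical of metazoan branch point placement.
#'
#' @param distances integer support (default 9:150).
#' @param shape,scale gamma parameters of the underlying continuous density,
#'   applied to `distance - 8`.
#' @return named numeric vector of probabilities (names = distances).
#' @export
default_bp_offsets <- function(distances = 9:150, shape = 6, scale = 3.6) {
  w <- stats::dgamma(distances - 8, shape = shape, scale = scale)
  p <- w / sum(w)
  names(p) <- distances
  p
}

#' Default generative branch-point PWM for simulation
#'
#' A high information content (about 13 bit) 7 x 4 probability matrix around
#' the canonical TACTAAC branch-point motif: at each position the consensus
#' base has probability 0.94 and the other three 0.02, giving a conserved T
#' at position 4 and the branch point A at position 6. The sharpness is a
#' simulation choice: planted heptamers must be identifiable against random
#' intronic background for recovery experiments to be meaningful; real BPS
#' are more degenerate (see the package vignette).
#'
#' @param consensus 7-base consensus the matrix concentrates on.
#' @param dominant probability of the consensus base at each position.
#' @return 7 x 4 matrix (columns A, C, G, T), rows summing to 1.
#' @export
default_generative_pwm <- function(consensus = "TACTAAC", dominant = 0.94) {
  stopifnot(nchar(consensus) == 7, dominant > 0.25, dominant <= 1)
  m <- matrix((1 - dominant) / 3, nrow = 7, ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(1:7, base_codes(consensus))] <- dominant
  m
}

#' Simulation configuration
#'
#' Parameters of the synthetic genome / annotation / variant generator.
#' Defaults describe a 2 Mb two-chromosome genome with ~340 protein-coding
#' genes (~1000 introns), one planted branch point heptamer per intron, a
#' genome-wide mutation rate of 3 SNVs per 100 bp, transitions at
#' probability 0.7 (Ti/Tv 2.33), and per-feature constraint multipliers
#' ordered splice site < branch point positions 4/6 < coding < UTR < intron
#' < intergenic.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param n_genes total number of non-overlapping genes.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_length integer range of exon lengths (bases).
#' @param intron_length integer range of intron lengths (bases); the minimum
#'   must accommodate the largest drawable branch-point offset plus the
#'   heptamer and donor clearance.
#' @param minus_strand_fraction probability a gene lies on the minus strand.
#' @param bp_offset_distribution named probability vector over branch point
#'   to 3' splice site distances; support must lie within \[9, 150\].
#' @param generative_pwm 7 x 4 probability matrix used to draw planted
#'   heptamers (rows sum to 1; strong T at row 4 and A at row 6 by default).
#' @param base_mutation_rate per-base mutation probability before feature
#'   multipliers.
#' @param transition_probability probability that a simulated SNV is a
#'   transition.
#' @param constraint_multipliers named multipliers on `base_mutation_rate`
#'   for classes `splice_site`, `bps_bp` (heptamer positions 4 and 6),
#'   `bps_other`, `coding`, `utr`, `intron`, `intergenic`.
#' @param n_fraction fraction of the genome masked as N (placed in
#'   intergenic sequence only).
#' @param n_studies number of submitter labels assigned to simulated SNVs.
#' @param utr5_length,utr3_length nominal UTR lengths in transcript bases.
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1000000L,
                       n_genes = 340L,
                       exons_per_gene = c(3L, 6L),
                       exon_length = c(120L, 300L),
                       intron_length = c(200L, 2000L),
                       minus_strand_fraction = 0.5,
                       bp_offset_distribution = default_bp_offsets(),
                       generative_pwm = default_generative_pwm(),
                       base_mutation_rate = 0.03,
                       transition_probability = 0.7,
                       constraint_multipliers = c(
                         splice_site = 0.02, bps_bp = 0.12, bps_other = 0.85,
                         coding = 0.35, utr = 0.7, intron = 0.9,
                         intergenic = 1.15
                       ),
                       n_fraction = 0.01,
                       n_studies = 3L,
                       utr5_length = 60L,
                       utr3_length = 120L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    minus_strand_fraction = minus_strand_fraction,
    bp_offset_distribution = bp_offset_distribution,
    generative_pwm = generative_pwm,
    base_mutation_rate = base_mutation_rate,
    transition_probability = transition_probability,
    constraint_multipliers = constraint_multipliers,
    n_fraction = n_fraction,
    n_studies = as.integer(n_studies),
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pwm <- cfg$generative_pwm
  if (!is.matrix(pwm) || nrow(pwm) != 7 || ncol(pwm) != 4)
    stop("generative_pwm must be a 7 x 4 matrix")
  if (any(abs(rowSums(pwm) - 1) > 1e-9))
    stop("generative_pwm rows must each sum to 1 (tolerance 1e-9)")
  if (any(pwm < 0)) stop("generative_pwm entries must be non-negative")

  p <- cfg$bp_offset_distribution
  d <- as.integer(names(p))
  if (anyNA(d)) stop("bp_offset_distribution must have integer distance names")
  if (any(d < 9) || any(d > 150))
    stop("bp_offset_distribution support must lie within [9, 150]; found ",
         min(d), "..", max(d))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("bp_offset_distribution must be a probability vector summing to 1")

  if (any(cfg$constraint_multipliers < 0))
    stop("constraint_multipliers must be >= 0")
  needed <- c("splice_site", "bps_bp", "bps_other", "coding", "utr",
              "intron", "intergenic")
  missing <- setdiff(needed, names(cfg$constraint_multipliers))
  if (length(missing))
    stop("constraint_multipliers missing classes: ",
         paste(missing, collapse = ", "))

  # every drawable offset must admit the heptamer inside the shortest intron,
  # clear of the donor dinucleotide: length >= offset + 8
  dmax <- max(d[p > 0])
  if (cfg$intron_length[1] < dmax + 8)
    stop("infeasible config: minimum intron length ", cfg$intron_length[1],
         " cannot accommodate a branch point offset of ", dmax,
         " (requires at least ", dmax + 8, " bases)")

  if (cfg$base_mutation_rate < 0 || cfg$base_mutation_rate > 1)
    stop("base_mutation_rate must be in [0, 1]")
  if (cfg$transition_probability < 0 || cfg$transition_probability > 1)
    stop("transition_probability must be in [0, 1]")
  if (cfg$n_fraction < 0 || cfg$n_fraction >= 1)
    stop("n_fraction must be in [0, 1)")
  if (cfg$exon_length[1] < 10) stop("exon_length minimum too small (< 10)")
  if (cfg$exons_per_gene[1] < 2)
    stop("exons_per_gene minimum must be >= 2 so that introns exist")
  invisible(cfg)
}

# draw an integer from an inclusive range
.draw_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a genome with annotated genes and planted branch points
#'
#' Places non-overlapping single-transcript protein-coding genes on random
#' chromosomes, writes one heptamer drawn from the generative PWM into each
#' intron at a drawn branch-point offset (reverse-complemented for
#' minus-strand genes), masks a fraction of intergenic sequence as N, and
#' returns the genome, an Ensembl-style annotation, and the planted truth.
#'
#' @param config a [sim_config()].
#' @return list of class `bps_simulation` with elements `genome`
#'   (DNAStringSet), `annotation` (GRanges with GTF-style columns), `truth`
#'   (data.frame: chrom, intron_start, intron_end, strand, gene_id,
#'   bp_pos, distance, heptamer), and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  clen <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(n_chrom))

  # per-gene structure
  n_genes <- config$n_genes
  n_ex <- .draw_range(n_genes, config$exons_per_gene)
  gene_struct <- vector("list", n_genes)
  glen <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    ex <- .draw_range(n_ex[i], config$exon_length)
    it <- .draw_range(n_ex[i] - 1L, config$intron_length)
    gene_struct[[i]] <- list(exon_len = ex, intron_len = it)
    glen[i] <- sum(ex) + sum(it)
  }
  strand <- ifelse(runif(n_genes) < config$minus_strand_fraction, "-", "+")

  # greedy assignment to the chromosome with most remaining capacity
  remaining <- rep(clen, n_chrom)
  chrom_of <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    j <- which.max(remaining)
    if (remaining[j] < glen[i] + 2L)
      stop("infeasible config: total gene length exceeds genome capacity")
    chrom_of[i] <- j
    remaining[j] <- remaining[j] - glen[i] - 1L
  }

  # random base sequence per chromosome
  seq_chars <- lapply(seq_len(n_chrom), function(j)
    sample(DNA_BASES, clen, replace = TRUE))

  # gene placement: random gap composition per chromosome
  gene_start <- integer(n_genes)
  for (j in seq_len(n_chrom)) {
    idx <- which(chrom_of == j)
    if (!length(idx)) next
    slack <- clen - sum(glen[idx]) - (length(idx) + 1L)
    if (slack < 0)
      stop("infeasible config: genes do not fit on chromosome ", chroms[j])
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, length(idx) + 1L))) + 1L
    starts <- cumsum(gaps[seq_along(idx)]) +
      cumsum(c(0L, glen[idx[-length(idx)]])) + 1L
    gene_start[idx] <- starts
  }

  # exon/intron genomic coordinates, planted heptamers, annotation records
  dists <- as.integer(names(config$bp_offset_distribution))
  dprob <- as.vector(config$bp_offset_distribution)
  pwm <- config$generative_pwm

  ann <- list()   # rows of the annotation
  truth <- list()
  for (i in seq_len(n_genes)) {
    st <- gene_struct[[i]]
    gid <- sprintf("gene%04d", i)
    tid <- paste0(gid, ".t1")
    chr <- chroms[chrom_of[i]]
    str <- strand[i]
    nex <- length(st$exon_len)

    ex_start <- integer(nex); ex_end <- integer(nex)
    pos <- gene_start[i]
    for (k in seq_len(nex)) {
      ex_start[k] <- pos
      ex_end[k] <- pos + st$exon_len[k] - 1L
      pos <- ex_end[k] + 1L
      if (k < nex) pos <- pos + st$intron_len[k]
    }
    gstart <- ex_start[1]; gend <- ex_end[nex]

    # plant one heptamer per intron
    for (k in seq_len(nex - 1L)) {
      s <- ex_end[k] + 1L
      e <- ex_start[k + 1L] - 1L
      d <- if (length(dists) == 1L) dists else sample(dists, 1L, prob = dprob)
      hept <- paste(vapply(1:7, function(r)
        sample(DNA_BASES, 1L, prob = pwm[r, ]), character(1)), collapse = "")
      if (str == "+") {
        bp <- e - d
        repl <- strsplit(hept, "")[[1]]
        seq_chars[[chrom_of[i]]][(bp - 5L):(bp + 1L)] <- repl
      } else {
        bp <- s + d
        repl <- strsplit(revcomp_chr(hept), "")[[1]]
        seq_chars[[chrom_of[i]]][(bp - 1L):(bp + 5L)] <- repl
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chr, intron_start = s, intron_end = e, strand = str,
        gene_id = gid, bp_pos = bp, distance = d, heptamer = hept,
        stringsAsFactors = FALSE)
    }

    # transcript-coordinate gene model: 5'UTR | CDS (multiple of 3) | 3'UTR
    tx_len <- sum(st$exon_len)
    u5 <- config$utr5_length; u3 <- config$utr3_length
    if (tx_len < u5 + u3 + 9L) {
      u5 <- max(3L, as.integer(tx_len * 0.15))
      u3 <- max(3L, as.integer(tx_len * 0.2))
    }
    cds_len <- tx_len - u5 - u3
    u3 <- u3 + cds_len %% 3L
    cds_len <- cds_len - cds_len %% 3L

    tx_feats <- rbind(
      data.frame(type = "five_prime_utr", from = 1L, to = u5),
      data.frame(type = "CDS", from = u5 + 1L, to = u5 + cds_len),
      data.frame(type = "start_codon", from = u5 + 1L, to = u5 + 3L),
      data.frame(type = "stop_codon", from = u5 + cds_len - 2L,
                 to = u5 + cds_len),
      data.frame(type = "three_prime_utr", from = u5 + cds_len + 1L,
                 to = tx_len)
    )

    add <- function(type, s0, e0) {
      ann[[length(ann) + 1L]] <<- data.frame(
        chrom = chr, start = s0, end = e0, strand = str, type = type,
        gene_id = gid, transcript_id = tid, stringsAsFactors = FALSE)
    }
    add("gene", gstart, gend)
    add("transcript", gstart, gend)
    for (k in seq_len(nex)) add("exon", ex_start[k], ex_end[k])
    for (r in seq_len(nrow(tx_feats))) {
      gi <- .tx_to_genomic(tx_feats$from[r], tx_feats$to[r],
                           ex_start, ex_end, str)
      for (q in seq_len(nrow(gi))) add(tx_feats$type[r], gi$start[q], gi$end[q])
    }
  }

  # N-masking of intergenic sequence only
  if (config$n_fraction > 0) {
    for (j in seq_len(n_chrom)) {
      in_gene <- rep(FALSE, clen)
      idx <- which(chrom_of == j)
      for (i in idx)
        in_gene[gene_start[i]:(gene_start[i] + glen[i] - 1L)] <- TRUE
      free <- which(!in_gene)
      n_mask <- min(length(free), round(config$n_fraction * clen))
      if (n_mask > 0)
        seq_chars[[j]][sample(free, n_mask)] <- "N"
    }
  }

  genome <- Biostrings::DNAStringSet(
    vapply(seq_chars, paste, character(1), collapse = ""))
  names(genome) <- chroms

  ann_df <- do.call(rbind, ann)
  annotation <- GenomicRanges::GRanges(
    seqnames = ann_df$chrom,
    ranges = IRanges::IRanges(ann_df$start, ann_df$end),
    strand = ann_df$strand,
    type = ann_df$type,
    source = "bpscan_sim",
    phase = ifelse(ann_df$type %in% c("CDS", "start_codon", "stop_codon"),
                   0L, NA_integer_),
    gene_id = ann_df$gene_id,
    transcript_id = ann_df$transcript_id,
    gene_biotype = "protein_coding",
    seqlengths = stats::setNames(rep(clen, n_chrom), chroms))

  truth_df <- do.call(rbind, truth)
  truth_df <- truth_df[order(truth_df$chrom, truth_df$intron_start), ]
  rownames(truth_df) <- NULL

  out <- list(genome = genome, annotation = annotation, truth = truth_df,
              config = config)
  class(out) <- "bps_simulation"
  out
}

# map a transcript-coordinate interval onto genomic intervals, splitting at
# exon boundaries; exons given left-to-right in genomic order
.tx_to_genomic <- function(from, to, ex_start, ex_end, strand) {
  ex_len <- ex_end - ex_start + 1L
  nex <- length(ex_len)
  # transcript order of exons
  ord <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
  offs <- cumsum(c(0L, ex_len[ord][-nex]))
  out <- list()
  for (q in seq_len(nex)) {
    k <- ord[q]
    a <- max(from, offs[q] + 1L)
    b <- min(to, offs[q] + ex_len[k])
    if (a > b) next
    if (strand == "+") {
      gs <- ex_start[k] + (a - offs[q] - 1L)
      ge <- ex_start[k] + (b - offs[q] - 1L)
    } else {
      ge <- ex_end[k] - (a - offs[q] - 1L)
      gs <- ex_end[k] - (b - offs[q] - 1L)
    }
    out[[length(out) + 1L]] <- data.frame(start = gs, end = ge)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' @export
print.bps_simulation <- function(x, ...) {
  cat("bps_simulation:", length(x$genome), "chromosome(s),",
      sum(Biostrings::width(x$genome)), "bases\n")
  cat("  genes:", length(unique(x$truth$gene_id)),
      " introns (planted BPS):", nrow(x$truth), "\n")
  invisible(x)
}

#' Simulate a variant catalogue over a simulated genome
#'
#' Each non-N base mutates independently with probability
#' `base_mutation_rate * multiplier(class)`, where the class is assigned by
#' the priority order splice site > branch point positions 4/6 > other
#' heptamer positions > coding > UTR > intron > intergenic. The alternate
#' allele is the transition partner with probability
#' `transition_probability`, otherwise one of the two transversions
#' uniformly. Each variant carries one submitter label.
#'
#' @param sim a `bps_simulation`.
#' @param config simulation configuration (defaults to `sim$config`).
#' @param seed RNG seed for the variant draw (defaults to `config$seed + 1`).
#' @return a `variant_catalog`.
#' @export
simulate_variants <- function(sim, config = sim$config,
                              seed = config$seed + 1L) {
  validate_sim_config(config)
  set.seed(seed)
  models <- parse_annotation(sim$annotation, sim$genome)
  introns <- derive_introns(models)
  feats <- build_feature_catalog(models, sim$genome, introns = introns)

  mult <- config$constraint_multipliers
  # class codes by ascending priority of painting (later overwrites earlier)
  rate_of <- c(0,                     # 0: N (no mutation)
               mult[["splice_site"]], # 1
               mult[["bps_bp"]],      # 2
               mult[["bps_other"]],   # 3
               mult[["coding"]],      # 4
               mult[["utr"]],         # 5
               mult[["intron"]],      # 6
               mult[["intergenic"]])  # 7

  chroms <- names(sim$genome)
  rows <- vector("list", length(chroms))
  for (j in seq_along(chroms)) {
    chr <- chroms[j]
    s <- strsplit(as.character(sim$genome[[j]]), "")[[1]]
    clen <- length(s)
    cls <- rep(7L, clen)

    paint <- function(gr, code) {
      gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
      if (!length(gr)) return()
      for (q in seq_along(gr)) {
        cls[GenomicRanges::start(gr)[q]:GenomicRanges::end(gr)[q]] <<- code
      }
    }
    paint(feats$intron, 6L)
    paint(c(feats$five_prime_utr, feats$three_prime_utr), 5L)
    paint(feats$coding, 4L)

    # planted heptamer positions, strand-aware
    tr <- sim$truth[sim$truth$chrom == chr, ]
    if (nrow(tr)) {
      sgn <- ifelse(tr$strand == "+", 1L, -1L)
      for (k in 1:7) {
        code <- if (k %in% c(4L, 6L)) 2L else 3L
        p <- tr$bp_pos + sgn * (k - 6L)
        if (k %in% c(4L, 6L)) next  # paint bp positions after the others
        cls[p] <- 3L
      }
      for (k in c(4L, 6L)) cls[tr$bp_pos + sgn * (k - 6L)] <- 2L
    }
    paint(c(feats$five_prime_ss, feats$three_prime_ss), 1L)
    cls[s == "N"] <- 0L

    rate <- config$base_mutation_rate * rate_of[cls + 1L]
    hit <- which(runif(clen) < rate)
    if (!length(hit)) { rows[[j]] <- NULL; next }
    ref <- s[hit]
    n <- length(hit)
    ts <- runif(n) < config$transition_probability
    alt <- ifelse(ts, TS_PARTNER[ref],
                  TV_PARTNERS[cbind(match(ref, DNA_BASES), sample(1:2, n, replace = TRUE))])
    sid <- paste0("S", sample.int(config$n_studies, n, replace = TRUE))
    rows[[j]] <- data.frame(chrom = chr, pos = hit, ref = ref, alt = alt,
                            sid = sid, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(variant_catalog(character(0), integer(0), character(0),
                           character(0), list()))
  }
  variant_catalog(df$chrom, df$pos, df$ref, df$alt, as.list(df$sid))
}

#' Inject a contaminating variant batch into a catalogue
#'
#' Emulates the two contamination patterns seen in biased public databases:
#' an exome-only submission (`exome_batch`: sites sampled uniformly from
#' exonic non-N bases) and an error-dominated submission (`error_batch`:
#' sites sampled uniformly genome-wide with the alternate allele uniform
#' over the three possibilities, expected Ti/Tv 0.5). Added variants carry
#' only `study_id`; collisions with existing sites merge submitter lists.
#'
#' @param catalog a `variant_catalog`.
#' @param genome the genome the positions resolve against.
#' @param mode `"exome_batch"` or `"error_batch"`.
#' @param n_added number of sites to add.
#' @param study_id submitter label for the batch.
#' @param seed RNG seed.
#' @param exons GRanges of exonic intervals (required for `exome_batch`).
#' @param restrict_to optional GRanges restricting candidate sites (e.g.
#'   splice-site neighbourhoods).
#' @param p_ts transition probability for `exome_batch` alleles.
#' @return the augmented `variant_catalog`.
#' @export
inject_contamination <- function(catalog, genome,
                                 mode = c("exome_batch", "error_batch"),
                                 n_added, study_id, seed = 1L,
                                 exons = NULL, restrict_to = NULL,
                                 p_ts = 0.7) {
  mode <- match.arg(mode)
  if (n_added == 0) return(catalog)
  set.seed(seed)

  if (mode == "exome_batch") {
    if (is.null(exons)) stop("exome_batch requires exon intervals")
    pool_gr <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  } else {
    pool_gr <- GenomicRanges::GRanges(
      names(genome),
      IRanges::IRanges(1L, Biostrings::width(genome)))
  }
  if (!is.null(restrict_to)) {
    pool_gr <- GenomicRanges::intersect(
      pool_gr, GenomicRanges::reduce(restrict_to, ignore.strand = TRUE),
      ignore.strand = TRUE)
  }

  chrs <- as.character(GenomicRanges::seqnames(pool_gr))
  pos <- unlist(mapply(seq, GenomicRanges::start(pool_gr),
                       GenomicRanges::end(pool_gr), SIMPLIFY = FALSE))
  chr <- rep(chrs, GenomicRanges::width(pool_gr))
  # drop N bases
  base <- character(length(pos))
  for (cn in unique(chr)) {
    i <- chr == cn
    base[i] <- strsplit(as.character(genome[[cn]]), "")[[1]][pos[i]]
  }
  ok <- base %in% DNA_BASES
  chr <- chr[ok]; pos <- pos[ok]; base <- base[ok]
  if (length(pos) < n_added)
    stop("not enough candidate sites (", length(pos), ") for n_added = ",
         n_added)

  pick <- sample.int(length(pos), n_added)
  chr <- chr[pick]; pos <- pos[pick]; ref <- base[pick]
  if (mode == "exome_batch") {
    ts <- runif(n_added) < p_ts
    alt <- ifelse(ts, TS_PARTNER[ref],
                  TV_PARTNERS[cbind(match(ref, DNA_BASES), sample(1:2, n_added, replace = TRUE))])
  } else {
    # uniform over the three alternatives: one transition, two transversions
    u <- sample.int(3L, n_added, replace = TRUE)
    alt <- character(n_added)
    alt[u == 1L] <- TS_PARTNER[ref[u == 1L]]
    alt[u != 1L] <- TV_PARTNERS[cbind(match(ref[u != 1L], DNA_BASES),
                                      u[u != 1L] - 1L)]
  }

  key_old <- paste(catalog$chrom, catalog$pos)
  key_new <- paste(chr, pos)
  dup <- key_new %in% key_old
  # merge submitter lists at colliding sites
  if (any(dup)) {
    at <- match(key_new[dup], key_old)
    for (i in unique(at)) {
      catalog$study_ids[[i]] <- unique(c(catalog$study_ids[[i]], study_id))
    }
  }
  add <- which(!dup & !duplicated(key_new))
  if (length(add)) {
    newdf <- variant_catalog(chr[add], pos[add], ref[add], alt[add],
                             rep(list(study_id), length(add)))
    catalog <- rbind_catalog(catalog, newdf, chrom_order = names(genome))
  }
  catalog
}

#' Write simulation outputs to disk
#'
#' Writes the genome as 60-column FASTA, the annotation as GTF, and the
#' planted truth as TSV.
#'
#' @param sim a `bps_simulation`.
#' @param dir output directory (created if absent).
#' @return invisible named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  tsv <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fa, width = 60L)
  rtracklayer::export(sim$annotation, gtf, format = "gtf")
  write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genome = fa, annotation = gtf, truth = tsv))
}
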