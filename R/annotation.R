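#' Read a genome assembly from FASTA
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet], names truncated to the first
#'   whitespace-delimited token, sequence uppercased.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate chromosome names in FASTA")
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Total non-N length of a genome
#' @param genome a DNAStringSet.
#' @return integer count of A/C/G/T bases.
#' @export
effective_genome_length <- function(genome) {
  sum(Biostrings::letterFrequency(genome, DNA_BASES))
}

#' Parse a GTF annotation into gene models
#'
#' Reads Ensembl-style GTF (attributes `gene_id`, `transcript_id`, optional
#' `gene_biotype`) and groups records into per-transcript gene models.
#' Records on chromosomes absent from the genome are skipped with a logged
#' count; exons extending beyond chromosome bounds are an error.
#'
#' @param x GTF file path, or a GRanges with GTF-style metadata columns
#'   (`type`, `gene_id`, `transcript_id`).
#' @param genome the genome assembly (DNAStringSet) the coordinates refer to.
#' @return list of class `gene_models` with GRanges elements `exons`, `cds`,
#'   `utr5`, `utr3`, `start_codon`, `stop_codon`, `genes`, and a named
#'   `gene_biotype` vector.
#' @export
parse_annotation <- function(x, genome) {
  if (is.character(x)) {
    lines <- readLines(x, warn = FALSE)
    if (!length(lines) || all(grepl("^#", lines) | !nzchar(lines))) {
      warning("empty GTF: no annotation records")
      return(.empty_gene_models())
    }
    gr <- tryCatch(
      rtracklayer::import(x, format = "gtf"),
      error = function(e) stop("failed to parse GTF '", x, "': ",
                               conditionMessage(e)))
  } else if (methods::is(x, "GRanges")) {
    gr <- x
  } else stop("x must be a GTF path or a GRanges")
  if (!length(gr)) {
    warning("empty GTF: no annotation records")
    return(.empty_gene_models())
  }

  known <- as.character(GenomicRanges::seqnames(gr)) %in% names(genome)
  if (any(!known)) {
    message(sum(!known), " annotation record(s) on unknown chromosomes skipped")
    gr <- gr[known]
  }
  if (!length(gr)) {
    warning("no annotation records on known chromosomes")
    return(.empty_gene_models())
  }
  clen <- Biostrings::width(genome)[match(
    as.character(GenomicRanges::seqnames(gr)), names(genome))]
  if (any(GenomicRanges::end(gr) > clen) || any(GenomicRanges::start(gr) < 1))
    stop("annotation record outside chromosome bounds")

  md <- S4Vectors::mcols(gr)
  if (is.null(md$type)) stop("GTF records lack a feature type")
  if (is.null(md$gene_id)) stop("GTF records lack gene_id attributes")
  biotype <- if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
             else rep("protein_coding", length(gr))

  pick <- function(t) gr[as.character(md$type) == t]
  exons <- pick("exon")
  if (!length(exons)) stop("GTF contains no exon records")
  gene_rows <- pick("gene")
  genes <- if (length(gene_rows)) gene_rows else {
    sp <- S4Vectors::split(exons, S4Vectors::mcols(exons)$gene_id)
    unlist(range(sp))
  }
  if (length(gene_rows)) names(genes) <- S4Vectors::mcols(gene_rows)$gene_id

  gb <- stats::setNames(biotype, as.character(md$gene_id))
  gb <- gb[!duplicated(names(gb))]

  out <- list(
    exons = exons,
    cds = pick("CDS"),
    utr5 = pick("five_prime_utr"),
    utr3 = pick("three_prime_utr"),
    start_codon = pick("start_codon"),
    stop_codon = pick("stop_codon"),
    genes = genes,
    gene_biotype = gb
  )
  class(out) <- "gene_models"
  out
}

.empty_gene_models <- function() {
  e <- GenomicRanges::GRanges()
  out <- list(exons = e, cds = e, utr5 = e, utr3 = e, start_codon = e,
              stop_codon = e, genes = e, gene_biotype = character(0))
  class(out) <- "gene_models"
  out
}

#' Derive introns from gene models
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated across transcripts by (chrom, start, end, strand). By
#' default only protein-coding genes contribute. Transcripts with
#' overlapping exons are skipped with a diagnostic.
#'
#' @param models a `gene_models` object.
#' @param protein_coding_only restrict to genes of biotype protein_coding.
#' @return GRanges of introns (metadata `gene_id`, `intron_id`), sorted.
#' @export
derive_introns <- function(models, protein_coding_only = TRUE) {
  ex <- models$exons
  if (!length(ex)) return(GenomicRanges::GRanges())
  if (protein_coding_only && length(models$gene_biotype)) {
    keep_genes <- names(models$gene_biotype)[
      models$gene_biotype == "protein_coding"]
    ex <- ex[S4Vectors::mcols(ex)$gene_id %in% keep_genes]
  }
  if (!length(ex)) return(GenomicRanges::GRanges())

  tx <- as.character(S4Vectors::mcols(ex)$transcript_id)
  rows <- list()
  skipped <- 0L
  for (t in unique(tx)) {
    e <- ex[tx == t]
    o <- order(GenomicRanges::start(e))
    st <- GenomicRanges::start(e)[o]; en <- GenomicRanges::end(e)[o]
    if (length(e) < 2L) next
    if (any(st[-1] <= en[-length(en)])) {
      skipped <- skipped + 1L
      next
    }
    rows[[t]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(e))[1],
      start = en[-length(en)] + 1L,
      end = st[-1] - 1L,
      strand = as.character(GenomicRanges::strand(e))[1],
      gene_id = as.character(S4Vectors::mcols(e)$gene_id)[1],
      stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " transcript(s) with overlapping exons skipped")
  if (!length(rows)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, rows)
  key <- paste(df$chrom, df$start, df$end, df$strand)
  df <- df[!duplicated(key), ]
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), df$strand,
    gene_id = df$gene_id,
    intron_id = paste0(df$chrom, ":", df$start, "-", df$end, ":", df$strand))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Donor (5' splice site) dinucleotides of introns
#'
#' The first two intron bases in transcript orientation: for plus-strand
#' introns the two lowest genomic coordinates, for minus-strand the two
#' highest.
#'
#' @param introns GRanges of introns.
#' @return GRanges of 2-base intervals.
#' @export
splice_donors <- function(introns) {
  GenomicRanges::resize(introns, width = 2L, fix = "start")
}

#' Acceptor (3' splice site) dinucleotides of introns
#' @param introns GRanges of introns.
#' @return GRanges of 2-base intervals (last two intron bases in transcript
#'   orientation).
#' @export
splice_acceptors <- function(introns) {
  GenomicRanges::resize(introns, width = 2L, fix = "end")
}

#' Build the feature catalogue used for constraint analysis
#'
#' Interval sets for the nine analyzed feature classes (5'/3' splice sites,
#' start/stop codons, 5'/3' UTR, exon, intron, intergenic) plus derived
#' classes `coding` and `genic`. Classes may overlap; counting is per-class.
#' UTRs are taken from GTF UTR records when present, otherwise derived from
#' CDS versus exon extents. `coding` defaults to exon together with start and
#' stop codons (every exonic base, UTRs included); `coding_mode = "cds"`
#' restricts to CDS.
#'
#' @param models a `gene_models` object.
#' @param genome the genome assembly.
#' @param introns optionally precomputed introns (from [derive_introns()]).
#' @param coding_mode `"exon"` (default) or `"cds"`.
#' @return list of class `feature_catalog` of GRanges per class.
#' @export
build_feature_catalog <- function(models, genome, introns = NULL,
                                  coding_mode = c("exon", "cds")) {
  coding_mode <- match.arg(coding_mode)
  if (is.null(introns)) introns <- derive_introns(models)

  utr5 <- models$utr5
  utr3 <- models$utr3
  if (!length(utr5) && !length(utr3) && length(models$cds)) {
    u <- .derive_utrs(models)
    utr5 <- u$utr5; utr3 <- u$utr3
  }

  genic <- GenomicRanges::reduce(
    c(GenomicRanges::granges(models$genes), GenomicRanges::granges(models$exons)),
    ignore.strand = TRUE)
  whole <- GenomicRanges::GRanges(
    names(genome), IRanges::IRanges(1L, Biostrings::width(genome)))
  intergenic <- GenomicRanges::setdiff(whole, genic, ignore.strand = TRUE)

  coding_base <- if (coding_mode == "exon") models$exons else models$cds
  coding <- c(GenomicRanges::granges(coding_base),
              GenomicRanges::granges(models$start_codon),
              GenomicRanges::granges(models$stop_codon))

  out <- list(
    five_prime_ss = splice_donors(introns),
    three_prime_ss = splice_acceptors(introns),
    start_codon = GenomicRanges::granges(models$start_codon),
    stop_codon = GenomicRanges::granges(models$stop_codon),
    five_prime_utr = GenomicRanges::granges(utr5),
    three_prime_utr = GenomicRanges::granges(utr3),
    exon = GenomicRanges::granges(models$exons),
    intron = GenomicRanges::granges(introns),
    intergenic = intergenic,
    coding = coding,
    genic = genic
  )
  class(out) <- "feature_catalog"
  out
}

# derive UTR intervals from CDS vs exon extents, per transcript
.derive_utrs <- function(models) {
  ex <- models$exons; cds <- models$cds
  tx_ex <- as.character(S4Vectors::mcols(ex)$transcript_id)
  tx_cds <- as.character(S4Vectors::mcols(cds)$transcript_id)
  u5 <- list(); u3 <- list()
  for (t in intersect(unique(tx_ex), unique(tx_cds))) {
    e <- ex[tx_ex == t]; cc <- cds[tx_cds == t]
    str <- as.character(GenomicRanges::strand(e))[1]
    cs <- min(GenomicRanges::start(cc)); ce <- max(GenomicRanges::end(cc))
    left <- GenomicRanges::setdiff(
      GenomicRanges::granges(e),
      GenomicRanges::GRanges(GenomicRanges::seqnames(e)[1],
                             IRanges::IRanges(cs, 536870912L),
                             strand = str))
    right <- GenomicRanges::setdiff(
      GenomicRanges::granges(e),
      GenomicRanges::GRanges(GenomicRanges::seqnames(e)[1],
                             IRanges::IRanges(1L, ce), strand = str))
    if (str == "+") { u5[[t]] <- left; u3[[t]] <- right }
    else { u5[[t]] <- right; u3[[t]] <- left }
  }
  cat0 <- function(l) if (length(l)) do.call(c, unname(l))
                      else GenomicRanges::GRanges()
  list(utr5 = cat0(u5), utr3 = cat0(u3))
}

#' Effective (non-N) length of an interval set
#'
#' Number of non-N bases in the union of the intervals (union first, so
#' overlapping intervals are not double-counted).
#'
#' @param intervals GRanges.
#' @param genome the genome assembly.
#' @return integer base count.
#' @export
effective_length <- function(intervals, genome) {
  r <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  if (!length(r)) return(0L)
  total <- 0L
  for (cn in unique(as.character(GenomicRanges::seqnames(r)))) {
    ri <- r[as.character(GenomicRanges::seqnames(r)) == cn]
    v <- Biostrings::Views(genome[[cn]], GenomicRanges::start(ri),
                           GenomicRanges::end(ri))
    total <- total + sum(Biostrings::letterFrequency(v, DNA_BASES))
  }
  as.integer(total)
}

#' Write feature classes as BED for inspection
#'
#' @param features a `feature_catalog`.
#' @param dir output directory.
#' @return invisible vector of paths.
#' @export
write_feature_bed <- function(features, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cl in names(features)) {
    p <- file.path(dir, paste0(cl, ".bed"))
    rtracklayer::export(features[[cl]], p, format = "bed")
    paths[cl] <- p
  }
  invisible(paths)
}
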