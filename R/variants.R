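#' Construct a variant catalogue
#'
#' A catalogue of biallelic SNV sites: chromosome, 1-based position, single
#' reference and alternate base, and a (possibly empty) set of submitter
#' labels per site.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions.
#' @param ref,alt single bases over A/C/G/T, `ref != alt`.
#' @param study_ids list of character vectors (one per variant), or NULL.
#' @return data.frame of class `variant_catalog` with a `study_ids` list
#'   column.
#' @export
variant_catalog <- function(chrom, pos, ref, alt, study_ids = NULL) {
  n <- length(chrom)
  if (is.null(study_ids)) study_ids <- rep(list(character(0)), n)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(study_ids) == n)
  if (n && (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES)))
    stop("ref and alt must be single bases over A/C/G/T")
  if (n && any(ref == alt)) stop("ref must differ from alt")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  df$study_ids <- study_ids
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  class(df) <- c("variant_catalog", "data.frame")
  df
}

# rbind two catalogues and re-sort (chromosomes in `chrom_order` when given)
rbind_catalog <- function(a, b, chrom_order = NULL) {
  df <- rbind(as.data.frame(a), as.data.frame(b))
  if (!is.null(chrom_order)) {
    df <- df[order(match(df$chrom, chrom_order), df$pos), ]
  } else {
    df <- df[order(df$chrom, df$pos), ]
  }
  rownames(df) <- NULL
  class(df) <- c("variant_catalog", "data.frame")
  df
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("variant_catalog:", nrow(x), "biallelic SNVs on",
      length(unique(x$chrom)), "chromosome(s); Ti/Tv =",
      round(titv_ratio(x), 3), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# GRanges view of the catalogue (width-1 ranges)
catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(catalog$chrom,
                         IRanges::IRanges(catalog$pos, catalog$pos))
}

#' Load biallelic SNVs from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) and keeps biallelic SNVs only.
#' Multi-allelic records, indels/MNVs/symbolic alleles, records on unknown
#' chromosomes, and records whose REF mismatches the genome are excluded,
#' with per-reason counts logged and stored in the `"exclusions"` attribute.
#' Submitter labels are read from the `study_key` INFO field when present
#' (comma-separated list).
#'
#' @param path VCF file.
#' @param genome optional genome assembly for chromosome and REF checks.
#' @param study_key INFO key holding submitter labels (default `"SID"`).
#' @param rename optional named character vector mapping VCF chromosome
#'   names to genome names (applied before any check).
#' @return a `variant_catalog` with attribute `exclusions`.
#' @export
load_variants <- function(path, genome = NULL, study_key = "SID",
                          rename = NULL) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  if (!is.null(rename)) {
    hit <- chrom %in% names(rename)
    chrom[hit] <- rename[chrom[hit]]
  }
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT

  n <- length(rr)
  excl <- c(multi_allelic = 0L, non_snv = 0L, unknown_chrom = 0L,
            ref_mismatch = 0L)
  drop <- rep(FALSE, n)

  multi <- S4Vectors::elementNROWS(altl) != 1L
  excl["multi_allelic"] <- sum(multi)
  drop <- drop | multi

  alt <- rep(NA_character_, n)
  alt[!multi] <- vapply(as.list(altl[!multi]), function(a)
    as.character(a[[1]]), character(1))
  bad <- !drop & (nchar(ref) != 1L | is.na(alt) | nchar(alt) != 1L |
                    !ref %in% DNA_BASES | !alt %in% DNA_BASES | ref == alt)
  excl["non_snv"] <- sum(bad)
  drop <- drop | bad

  if (!is.null(genome)) {
    unk <- !drop & !chrom %in% names(genome)
    excl["unknown_chrom"] <- sum(unk)
    drop <- drop | unk
    chk <- which(!drop)
    if (length(chk)) {
      actual <- character(length(chk))
      for (cn in unique(chrom[chk])) {
        i <- chk[chrom[chk] == cn]
        actual[match(i, chk)] <-
          strsplit(as.character(genome[[cn]]), "")[[1]][pos[i]]
      }
      mism <- actual != ref[chk]
      excl["ref_mismatch"] <- sum(mism)
      drop[chk[mism]] <- TRUE
    }
  }

  ids <- rep(list(character(0)), n)
  inf <- VariantAnnotation::info(vcf)
  if (study_key %in% colnames(inf)) {
    raw <- inf[[study_key]]
    ids <- lapply(as.list(raw), function(v) {
      v <- unlist(strsplit(as.character(v), ","))
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v)) v else character(0)
    })
  }

  keep <- which(!drop)
  message("load_variants: kept ", length(keep), " of ", n, " records (",
          paste(names(excl), excl, sep = "=", collapse = ", "), ")")
  out <- variant_catalog(chrom[keep], pos[keep], ref[keep], alt[keep],
                         ids[keep])
  if (!is.null(genome))
    out <- rbind_catalog(out[0, ], out, chrom_order = names(genome))
  attr(out, "exclusions") <- excl
  out
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; all other ref/alt pairs are
#' transversions. Returns `NA` (undefined) when the catalogue is empty or
#' has no transversions.
#'
#' @param x a `variant_catalog` or data.frame with `ref` and `alt`.
#' @return numeric ratio, or NA.
#' @export
titv_ratio <- function(x) {
  if (!nrow(x)) return(NA_real_)
  ti <- sum(is_transition(x$ref, x$alt))
  tv <- nrow(x) - ti
  if (tv == 0) return(NA_real_)
  ti / tv
}

#' Genome-wide variant density per 100 bases
#'
#' Total variant count divided by the effective (non-N) genome length,
#' scaled to 100 bases.
#'
#' @param catalog a `variant_catalog`.
#' @param genome the genome assembly.
#' @return variants per 100 bp.
#' @export
genome_wide_density <- function(catalog, genome) {
  eff <- effective_genome_length(genome)
  if (eff == 0) stop("effective genome length is zero")
  100 * nrow(catalog) / eff
}

#' Filter a catalogue by submission metadata
#'
#' Two mutually exclusive modes. Min-count mode
#' (`min_submissions = k`) keeps variants carrying at least `k` submitter
#' labels; with `k > 1`, variants without metadata are dropped (logged);
#' `k = 1` is the identity. Exclude mode (`exclude_private_to = label`)
#' drops variants whose submitter set is exactly `{label}` (private to that
#' batch) and keeps variants the batch shares with other submitters.
#'
#' @param catalog a `variant_catalog`.
#' @param min_submissions integer, or NULL.
#' @param exclude_private_to submitter label, or NULL.
#' @return filtered `variant_catalog`.
#' @export
filter_by_submission <- function(catalog, min_submissions = NULL,
                                 exclude_private_to = NULL) {
  if (!is.null(min_submissions) && !is.null(exclude_private_to))
    stop("choose one mode: min_submissions or exclude_private_to ",
         "(apply sequentially for both)")
  if (is.null(min_submissions) && is.null(exclude_private_to))
    return(catalog)
  if (!is.null(min_submissions)) {
    if (min_submissions <= 1) return(catalog)
    nsub <- lengths(catalog$study_ids)
    nometa <- sum(nsub == 0)
    if (nometa)
      message(nometa, " variant(s) without submission metadata dropped ",
              "(min_submissions = ", min_submissions, ")")
    keep <- nsub >= min_submissions
  } else {
    keep <- !vapply(catalog$study_ids, function(v)
      length(v) > 0 && all(v == exclude_private_to), logical(1))
  }
  out <- catalog[keep, ]
  rownames(out) <- NULL
  class(out) <- c("variant_catalog", "data.frame")
  out
}

#' Write a catalogue as a sites-only VCF 4.2
#'
#' @param catalog a `variant_catalog`.
#' @param path output path.
#' @param genome optional genome for contig header lines.
#' @param study_key INFO key for submitter labels.
#' @export
write_vcf <- function(catalog, path, genome = NULL, study_key = "SID") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(genome)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(genome),
                       Biostrings::width(genome)), con)
  }
  writeLines(sprintf(
    "##INFO=<ID=%s,Number=.,Type=String,Description=\"Submitter study identifiers\">",
    study_key), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(catalog)) {
    info <- vapply(catalog$study_ids, function(v)
      if (length(v)) paste0(study_key, "=", paste(v, collapse = ","))
      else ".", character(1))
    writeLines(paste(catalog$chrom, catalog$pos, ".", catalog$ref,
                     catalog$alt, ".", ".", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Summary metrics of a catalogue
#'
#' Count, Ti/Tv, genome-wide density, and (when a feature catalogue is
#' given) the percentage and Ti/Tv of coding variants.
#'
#' @param catalog a `variant_catalog`.
#' @param genome the genome assembly.
#' @param features optional `feature_catalog` for coding metrics.
#' @return list of class `catalog_summary`.
#' @export
catalog_summary <- function(catalog, genome, features = NULL) {
  out <- list(n_snvs = nrow(catalog),
              titv = titv_ratio(catalog),
              density = genome_wide_density(catalog, genome),
              pct_coding = NA_real_, titv_coding = NA_real_)
  if (!is.null(features) && nrow(catalog)) {
    r <- GenomicRanges::reduce(features$coding, ignore.strand = TRUE)
    hit <- GenomicRanges::countOverlaps(catalog_granges(catalog), r) > 0
    out$pct_coding <- 100 * mean(hit)
    out$titv_coding <- titv_ratio(catalog[hit, ])
  }
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("SNVs: %d (Ti/Tv %.2f), density %.3f per 100 bp",
              x$n_snvs, x$titv, x$density))
  if (!is.na(x$pct_coding))
    cat(sprintf(", coding %.2f%% (Ti/Tv %.2f)", x$pct_coding, x$titv_coding))
  cat("\n")
  invisible(x)
}
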