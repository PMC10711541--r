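# Small in-code fixtures shared across test files.

tiny_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(g) <- paste0("chr", seq_along(seqs))
  g
}

random_genome <- function(len, seed = 1, nfrac = 0) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (nfrac > 0) chars[sample(len, round(nfrac * len))] <- "N"
  tiny_genome(c(chr1 = paste(chars, collapse = "")))
}

gtf_line <- function(chrom, type, start, end, strand, gene = "g1",
                     tx = "g1.t1", biotype = "protein_coding") {
  sprintf(paste0('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s"; gene_biotype "%s";'),
          chrom, type, start, end, strand, gene, tx, biotype)
}

write_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

write_test_vcf <- function(body_lines, contigs = NULL,
                           info_sid = TRUE) {
  path <- tempfile(fileext = ".vcf")
  hdr <- "##fileformat=VCFv4.2"
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          contigs))
  if (info_sid)
    hdr <- c(hdr, paste0("##INFO=<ID=SID,Number=.,Type=String,",
                         "Description=\"Submitters\">"))
  writeLines(c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               body_lines), path)
  path
}

# a two-exon plus-strand gene and a two-exon minus-strand gene on a 1 kb
# chromosome; returns list(genome, gtf_path)
toy_gene_fixture <- function(seed = 42) {
  genome <- random_genome(1000, seed = seed)
  lines <- c(
    gtf_line("chr1", "gene", 1, 300, "+"),
    gtf_line("chr1", "transcript", 1, 300, "+"),
    gtf_line("chr1", "exon", 1, 100, "+"),
    gtf_line("chr1", "exon", 201, 300, "+"),
    gtf_line("chr1", "gene", 401, 700, "-", gene = "g2", tx = "g2.t1"),
    gtf_line("chr1", "transcript", 401, 700, "-", gene = "g2", tx = "g2.t1"),
    gtf_line("chr1", "exon", 401, 500, "-", gene = "g2", tx = "g2.t1"),
    gtf_line("chr1", "exon", 601, 700, "-", gene = "g2", tx = "g2.t1")
  )
  list(genome = genome, gtf = write_gtf(lines))
}

# moderately sized simulation reused by several test files
small_sim_config <- function(seed = 3L, chrom_length = 300000L,
                             n_genes = 40L, ...) {
  sim_config(n_chromosomes = 1L, chrom_length = chrom_length,
             n_genes = n_genes, seed = seed, ...)
}

as_pwm <- function(m) structure(m, class = "bps_pwm")
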