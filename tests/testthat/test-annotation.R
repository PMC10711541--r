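# GTF parsing, intron derivation, feature catalogue, effective lengths.

test_that("a two-exon gene parses with correct exons, gene span and strand symmetry", {
  fx <- toy_gene_fixture()
  models <- parse_annotation(fx$gtf, fx$genome)
  ex1 <- models$exons[S4Vectors::mcols(models$exons)$gene_id == "g1"]
  expect_length(ex1, 2)
  expect_identical(GenomicRanges::start(ex1), c(1L, 201L))
  expect_identical(GenomicRanges::end(ex1), c(100L, 300L))
  g1 <- models$genes[S4Vectors::mcols(models$genes)$gene_id == "g1" |
                       names(models$genes) == "g1"]
  expect_identical(GenomicRanges::start(g1), 1L)
  expect_identical(GenomicRanges::end(g1), 300L)
  # minus-strand gene: identical interval geometry, opposite strand
  ex2 <- models$exons[S4Vectors::mcols(models$exons)$gene_id == "g2"]
  expect_identical(GenomicRanges::width(ex2), GenomicRanges::width(ex1))
  expect_identical(as.character(GenomicRanges::strand(ex2)), c("-", "-"))
})

test_that("records on unknown chromosomes are skipped; out-of-bounds exons rejected", {
  fx <- toy_gene_fixture()
  lines <- c(readLines(fx$gtf),
             gtf_line("chrUn", "exon", 1, 50, "+", gene = "g3", tx = "g3.t1"))
  expect_message(
    models <- parse_annotation(write_gtf(lines), fx$genome),
    "unknown chromosome")
  expect_false("g3" %in% S4Vectors::mcols(models$exons)$gene_id)

  bad <- write_gtf(gtf_line("chr1", "exon", 990, 1200, "+"))
  expect_error(parse_annotation(bad, fx$genome), "bounds")
})

test_that("empty GTF yields an empty model set with a warning", {
  p <- write_gtf(character(0))
  expect_warning(models <- parse_annotation(p, tiny_genome(c(chr1 = "ACGT"))),
                 "empty")
  expect_length(models$exons, 0)
  expect_length(derive_introns(models), 0)
})

test_that("introns are exon gaps with strand-aware donors and acceptors", {
  fx <- toy_gene_fixture()
  models <- parse_annotation(fx$gtf, fx$genome)
  introns <- derive_introns(models)
  expect_length(introns, 2)

  plus <- introns[as.character(GenomicRanges::strand(introns)) == "+"]
  expect_identical(GenomicRanges::start(plus), 101L)
  expect_identical(GenomicRanges::end(plus), 200L)
  d <- splice_donors(plus); a <- splice_acceptors(plus)
  expect_identical(c(GenomicRanges::start(d), GenomicRanges::end(d)),
                   c(101L, 102L))
  expect_identical(c(GenomicRanges::start(a), GenomicRanges::end(a)),
                   c(199L, 200L))

  minus <- introns[as.character(GenomicRanges::strand(introns)) == "-"]
  expect_identical(GenomicRanges::start(minus), 501L)
  expect_identical(GenomicRanges::end(minus), 600L)
  d <- splice_donors(minus); a <- splice_acceptors(minus)
  # donor has the higher genomic coordinates on the minus strand
  expect_identical(c(GenomicRanges::start(d), GenomicRanges::end(d)),
                   c(599L, 600L))
  expect_identical(c(GenomicRanges::start(a), GenomicRanges::end(a)),
                   c(501L, 502L))
  # donor and acceptor inside the intron, width 2
  expect_true(all(GenomicRanges::width(splice_donors(introns)) == 2))
  expect_true(all(GenomicRanges::width(splice_acceptors(introns)) == 2))
})

test_that("single-exon transcripts, shared introns, and overlapping exons are handled", {
  genome <- random_genome(1000)
  lines <- c(
    gtf_line("chr1", "exon", 1, 100, "+"),
    gtf_line("chr1", "exon", 201, 300, "+"),
    # second transcript of the same gene sharing the intron
    gtf_line("chr1", "exon", 1, 100, "+", tx = "g1.t2"),
    gtf_line("chr1", "exon", 201, 320, "+", tx = "g1.t2"),
    # single-exon transcript
    gtf_line("chr1", "exon", 400, 500, "+", gene = "g2", tx = "g2.t1"),
    # transcript with overlapping exons -> skipped
    gtf_line("chr1", "exon", 600, 700, "+", gene = "g3", tx = "g3.t1"),
    gtf_line("chr1", "exon", 650, 800, "+", gene = "g3", tx = "g3.t1")
  )
  expect_message(
    introns <- derive_introns(parse_annotation(write_gtf(lines), genome)),
    "overlapping exons")
  expect_length(introns, 1)  # deduplicated across transcripts
  expect_identical(GenomicRanges::start(introns), 101L)

  # non-protein-coding genes excluded from intron derivation
  lines_nc <- c(lines[1:2],
                gtf_line("chr1", "exon", 400, 450, "+", gene = "g4",
                         tx = "g4.t1", biotype = "lincRNA"),
                gtf_line("chr1", "exon", 480, 520, "+", gene = "g4",
                         tx = "g4.t1", biotype = "lincRNA"))
  introns_nc <- derive_introns(parse_annotation(write_gtf(lines_nc), genome))
  expect_length(introns_nc, 1)
})

test_that("feature catalogue: intergenic complement and splice-site sizes", {
  fx <- toy_gene_fixture()
  models <- parse_annotation(fx$gtf, fx$genome)
  introns <- derive_introns(models)
  feats <- build_feature_catalog(models, fx$genome, introns = introns)

  # gene bodies [1,300] and [401,700] excluded
  inter <- GenomicRanges::reduce(feats$intergenic)
  expect_identical(GenomicRanges::start(inter), c(301L, 701L))
  expect_identical(GenomicRanges::end(inter), c(400L, 1000L))

  # 4 splice-site bases per intron (2 donor + 2 acceptor)
  expect_identical(sum(GenomicRanges::width(feats$five_prime_ss)) +
                     sum(GenomicRanges::width(feats$three_prime_ss)),
                   4L * length(introns))

  # intergenic disjoint from exon and intron
  expect_length(GenomicRanges::intersect(
    feats$intergenic, GenomicRanges::granges(feats$exon),
    ignore.strand = TRUE), 0)
  expect_length(GenomicRanges::intersect(
    feats$intergenic, GenomicRanges::granges(feats$intron),
    ignore.strand = TRUE), 0)
})

test_that("effective length excludes N, is union-idempotent, and matches brute force", {
  g <- tiny_genome(c(chr1 = paste0(paste(rep("A", 50), collapse = ""),
                                   paste(rep("N", 10), collapse = ""),
                                   paste(rep("C", 40), collapse = ""))))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_identical(effective_length(gr, g), 90L)
  expect_identical(effective_length(c(gr, gr), g), 90L)

  # random interval sets vs the per-base oracle
  genome <- random_genome(10000, seed = 31, nfrac = 0.05)
  set.seed(32)
  for (rep in 1:5) {
    st <- sort(sample(9000, 20))
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(st, st + sample(500, 20)))
    expect_identical(effective_length(gr, genome),
                     oracle_effective_length(gr, genome))
  }
  expect_identical(effective_length(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 10000)), genome),
    effective_genome_length(genome))
})

test_that("feature classification matches a per-base brute-force classifier", {
  cfg <- small_sim_config(seed = 17L, chrom_length = 80000L, n_genes = 8L)
  sim <- simulate_genome(cfg)
  models <- parse_annotation(sim$annotation, sim$genome)
  introns <- derive_introns(models)
  feats <- build_feature_catalog(models, sim$genome, introns = introns)
  len <- Biostrings::width(sim$genome)[1]
  masks <- lapply(c("exon", "intron", "intergenic", "coding",
                    "five_prime_utr", "three_prime_utr"), function(cl)
    oracle_base_mask(GenomicRanges::reduce(feats[[cl]], ignore.strand = TRUE),
                     "chr1", len))
  names(masks) <- c("exon", "intron", "intergenic", "coding",
                    "five_prime_utr", "three_prime_utr")
  # exon+intron+intergenic tile the chromosome (single-transcript genes)
  expect_true(all(masks$exon | masks$intron | masks$intergenic))
  expect_false(any(masks$exon & masks$intergenic))
  expect_false(any(masks$intron & masks$intergenic))
  # brute-force effective length agrees per class
  for (cl in names(masks)) {
    expect_identical(effective_length(feats[[cl]], sim$genome),
                     oracle_effective_length(feats[[cl]], sim$genome))
  }
  # UTRs lie inside exons; coding (exon mode) equals exon union here
  expect_true(all(masks$exon[masks$five_prime_utr]))
  expect_true(all(masks$exon[masks$three_prime_utr]))
  expect_identical(masks$coding, masks$exon)
})
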