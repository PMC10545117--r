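test_that("read_variants keeps only biallelic SNVs and joins effects", {
  vcf <- write_test_vcf(
    withr::local_tempfile(fileext = ".vcf"), c("a", "b"),
    c("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
      "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t1/1\t./.",
      "chr1\t300\t.\tG\tGA\t.\tPASS\t.\tGT\t0/0\t0/0",   # indel
      "chr1\t400\t.\tT\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0",  # triallelic
      "chr1\t500\t.\tT\tC\t.\tPASS\t.\tGT\t0/1\t1/1")
  )
  eff <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(chrom = "chr1", pos = c(200L, 999L), ref = c("C", "A"),
                          alt = c("G", "T"), class = c("missense", "lof")), eff)
  g <- suppressWarnings(read_variants(vcf, eff))
  expect_equal(ncol(g$geno), 3)           # 3 SNVs retained
  expect_equal(g$sites$pos, c(100L, 200L, 500L))
  expect_equal(g$sites$effect, c("unknown", "missense", "unknown"))
  expect_true(is.na(g$geno["b", 2]))      # ./. is missing, not 0
  expect_equal(unname(g$geno["a", 2]), 2L)
  log <- attr(g, "drop_log")
  expect_equal(sum(log$n), 2)
})

test_that("VCF round trip reproduces genotypes exactly", {
  dos <- random_geno(6, 40, seed = 11)
  g <- toy_geno(dos, ref = rep(c("A", "C"), 20), alt = rep(c("G", "T"), 20))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(g, path)
  g2 <- read_variants(path)
  expect_identical(unname(g2$geno), unname(g$geno))
  expect_equal(g2$sites$pos, g$sites$pos)
  expect_equal(g2$samples, g$samples)
})

test_that("gene models: spliced length, strand, frame flag, longest CDS", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t250\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t100\t250\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tx\tCDS\t100\t150\t.\t+\t0\tID=c1;Parent=gA.t1",
    "chr1\tx\tCDS\t200\t250\t.\t+\t0\tID=c2;Parent=gA.t1",
    "chr1\tx\tgene\t300\t450\t.\t-\t.\tID=gB",
    "chr1\tx\tmRNA\t300\t450\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tx\tCDS\t300\t350\t.\t-\t0\tID=c3;Parent=gB.t1",
    "chr1\tx\tCDS\t400\t450\t.\t-\t0\tID=c4;Parent=gB.t1",
    "chr1\tx\tgene\t500\t600\t.\t+\t.\tID=gC",
    "chr1\tx\tmRNA\t500\t600\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr1\tx\tCDS\t500\t551\t.\t+\t0\tID=c5;Parent=gC.t1",  # 52 bp: frame off
    "chr1\tx\tgene\t700\t900\t.\t+\t.\tID=gD",
    "chr1\tx\tmRNA\t700\t900\t.\t+\t.\tID=gD.t1;Parent=gD",
    "chr1\tx\tCDS\t700\t759\t.\t+\t0\tID=c6;Parent=gD.t1",
    "chr1\tx\tmRNA\t700\t900\t.\t+\t.\tID=gD.t2;Parent=gD",
    "chr1\tx\tCDS\t700\t789\t.\t+\t0\tID=c7;Parent=gD.t2"
  ), gff)
  gm <- suppressMessages(load_gene_models(gff))
  a <- gm[gm$gene_id == "gA", ]
  expect_equal(a$cds_len, 102L)
  expect_true(a$in_frame)
  expect_false(gm$in_frame[gm$gene_id == "gC"])
  # longest CDS wins for gD (90 bp transcript t2)
  expect_equal(gm$transcript_id[gm$gene_id == "gD"], "gD.t2")
  # minus strand coding positions are reversed genomic order
  b <- gm[gm$gene_id == "gB", ]
  pos <- surfload:::coding_positions(b)
  expect_equal(pos[1], 450L)
  expect_equal(tail(pos, 1), 300L)
})

test_that("region sets merge, reject degenerate rows and handle empty files", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr31\t0\t1000", "chr31\t500\t2000", "chr1\t10\t10"), bed)
  rs <- suppressWarnings(read_region_set(bed, "tetraploid"))
  expect_equal(nrow(rs), 1)
  expect_equal(rs$start, 0L)
  expect_equal(rs$end, 2000L)
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_region_set(empty)), 0)
})

ref_toy <- c(chr1 = paste0(
  strrep("T", 99),
  "ATGGCTGCAGCT",    # gene gX CDS at 100..111
  strrep("T", 50)
))
gm_toy <- tibble(
  gene_id = "gX", transcript_id = "gX.t1", chrom = "chr1", strand = "+",
  cds = list(tibble(start = 100L, end = 111L, phase = 0L)),
  cds_len = 12L, start = 100L, end = 111L, in_frame = TRUE
)

test_that("CDS reconstruction substitutes alleles and conserves counts", {
  # site at pos 103 (G->A), pos 107 (C->T), pos 200 outside CDS
  dos <- rbind(c(2L, 1L, 2L), c(0L, NA, 0L), c(1L, 1L, 1L))
  g <- toy_geno(dos, pos = c(103L, 107L, 200L), ref = c("G", "C", "T"),
                alt = c("A", "T", "A"))
  aln <- reconstruct_cds_alignment(gm_toy, g, ref_toy, seed = 5)
  expect_equal(ncol(aln$seqs), 12)
  # hom alt: both haplotypes carry A at column 4
  expect_equal(unname(aln$seqs[1:2, 4]), c("A", "A"))
  # missing genotype: N on both haplotypes of individual 2 at column 8
  expect_equal(unname(aln$seqs[3:4, 8]), c("N", "N"))
  # het: exactly one haplotype carries the alt
  expect_equal(sum(aln$seqs[5:6, 4] == "A"), 1)
  # allele counts recomputed from the alignment match the genotype matrix
  for (v in 1:2) {
    col <- c(4, 8)[v]
    alt_n <- sum(aln$seqs[, col] == g$sites$alt[v])
    expect_equal(alt_n, sum(g$geno[, v], na.rm = TRUE))
  }
  # determinism under the same seed
  aln2 <- reconstruct_cds_alignment(gm_toy, g, ref_toy, seed = 5)
  expect_identical(aln$seqs, aln2$seqs)
})

test_that("reconstruction with zero variants returns the reference CDS", {
  g <- toy_geno(matrix(0L, 2, 1), pos = 103L, ref = "G", alt = "A")
  aln <- reconstruct_cds_alignment(gm_toy, g, ref_toy, seed = 1)
  expect_true(all(aln$seqs == matrix(rep(strsplit("ATGGCTGCAGCT", "")[[1]],
                                         each = 4), nrow = 4)))
})

test_that("reference/variant disagreement is a hard error", {
  g <- toy_geno(matrix(1L, 2, 1), pos = 103L, ref = "C", alt = "A")
  expect_error(reconstruct_cds_alignment(gm_toy, g, ref_toy, seed = 1),
               "disagrees")
})
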