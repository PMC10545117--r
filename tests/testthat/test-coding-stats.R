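test_that("NG86 codon site fractions match enumeration of all 9 changes", {
  # printed cases
  tt <- classify_codon_sites("TTT")
  expect_equal(tt$syn, c(0, 0, 1 / 3))
  expect_equal(sum(tt$syn), 1 / 3)
  expect_equal(sum(tt$nonsyn), 8 / 3)
  gg <- classify_codon_sites("GGG")
  expect_equal(gg$syn[3], 1)
  expect_equal(nrow(classify_codon_sites("TAA")), 0)
  # every sense codon against the independent enumeration oracle
  codons <- names(GEN_CODE)[GEN_CODE != "*"]
  for (cod in codons) {
    expect_equal(classify_codon_sites(cod)$syn, oracle_ng86_codon(cod),
                 tolerance = 1e-12, label = cod)
  }
})

test_that("site counts sum to 3 per usable codon", {
  withr::with_seed(21, {
    codons <- sample(names(GEN_CODE)[GEN_CODE != "*"], 30, replace = TRUE)
    haps <- rep(paste(codons, collapse = ""), 4)
  })
  st <- codon_site_stats(aln_from_strings(haps))
  expect_equal(st$syn_sites + st$nonsyn_sites, 3 * st$codons_used,
               tolerance = 1e-9)
  expect_equal(st$codons_used, 30)
})

test_that("piS for two haplotypes differing at one synonymous unit", {
  # GGA<->GGG is synonymous; 100 codons, one polymorphic third position
  base <- strrep("GGA", 100)
  h2 <- paste0(substr(base, 1, 299), "G")
  st <- codon_site_stats(aln_from_strings(c(base, h2)))
  expect_equal(st$syn_diffs, 1)          # n=2 unbiased per-site diff = 1
  expect_equal(st$pi_s, 1 / st$syn_sites)
  # identical haplotypes give zero diversity
  st0 <- codon_site_stats(aln_from_strings(c(base, base)))
  expect_equal(st0$pi_n + st0$pi_s, 0)
})

test_that("piN/piS equals the all-pairs brute-force oracle", {
  withr::with_seed(31, {
    sense <- names(GEN_CODE)[GEN_CODE != "*"]
    base <- sample(sense, 40, replace = TRUE)
    haps <- replicate(6, {
      cod <- base
      for (k in sample(40, 5)) {
        b <- strsplit(cod[k], "")[[1]]
        j <- sample(3, 1)
        b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
        cand <- paste(b, collapse = "")
        if (GEN_CODE[[cand]] != "*") cod[k] <- cand
      }
      paste(cod, collapse = "")
    })
  })
  aln <- aln_from_strings(haps)
  got <- pi_n_pi_s(codon_site_stats(aln))
  want <- oracle_pi_classes(aln$seqs)
  # all-pairs difference proportion equals 2p(1-p) n/(n-1) exactly
  expect_equal(got$syn_sites, want$syn_sites, tolerance = 1e-9)
  expect_equal(got$nonsyn_sites, want$nonsyn_sites, tolerance = 1e-9)
  expect_equal(got$pi_s, want$pi_s, tolerance = 1e-12)
  expect_equal(got$pi_n, want$pi_n, tolerance = 1e-12)
})

test_that("gc3 counts third positions and excludes N-only columns", {
  st <- codon_site_stats(aln_from_strings(c("GACGAT", "GACGAT")))
  expect_equal(st$gc3, 0.5)
  st2 <- codon_site_stats(aln_from_strings(c("GGGCCC", "GGGCCC")))
  expect_equal(st2$gc3, 1)
  st3 <- gc3(aln_from_strings(c("ATGGAN", "ATGGAN")))
  expect_equal(st3$gc3, 1)               # only the G third position usable
  expect_equal(st3$third_positions_used, 1)
})

test_that("gene-space windows pack greedily and flag the trailing window", {
  stats <- tibble(gene_id = sprintf("g%02d", 1:10),
                  syn_sites = 10, nonsyn_sites = 30,
                  syn_diffs = 1, nonsyn_diffs = 1)
  gm <- tibble(gene_id = stats$gene_id, chrom = "chr1",
               start = seq(1, by = 2e6, length.out = 10), cds_len = 1e6)
  w <- window_pinpis(stats, gm, window_span = 4e6)
  expect_equal(nrow(w), 3)
  expect_equal(w$cds_len, c(4e6, 4e6, 2e6))
  expect_equal(w$complete, c(TRUE, TRUE, FALSE))
  expect_false(any(w$short))
  # permuting gene order within the same windows leaves pi unchanged
  w2 <- window_pinpis(stats[sample(10), ], gm, window_span = 4e6)
  expect_equal(w$ratio, w2$ratio)
  # a single gene larger than the span gets its own complete window
  w3 <- window_pinpis(stats[1, ], gm[1, ] |> dplyr::mutate(cds_len = 5e6),
                      window_span = 4e6)
  expect_equal(nrow(w3), 1)
  expect_true(w3$complete)
})

test_that("GC3 bins are equal-count with non-decreasing medians", {
  withr::with_seed(5, {
    stats <- tibble(gene_id = sprintf("g%03d", 1:100),
                    gc3 = runif(100, 0.3, 0.8),
                    syn_sites = 10, nonsyn_sites = 30,
                    syn_diffs = runif(100), nonsyn_diffs = runif(100))
  })
  b <- bin_genes_by_gc3(stats, n_bins = 10)
  expect_equal(b$n_genes, rep(10, 10))
  expect_true(all(diff(b$gc3_median) >= 0))
  same <- bin_genes_by_gc3(stats |> dplyr::mutate(gc3 = 0.5), n_bins = 4)
  expect_true(all(same$gc3_median == 0.5))
  expect_error(bin_genes_by_gc3(stats, n_bins = 101), "more bins")
})

test_that("GC-conservative filter keeps only A/T and C/G pairs", {
  g <- toy_geno(matrix(0L, 2, 3), ref = c("A", "A", "C"),
                alt = c("T", "G", "G"))
  kept <- gc_conservative_filter(g)
  expect_equal(kept$sites$pos, g$sites$pos[c(1, 3)])
})
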