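# Small configurations keep these runs to seconds; the full-scale surfing
# replicates live in the acceptance suite.
small_cfg <- function(seed, ...) {
  expansion_config(n_demes = 3, N = 80, K = 10, T_found = 30, burnin = 240,
                   post_gens = 40, n_genes = 24, n_sample = 6, seed = seed,
                   ...)
}

test_that("PRF sampler: determinism, empty class, and expectation", {
  s1 <- sample_prf_sfs(10, 500, 800, shape = 0.3, mean_Sd = -100, seed = 4)
  s2 <- sample_prf_sfs(10, 500, 800, shape = 0.3, mean_Sd = -100, seed = 4)
  expect_identical(s1$syn_sfs, s2$syn_sfs)
  expect_identical(s1$nonsyn_sfs, s2$nonsyn_sfs)
  s0 <- sample_prf_sfs(10, 500, 0, shape = 0.3, mean_Sd = -100, seed = 4)
  expect_true(all(s0$nonsyn_sfs == 0))
  # law of large numbers on the singleton class
  e <- expected_sfs(10, 500, 800, shape = 0.3, mean_Sd = -100)
  draws <- vapply(1:300, function(k) {
    sample_prf_sfs(10, 500, 800, shape = 0.3, mean_Sd = -100,
                   seed = 1000 + k)$syn_sfs[1]
  }, numeric(1))
  se <- sqrt(e$syn[1] / 300)
  expect_lt(abs(mean(draws) - e$syn[1]), 3 * se)
})

test_that("single-locus fixation probabilities match the diffusion formula", {
  N <- 100
  for (S in c(-2, 0, 2)) {
    s <- -S / (2 * N)             # additive per-allele effect a = -s/2
    got <- fixation_probability(N, s, h = 0.5, n_trials = 6e4, seed = 71)
    want <- fixation_rel(S) / (2 * N)
    se <- sqrt(want * (1 - want) / got$trials)
    expect_lt(abs(got$p_fix - want), 4 * se + 1e-12)
  }
})

test_that("simulation output is deterministic and internally consistent", {
  sim1 <- simulate_expansion(small_cfg(42))
  sim2 <- simulate_expansion(small_cfg(42))
  expect_identical(sim1$geno, sim2$geno)
  expect_identical(sim1$sites$pos, sim2$sites$pos)
  expect_true(all(sim1$deme_freq >= 0 & sim1$deme_freq <= 1))
  expect_true(all(sim1$sites$effect %in% c("synonymous", "missense", "lof")))
  # synonymous truth carries s = 0, lof sits in the deleterious tail
  expect_true(all(sim1$sites$s[sim1$sites$effect == "synonymous"] == 0))
  lof_s <- sim1$sites$s[sim1$sites$effect == "lof"]
  mis_s <- sim1$sites$s[sim1$sites$effect == "missense" & sim1$sites$s > 0]
  if (length(lof_s) && length(mis_s)) expect_gt(min(lof_s), max(0, min(mis_s)))
})

test_that("no-founder-effect control shows no heterozygosity gradient", {
  cfg <- expansion_config(n_demes = 4, N = 100, K = 100, T_found = 25,
                          burnin = 300, post_gens = 50, n_genes = 30,
                          m = 0.2, growth_rate = 2, capacity_gradient = 0,
                          n_sample = 8, seed = 77)
  sim <- simulate_expansion(cfg)
  vd <- as_variant_data(sim)
  ho <- observed_heterozygosity(vd$geno, vd$popmap)
  fit <- lm(ho$ho ~ seq_len(nrow(ho)))
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("neutral single-deme equilibrium has Tajima's D near zero", {
  dvals <- vapply(1:12, function(k) {
    cfg <- expansion_config(n_demes = 1, N = 120, K = 120, burnin = 480,
                            post_gens = 0, n_genes = 20, n_sample = 10,
                            capacity_gradient = 0, neutral = TRUE, seed = k)
    sim <- simulate_expansion(cfg)
    vd <- as_variant_data(sim)
    tajimas_d(vd$geno, vd$popmap, window_bp = 1e7)$summary$tajima_d_mean
  }, numeric(1))
  expect_lt(abs(mean(dvals)), 0.3)
})

test_that("polarization recovers the true ancestral states", {
  sim <- simulate_expansion(small_cfg(7))
  vd <- as_variant_data(sim)
  asg <- infer_ancestral(vd$geno, vd$outgroup)
  assigned <- !is.na(asg$anc_base)
  acc <- mean(asg$anc_base[assigned] == vd$truth$ancestral_base[assigned])
  expect_gt(mean(assigned), 0.85)
  expect_gt(acc, 0.95)
  # and derived frequencies line up with the simulation truth
  pol <- polarize_genotypes(vd$geno, asg)
  keep <- paste(vd$truth$chrom, vd$truth$pos) %in%
    paste(pol$sites$chrom, pol$sites$pos)
  truth_freq <- colSums(sim$geno[, keep, drop = FALSE]) /
    (2 * nrow(sim$geno))
  obs_freq <- colSums(pol$geno, na.rm = TRUE) /
    (2 * colSums(!is.na(pol$geno)))
  expect_gt(cor(truth_freq, obs_freq, method = "spearman"), 0.99)
})

test_that("emitted files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_expansion(small_cfg(13))
  manifest <- emit_dataset(sim, dir)
  expect_true(all(file.exists(manifest$file)))
  expect_false(anyNA(manifest$md5))
  vd <- as_variant_data(sim)
  g <- read_variants(file.path(dir, "focal.vcf"),
                     file.path(dir, "effects.tsv"))
  expect_identical(unname(g$geno), unname(vd$geno$geno))
  expect_equal(g$sites$effect, vd$geno$sites$effect)
  # truth table covers every emitted variant
  truth <- readr::read_tsv(file.path(dir, "truth_sites.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(g$sites))
  # gene models parse and CDS spans sit inside the FASTA
  gm <- load_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(nrow(gm), 24)
  expect_true(all(gm$in_frame))
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(ref) <- sub(" .*", "", names(ref))
  expect_true(all(gm$end <= Biostrings::width(ref)[match(gm$chrom,
                                                         names(ref))]))
  # reconstruction from files equals reconstruction from memory
  aln1 <- reconstruct_cds_alignment(gm, g, as.character(ref), seed = 3)
  aln2 <- reconstruct_cds_alignment(vd$gene_models, vd$geno, vd$ref, seed = 3)
  expect_identical(aln1$seqs, aln2$seqs)
  # outgroup panel and popmap load cleanly
  og <- read_outgroup_panel(file.path(dir, "outgroup.vcf"))
  expect_equal(length(og$samples), 15)
  pm <- read_popmap(file.path(dir, "popmap.tsv"))
  expect_equal(nrow(pm), nrow(sim$popmap))
})
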