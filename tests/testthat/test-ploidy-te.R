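toy_models <- function(chroms, starts = NULL) {
  n <- length(chroms)
  if (is.null(starts)) starts <- seq(1000L, by = 10000L, length.out = n)
  tibble(gene_id = sprintf("g%03d", seq_len(n)), chrom = chroms,
         start = starts, end = starts + 999L, cds_len = 900L)
}

test_that("chromosome rule and BED override assign compartments", {
  gm <- toy_models(c("chr12", "chr33", "chr12"))
  part <- assign_ploidy(gm)
  expect_equal(part$compartment, c("diploid", "tetraploid", "diploid"))
  bed <- tibble(chrom = "chr12", start = 500L, end = 2500L,
                label = "tetraploid")
  part2 <- assign_ploidy(gm, tetraploid_regions = bed)
  expect_equal(part2$compartment, c("tetraploid", "tetraploid", "diploid"))
  gm3 <- toy_models(c("chr12", "scaffold_x"))
  part3 <- suppressMessages(assign_ploidy(gm3))
  expect_equal(nrow(part3), 1)   # unassignable gene dropped
})

fake_stats <- function(n, ratio_scale = 1, seed = 1) {
  withr::with_seed(seed, tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    gc3 = runif(n, 0.3, 0.7),
    syn_sites = 50, nonsyn_sites = 150,
    syn_diffs = runif(n, 0.5, 1.5),
    nonsyn_diffs = runif(n, 0.5, 1.5) * ratio_scale
  ))
}

test_that("diploid resampling null is seed-stable with a sane quantile", {
  stats <- fake_stats(80)
  part <- tibble(gene_id = stats$gene_id,
                 compartment = rep(c("diploid", "tetraploid"), c(60, 20)))
  r1 <- suppressMessages(resample_diploid_load(stats, part, n_resamples = 50,
                                               genes_per_set = 4000, seed = 9))
  r2 <- suppressMessages(resample_diploid_load(stats, part, n_resamples = 50,
                                               genes_per_set = 4000, seed = 9))
  expect_identical(r1$null, r2$null)
  expect_equal(length(r1$null), 50)
  expect_lt(r1$genes_per_set, 60)        # scaled down, with a message
  expect_gte(r1$quantile, 0); expect_lte(r1$quantile, 1)
  # an inflated tetraploid set sits above the whole null
  stats_hi <- stats
  stats_hi$nonsyn_diffs[61:80] <- stats_hi$nonsyn_diffs[61:80] * 20
  r3 <- suppressMessages(resample_diploid_load(stats_hi, part,
                                               n_resamples = 50, seed = 9))
  expect_true(all(r3$null < r3$observed))
  expect_gt(r3$quantile, 0.98)
  # identical genes everywhere: degenerate null, midrank quantile 1/2
  stats_flat <- stats |>
    dplyr::mutate(syn_diffs = 1, nonsyn_diffs = 1)
  r4 <- suppressMessages(resample_diploid_load(stats_flat, part,
                                               n_resamples = 50, seed = 9))
  expect_equal(r4$quantile, 0.5, tolerance = 0.01)
})

test_that("negative control: relabeled diploid genes fall inside the null", {
  stats <- fake_stats(120, seed = 4)
  withr::with_seed(11, fake_tetra <- sample(stats$gene_id, 30))
  part <- tibble(gene_id = stats$gene_id,
                 compartment = ifelse(stats$gene_id %in% fake_tetra,
                                      "tetraploid", "diploid"))
  r <- suppressMessages(resample_diploid_load(stats, part, n_resamples = 200,
                                              seed = 2))
  expect_gt(r$quantile, 0.025)
  expect_lt(r$quantile, 0.975)
})

test_that("GC-matched contrast is null for identical compartments", {
  # mirror-image compartments: same stats, same window layout
  n <- 40
  stats <- fake_stats(n, seed = 7)
  gm <- toy_models(rep(c("chr1", "chr31"), each = n / 2),
                   starts = rep(seq(1000L, by = 10000L, length.out = n / 2), 2))
  stats$gc3 <- rep(stats$gc3[1:(n / 2)], 2)
  stats$syn_diffs <- rep(stats$syn_diffs[1:(n / 2)], 2)
  stats$nonsyn_diffs <- rep(stats$nonsyn_diffs[1:(n / 2)], 2)
  part <- assign_ploidy(gm)
  ct <- gc_matched_contrast(stats, part, gm, gc_window_mb = 0.02, n_bins = 2)
  wide <- tidyr::pivot_wider(ct[, c("compartment", "gc_bin", "ratio")],
                             names_from = "compartment",
                             values_from = "ratio")
  expect_equal(wide$diploid, wide$tetraploid, tolerance = 1e-12)
  expect_true(any(ct$lowest))
})

test_that("TE comparison: relative lengths and exact U statistic", {
  te <- tibble(chrom = c("chr1", rep(c("chr1", "chr31"), each = 10)),
               start = 0L,
               end = c(1000L, 101:110 * 10L, 201:210 * 10L),
               label = "TE:LINE")
  lens <- tibble(chrom = c("chr1", "chr31"), length = c(1e6, 1e6))
  comp <- tibble(chrom = c("chr1", "chr31"),
                 compartment = c("diploid", "tetraploid"))
  res <- te_compare(te[1, ], dplyr::bind_rows(comp, comp), lens) |>
    try(silent = TRUE)          # single compartment errors
  expect_s3_class(res, "try-error")
  res2 <- te_compare(te[-1, ], comp, lens)
  expect_equal(res2$per_te$rel_len[1], 1010 / 1e6)
  # U from wilcox.test equals the exhaustive midrank computation
  x <- res2$per_te$rel_len[res2$per_te$compartment == "diploid"]
  y <- res2$per_te$rel_len[res2$per_te$compartment == "tetraploid"]
  expect_equal(unname(res2$test$statistic), oracle_mann_whitney_u(x, y))
  # identical sets in both compartments: two-sided p = 1
  te_same <- dplyr::bind_rows(
    te[2:11, ],
    te[2:11, ] |> dplyr::mutate(chrom = "chr31")
  )
  res3 <- te_compare(te_same, comp, lens)
  expect_equal(res3$test$p_value, 1, tolerance = 1e-9)
})
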