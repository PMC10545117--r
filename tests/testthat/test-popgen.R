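test_that("observed heterozygosity matches a hand recount", {
  g <- toy_geno(matrix(1L, 4, 1))
  pm <- toy_popmap(g$samples, rep("p1", 4))
  expect_equal(observed_heterozygosity(g, pm)$ho, 1)
  g0 <- toy_geno(matrix(c(0L, 2L, 2L, 0L), 4, 1))
  expect_equal(observed_heterozygosity(g0, pm)$ho, 0)
  dos <- random_geno(6, 30, seed = 2)
  g2 <- toy_geno(dos)
  pm2 <- toy_popmap(g2$samples, rep(c("a", "b"), each = 3))
  got <- observed_heterozygosity(g2, pm2)
  for (p in c("a", "b")) {
    sub <- dos[match(pm2$sample[pm2$population == p], g2$samples), ]
    vals <- c()
    for (v in seq_len(ncol(sub))) {
      x <- sub[, v][!is.na(sub[, v])]
      if (length(x)) vals <- c(vals, mean(x == 1))
    }
    expect_equal(got$ho[got$population == p], mean(vals), tolerance = 1e-12)
  }
})

test_that("beta_st matches draw-pair enumeration and is allele-label invariant", {
  dos1 <- rbind(c(0L, 2L), c(1L, 2L), c(0L, 1L))
  dos2 <- rbind(c(2L, 0L), c(2L, 1L), c(1L, 0L))
  g <- toy_geno(rbind(dos1, dos2))
  pm <- toy_popmap(g$samples, rep(c("a", "b"), each = 3))
  got <- beta_st(g, pm)
  want <- oracle_beta_st(list(dos1, dos2))
  expect_equal(got$beta_st, want, tolerance = 1e-12)
  # relabeling ref/alt (dosage 2 - x) leaves beta unchanged
  g2 <- toy_geno(rbind(2L - dos1, 2L - dos2))
  expect_equal(beta_st(g2, pm)$beta_st, got$beta_st, tolerance = 1e-12)
  # duplicated samples are exchangeable: equal beta in both populations
  # (the distinct-draw within-population matching makes the shared value
  # slightly negative on finite samples, as for the enumeration oracle)
  g3 <- toy_geno(rbind(dos1, dos1))
  b3 <- beta_st(g3, pm)$beta_st
  expect_equal(b3[1], b3[2], tolerance = 1e-12)
  expect_equal(b3, oracle_beta_st(list(dos1, dos1)), tolerance = 1e-12)
})

test_that("Tajima's D matches the closed-form oracle and handles S = 0", {
  # n = 4 haploids (2 diploids would be n=4): use 2 diploids? need >= 4 haps
  dos <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L))   # 3 singleton sites, n = 4
  g <- toy_geno(dos)
  pm <- toy_popmap(g$samples, c("p1", "p1"))
  d <- tajimas_d(g, pm, window_bp = 1e6, min_s = 3)
  expect_lt(d$summary$tajima_d_mean, 0)        # all singletons push D down
  # windows with no segregating sites are missing
  g0 <- toy_geno(matrix(0L, 2, 3))
  d0 <- tajimas_d(g0, pm, window_bp = 1e6)
  expect_true(all(is.na(d0$windows$D)))
  # random windows against the from-scratch formula
  withr::with_seed(9, {
    for (rep in 1:20) {
      n_ind <- sample(3:6, 1)
      dos <- matrix(sample(0:2, n_ind * 25, replace = TRUE), n_ind)
      g <- toy_geno(dos)
      pm <- toy_popmap(g$samples, rep("p", n_ind))
      got <- tajimas_d(g, pm, window_bp = 1e6, min_s = 1)$windows
      n <- 2 * n_ind
      frq <- colSums(dos) / n
      seg <- frq > 0 & frq < 1
      pi_sum <- sum(2 * frq[seg] * (1 - frq[seg]) * n / (n - 1))
      want <- oracle_tajima_d(pi_sum, sum(seg), n)
      expect_equal(got$D, want, tolerance = 1e-9)
    }
  })
})

test_that("Weir-Cockerham FST: fixed difference, null case, and components", {
  gA <- matrix(2L, 4, 5); gB <- matrix(0L, 4, 5)
  g <- toy_geno(rbind(gA, gB))
  pm <- toy_popmap(g$samples, rep(c("a", "b"), each = 4))
  expect_equal(wc_fst(g, pm)["a", "b"], 1, tolerance = 1e-12)
  withr::with_seed(13, {
    frq <- runif(1000, 0.2, 0.8)
    mk <- function() t(replicate(8, rbinom(1000, 2, frq)))
    g2 <- toy_geno(rbind(mk(), mk()))
  })
  pm2 <- toy_popmap(g2$samples, rep(c("a", "b"), each = 8))
  expect_lt(abs(wc_fst(g2, pm2)["a", "b"]), 0.02)
  # variance-components brute force on a small toy
  d1 <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L))
  d2 <- rbind(c(2L, 2L, 0L), c(2L, 1L, 0L), c(1L, 2L, 1L))
  g3 <- toy_geno(rbind(d1, d2))
  pm3 <- toy_popmap(g3$samples, rep(c("a", "b"), each = 3))
  expect_equal(wc_fst(g3, pm3)["a", "b"], oracle_wc_fst(d1, d2),
               tolerance = 1e-12)
})

test_that("LD decay: duplicated site has r2 = 1; independence limit", {
  withr::with_seed(4, x <- sample(0:2, 40, replace = TRUE))
  dos <- cbind(x, x, sample(x))
  g <- toy_geno(dos, pos = c(100L, 600L, 5000L))
  pm <- toy_popmap(g$samples, rep("p", 40))
  curve <- ld_decay(g, pm, maf = 0.05, max_dist_bp = 1e4, n_bins = 6)
  near <- curve[which.min(curve$dist_mid), ]
  expect_equal(near$mean_r2, 1, tolerance = 1e-12)
  # independent sites: mean r2 near the 1/n sampling bias level
  withr::with_seed(8, {
    dos2 <- matrix(rbinom(50 * 60, 2, 0.5), 50)
  })
  g2 <- toy_geno(dos2, pos = seq(100L, by = 50L, length.out = 60))
  curve2 <- ld_decay(g2, toy_popmap(g2$samples, rep("p", 50)),
                     maf = 0.05, max_dist_bp = 3000, n_bins = 4)
  expect_lt(mean(curve2$mean_r2), 3 / 50)
  hm <- ld_halfmax(curve)
  expect_true(is.finite(hm$halfmax_bp))
})

test_that("NJ tree recovers an additive topology and roots by beta_st", {
  # additive 4-taxon matrix: ((a,b),(c,d))
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 0.2
  dm["a", "c"] <- dm["c", "a"] <- 0.7
  dm["a", "d"] <- dm["d", "a"] <- 0.8
  dm["b", "c"] <- dm["c", "b"] <- 0.7
  dm["b", "d"] <- dm["d", "b"] <- 0.8
  dm["c", "d"] <- dm["d", "c"] <- 0.3
  beta <- tibble(population = letters[1:4], beta_st = c(-0.1, 0, 0.1, 0.2))
  tr <- fst_tree(dm, beta = beta)
  expect_equal(tr$root_population, "a")
  expect_true(ape::is.monophyletic(ape::unroot(tr$tree), c("c", "d")))
  expect_equal(sort(tr$root_distance$population), letters[1:4])
  expect_true(all(tr$root_distance$root_distance >= 0))
  # ultrametric 3-taxon distances give equal root-to-leaf depths
  dm3 <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dm3) <- 0
  tr3 <- fst_tree(dm3, root = "a")
  d3 <- tr3$root_distance$root_distance[tr3$root_distance$population != "a"]
  expect_equal(d3[1], d3[2], tolerance = 1e-9)
})
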