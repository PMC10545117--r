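test_that("neutral expectations are analytic: E[syn_i] = theta r_i / i", {
  n <- 10
  e <- expected_sfs(n, theta_s = 1, theta_n = 1, shape = 0.3, mean_Sd = -100)
  expect_equal(e$syn, 1 / (1:9), tolerance = 1e-10)
  r <- c(1, runif(n - 2, 0.5, 2))
  e2 <- expected_sfs(n, theta_s = 3, theta_n = 1, shape = 0.3,
                     mean_Sd = -100, r = r)
  expect_equal(e2$syn, 3 * r / (1:9), tolerance = 1e-10)
})

test_that("sojourn density: neutral limit 1/x and stability at strong S", {
  x <- seq(0.01, 0.99, by = 0.01)
  expect_equal(sojourn_density(x, 1e-9), 1 / x, tolerance = 1e-8)
  expect_equal(sojourn_density(x, -1e-6), 1 / x, tolerance = 1e-4)
  h <- sojourn_density(x, -1e5)
  expect_true(all(is.finite(h)) && all(h >= 0))
  expect_lt(h[50], 1e-10)                     # e^{-Sx} collapse
})

test_that("misorientation eps = 0.5 symmetrizes the spectra", {
  e <- expected_sfs(10, 2, 5, shape = 0.5, mean_Sd = -50, eps_anc = 0.4999)
  expect_equal(e$nonsyn, rev(e$nonsyn), tolerance = 1e-3)
  e0 <- expected_sfs(10, 2, 5, shape = 0.5, mean_Sd = -50, eps_anc = 0)
  expect_gt(e0$nonsyn[1], e0$nonsyn[9])       # polarized spectrum is skewed
})

test_that("strong purifying selection enriches singletons (quadrature oracle)", {
  n <- 10
  # independent fine-grid oracle with stats::integrate per class
  oracle_class <- function(S, i) {
    stats::integrate(function(x) {
      (1 - exp(-S * (1 - x))) / (x * (1 - x) * (1 - exp(-S))) *
        choose(n, i) * x^i * (1 - x)^(n - i)
    }, 0, 1, rel.tol = 1e-10)$value
  }
  I_oracle <- vapply(1:(n - 1), function(i) oracle_class(-100, i), numeric(1))
  grid <- surfload:::prf_grid(n)
  k <- which.min(abs(grid$del$S_abs - 100))
  S_used <- -grid$del$S_abs[k]
  I_pkg <- grid$del$I[, k]
  I_oracle2 <- vapply(1:(n - 1), function(i) oracle_class(S_used, i),
                      numeric(1))
  expect_equal(I_pkg, I_oracle2, tolerance = 1e-6)
  # singleton fraction exceeds the neutral value under strong selection
  expect_gt(I_oracle[1] / sum(I_oracle), (1 / 1) / sum(1 / (1:(n - 1))))
})

test_that("the fitted DFE density integrates to one", {
  grid <- surfload:::prf_grid(8)
  for (shape in c(0.1, 0.3, 1, 3)) {
    for (mean_abs in c(0.5, 10, 1000, 1e4)) {
      gw <- surfload:::gamma_grid_weights(grid, shape, mean_abs)
      expect_equal(sum(gw$w) + gw$p_small + gw$p_tail, 1, tolerance = 1e-8)
    }
  }
})

test_that("relative fixation probability matches its diffusion definition", {
  expect_equal(fixation_rel(0), 1)
  expect_equal(fixation_rel(-2), 2 * exp(-2) / (1 - exp(-2)),
               tolerance = 1e-12)
  # numeric limit of (1 - e^{-S/2N x0})/(1 - e^{-S}) / (1/2N) as x0 -> 0
  for (S in c(-5, -2, 2)) {
    x0 <- 1e-9
    expect_equal(fixation_rel(S), (1 - exp(-S * x0)) / (1 - exp(-S)) / x0,
                 tolerance = 1e-6)
  }
  # monotone increasing in S
  expect_true(all(diff(fixation_rel(seq(-50, 10, by = 1))) > 0))
})

test_that("selection summary identities are exact", {
  sfs <- new_sfs_pair(8, rep(10, 7), rep(20, 7), 1000, 3000,
                      D_syn = 60, D_nonsyn = 27)
  fit <- fit_gamma_expo(sfs, "GammaZero", n_starts = 2, seed = 1,
                        fit_distortion = FALSE, fit_misorientation = FALSE)
  s <- selection_summary(fit)
  expect_equal(s$dnds_obs, (27 / 3000) / (60 / 1000), tolerance = 1e-12)
  expect_equal(s$omega_a + s$omega_na, s$dnds_obs, tolerance = 1e-12)
  expect_equal(s$alpha, s$omega_a / s$dnds_obs, tolerance = 1e-12)
  expect_lte(s$alpha, 1)
  expect_gte(s$omega_na, 0)
})

test_that("a neutral DFE implies omega_na and piN/piS of one", {
  # all DFE mass below the neutral cutoff
  e <- expected_sfs(10, 1, 1, shape = 0.3, mean_Sd = -1e-5)
  expect_equal(e$nonsyn, e$syn, tolerance = 1e-6)
  sfs <- sample_prf_sfs(10, 4000, 4000, shape = 0.3, mean_Sd = -1e-5,
                        seed = 2, L_syn = 1e5, L_nonsyn = 1e5)
  fit <- fit_gamma_expo(sfs, "GammaZero", n_starts = 4, seed = 3,
                        fit_distortion = FALSE, fit_misorientation = FALSE)
  expect_equal(dfe_expected_pinpis(fit), 1, tolerance = 0.05)
})

test_that("stronger purifying selection lowers expected piN/piS and omega_na", {
  fits <- lapply(c(-1, -100, -5000), function(ms) {
    list(n = 10, params = list(shape = 0.4, mean_Sd = ms, p_b = 0,
                               mean_Sb = 1))
  })
  pp <- vapply(fits, function(f) {
    class(f) <- "surf_dfe_fit"
    dfe_expected_pinpis(f)
  }, numeric(1))
  expect_true(all(diff(pp) < 0))
  om <- vapply(c(-1, -100, -5000), function(ms) {
    grid <- surfload:::prf_grid(10)
    gw <- surfload:::gamma_grid_weights(grid, 0.4, abs(ms))
    sum(gw$w * fixation_rel(-grid$del$S_abs)) + gw$p_small
  }, numeric(1))
  expect_true(all(diff(om) < 0))
})

test_that("distortion-free data do not reject the simple model", {
  sfs <- sample_prf_sfs(8, 3000, 3000, shape = 0.3, mean_Sd = -300,
                        seed = 11, L_syn = 1e5, L_nonsyn = 1e5)
  full <- fit_gamma_expo(sfs, "GammaZero", n_starts = 3, seed = 1)
  simple <- fit_gamma_expo(sfs, "GammaZero", n_starts = 3, seed = 1,
                           fit_distortion = FALSE, fit_misorientation = FALSE)
  extra_df <- full$n_par - simple$n_par
  lrt <- 2 * (full$loglik - simple$loglik)
  expect_gte(lrt, -1e-6)
  expect_lt(lrt, qchisq(0.99, extra_df))
})

test_that("dofe text format round-trips", {
  sfs <- new_sfs_pair(8, c(5, 4, 3, 2, 2, 1, 1), c(9, 6, 4, 3, 2, 2, 1),
                      500, 1500, D_syn = 12, D_nonsyn = 20)
  path <- withr::local_tempfile(fileext = ".dofe")
  write_dofe(sfs, path, name = "toy")
  back <- read_dofe(path)
  expect_equal(back$syn_sfs, sfs$syn_sfs)
  expect_equal(back$nonsyn_sfs, sfs$nonsyn_sfs)
  expect_equal(back$L_syn, sfs$L_syn)
  expect_equal(back$D_nonsyn, sfs$D_nonsyn)
  expect_equal(readLines(path)[1], "#unfolded")
})
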