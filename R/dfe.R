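# Poisson random field machinery for estimating the distribution of fitness
# effects (gamma deleterious + exponential beneficial, "GammaExpo") from an
# unfolded SFS pair, and deriving alpha / omegaA / omegaNA from observed
# divergence. Scaled coefficients use S = 4*Ne*s (negative = deleterious)
# and the relative fixation probability u(S) = S / (1 - exp(-S)), u(0) = 1.

#' Unfolded SFS pair
#'
#' Bundle of synonymous and nonsynonymous unfolded site-frequency spectra
#' with analyzed site totals and substitution counts to the outgroup.
#'
#' @param n haploid sample size (>= 4).
#' @param syn_sfs,nonsyn_sfs numeric vectors of length `n - 1` (class
#'   `i = 1..n-1`); fractional counts from hypergeometric projection are
#'   allowed.
#' @param L_syn,L_nonsyn analyzed synonymous / nonsynonymous site totals.
#' @param D_syn,D_nonsyn substitution counts to the outgroup.
#' @param filter_log optional tibble recording what was filtered.
#' @return Object of class `surf_sfs`.
#' @export
new_sfs_pair <- function(n, syn_sfs, nonsyn_sfs, L_syn, L_nonsyn,
                         D_syn = NA_real_, D_nonsyn = NA_real_,
                         filter_log = NULL) {
  n <- as.integer(n)
  if (n < 4) abort("haploid sample size must be >= 4")
  stopifnot(length(syn_sfs) == n - 1, length(nonsyn_sfs) == n - 1)
  if (any(syn_sfs < 0) || any(nonsyn_sfs < 0)) abort("SFS counts must be >= 0")
  if (sum(syn_sfs) > L_syn + 1e-9 || sum(nonsyn_sfs) > L_nonsyn + 1e-9) {
    abort("SFS counts exceed analyzed site totals")
  }
  structure(list(n = n, syn_sfs = as.numeric(syn_sfs),
                 nonsyn_sfs = as.numeric(nonsyn_sfs),
                 L_syn = L_syn, L_nonsyn = L_nonsyn,
                 D_syn = D_syn, D_nonsyn = D_nonsyn,
                 filter_log = filter_log),
            class = "surf_sfs")
}

#' @export
print.surf_sfs <- function(x, ...) {
  cat(sprintf(
    "<surf_sfs> n=%d | syn: %.1f SNPs / %.0f sites, D=%.0f | nonsyn: %.1f SNPs / %.0f sites, D=%.0f\n",
    x$n, sum(x$syn_sfs), x$L_syn, x$D_syn,
    sum(x$nonsyn_sfs), x$L_nonsyn, x$D_nonsyn))
  invisible(x)
}

#' Sojourn density of a derived allele under selection
#'
#' `H(x; S) = (1 - exp(-S(1-x))) / (x (1-x) (1 - exp(-S)))`, the expected
#' time a new semidominant mutation with scaled coefficient `S = 4*Ne*s`
#' spends at frequency `x` (up to a constant absorbed into theta). The
#' neutral limit is `1/x`. Evaluated in a numerically stable form for
#' strongly deleterious S.
#'
#' @param x frequencies in (0, 1).
#' @param S scaled selection coefficient (negative = deleterious).
#' @return Numeric vector of densities.
#' @export
sojourn_density <- function(x, S) {
  if (abs(S) < 1e-8) return(1 / x)
  if (S < 0) {
    t <- -S
    exp(-t * x) * (1 - exp(-t * (1 - x))) / ((1 - exp(-t)) * x * (1 - x))
  } else {
    (1 - exp(-S * (1 - x))) / (x * (1 - x) * (1 - exp(-S)))
  }
}

#' Relative fixation probability
#'
#' `u(S) = S / (1 - exp(-S))` with `u(0) = 1`: the fixation probability of a
#' new mutation relative to a neutral one under the diffusion approximation.
#'
#' @param S scaled selection coefficient(s).
#' @return Numeric vector.
#' @export
fixation_rel <- function(S) {
  out <- numeric(length(S))
  tiny <- abs(S) < 1e-8
  out[tiny] <- 1
  neg <- !tiny & S < 0
  t <- -S[neg]
  out[neg] <- t * exp(-t) / (1 - exp(-t))
  pos <- !tiny & S > 0
  out[pos] <- S[pos] / (1 - exp(-S[pos]))
  out
}

# Gauss-Legendre nodes/weights on [a, b]
gl_nodes <- function(n, a, b) {
  g <- pracma::gaussLegendre(n, a, b)
  list(x = g$x, w = g$w)
}

# Quadrature scaffolding for one sample size: binomial-weighted sojourn
# integrals I_i(S) on fixed log-spaced S grids (deleterious and beneficial).
prf_grid_cache <- new.env(parent = emptyenv())

prf_grid <- function(n, n_x_log = 220, n_x_lin = 64, n_s = 160,
                     s_lo = 1e-4, s_hi_del = 1e5, s_hi_ben = 1e4) {
  key <- paste(n, n_x_log, n_x_lin, n_s, sep = "_")
  if (!is.null(prf_grid_cache[[key]])) return(prf_grid_cache[[key]])
  # x-quadrature: log panel near 0 plus linear panel to 1
  lp <- gl_nodes(n_x_log, log(1e-9), log(0.5))
  xp1 <- exp(lp$x); wp1 <- lp$w * xp1
  lp2 <- gl_nodes(n_x_lin, 0.5, 1 - 1e-12)
  x <- c(xp1, lp2$x); w <- c(wp1, lp2$w)
  i_vec <- seq_len(n - 1)
  logB <- outer(i_vec, x, function(i, xx) {
    lchoose(n, i) + i * log(xx) + (n - i) * log1p(-xx)
  })
  B <- exp(logB)                              # (n-1) x n_x
  Bw <- sweep(B, 2, w, `*`)
  grid_half <- function(s_hi, sign) {
    gs <- gl_nodes(n_s, log10(s_lo), log10(s_hi))
    S_abs <- 10^gs$x
    I <- vapply(seq_along(S_abs), function(k) {
      as.numeric(Bw %*% sojourn_density(x, sign * S_abs[k]))
    }, numeric(n - 1))
    list(S_abs = S_abs, t_w = gs$w, I = I)    # I: (n-1) x n_s
  }
  g <- list(
    n = n, i_neutral = 1 / i_vec,
    del = grid_half(s_hi_del, -1), ben = grid_half(s_hi_ben, +1),
    s_lo = s_lo, s_hi_del = s_hi_del, s_hi_ben = s_hi_ben
  )
  prf_grid_cache[[key]] <- g
  g
}

# mixture weights of the deleterious gamma on the grid (plus boundary masses)
gamma_grid_weights <- function(grid, shape, mean_abs) {
  scale <- mean_abs / shape
  dens <- dgamma(grid$del$S_abs, shape = shape, scale = scale)
  w <- dens * grid$del$S_abs * log(10) * grid$del$t_w
  list(w = w,
       p_small = pgamma(grid$s_lo, shape = shape, scale = scale),
       p_tail = pgamma(grid$s_hi_del, shape = shape, scale = scale,
                       lower.tail = FALSE))
}

exp_grid_weights <- function(grid, mean_sb) {
  dens <- dexp(grid$ben$S_abs, rate = 1 / mean_sb)
  w <- dens * grid$ben$S_abs * log(10) * grid$ben$t_w
  list(w = w,
       p_small = pexp(grid$s_lo, rate = 1 / mean_sb),
       p_tail = pexp(grid$s_hi_ben, rate = 1 / mean_sb, lower.tail = FALSE))
}

# E[nonsyn_i]/theta_n/r_i: DFE-averaged sojourn integral per frequency class
dfe_class_integrals <- function(grid, shape, mean_Sd, p_b, mean_Sb) {
  gw <- gamma_grid_weights(grid, shape, abs(mean_Sd))
  del_part <- as.numeric(grid$del$I %*% gw$w) +
    gw$p_small * grid$i_neutral +
    gw$p_tail * grid$del$I[, ncol(grid$del$I)]
  if (p_b > 0) {
    ew <- exp_grid_weights(grid, mean_Sb)
    ben_part <- as.numeric(grid$ben$I %*% ew$w) +
      ew$p_small * grid$i_neutral +
      ew$p_tail * grid$ben$I[, ncol(grid$ben$I)]
    (1 - p_b) * del_part + p_b * ben_part
  } else {
    del_part
  }
}

#' Expected unfolded SFS under the Poisson random field model
#'
#' Synonymous classes are neutral, `E[syn_i] = theta_s * r_i / i` (computed
#' analytically). Nonsynonymous classes integrate the sojourn density over
#' the DFE: a reflected gamma (shape `shape`, mean `mean_Sd < 0`) with an
#' optional exponential beneficial tail of mass `p_b` and mean `mean_Sb`.
#' The distortion multipliers `r_i` (`r_1 = 1`) absorb demography, linked
#' selection and genotyping error; `eps_anc` mixes class `i` with `n - i`
#' to model ancestral misorientation.
#'
#' @param n haploid sample size.
#' @param theta_s,theta_n mutational input per class (scaled).
#' @param shape gamma shape of the deleterious DFE.
#' @param mean_Sd mean scaled deleterious effect (negative).
#' @param p_b beneficial fraction in `[0, 1)`.
#' @param mean_Sb mean scaled beneficial effect (> 0).
#' @param r distortion multipliers, length `n - 1` with `r[1] == 1`.
#' @param eps_anc misorientation probability in `[0, 0.5)`.
#' @return List with numeric vectors `syn` and `nonsyn` of length `n - 1`.
#' @export
expected_sfs <- function(n, theta_s, theta_n, shape, mean_Sd, p_b = 0,
                         mean_Sb = 1, r = rep(1, n - 1), eps_anc = 0) {
  stopifnot(length(r) == n - 1, abs(r[1] - 1) < 1e-12, shape > 0,
            mean_Sd < 0, p_b >= 0, p_b < 1, eps_anc >= 0, eps_anc < 0.5)
  grid <- prf_grid(n)
  syn <- theta_s * r * grid$i_neutral
  J <- dfe_class_integrals(grid, shape, mean_Sd, p_b, mean_Sb)
  nonsyn <- theta_n * r * J
  mix <- function(e) (1 - eps_anc) * e + eps_anc * rev(e)
  list(syn = mix(syn), nonsyn = mix(nonsyn))
}

# Poisson log-likelihood (lgamma term dropped; constant in parameters)
sfs_loglik <- function(obs, expd) {
  e <- pmax(unlist(expd), 1e-12)
  o <- unlist(obs)
  sum(o * log(e) - e)
}

#' Fit a GammaExpo or GammaZero DFE to an unfolded SFS pair
#'
#' Maximizes the Poisson likelihood of the observed synonymous and
#' nonsynonymous class counts under [expected_sfs()], with multi-start
#' box-constrained quasi-Newton optimization. `GammaZero` fixes the
#' beneficial mass at zero. When `compare_null = TRUE` the nested model is
#' also fitted and a likelihood-ratio comparison reported.
#'
#' @param sfs a `surf_sfs`.
#' @param model `"GammaExpo"` or `"GammaZero"`.
#' @param n_starts number of optimization starts (>= 1).
#' @param seed seed for start-point dispersion.
#' @param fit_distortion fit the `r_i` multipliers (else fixed at 1).
#' @param tie_theta constrain the per-site mutational input to be equal for
#'   the two classes, `theta_n / theta_s = L_nonsyn / L_syn` (default). The
#'   absolute deficit of nonsynonymous polymorphism relative to its
#'   mutational opportunity then informs the deleterious mass; with both
#'   thetas free that information is discarded and small spectra become
#'   nearly unidentifiable.
#' @param fit_misorientation fit `eps_anc` (else fixed at 0).
#' @param compare_null also fit the nested GammaZero model for a
#'   likelihood-ratio comparison (ignored when `model = "GammaZero"`).
#' @return Object of class `surf_dfe_fit`.
#' @export
fit_gamma_expo <- function(sfs, model = c("GammaExpo", "GammaZero"),
                           n_starts = 5, seed = 1, fit_distortion = TRUE,
                           fit_misorientation = TRUE, tie_theta = TRUE,
                           compare_null = FALSE) {
  model <- match.arg(model)
  n <- sfs$n
  grid <- prf_grid(n)
  has_pb <- model == "GammaExpo"
  nr <- if (fit_distortion) n - 2 else 0
  lr <- sfs$L_nonsyn / sfs$L_syn

  # parameter vector: log(theta_s), [log(theta_n)], log(shape),
  # log10|mean_Sd|, [qlogis(p_b), log(mean_Sb)], [log(r_2..r_{n-1})],
  # [qlogis(2*eps)]
  unpack <- function(par) {
    if (tie_theta) {
      theta_s <- exp(par[1]); theta_n <- theta_s * lr; k <- 3
    } else {
      theta_s <- exp(par[1]); theta_n <- exp(par[2]); k <- 4
    }
    shape <- exp(par[k - 1]); lSd <- par[k]
    p_b <- 0; mean_Sb <- 1
    if (has_pb) {
      p_b <- stats::plogis(par[k + 1]); mean_Sb <- exp(par[k + 2]); k <- k + 2
    }
    r <- rep(1, n - 1)
    if (fit_distortion) {
      r[2:(n - 1)] <- exp(par[(k + 1):(k + nr)]); k <- k + nr
    }
    eps <- if (fit_misorientation) 0.5 * stats::plogis(par[k + 1]) else 0
    list(theta_s = theta_s, theta_n = theta_n, shape = shape,
         mean_Sd = -10^lSd, p_b = p_b, mean_Sb = mean_Sb, r = r,
         eps = eps)
  }
  negll <- function(par) {
    p <- unpack(par)
    e <- tryCatch(
      expected_sfs(n, p$theta_s, p$theta_n, p$shape, p$mean_Sd, p$p_b,
                   p$mean_Sb, p$r, p$eps),
      error = function(err) NULL
    )
    if (is.null(e)) return(1e10)
    v <- -sfs_loglik(list(sfs$syn_sfs, sfs$nonsyn_sfs), e)
    if (!is.finite(v)) 1e10 else v
  }
  theta_s0 <- max(sum(sfs$syn_sfs) / sum(grid$i_neutral), 1e-3)
  theta_n0 <- max(sum(sfs$nonsyn_sfs) / sum(grid$i_neutral), 1e-3)
  if (tie_theta) {
    base0 <- c(log(theta_s0), log(0.3), 2)
    lo <- c(-30, log(0.02), -3)
    hi <- c(30, log(20), 4.9)
  } else {
    base0 <- c(log(theta_s0), log(theta_n0), log(0.3), 2)
    lo <- c(rep(-30, 2), log(0.02), -3)
    hi <- c(rep(30, 2), log(20), 4.9)
  }
  if (has_pb) {
    base0 <- c(base0, stats::qlogis(0.02), log(2))
    lo <- c(lo, -12, log(1e-3)); hi <- c(hi, stats::qlogis(0.6), log(1e3))
  }
  if (fit_distortion) {
    base0 <- c(base0, rep(0, nr)); lo <- c(lo, rep(-4, nr))
    hi <- c(hi, rep(4, nr))
  }
  if (fit_misorientation) {
    base0 <- c(base0, stats::qlogis(0.05))
    lo <- c(lo, -12); hi <- c(hi, 6)
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1) return(base0)
      jit <- base0 + stats::rnorm(length(base0), 0, 1)
      ksh <- if (tie_theta) 2 else 3
      jit[ksh] <- log(runif(1, 0.05, 3))        # shape
      jit[ksh + 1] <- runif(1, -1, 4.5)         # log10|mean_Sd|
      pmin(pmax(jit, lo + 1e-6), hi - 1e-6)
    })
  })
  fits <- lapply(starts, function(st) {
    tryCatch(nlminb(st, negll, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1200)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (!length(fits)) abort("all optimization starts failed")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  p <- unpack(best$par)
  n_par <- length(best$par)
  out <- structure(list(
    model = model, n = n, params = p,
    loglik = -best$objective, n_par = n_par,
    aic = 2 * n_par + 2 * best$objective,
    convergence = tibble(
      start = seq_along(fits),
      objective = vapply(fits, `[[`, numeric(1), "objective"),
      converged = vapply(fits, function(f) f$convergence == 0, logical(1))
    ),
    sfs = sfs
  ), class = "surf_dfe_fit")
  if (compare_null && model == "GammaExpo") {
    null_fit <- fit_gamma_expo(sfs, "GammaZero", n_starts = n_starts,
                               seed = seed + 1, fit_distortion = fit_distortion,
                               fit_misorientation = fit_misorientation,
                               tie_theta = tie_theta)
    out$lrt <- tibble(
      model = c("GammaExpo", "GammaZero"),
      loglik = c(out$loglik, null_fit$loglik),
      n_par = c(out$n_par, null_fit$n_par),
      aic = c(out$aic, null_fit$aic)
    )
  }
  out
}

#' @export
print.surf_dfe_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<surf_dfe_fit> %s (n=%d)  logL=%.2f\n  shape=%.3f mean_Sd=%.1f p_b=%.4f mean_Sb=%.2f eps=%.3f\n",
    x$model, x$n, x$loglik, p$shape, p$mean_Sd, p$p_b, p$mean_Sb, p$eps))
  invisible(x)
}

#' @export
tidy.surf_dfe_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("theta_s", "theta_n", "shape", "mean_Sd", "p_b", "mean_Sb",
             "eps_anc", paste0("r_", 2:(x$n - 1))),
    estimate = c(p$theta_s, p$theta_n, p$shape, p$mean_Sd, p$p_b, p$mean_Sb,
                 p$eps, p$r[-1])
  )
}

#' @export
glance.surf_dfe_fit <- function(x, ...) {
  tibble(model = x$model, loglik = x$loglik, n_par = x$n_par, aic = x$aic,
         n = x$n)
}

#' Expected piN/piS implied by a fitted DFE
#'
#' Ratio of DFE-averaged to neutral pairwise diversity, obtained from the
#' expected SFS class contributions without distortion.
#'
#' @param fit a `surf_dfe_fit`.
#' @return Numeric scalar.
#' @export
dfe_expected_pinpis <- function(fit) {
  n <- fit$n
  p <- fit$params
  grid <- prf_grid(n)
  J <- dfe_class_integrals(grid, p$shape, p$mean_Sd, p$p_b, p$mean_Sb)
  i <- seq_len(n - 1)
  wpi <- 2 * i * (n - i) / (n * (n - 1))       # per-class pairwise weight
  sum(wpi * J) / sum(wpi * grid$i_neutral)
}

#' Selection efficacy summary: alpha, omegaA, omegaNA
#'
#' `omega_NA` is the expected dN/dS under the fitted deleterious DFE,
#' `integral of phi(S) u(S)` over `S <= 0`; `omega_A = dN/dS - omega_NA` and
#' `alpha = omega_A / (dN/dS)` follow as exact identities from the observed
#' divergence.
#'
#' @param fit a `surf_dfe_fit`.
#' @param sfs a `surf_sfs` carrying the divergence counts (defaults to the
#'   pair the model was fitted to).
#' @return One-row tibble: `dnds_obs`, `omega_na`, `omega_a`, `alpha`.
#' @export
selection_summary <- function(fit, sfs = fit$sfs) {
  if (!is.finite(sfs$D_syn) || sfs$D_syn <= 0) {
    abort("divergence counts required (D_syn > 0)")
  }
  dnds <- (sfs$D_nonsyn / sfs$L_nonsyn) / (sfs$D_syn / sfs$L_syn)
  p <- fit$params
  grid <- prf_grid(fit$n)
  gw <- gamma_grid_weights(grid, p$shape, abs(p$mean_Sd))
  u_grid <- fixation_rel(-grid$del$S_abs)
  omega_na <- (1 - p$p_b) *
    (sum(gw$w * u_grid) + gw$p_small * 1 +
       gw$p_tail * fixation_rel(-grid$s_hi_del))
  tibble(
    dnds_obs = dnds, omega_na = omega_na,
    omega_a = dnds - omega_na,
    alpha = if (dnds > 0) (dnds - omega_na) / dnds else NA_real_
  )
}

#' Write an SFS pair in dofe-style text format
#'
#' One header line (`#unfolded`) and one data line: dataset name, n,
#' nonsynonymous site total and class counts 1..n-1, synonymous site total
#' and class counts, then divergence site totals and counts. The dialect
#' mirrors the input format of SFS-based DFE tools so fits can be
#' cross-checked externally.
#'
#' @param sfs a `surf_sfs`.
#' @param path output file.
#' @param name dataset label.
#' @return `path`, invisibly.
#' @export
write_dofe <- function(sfs, path, name = "dataset") {
  line <- paste(c(
    name, sfs$n,
    sfs$L_nonsyn, sfs$nonsyn_sfs,
    sfs$L_syn, sfs$syn_sfs,
    sfs$L_nonsyn, sfs$D_nonsyn, sfs$L_syn, sfs$D_syn
  ), collapse = "\t")
  writeLines(c("#unfolded", line), path)
  invisible(path)
}

#' Read a dofe-style SFS file written by [write_dofe()]
#' @param path input file.
#' @return A `surf_sfs`.
#' @export
read_dofe <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines[2], "\t")[[1]]
  n <- as.integer(fields[2])
  v <- as.numeric(fields[-(1:2)])
  k <- n - 1
  new_sfs_pair(
    n = n,
    nonsyn_sfs = v[2:(k + 1)], L_nonsyn = v[1],
    syn_sfs = v[(k + 3):(2 * k + 2)], L_syn = v[k + 2],
    D_nonsyn = v[2 * k + 4], D_syn = v[2 * k + 6]
  )
}
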