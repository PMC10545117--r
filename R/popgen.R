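# Classical population statistics used for the demographic backdrop of an
# expansion: Ho, beta_ST, Tajima's D, Weir-Cockerham FST, LD decay, and the
# FST-based population tree rooted on the most ancestral population.

#' Observed heterozygosity per population
#'
#' Per population, the mean over sites of the fraction of non-missing
#' individuals that are heterozygous (Nei's Ho).
#'
#' @param g a [surf_geno].
#' @param popmap tibble from [read_popmap()].
#' @return Tibble `population`, `ho`, `n_sites`.
#' @export
observed_heterozygosity <- function(g, popmap) {
  pops <- pop_index(g, popmap)
  purrr::map_dfr(levels(pops), function(p) {
    gp <- g$geno[pops == p, , drop = FALSE]
    nn <- colSums(!is.na(gp))
    het <- colSums(gp == 1L, na.rm = TRUE)
    use <- nn > 0
    tibble(population = p,
           ho = if (any(use)) mean(het[use] / nn[use]) else 0,
           n_sites = sum(use))
  })
}

# per-locus allele counts by population: list(a = alt count, n = allele number)
pop_allele_counts <- function(g, pops) {
  lapply(levels(pops), function(p) {
    gp <- g$geno[pops == p, , drop = FALSE]
    list(a = colSums(gp, na.rm = TRUE), n = 2 * colSums(!is.na(gp)))
  })
}

#' Population-specific differentiation (beta_ST)
#'
#' Weir-Goudet allele-matching formulation: within-population matching
#' \eqn{M_{ii}} uses distinct draws, \eqn{M_B} is the mean cross-population
#' matching, and \eqn{\beta_i = (M_{ii} - M_B)/(1 - M_B)}. Negative values
#' flag likely ancestral populations.
#'
#' @param g a [surf_geno].
#' @param popmap tibble from [read_popmap()].
#' @return Tibble `population`, `beta_st`, plus `m_within`; `NA` when all
#'   populations are monomorphic and identical.
#' @export
beta_st <- function(g, popmap) {
  pops <- pop_index(g, popmap)
  r <- nlevels(pops)
  if (r < 2) abort("beta_st needs at least two populations")
  ac <- pop_allele_counts(g, pops)
  m_within <- vapply(ac, function(x) {
    use <- x$n >= 2
    a <- x$a[use]; n <- x$n[use]; b <- n - a
    mean((a * (a - 1) + b * (b - 1)) / (n * (n - 1)))
  }, numeric(1))
  mb_sum <- 0; mb_n <- 0
  for (i in 1:(r - 1)) for (j in (i + 1):r) {
    use <- ac[[i]]$n > 0 & ac[[j]]$n > 0
    pi_ <- ac[[i]]$a[use] / ac[[i]]$n[use]
    pj <- ac[[j]]$a[use] / ac[[j]]$n[use]
    mb_sum <- mb_sum + mean(pi_ * pj + (1 - pi_) * (1 - pj))
    mb_n <- mb_n + 1
  }
  m_b <- mb_sum / mb_n
  beta <- if (abs(1 - m_b) < 1e-12) rep(NA_real_, r) else {
    (m_within - m_b) / (1 - m_b)
  }
  tibble(population = levels(pops), beta_st = beta, m_within = m_within)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D per population
#'
#' Standard D per non-overlapping physical window; the population mean is
#' taken over windows with at least `min_s` segregating sites.
#'
#' @param g a [surf_geno].
#' @param popmap tibble from [read_popmap()].
#' @param window_bp window size in bp (default 100 kb).
#' @param min_s minimum segregating sites for a window to enter the mean.
#' @return List with `windows` (population, chrom, window, S, pi, D) and
#'   `summary` (population, tajima_d_mean, n_windows).
#' @export
tajimas_d <- function(g, popmap, window_bp = 1e5, min_s = 3) {
  pops <- pop_index(g, popmap)
  win <- paste(g$sites$chrom, (g$sites$pos - 1) %/% window_bp)
  rows <- purrr::map_dfr(levels(pops), function(p) {
    gp <- g$geno[pops == p, , drop = FALSE]
    n <- 2 * nrow(gp)
    if (n < 4) return(tibble())
    cst <- tajima_constants(n)
    nn <- 2 * colSums(!is.na(gp))
    ad <- colSums(gp, na.rm = TRUE)
    seg <- nn >= 2 & ad > 0 & ad < nn
    pfrq <- ifelse(nn > 0, ad / nn, NA)
    pi_site <- ifelse(seg, 2 * pfrq * (1 - pfrq) * nn / (nn - 1), 0)
    tibble(population = p, window = win,
           seg = as.numeric(seg), pi = pi_site) |>
      group_by(.data$population, .data$window) |>
      summarise(S = sum(.data$seg), pi = sum(.data$pi), .groups = "drop") |>
      mutate(
        D = ifelse(.data$S > 0,
                   (.data$pi - .data$S / cst$a1) /
                     sqrt(cst$e1 * .data$S + cst$e2 * .data$S * (.data$S - 1)),
                   NA_real_)
      )
  })
  summary <- rows |>
    filter(.data$S >= min_s, is.finite(.data$D)) |>
    group_by(population = .data$population) |>
    summarise(tajima_d_mean = mean(.data$D), n_windows = dplyr::n(),
              .groups = "drop")
  list(windows = rows, summary = summary)
}

wc_pair_fst <- function(ai, ni, hi, aj, nj, hj) {
  # Weir & Cockerham (1984) variance components, two populations,
  # multi-locus ratio of averages
  use <- ni >= 4 & nj >= 4
  if (!any(use)) return(NA_real_)
  n1 <- ni[use] / 2; n2 <- nj[use] / 2         # diploid counts
  p1 <- ai[use] / ni[use]; p2 <- aj[use] / nj[use]
  h1 <- hi[use]; h2 <- hj[use]
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- sum(a + b + cc)
  if (abs(denom) < 1e-300) NA_real_ else sum(a) / denom
}

#' Pairwise Weir-Cockerham FST matrix
#'
#' Multi-locus ratio-of-averages estimator (Weir & Cockerham 1984) for every
#' population pair.
#'
#' @param g a [surf_geno].
#' @param popmap tibble from [read_popmap()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
wc_fst <- function(g, popmap) {
  pops <- pop_index(g, popmap)
  r <- nlevels(pops)
  if (r < 2) abort("need at least two populations")
  stats <- lapply(levels(pops), function(p) {
    gp <- g$geno[pops == p, , drop = FALSE]
    list(a = colSums(gp, na.rm = TRUE), n = 2 * colSums(!is.na(gp)),
         h = colSums(gp == 1L, na.rm = TRUE) /
           pmax(colSums(!is.na(gp)), 1L))
  })
  out <- matrix(0, r, r, dimnames = list(levels(pops), levels(pops)))
  for (i in 1:(r - 1)) for (j in (i + 1):r) {
    f <- wc_pair_fst(stats[[i]]$a, stats[[i]]$n, stats[[i]]$h,
                     stats[[j]]$a, stats[[j]]$n, stats[[j]]$h)
    out[i, j] <- out[j, i] <- f
  }
  out
}

#' Linkage-disequilibrium decay curve
#'
#' Squared correlation between genotype dosages for all site pairs within
#' `max_dist_bp` on the same chromosome, after a per-population MAF filter,
#' binned by physical distance (log-spaced bins).
#'
#' @param g a [surf_geno].
#' @param popmap tibble from [read_popmap()].
#' @param maf minor-allele-frequency cutoff (default 0.05).
#' @param max_dist_bp largest pair distance considered.
#' @param n_bins number of log-spaced distance bins.
#' @return Tibble per population and bin: `dist_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(g, popmap, maf = 0.05, max_dist_bp = 5e4, n_bins = 12) {
  pops <- pop_index(g, popmap)
  breaks <- exp(seq(log(1), log(max_dist_bp), length.out = n_bins + 1))
  purrr::map_dfr(levels(pops), function(p) {
    gp <- g$geno[pops == p, , drop = FALSE]
    nn <- colSums(!is.na(gp))
    frq <- ifelse(nn > 0, colSums(gp, na.rm = TRUE) / (2 * nn), NA)
    keep <- which(!is.na(frq) & pmin(frq, 1 - frq) >= maf)
    if (length(keep) < 2) return(tibble())
    purrr::map_dfr(unique(g$sites$chrom), function(ch) {
      on_ch <- keep[g$sites$chrom[keep] == ch]
      if (length(on_ch) < 2) return(tibble())
      pos <- g$sites$pos[on_ch]
      pr <- which(outer(pos, pos, function(x, y) {
        d <- y - x; d > 0 & d <= max_dist_bp
      }), arr.ind = TRUE)
      if (nrow(pr) == 0) return(tibble())
      d <- pos[pr[, 2]] - pos[pr[, 1]]
      r2 <- vapply(seq_len(nrow(pr)), function(k) {
        x <- gp[, on_ch[pr[k, 1]]]; y <- gp[, on_ch[pr[k, 2]]]
        okk <- !is.na(x) & !is.na(y)
        if (sum(okk) < 3 || var(x[okk]) == 0 || var(y[okk]) == 0) {
          return(NA_real_)
        }
        cor(x[okk], y[okk])^2
      }, numeric(1))
      tibble(population = p, dist = d, r2 = r2)
    }) |>
      filter(!is.na(.data$r2)) |>
      mutate(bin = cut(.data$dist, breaks = breaks, include.lowest = TRUE,
                       labels = FALSE)) |>
      group_by(population = .data$population, bin = .data$bin) |>
      summarise(
        dist_mid = sqrt(breaks[.data$bin[1]] * breaks[.data$bin[1] + 1]),
        mean_r2 = mean(.data$r2), n_pairs = dplyr::n(), .groups = "drop"
      )
  })
}

#' Distance at which LD has decayed to half its maximum
#' @param curve output of [ld_decay()].
#' @return Tibble `population`, `halfmax_bp` (smallest bin mid-distance with
#'   mean r-squared at or below half the curve maximum; `NA` if never).
#' @export
ld_halfmax <- function(curve) {
  curve |>
    group_by(population = .data$population) |>
    arrange(.data$dist_mid, .by_group = TRUE) |>
    summarise(
      halfmax_bp = {
        thr <- max(.data$mean_r2) / 2
        i <- which(.data$mean_r2 <= thr)
        if (length(i)) .data$dist_mid[min(i)] else NA_real_
      },
      .groups = "drop"
    )
}

#' Neighbor-joining population tree from an FST matrix
#'
#' Builds an NJ tree on the FST distance matrix, roots it at the most
#' ancestral population (minimal beta_ST unless `root` is given), clamps any
#' negative NJ branch length to zero, and reports each population's summed
#' branch length to the root (a proxy for the travelled expansion route).
#'
#' @param fst symmetric FST matrix from [wc_fst()].
#' @param beta optional tibble from [beta_st()] used to pick the root.
#' @param root optional population id overriding the beta_ST rule.
#' @return List of class `surf_poptree`: `tree` (an `ape::phylo`),
#'   `root_population`, and `root_distance` tibble.
#' @export
fst_tree <- function(fst, beta = NULL, root = NULL) {
  if (is.null(root)) {
    if (is.null(beta)) abort("give either `beta` or an explicit `root`")
    root <- beta$population[which.min(beta$beta_st)]
  }
  tr <- ape::nj(stats::as.dist(fst))
  if (any(tr$edge.length < 0)) {
    warn(sprintf("%d negative NJ branch length(s) clamped to 0",
                 sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr <- ape::root(tr, outgroup = root, resolve.root = TRUE)
  depth <- ape::node.depth.edgelength(tr)
  out <- structure(
    list(tree = tr, root_population = root,
         root_distance = tibble(population = tr$tip.label,
                                root_distance = depth[seq_along(tr$tip.label)])),
    class = "surf_poptree"
  )
  out
}

#' @export
print.surf_poptree <- function(x, ...) {
  cat(sprintf("<surf_poptree> %d populations, rooted at %s\n",
              length(x$tree$tip.label), x$root_population))
  invisible(x)
}
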