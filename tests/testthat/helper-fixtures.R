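# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (loops, enumeration) so they share no code path with the
# package implementations they check.

library(tibble)

toy_geno <- function(dos, chrom = "chr1", pos = NULL, ref = "A", alt = "T",
                     effect = "unknown", samples = NULL) {
  dos <- as.matrix(dos)
  n_site <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(n_site) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(dos)))
  surf_geno(
    dos,
    tibble(chrom = rep_len(chrom, n_site), pos = pos,
           ref = rep_len(ref, n_site), alt = rep_len(alt, n_site),
           effect = rep_len(effect, n_site)),
    samples = samples
  )
}

toy_popmap <- function(samples, pops) {
  tibble(sample = samples, population = pops,
         distance_south = as.numeric(match(pops, unique(pops)) - 1) * 100,
         distance_ocean = 0)
}

random_geno <- function(n_ind, n_site, seed, p_missing = 0.05) {
  withr::with_seed(seed, {
    dos <- matrix(sample(0:2, n_ind * n_site, replace = TRUE), n_ind)
    dos[runif(n_ind * n_site) < p_missing] <- NA_integer_
    dos
  })
}

# write a small VCF with arbitrary body lines
write_test_vcf <- function(path, samples, body_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines
  ), path)
  path
}

# one-gene alignment from explicit haplotype strings
aln_from_strings <- function(haps, gene_id = "g1", chrom = "chr1") {
  seqs <- do.call(rbind, lapply(haps, function(h) strsplit(h, "")[[1]]))
  n <- ncol(seqs)
  structure(list(
    seqs = seqs,
    ref = strsplit(haps[[1]], "")[[1]],
    samples = sprintf("s%02d", seq_len(nrow(seqs) / 2)),
    hap_sample = rep(sprintf("s%02d", seq_len(nrow(seqs) / 2)), each = 2),
    gene_map = tibble(gene_id = gene_id, chrom = chrom, strand = "+",
                      start_col = 1L, end_col = n),
    col_chrom = rep(chrom, n), col_gpos = seq_len(n) + 1000L,
    col_strand = rep("+", n)
  ), class = "surf_cds_aln")
}

# ---- oracles ---------------------------------------------------------------

GEN_CODE <- Biostrings::GENETIC_CODE

# enumerate the 9 single-base changes of a codon (NG86 convention)
oracle_ng86_codon <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa0 <- GEN_CODE[[codon]]
  if (aa0 == "*") return(NULL)
  syn <- numeric(3)
  for (j in 1:3) {
    n_syn <- 0; n_cnt <- 0
    for (nb in setdiff(c("A", "C", "G", "T"), b[j])) {
      b2 <- b; b2[j] <- nb
      aa <- GEN_CODE[[paste(b2, collapse = "")]]
      if (aa == "*") next
      n_cnt <- n_cnt + 1
      if (aa == aa0) n_syn <- n_syn + 1
    }
    syn[j] <- if (n_cnt > 0) n_syn / n_cnt else 0
  }
  syn
}

# all-pairs average pairwise difference per class on a haplotype matrix,
# classifying each polymorphic column against the consensus codon
oracle_pi_classes <- function(seqs) {
  n <- nrow(seqs)
  syn_d <- 0; nonsyn_d <- 0; syn_L <- 0; nonsyn_L <- 0
  for (cod in seq_len(ncol(seqs) / 3)) {
    cols <- (cod - 1) * 3 + 1:3
    sub <- seqs[, cols, drop = FALSE]
    if (any(sub == "N")) next
    cons <- apply(sub, 2, function(x) names(which.max(table(factor(x, levels = c("A","C","G","T"))))))
    if (GEN_CODE[[paste(cons, collapse = "")]] == "*") next
    if (any(apply(sub, 2, function(x) length(unique(x))) > 2)) next
    sy <- oracle_ng86_codon(paste(cons, collapse = ""))
    syn_L <- syn_L + sum(sy); nonsyn_L <- nonsyn_L + sum(1 - sy)
    for (j in 1:3) {
      al <- unique(sub[, j])
      if (length(al) != 2) next
      d <- 0
      for (a in 1:(n - 1)) for (bb in (a + 1):n) {
        if (sub[a, j] != sub[bb, j]) d <- d + 1
      }
      d <- d / choose(n, 2)
      c1 <- cons; c1[j] <- al[1]
      c2 <- cons; c2[j] <- al[2]
      aa1 <- GEN_CODE[[paste(c1, collapse = "")]]
      aa2 <- GEN_CODE[[paste(c2, collapse = "")]]
      if (aa1 == aa2 && aa1 != "*") syn_d <- syn_d + d
      else nonsyn_d <- nonsyn_d + d
    }
  }
  list(pi_s = syn_d / syn_L, pi_n = nonsyn_d / nonsyn_L,
       syn_sites = syn_L, nonsyn_sites = nonsyn_L)
}

# Tajima's D from first principles
oracle_tajima_d <- function(pi_sum, S, n) {
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) a, b, c components, loop form, two populations
oracle_wc_fst <- function(dos1, dos2) {
  A <- 0; BC <- 0
  for (l in seq_len(ncol(dos1))) {
    x1 <- dos1[, l]; x2 <- dos2[, l]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) next
    n1 <- length(x1); n2 <- length(x2); r <- 2
    p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; BC <- BC + a + b + cc
  }
  A / BC
}

# allele-matching probabilities by draw enumeration
oracle_beta_st <- function(dos_list) {
  r <- length(dos_list)
  m_within <- sapply(dos_list, function(d) {
    vals <- numeric(0)
    for (l in seq_len(ncol(d))) {
      x <- d[, l][!is.na(d[, l])]
      al <- unlist(lapply(x, function(g) c(rep(1, g), rep(0, 2 - g))))
      n <- length(al)
      if (n < 2) next
      same <- 0; tot <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        tot <- tot + 1; if (al[i] == al[j]) same <- same + 1
      }
      vals <- c(vals, same / tot)
    }
    mean(vals)
  })
  mb <- numeric(0)
  for (i in 1:(r - 1)) for (j in (i + 1):r) {
    vals <- numeric(0)
    for (l in seq_len(ncol(dos_list[[i]]))) {
      xi <- dos_list[[i]][, l][!is.na(dos_list[[i]][, l])]
      xj <- dos_list[[j]][, l][!is.na(dos_list[[j]][, l])]
      ai <- unlist(lapply(xi, function(g) c(rep(1, g), rep(0, 2 - g))))
      aj <- unlist(lapply(xj, function(g) c(rep(1, g), rep(0, 2 - g))))
      if (!length(ai) || !length(aj)) next
      same <- 0; tot <- 0
      for (a in ai) for (b in aj) { tot <- tot + 1; if (a == b) same <- same + 1 }
      vals <- c(vals, same / tot)
    }
    mb <- c(mb, mean(vals))
  }
  m_b <- mean(mb)
  (m_within - m_b) / (1 - m_b)
}

# closed-form OLS via normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Mann-Whitney U by exhaustive midranks
oracle_mann_whitney_u <- function(x, y) {
  all <- c(x, y)
  rk <- rank(all)
  sum(rk[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Tukey studentized-range q statistic for one contrast
oracle_tukey_q <- function(y, g, lev1, lev2) {
  ms_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) /
    (length(y) - length(unique(g)))
  n_h <- length(y) / length(unique(g)) # balanced designs only
  abs(mean(y[g == lev1]) - mean(y[g == lev2])) / sqrt(ms_within / n_h)
}
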