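# Codon-level machinery. Site counting follows Nei & Gojobori (1986):
# each codon position contributes one site, split into synonymous and
# nonsynonymous fractions according to how many of its three single-base
# changes preserve the amino acid, with changes to stop codons removed from
# the denominator.

BASES <- c("A", "C", "G", "T")

codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
    # index = 16*b1 + 4*b2 + b3 + 1 with A=0 C=1 G=2 T=3
    idx <- function(cod) {
      b <- match(strsplit(cod, "")[[1]], BASES) - 1L
      16L * b[1] + 4L * b[2] + b[3] + 1L
    }
    ord <- vapply(codons, idx, integer(1))
    aa <- rep(NA_character_, 64)
    gc <- Biostrings::GENETIC_CODE
    aa[ord] <- unname(gc[codons])
    is_stop <- aa == "*"
    syn_frac <- matrix(NA_real_, 64, 3)
    for (ci in 1:64) {
      if (is_stop[ci]) next
      b <- c((ci - 1) %/% 16, ((ci - 1) %/% 4) %% 4, (ci - 1) %% 4)
      for (j in 1:3) {
        n_syn <- 0L; n_cnt <- 0L
        for (nb in 0:3) {
          if (nb == b[j]) next
          b2 <- b; b2[j] <- nb
          ci2 <- 16L * b2[1] + 4L * b2[2] + b2[3] + 1L
          if (is_stop[ci2]) next
          n_cnt <- n_cnt + 1L
          if (aa[ci2] == aa[ci]) n_syn <- n_syn + 1L
        }
        syn_frac[ci, j] <- if (n_cnt > 0) n_syn / n_cnt else NA_real_
      }
    }
    cache <<- list(aa = aa, is_stop = is_stop, syn_frac = syn_frac)
    cache
  }
})

codon_index <- function(b1, b2, b3) 16L * b1 + 4L * b2 + b3 + 1L

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Nei-Gojobori equal-weight counting under the standard genetic code:
#' every position contributes one site, split by the fraction of its
#' single-base changes (changes to stops excluded from the denominator)
#' that preserve the amino acid.
#'
#' @param codon three-letter string over A/C/G/T.
#' @return Tibble with rows `position = 1:3` and columns `syn`, `nonsyn`
#'   (summing to one per position); zero rows for a stop codon.
#' @export
classify_codon_sites <- function(codon) {
  tb <- codon_tables()
  b <- match(strsplit(toupper(codon), "")[[1]], BASES) - 1L
  if (length(b) != 3 || anyNA(b)) abort("codon must be three of A/C/G/T")
  ci <- codon_index(b[1], b[2], b[3])
  if (tb$is_stop[ci]) {
    return(tibble(position = integer(), syn = numeric(), nonsyn = numeric()))
  }
  sf <- tb$syn_frac[ci, ]
  sf[is.na(sf)] <- 0
  tibble(position = 1:3, syn = sf, nonsyn = 1 - sf)
}

# per-column base counts of a haplotype matrix
aln_counts <- function(seqs) {
  cnt <- vapply(BASES, function(b) colSums(seqs == b), numeric(ncol(seqs)))
  cnt <- matrix(cnt, ncol = 4, dimnames = list(NULL, BASES))
  list(cnt = cnt, nN = nrow(seqs) - rowSums(cnt))
}

#' Per-gene codon statistics: sites, differences and GC3
#'
#' Walks the codon columns of a coding alignment and accumulates, per gene,
#' NG86 synonymous/nonsynonymous site totals, mean pairwise differences per
#' class (via the unbiased per-site heterozygosity `2p(1-p) n/(n-1)`), and
#' GC3 on the consensus sequence. Codon columns containing an `N` in any
#' haplotype, a stop consensus codon, or more than two alleles at a position
#' are excluded alignment-wide so site totals stay shared across haplotypes.
#'
#' @param aln a `surf_cds_aln` from [reconstruct_cds_alignment()].
#' @return Tibble with one row per gene: `gene_id`, `codons_used`,
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `pi_n`,
#'   `pi_s`, `gc3`, `third_positions_used`.
#' @export
codon_site_stats <- function(aln) {
  tb <- codon_tables()
  ac <- aln_counts(aln$seqs)
  cnt <- ac$cnt
  M <- nrow(cnt)
  stopifnot(M %% 3 == 0)
  C <- M %/% 3
  n_hap <- nrow(aln$seqs)

  n_alleles <- rowSums(cnt > 0)
  cons <- max.col(cnt, ties.method = "first")       # 1..4
  cons[rowSums(cnt) == 0] <- NA_integer_
  has_N <- ac$nN > 0

  pos_in_codon <- rep.int(1:3, C)
  codon_of_col <- rep(seq_len(C), each = 3)
  bm <- matrix(cons - 1L, nrow = 3)                 # digits per codon
  ci <- codon_index(bm[1, ], bm[2, ], bm[3, ])      # NA if any digit NA
  codon_N <- colSums(matrix(has_N, nrow = 3)) > 0
  codon_multi <- colSums(matrix(n_alleles > 2, nrow = 3)) > 0
  ci_safe <- ifelse(is.na(ci), 1L, ci)
  ok <- !codon_N & !codon_multi & !is.na(ci) & !tb$is_stop[ci_safe]

  # site totals per codon
  sf <- tb$syn_frac[ci, , drop = FALSE]             # C x 3
  sf[is.na(sf)] <- 0
  wt <- matrix(0, C, 3)
  wt[!is.na(tb$syn_frac[ci, , drop = FALSE])] <- 1  # positions with counted changes
  syn_codon <- ifelse(ok, rowSums(sf), 0)
  nonsyn_codon <- ifelse(ok, rowSums(wt - sf), 0)

  # pairwise differences at biallelic columns of usable codons
  poly <- which(n_alleles == 2 & ok[codon_of_col] & !has_N)
  syn_diff_codon <- numeric(C)
  nonsyn_diff_codon <- numeric(C)
  if (length(poly)) {
    cnt2 <- cnt[poly, , drop = FALSE]
    maj <- cons[poly]
    cnt_min <- cnt2
    cnt_min[cbind(seq_along(poly), maj)] <- 0L
    minr <- max.col(cnt_min, ties.method = "first")
    n1 <- cnt2[cbind(seq_along(poly), maj)]
    n2 <- cnt2[cbind(seq_along(poly), minr)]
    n <- n1 + n2
    p <- n1 / n
    d <- 2 * p * (1 - p) * n / (n - 1)
    j <- pos_in_codon[poly]
    cod <- codon_of_col[poly]
    base_ci <- ci[cod]
    digit <- (maj - 1L)
    pow <- c(16L, 4L, 1L)[j]
    ci_min <- base_ci + ((minr - 1L) - digit) * pow
    syn_chg <- tb$aa[base_ci] == tb$aa[ci_min] & !tb$is_stop[ci_min]
    syn_chg[is.na(syn_chg)] <- FALSE                # stop-creating => nonsyn
    for (k in seq_along(poly)) {
      if (syn_chg[k]) {
        syn_diff_codon[cod[k]] <- syn_diff_codon[cod[k]] + d[k]
      } else {
        nonsyn_diff_codon[cod[k]] <- nonsyn_diff_codon[cod[k]] + d[k]
      }
    }
  }

  # GC3 on the consensus sequence (N-only columns excluded)
  third <- seq(3, M, by = 3)
  gc3_col <- !is.na(cons[third]) & cons[third] %in% c(2L, 3L)
  third_def <- !is.na(cons[third])

  gm <- aln$gene_map
  gene_of_codon <- rep(NA_integer_, C)
  for (i in seq_len(nrow(gm))) {
    gene_of_codon[((gm$start_col[i] - 1) %/% 3 + 1):(gm$end_col[i] %/% 3)] <- i
  }
  agg <- function(x) as.numeric(rowsum(x, gene_of_codon))
  res <- tibble(
    gene_id = gm$gene_id,
    codons_used = agg(as.numeric(ok)),
    syn_sites = agg(syn_codon),
    nonsyn_sites = agg(nonsyn_codon),
    syn_diffs = agg(syn_diff_codon),
    nonsyn_diffs = agg(nonsyn_diff_codon),
    third_positions_used = agg(as.numeric(third_def)),
    gc3_count = agg(as.numeric(gc3_col))
  )
  res |>
    mutate(
      pi_s = ifelse(.data$syn_sites > 0, .data$syn_diffs / .data$syn_sites,
                    NA_real_),
      pi_n = ifelse(.data$nonsyn_sites > 0,
                    .data$nonsyn_diffs / .data$nonsyn_sites, NA_real_),
      gc3 = ifelse(.data$third_positions_used > 0,
                   .data$gc3_count / .data$third_positions_used, NA_real_)
    ) |>
    select(-"gc3_count")
}

#' GC content at third codon positions, per gene
#'
#' @param aln a `surf_cds_aln`.
#' @return Tibble `gene_id`, `gc3`, `third_positions_used`.
#' @export
gc3 <- function(aln) {
  codon_site_stats(aln) |>
    select("gene_id", "gc3", "third_positions_used")
}

#' Concatenated piN/piS over a gene set
#'
#' Sums NG86 site and difference totals over genes (concatenation, a
#' ratio-of-sums, not a mean of per-gene ratios) and returns piN, piS and
#' their ratio. The ratio is `NA` when piS is zero.
#'
#' @param stats per-gene tibble from [codon_site_stats()], or a
#'   `surf_cds_aln` (computed on the fly).
#' @param genes optional character vector of gene ids to concatenate.
#' @return One-row tibble: site and difference totals, `pi_n`, `pi_s`,
#'   `ratio`.
#' @export
pi_n_pi_s <- function(stats, genes = NULL) {
  if (inherits(stats, "surf_cds_aln")) stats <- codon_site_stats(stats)
  if (!is.null(genes)) stats <- filter(stats, .data$gene_id %in% genes)
  out <- summarise(
    stats,
    n_genes = dplyr::n(),
    syn_sites = sum(.data$syn_sites), nonsyn_sites = sum(.data$nonsyn_sites),
    syn_diffs = sum(.data$syn_diffs), nonsyn_diffs = sum(.data$nonsyn_diffs)
  )
  out |>
    mutate(
      pi_s = ifelse(.data$syn_sites > 0, .data$syn_diffs / .data$syn_sites,
                    NA_real_),
      pi_n = ifelse(.data$nonsyn_sites > 0,
                    .data$nonsyn_diffs / .data$nonsyn_sites, NA_real_),
      ratio = ifelse(!is.na(.data$pi_s) & .data$pi_s > 0,
                     .data$pi_n / .data$pi_s, NA_real_)
    )
}

#' piN/piS over concatenated gene-space windows
#'
#' Packs genes, in genomic order and restarting at chromosome boundaries,
#' into windows whose concatenated CDS length first reaches `window_span`
#' (default 4 Mb of gene space; large windows damp the stochasticity of low
#' piS values). Each window reports concatenated piN/piS.
#'
#' @param stats per-gene tibble from [codon_site_stats()].
#' @param gene_models tibble from [load_gene_models()] providing
#'   `gene_id`, `chrom`, `start`, `cds_len`.
#' @param window_span window size in bp of concatenated CDS.
#' @return Tibble, one row per window, with `complete = FALSE` on a
#'   trailing window that did not reach the span and `short = TRUE` when it
#'   is under a quarter of the span.
#' @export
window_pinpis <- function(stats, gene_models, window_span = 4e6) {
  gm <- gene_models |>
    filter(.data$gene_id %in% stats$gene_id) |>
    arrange(.data$chrom, .data$start)
  win <- integer(nrow(gm))
  w <- 1L; acc <- 0
  last_chrom <- ""
  for (i in seq_len(nrow(gm))) {
    if (gm$chrom[i] != last_chrom && i > 1) { w <- w + 1L; acc <- 0 }
    last_chrom <- gm$chrom[i]
    win[i] <- w
    acc <- acc + gm$cds_len[i]
    if (acc >= window_span) { w <- w + 1L; acc <- 0 }
  }
  joined <- left_join(
    tibble(gene_id = gm$gene_id, chrom = gm$chrom, window = win,
           cds_len = gm$cds_len),
    stats, by = "gene_id"
  )
  joined |>
    group_by(window_id = .data$window, chrom = .data$chrom) |>
    summarise(
      n_genes = dplyr::n(), cds_len = sum(.data$cds_len),
      syn_sites = sum(.data$syn_sites), nonsyn_sites = sum(.data$nonsyn_sites),
      syn_diffs = sum(.data$syn_diffs), nonsyn_diffs = sum(.data$nonsyn_diffs),
      .groups = "drop"
    ) |>
    mutate(
      pi_s = ifelse(.data$syn_sites > 0, .data$syn_diffs / .data$syn_sites,
                    NA_real_),
      pi_n = ifelse(.data$nonsyn_sites > 0,
                    .data$nonsyn_diffs / .data$nonsyn_sites, NA_real_),
      ratio = ifelse(!is.na(.data$pi_s) & .data$pi_s > 0,
                     .data$pi_n / .data$pi_s, NA_real_),
      complete = .data$cds_len >= window_span,
      short = .data$cds_len < window_span / 4
    )
}

#' piN/piS in equal-count bins of ascending GC3
#'
#' Sorts genes by ascending GC3 and cuts them into `n_bins` equal-count bins
#' (any remainder spread over the first bins), so each ratio is computed
#' from genes of similar GC3, the package's recombination proxy.
#'
#' @param stats per-gene tibble from [codon_site_stats()] (carries `gc3`).
#' @param n_bins number of bins (default 20).
#' @return Tibble per bin: `bin`, `n_genes`, `gc3_median`, `pi_n`, `pi_s`,
#'   `ratio`.
#' @export
bin_genes_by_gc3 <- function(stats, n_bins = 20) {
  usable <- stats |> filter(!is.na(.data$gc3)) |> arrange(.data$gc3)
  n <- nrow(usable)
  if (n_bins > n) abort("more bins than genes with defined GC3")
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  usable$bin <- rep(seq_len(n_bins), times = sizes)
  usable |>
    group_by(bin = .data$bin) |>
    summarise(
      n_genes = dplyr::n(), gc3_median = median(.data$gc3),
      syn_sites = sum(.data$syn_sites), nonsyn_sites = sum(.data$nonsyn_sites),
      syn_diffs = sum(.data$syn_diffs), nonsyn_diffs = sum(.data$nonsyn_diffs),
      .groups = "drop"
    ) |>
    mutate(
      pi_s = ifelse(.data$syn_sites > 0, .data$syn_diffs / .data$syn_sites,
                    NA_real_),
      pi_n = ifelse(.data$nonsyn_sites > 0,
                    .data$nonsyn_diffs / .data$nonsyn_sites, NA_real_),
      ratio = ifelse(!is.na(.data$pi_s) & .data$pi_s > 0,
                     .data$pi_n / .data$pi_s, NA_real_)
    )
}

#' Keep only GC-conservative polymorphisms
#'
#' Retains A/T and C/G segregating pairs, i.e. mutations unaffected by
#' GC-biased gene conversion.
#'
#' @param x a [surf_geno] or a sites tibble with allele columns.
#' @return Object of the same type restricted to GC-conservative sites.
#' @export
gc_conservative_filter <- function(x) {
  sites <- if (inherits(x, "surf_geno")) x$sites else x
  al <- if ("ref" %in% names(sites)) {
    cbind(sites$ref, sites$alt)
  } else {
    cbind(sites$ancestral_allele, sites$derived_allele)
  }
  pair <- paste(pmin(al[, 1], al[, 2]), pmax(al[, 1], al[, 2]))
  keep <- pair %in% c("A T", "C G")
  if (inherits(x, "surf_geno")) geno_subset(x, sites = keep)
  else x[keep, , drop = FALSE]
}
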