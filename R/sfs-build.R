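# Building filtered, polarized, down-projected SFS pairs from coding
# alignments: the bridge between reconstructed per-individual CDS sequences
# and the PRF likelihood.

#' Outgroup consensus over the coding columns of an alignment
#'
#' The consensus is the reference CDS with the modal homozygous outgroup
#' allele substituted wherever the panel covers a site (complemented on
#' minus-strand genes).
#'
#' @param aln a `surf_cds_aln` (carries the reference row).
#' @param outgroup a `surf_outgroup`.
#' @param samples optional subset of outgroup individuals (e.g. one species
#'   of a pooled panel) to build the consensus from; divergence is usually
#'   counted against the closest outgroup while polarization pools all.
#' @return Character vector, one base per alignment column (`N` where the
#'   outgroup is uninformative at a covered site).
#' @export
outgroup_consensus_cds <- function(aln, outgroup, samples = NULL) {
  if (!is.null(samples)) {
    keep <- outgroup$samples %in% samples
    outgroup$a1 <- outgroup$a1[keep, , drop = FALSE]
    outgroup$a2 <- outgroup$a2[keep, , drop = FALSE]
    outgroup$samples <- outgroup$samples[keep]
  }
  cons <- aln$ref
  key_a <- paste(aln$col_chrom, aln$col_gpos)
  key_o <- paste(outgroup$sites$chrom, outgroup$sites$pos)
  idx <- match(key_o, key_a)
  hit <- which(!is.na(idx))
  for (v in hit) {
    a1 <- outgroup$a1[, v]; a2 <- outgroup$a2[, v]
    ok <- !is.na(a1) & !is.na(a2) & a1 == a2
    if (!any(ok)) next
    tab <- table(a1[ok])
    b <- names(tab)[which.max(tab)]
    cc <- idx[v]
    cons[cc] <- if (aln$col_strand[cc] == "-") unname(COMPLEMENT[b]) else b
  }
  cons
}

#' Build a filtered unfolded SFS pair for one population
#'
#' Applies the classical alignment filters before spectrum construction:
#' haplotype sequences with more than `gapN_seq` missing data are dropped;
#' genes with fewer than `min_nb_codon` complete codons, or with an internal
#' stop codon outside the initial/terminal `tolerance_zone`, are excluded;
#' a site enters only when at least `gapN_site` haplotypes are ungapped
#' there. Segregating sites are polarized with the ancestral assignments and
#' down-projected to `sample_size` haploids by the expected hypergeometric
#' projection (fractional counts, deterministic). Divergence is counted
#' against the outgroup consensus at monomorphic columns, position by
#' position with NG86 classification.
#'
#' @param aln a `surf_cds_aln` restricted to one population's individuals
#'   (see [aln_subset()]).
#' @param assignments ancestral assignments from [infer_ancestral()].
#' @param outgroup_cds outgroup consensus bases per alignment column, from
#'   [outgroup_consensus_cds()]; `NULL` skips divergence counting.
#' @param sample_size projection size in haploids (default 8).
#' @param gapN_site minimum ungapped haplotypes per retained site.
#' @param gapN_seq maximum missing fraction per haplotype sequence.
#' @param min_nb_codon minimum complete codons per retained gene.
#' @param tolerance_zone codons at each gene end where stops are tolerated.
#' @param allow_internal_stop keep genes with internal stops (default off).
#' @param population label used in error messages.
#' @return A `surf_sfs`.
#' @export
build_sfs <- function(aln, assignments, outgroup_cds = NULL, sample_size = 8,
                      gapN_site = 10, gapN_seq = 0.5, min_nb_codon = 6,
                      tolerance_zone = 20, allow_internal_stop = FALSE,
                      population = "pop") {
  tb <- codon_tables()
  seqs <- aln$seqs
  # 1. drop gappy haplotypes
  frac_N <- rowMeans(seqs == "N")
  keep_hap <- frac_N <= gapN_seq
  n_hap_drop <- sum(!keep_hap)
  seqs <- seqs[keep_hap, , drop = FALSE]
  if (nrow(seqs) < sample_size) {
    abort(sprintf("population %s: only %d haplotypes pass filters (< %d)",
                  population, nrow(seqs), sample_size))
  }
  M <- ncol(seqs); C <- M %/% 3
  gm <- aln$gene_map
  gene_of_codon <- rep(NA_integer_, C)
  for (i in seq_len(nrow(gm))) {
    gene_of_codon[((gm$start_col[i] - 1) %/% 3 + 1):(gm$end_col[i] %/% 3)] <- i
  }

  ac <- aln_counts(seqs)
  cnt <- ac$cnt; nN <- ac$nN
  n_avail <- rowSums(cnt)
  complete_codon <- colSums(matrix(nN > 0, nrow = 3)) == 0

  # 2. gene retention: complete codons and internal stops
  n_complete <- as.numeric(rowsum(as.numeric(complete_codon), gene_of_codon))
  gene_stop <- rep(FALSE, nrow(gm))
  if (!allow_internal_stop) {
    is_stop_cod <- tb$is_stop
    for (i in seq_len(nrow(gm))) {
      cods <- ((gm$start_col[i] - 1) %/% 3 + 1):(gm$end_col[i] %/% 3)
      nc <- length(cods)
      if (nc <= 2 * tolerance_zone) next
      internal <- cods[(tolerance_zone + 1):(nc - tolerance_zone)]
      cols <- as.vector(outer(1:3, (internal - 1) * 3, `+`))
      sub <- seqs[, cols, drop = FALSE]
      b <- matrix(match(t(sub), BASES) - 1L, nrow = 3)   # 3 x (nhap*ncod)
      ok_b <- colSums(is.na(b)) == 0
      if (!any(ok_b)) next
      ci <- codon_index(b[1, ok_b], b[2, ok_b], b[3, ok_b])
      if (any(is_stop_cod[ci])) gene_stop[i] <- TRUE
    }
  }
  gene_keep <- n_complete >= min_nb_codon & !gene_stop
  codon_in_kept_gene <- gene_keep[gene_of_codon]

  # usable codon: kept gene, consensus defined and non-stop, <= 2 alleles.
  # Unlike the diversity statistics, partial missingness does not exclude a
  # codon here; the per-site gapN_site coverage rule governs instead.
  cons <- max.col(cnt, ties.method = "first")
  cons[n_avail == 0] <- NA_integer_
  bm <- matrix(cons - 1L, nrow = 3)
  ci <- codon_index(bm[1, ], bm[2, ], bm[3, ])
  ci_safe <- ifelse(is.na(ci), 1L, ci)
  n_alleles <- rowSums(cnt > 0)
  codon_multi <- colSums(matrix(n_alleles > 2, nrow = 3)) > 0
  ok_codon <- codon_in_kept_gene & !codon_multi &
    !is.na(ci) & !tb$is_stop[ci_safe]

  # site totals (NG86 fractional counts on the consensus codon)
  sf <- tb$syn_frac[ci_safe, , drop = FALSE]
  wt <- !is.na(sf)
  sf[!wt] <- 0
  L_syn <- sum(rowSums(sf)[ok_codon])
  L_nonsyn <- sum(rowSums(wt - sf)[ok_codon])

  # ancestral base per column (reference unless an assignment says alt)
  anc_col <- aln$ref
  key_a <- paste(aln$col_chrom, aln$col_gpos)
  key_s <- paste(assignments$chrom, assignments$pos)
  idx <- match(key_s, key_a)
  hit <- which(!is.na(idx))
  for (v in hit) {
    cc <- idx[v]
    b <- assignments$anc_base[v]
    anc_col[cc] <- if (is.na(b)) "N" else if (aln$col_strand[cc] == "-") {
      unname(COMPLEMENT[b])
    } else b
  }

  n <- as.integer(sample_size)
  syn_sfs <- numeric(n - 1); nonsyn_sfs <- numeric(n - 1)
  n_unpolarized <- 0L; n_lowcov <- 0L; n_fixed_derived <- 0
  pos_in_codon <- rep.int(1:3, C)
  codon_of_col <- rep(seq_len(C), each = 3)
  poly <- which(n_alleles == 2 & ok_codon[codon_of_col])
  proj_i <- seq_len(n - 1)
  for (cc in poly) {
    m <- n_avail[cc]
    if (m < gapN_site || m < n) { n_lowcov <- n_lowcov + 1L; next }
    al <- which(cnt[cc, ] > 0)
    anc <- match(anc_col[cc], BASES)
    if (is.na(anc) || !(anc %in% al)) { n_unpolarized <- n_unpolarized + 1L; next }
    der <- setdiff(al, anc)
    k <- cnt[cc, der]
    # syn/nonsyn from the codon context (consensus background)
    cod <- codon_of_col[cc]; j <- pos_in_codon[cc]
    base_ci <- ci[cod]
    pow <- c(16L, 4L, 1L)[j]
    ci_anc <- base_ci + (anc - cons[cc]) * pow
    ci_der <- base_ci + (der - cons[cc]) * pow
    is_syn <- !is.na(tb$aa[ci_anc]) && !is.na(tb$aa[ci_der]) &&
      !tb$is_stop[ci_anc] && !tb$is_stop[ci_der] &&
      tb$aa[ci_anc] == tb$aa[ci_der]
    w <- dhyper(proj_i, k, m - k, n)
    n_fixed_derived <- n_fixed_derived + dhyper(n, k, m - k, n)
    if (is_syn) syn_sfs <- syn_sfs + w else nonsyn_sfs <- nonsyn_sfs + w
  }

  # divergence at monomorphic usable columns vs outgroup consensus
  D_syn <- NA_real_; D_nonsyn <- NA_real_
  if (!is.null(outgroup_cds)) {
    D_syn <- 0; D_nonsyn <- 0
    mono <- which(n_alleles == 1 & ok_codon[codon_of_col])
    og <- match(outgroup_cds[mono], BASES)
    fo <- cons[mono]
    diffc <- which(!is.na(og) & og != fo)
    for (q in diffc) {
      cc <- mono[q]
      cod <- codon_of_col[cc]; j <- pos_in_codon[cc]
      base_ci <- ci[cod]
      pow <- c(16L, 4L, 1L)[j]
      ci_out <- base_ci + (og[q] - cons[cc]) * pow
      if (tb$is_stop[ci_out]) next
      if (tb$aa[ci_out] == tb$aa[base_ci]) D_syn <- D_syn + 1
      else D_nonsyn <- D_nonsyn + 1
    }
  }

  new_sfs_pair(
    n = n, syn_sfs = syn_sfs, nonsyn_sfs = nonsyn_sfs,
    L_syn = L_syn, L_nonsyn = L_nonsyn,
    D_syn = D_syn, D_nonsyn = D_nonsyn,
    filter_log = tibble(
      what = c("haplotypes_dropped", "genes_dropped_short",
               "genes_dropped_stop", "sites_low_coverage",
               "sites_unpolarized", "fixed_derived_mass"),
      n = c(n_hap_drop, sum(n_complete < min_nb_codon), sum(gene_stop),
            n_lowcov, n_unpolarized, n_fixed_derived)
    )
  )
}
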