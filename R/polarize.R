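#' Read an outgroup genotype panel
#'
#' Loads outgroup genotypes called against the focal reference, keeping the
#' actual bases carried by each outgroup individual (a VCF emitted by
#' all-sites calling: REF/ALT plus GT). Only biallelic SNV records and
#' invariant records are used.
#'
#' @param vcf_path outgroup VCF aligned to focal coordinates.
#' @return An object of class `surf_outgroup`: two character matrices
#'   (`a1`, `a2`; individuals x sites) of carried bases (`NA` = missing) and
#'   a `sites` tibble with `chrom`, `pos`.
#' @export
read_outgroup_panel <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- ref %in% c("A", "C", "G", "T") &
    (is.na(alt) | alt %in% c("A", "C", "G", "T", "."))
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]
  alt[is.na(alt) | alt == "."] <- "N"
  code <- function(ch) {
    out <- matrix(NA_character_, nrow(gt), ncol(gt))
    is0 <- !is.na(ch) & ch == "0"
    is1 <- !is.na(ch) & ch == "1"
    out[is0] <- rep(ref, ncol(gt))[is0]
    out[is1] <- rep(alt, ncol(gt))[is1]
    out[!is.na(out) & out == "N"] <- NA_character_
    out
  }
  a1 <- code(substr(gt, 1, 1))
  a2 <- code(substr(gt, 3, 3))
  new_outgroup_panel(t(a1), t(a2),
                     tibble(chrom = fix[keep, "CHROM"],
                            pos = as.integer(fix[keep, "POS"])),
                     samples = colnames(gt))
}

#' Construct an outgroup panel from allele matrices
#' @param a1,a2 character matrices (individuals x sites) of carried bases.
#' @param sites tibble with `chrom`, `pos`.
#' @param samples outgroup individual ids.
#' @return A `surf_outgroup`.
#' @export
new_outgroup_panel <- function(a1, a2, sites, samples = NULL) {
  stopifnot(all(dim(a1) == dim(a2)), ncol(a1) == nrow(sites))
  if (is.null(samples)) samples <- paste0("OUT", seq_len(nrow(a1)))
  structure(list(a1 = a1, a2 = a2, sites = as_tibble(sites),
                 samples = samples),
            class = "surf_outgroup")
}

#' @export
print.surf_outgroup <- function(x, ...) {
  cat(sprintf("<surf_outgroup> %d individuals x %d sites\n",
              length(x$samples), nrow(x$sites)))
  invisible(x)
}

#' Infer ancestral alleles from an outgroup panel
#'
#' At each focal SNP the modal homozygous outgroup allele is taken as
#' ancestral when (1) at least `threshold` of the non-missing outgroup
#' individuals are homozygous for that allele and (2) it equals the focal
#' ref or alt allele. Sites failing either rule are returned as missing and
#' are excluded from downstream load analyses.
#'
#' @param g a [surf_geno] of focal genotypes.
#' @param outgroup a `surf_outgroup` (see [read_outgroup_panel()]).
#' @param threshold minimum fraction of non-missing outgroup individuals
#'   homozygous for the modal allele (default 0.90).
#' @return Tibble, one row per focal site: `chrom`, `pos`, `ancestral`
#'   (`"ref"`, `"alt"` or `NA`), `anc_base`, `support`, `reason`.
#' @export
infer_ancestral <- function(g, outgroup, threshold = 0.90) {
  key_f <- paste(g$sites$chrom, g$sites$pos)
  key_o <- paste(outgroup$sites$chrom, outgroup$sites$pos)
  idx <- match(key_f, key_o)
  n_sites <- nrow(g$sites)
  anc_base <- rep(NA_character_, n_sites)
  support <- rep(NA_real_, n_sites)
  reason <- rep("no_outgroup_data", n_sites)

  hit <- which(!is.na(idx))
  if (length(hit)) {
    a1 <- outgroup$a1[, idx[hit], drop = FALSE]
    a2 <- outgroup$a2[, idx[hit], drop = FALSE]
    nonmiss <- !is.na(a1) & !is.na(a2)
    n_nm <- colSums(nonmiss)
    hom_counts <- vapply(c("A", "C", "G", "T"), function(b) {
      colSums(nonmiss & a1 == b & a2 == b, na.rm = TRUE)
    }, numeric(length(hit)))
    hom_counts <- matrix(hom_counts, ncol = 4,
                         dimnames = list(NULL, c("A", "C", "G", "T")))
    modal <- max.col(hom_counts, ties.method = "first")
    modal_n <- hom_counts[cbind(seq_along(hit), modal)]
    sup <- ifelse(n_nm > 0, modal_n / n_nm, NA_real_)
    base <- c("A", "C", "G", "T")[modal]
    ok_support <- !is.na(sup) & sup >= threshold
    matches <- base == g$sites$ref[hit] | base == g$sites$alt[hit]
    support[hit] <- sup
    reason[hit] <- dplyr::case_when(
      n_nm == 0 ~ "no_outgroup_data",
      !ok_support ~ "below_threshold",
      !matches ~ "allele_mismatch",
      TRUE ~ "ok"
    )
    ok <- hit[reason[hit] == "ok"]
    anc_base[ok] <- base[match(ok, hit)]
  }
  tibble(
    chrom = g$sites$chrom, pos = g$sites$pos,
    ancestral = dplyr::case_when(
      is.na(anc_base) ~ NA_character_,
      anc_base == g$sites$ref ~ "ref",
      TRUE ~ "alt"
    ),
    anc_base = anc_base, support = support, reason = reason
  )
}

#' Re-express genotypes as derived-allele dosages
#'
#' Flips dosages at sites whose ancestral allele is the alternate allele and
#' drops sites with missing ancestral state.
#'
#' @param g a [surf_geno] with ref/alt dosages.
#' @param assignments output of [infer_ancestral()] covering `g`'s sites.
#' @return A polarized [surf_geno]; the number of dropped sites is attached
#'   as attribute `n_dropped`.
#' @export
polarize_genotypes <- function(g, assignments) {
  key_g <- paste(g$sites$chrom, g$sites$pos)
  key_a <- paste(assignments$chrom, assignments$pos)
  anc <- assignments$ancestral[match(key_g, key_a)]
  keep <- !is.na(anc)
  out <- geno_subset(g, sites = keep)
  anc <- anc[keep]
  flip <- which(anc == "alt")
  if (length(flip)) out$geno[, flip] <- 2L - out$geno[, flip]
  # after flipping, derived allele = what was ref at flipped sites
  sw <- out$sites$ref[flip]
  out$sites$ref[flip] <- out$sites$alt[flip]
  out$sites$alt[flip] <- sw
  names(out$sites)[names(out$sites) == "ref"] <- "ancestral_allele"
  names(out$sites)[names(out$sites) == "alt"] <- "derived_allele"
  out$polarized <- TRUE
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Mean derived allele frequencies by population and effect class
#'
#' @param g a polarized [surf_geno].
#' @param popmap tibble from [read_popmap()].
#' @param classes effect classes to tabulate.
#' @return Tibble with one row per (population, effect): `n_sites`,
#'   `mean_daf`, and the per-site frequencies in list-column `daf`.
#' @export
derived_frequency_table <- function(g, popmap,
                                    classes = c("synonymous", "missense",
                                                "lof")) {
  if (!g$polarized) abort("genotypes must be polarized first")
  pops <- pop_index(g, popmap)
  purrr::map_dfr(levels(pops), function(p) {
    gp <- g$geno[pops == p, , drop = FALSE]
    nn <- colSums(!is.na(gp))
    daf_all <- ifelse(nn > 0, colSums(gp, na.rm = TRUE) / (2 * nn), NA_real_)
    purrr::map_dfr(classes, function(cl) {
      use <- g$sites$effect == cl & !is.na(daf_all)
      tibble(population = p, effect = cl, n_sites = sum(use),
             mean_daf = if (any(use)) mean(daf_all[use]) else NA_real_,
             daf = list(daf_all[use]))
    })
  })
}
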