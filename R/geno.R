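#' Genotype container
#'
#' A light container pairing an integer genotype matrix (samples x sites,
#' entries 0/1/2 = alternate- or derived-allele dosage, `NA` = missing) with a
#' site table and sample ids. Most functions in the package take and return
#' this object or plain tibbles derived from it.
#'
#' @param geno integer matrix, samples in rows, sites in columns. `NA` encodes
#'   a missing genotype, distinct from 0.
#' @param sites tibble with one row per site: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `effect` (one of `"synonymous"`, `"missense"`, `"lof"`,
#'   `"noncoding"`, `"unknown"`), `gene_id` (may be `NA`).
#' @param samples character vector of sample ids, one per matrix row.
#' @param polarized logical; `TRUE` once genotypes count derived (not
#'   alternate) alleles.
#'
#' @return An object of class `surf_geno`.
#' @export
surf_geno <- function(geno, sites, samples, polarized = FALSE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- as_tibble(sites)
  stopifnot(nrow(geno) == length(samples), ncol(geno) == nrow(sites))
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    abort("`sites` needs columns chrom, pos, ref, alt")
  }
  if (is.null(sites[["effect"]])) sites$effect <- "unknown"
  if (is.null(sites[["gene_id"]])) sites$gene_id <- NA_character_
  bad <- sites$ref == sites$alt | sites$pos < 1
  if (any(bad)) abort("invalid sites: ref == alt or pos < 1")
  ok <- geno %in% c(NA_integer_, 0L, 1L, 2L)
  if (!all(ok)) abort("genotype dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples
  structure(
    list(geno = geno, sites = sites, samples = samples, polarized = polarized),
    class = "surf_geno"
  )
}

#' @export
print.surf_geno <- function(x, ...) {
  cat(sprintf(
    "<surf_geno> %d samples x %d sites (%s)\n",
    length(x$samples), nrow(x$sites),
    if (x$polarized) "polarized: derived dosage" else "ref/alt dosage"
  ))
  eff <- table(x$sites$effect)
  cat("  effects:", paste(names(eff), eff, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.surf_geno <- function(x) dim(x$geno)

#' Site table of a genotype container
#' @param g a [surf_geno] object.
#' @return Tibble with one row per site.
#' @export
sites_of <- function(g) g$sites

#' Subset a genotype container by sites and/or samples
#' @param g a [surf_geno] object.
#' @param sites logical or integer index over sites.
#' @param samples logical, integer or character index over samples.
#' @return A [surf_geno] with the selected rows/columns.
#' @export
geno_subset <- function(g, sites = NULL, samples = NULL) {
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, g$samples)
    g$geno <- g$geno[samples, , drop = FALSE]
    g$samples <- g$samples[samples]
  }
  if (!is.null(sites)) {
    g$geno <- g$geno[, sites, drop = FALSE]
    g$sites <- g$sites[sites, , drop = FALSE]
  }
  g
}

#' Long-format view of genotypes
#' @param x a [surf_geno] object.
#' @param ... unused.
#' @return Tibble with columns sample, chrom, pos, dosage.
#' @export
as_tibble.surf_geno <- function(x, ...) {
  tibble(
    sample = rep(x$samples, times = ncol(x$geno)),
    chrom = rep(x$sites$chrom, each = nrow(x$geno)),
    pos = rep(x$sites$pos, each = nrow(x$geno)),
    dosage = as.integer(x$geno)
  )
}

#' Read a population map
#'
#' Tab-separated file assigning samples to populations, with optional
#' population-level covariates (`distance_south`, `distance_ocean`,
#' `ne_proxy`, all in the file's units, typically km).
#'
#' @param path TSV with at least columns `sample` and `population`.
#' @return Tibble, one row per sample, covariates repeated within population.
#' @export
read_popmap <- function(path) {
  pm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "population") %in% names(pm))) {
    abort("popmap needs columns `sample` and `population`")
  }
  if (anyDuplicated(pm$sample)) abort("samples assigned more than once")
  num <- intersect(c("distance_south", "distance_ocean", "ne_proxy"), names(pm))
  for (cc in num) {
    if (any(pm[[cc]] < 0, na.rm = TRUE)) abort("covariates must be >= 0")
  }
  as_tibble(pm)
}

# population factor aligned to g$samples
pop_index <- function(g, popmap) {
  p <- popmap$population[match(g$samples, popmap$sample)]
  if (anyNA(p)) abort("some samples missing from the population map")
  factor(p, levels = unique(popmap$population))
}
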