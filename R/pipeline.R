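# End-to-end orchestration: from variant-space inputs to the population
# metric table (heterozygosity, load, piN/piS, DFE-based selection efficacy)
# and its distance regressions.

#' Run the expansion-load pipeline on variant-space inputs
#'
#' Chains the full analysis: ancestral inference against the outgroup panel,
#' polarization, coding-alignment reconstruction, per-population piN/piS,
#' additive/recessive load counts, classical population statistics, and
#' (optionally) per-population DFE fits with alpha/omegaA/omegaNA.
#'
#' @param vd list of variant-space inputs as produced by
#'   [as_variant_data()] (fields `geno`, `ref`, `gene_models`, `outgroup`,
#'   `popmap`), or assembled from files via [read_variants()] and friends.
#' @param fit_dfe fit a DFE per population (the slowest stage).
#' @param sample_size haploid projection size for the SFS (default 8).
#' @param gapN_site minimum ungapped haplotypes per SFS site.
#' @param n_starts optimization starts per DFE fit.
#' @param dfe_model DFE model for the per-population fits (default
#'   `"GammaZero"`: the beneficial fraction is weakly identified from
#'   single-population spectra of desk-scale size; `"GammaExpo"` is
#'   available).
#' @param div_samples optional outgroup individuals used for the divergence
#'   consensus (e.g. the closest species); polarization always pools the
#'   whole panel.
#' @param seed seed for haplotype assignment and DFE starts.
#' @return List of class `surf_pipeline`: `metrics` (one row per
#'   population), `assignments`, `loads`, `load_summary`, `sfs`, `dfe_fits`,
#'   `gene_stats` (per population), `fst`, `tree`.
#' @export
run_expansion_pipeline <- function(vd, fit_dfe = TRUE, sample_size = 8,
                                   gapN_site = 10, n_starts = 5,
                                   dfe_model = "GammaZero",
                                   div_samples = NULL, seed = 1) {
  popmap <- vd$popmap
  assignments <- infer_ancestral(vd$geno, vd$outgroup)
  pol <- polarize_genotypes(vd$geno, assignments)
  aln <- reconstruct_cds_alignment(vd$gene_models, vd$geno, vd$ref,
                                   seed = seed)
  og_cds <- outgroup_consensus_cds(aln, vd$outgroup, samples = div_samples)

  ho <- observed_heterozygosity(vd$geno, popmap)
  beta <- beta_st(vd$geno, popmap)
  taj <- tajimas_d(vd$geno, popmap)$summary
  fst <- wc_fst(vd$geno, popmap)
  tree <- fst_tree(fst, beta = beta)

  loads <- bind_rows(lapply(c("missense", "lof", "synonymous"),
                            function(cl) individual_load(pol, cl)))
  load_sum <- population_load_summary(loads, popmap)

  pops <- unique(popmap$population)
  per_pop <- lapply(pops, function(p) {
    ids <- popmap$sample[popmap$population == p]
    aln_p <- aln_subset(aln, ids)
    stats_p <- codon_site_stats(aln_p)
    pp <- pi_n_pi_s(stats_p)
    res <- list(gene_stats = stats_p, pinpis = pp, sfs = NULL, fit = NULL,
                sel = NULL)
    if (fit_dfe) {
      res$sfs <- build_sfs(aln_p, assignments, og_cds,
                           sample_size = sample_size, gapN_site = gapN_site,
                           population = p)
      res$fit <- fit_gamma_expo(res$sfs, dfe_model, n_starts = n_starts,
                                seed = seed, fit_misorientation = FALSE)
      res$sel <- selection_summary(res$fit)
    }
    res
  })
  names(per_pop) <- pops

  pinpis_tbl <- purrr::map_dfr(pops, function(p) {
    per_pop[[p]]$pinpis |> mutate(population = p) |>
      select("population", pin_pis = "ratio", "pi_n", "pi_s")
  })
  load_wide <- load_sum |>
    mutate(col = paste(.data$load_type, .data$effect, sep = "_")) |>
    select("population", "col", "mean") |>
    tidyr::pivot_wider(names_from = "col", values_from = "mean")
  sel_tbl <- if (fit_dfe) {
    purrr::map_dfr(pops, function(p) {
      per_pop[[p]]$sel |> mutate(population = p)
    })
  } else NULL

  covar <- popmap |>
    distinct(.data$population, .keep_all = TRUE) |>
    select(-"sample")
  args <- list(
    covariates = covar, ho = ho,
    beta = beta |> select("population", "beta_st"),
    tajima = taj, pinpis = pinpis_tbl, load = load_wide,
    tree = tree$root_distance
  )
  if (!is.null(sel_tbl)) args$dfe <- sel_tbl
  metrics <- do.call(assemble_metric_table, args)

  structure(list(
    metrics = metrics, assignments = assignments, polarized = pol,
    loads = loads, load_summary = load_sum, per_pop = per_pop,
    fst = fst, tree = tree
  ), class = "surf_pipeline")
}

#' @export
print.surf_pipeline <- function(x, ...) {
  cat(sprintf("<surf_pipeline> %d populations\n", nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}
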