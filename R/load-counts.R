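# Per-individual counts of putatively deleterious derived alleles: the
# additive (total) load Ntotal = 2*Nhomo + Nhetero and the recessive (fixed)
# load Nhomo, by effect class, with among-population tests.

#' Per-individual deleterious allele counts
#'
#' Counts, over the non-missing polarized genotypes of one effect class,
#' each individual's homozygous-derived sites (recessive load) and
#' heterozygous sites, with the additive load `2 * n_hom + n_het`.
#'
#' @param g a polarized [surf_geno].
#' @param effect_class one of `"missense"`, `"lof"`, `"synonymous"`.
#' @param per_site divide counts by the number of genotyped sites
#'   (robustness option for unequal missingness; default `FALSE`, matching
#'   raw per-individual counts).
#' @return Tibble per individual: `sample`, `effect`, `n_hom_derived`,
#'   `n_het`, `additive`, `recessive`, `sites_used`.
#' @export
individual_load <- function(g, effect_class = "missense", per_site = FALSE) {
  if (!g$polarized) abort("genotypes must be polarized first")
  use <- g$sites$effect == effect_class
  if (!any(use)) {
    warn(sprintf("no sites of class %s", effect_class))
    return(tibble(sample = g$samples, effect = effect_class,
                  n_hom_derived = 0, n_het = 0, additive = 0, recessive = 0,
                  sites_used = 0L))
  }
  gm <- g$geno[, use, drop = FALSE]
  n_hom <- unname(rowSums(gm == 2L, na.rm = TRUE))
  n_het <- unname(rowSums(gm == 1L, na.rm = TRUE))
  used <- unname(rowSums(!is.na(gm)))
  out <- tibble(
    sample = g$samples, effect = effect_class,
    n_hom_derived = n_hom, n_het = n_het,
    additive = 2 * n_hom + n_het, recessive = n_hom, sites_used = used
  )
  if (per_site) {
    out <- mutate(out, across(c("n_hom_derived", "n_het", "additive",
                                "recessive"),
                              ~ ifelse(used > 0, .x / used, NA_real_)))
  }
  out
}

#' Population means and SDs of individual load
#'
#' @param loads tibble from [individual_load()] (possibly several classes
#'   bound together).
#' @param popmap tibble from [read_popmap()].
#' @return Tibble per population, effect class and load type (`additive` /
#'   `recessive`): `mean`, `sd` (`NA` for single-individual populations),
#'   `n`.
#' @export
population_load_summary <- function(loads, popmap) {
  loads |>
    left_join(popmap |> select("sample", "population"), by = "sample") |>
    tidyr::pivot_longer(c("additive", "recessive"), names_to = "load_type",
                        values_to = "count") |>
    group_by(.data$population, .data$effect, .data$load_type) |>
    summarise(mean = mean(.data$count), sd = sd(.data$count),
              n = dplyr::n(), .groups = "drop")
}

#' Among-population tests of load differences
#'
#' One-way ANOVA of per-individual counts across populations, followed by
#' Tukey HSD pairwise contrasts with an additional Bonferroni correction
#' across contrasts.
#'
#' @param loads tibble from [individual_load()] for one effect class.
#' @param popmap tibble from [read_popmap()].
#' @param load_type `"additive"` or `"recessive"`.
#' @return List of class `surf_load_test`: `anova` (one-row tibble with F
#'   and p), `pairwise` (per pair: difference, Tukey p, Bonferroni-adjusted
#'   p), `degenerate` flag when no within-population variance exists.
#' @export
compare_loads <- function(loads, popmap, load_type = "additive") {
  df <- loads |>
    left_join(popmap |> select("sample", "population"), by = "sample") |>
    mutate(population = factor(.data$population))
  if (nlevels(df$population) < 2) abort("need at least two populations")
  y <- df[[load_type]]
  degenerate <- all(tapply(y, df$population, function(v) {
    length(v) < 2 || var(v) == 0
  }))
  if (degenerate) {
    warn("no within-population variance; tests undefined")
    return(structure(list(
      anova = tibble(effect = loads$effect[1], load_type = load_type,
                     anova_f = NA_real_, anova_p = NA_real_),
      pairwise = tibble(), degenerate = TRUE
    ), class = "surf_load_test"))
  }
  fit <- aov(y ~ population, data = df)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$population
  pw <- tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_tukey = unname(tk[, "p adj"]),
    p_adj = pmin(unname(tk[, "p adj"]) * nrow(tk), 1)
  )
  structure(list(
    anova = tibble(effect = loads$effect[1], load_type = load_type,
                   anova_f = sm$`F value`[1], anova_p = sm$`Pr(>F)`[1]),
    pairwise = pw, degenerate = FALSE
  ), class = "surf_load_test")
}

#' @export
print.surf_load_test <- function(x, ...) {
  cat("<surf_load_test>\n")
  print(x$anova)
  cat(sprintf("  %d pairwise contrasts\n", nrow(x$pairwise)))
  invisible(x)
}

#' @export
tidy.surf_load_test <- function(x, ...) x$pairwise

#' @export
glance.surf_load_test <- function(x, ...) x$anova
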