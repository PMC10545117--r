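# Contrasts between diploid chromosomes and regions of residual tetraploidy:
# gene-set resampling nulls, GC-matched bins, and TE content comparisons.

#' Assign genes to the diploid or tetraploid compartment
#'
#' Default rule follows the salmonid chromosome convention: chromosomes
#' numbered 1-30 are treated as diploid, 31-38 as residually tetraploid. An
#' explicit region set (BED) overrides the rule where both are given.
#'
#' @param gene_models tibble from [load_gene_models()].
#' @param tetraploid_regions optional region tibble from
#'   [read_region_set()].
#' @param tetraploid_chroms chromosome numbers treated as tetraploid by the
#'   naming rule (default 31:38; chromosome labels are parsed for a
#'   trailing integer).
#' @return Tibble `gene_id`, `chrom`, `compartment` (`"diploid"` /
#'   `"tetraploid"`); genes assignable by neither source are dropped with a
#'   message.
#' @export
assign_ploidy <- function(gene_models, tetraploid_regions = NULL,
                          tetraploid_chroms = 31:38) {
  num <- suppressWarnings(as.integer(stringr::str_extract(gene_models$chrom,
                                                          "\\d+$")))
  comp <- dplyr::case_when(
    num %in% tetraploid_chroms ~ "tetraploid",
    !is.na(num) ~ "diploid",
    TRUE ~ NA_character_
  )
  if (!is.null(tetraploid_regions) && nrow(tetraploid_regions)) {
    gr_g <- GenomicRanges::GRanges(
      gene_models$chrom,
      IRanges::IRanges(gene_models$start, gene_models$end)
    )
    gr_t <- GenomicRanges::GRanges(
      tetraploid_regions$chrom,
      IRanges::IRanges(tetraploid_regions$start + 1L, tetraploid_regions$end)
    )
    hit <- GenomicRanges::countOverlaps(gr_g, gr_t) > 0
    comp[hit] <- "tetraploid"
    comp[!hit & gene_models$chrom %in% tetraploid_regions$chrom] <- "diploid"
  }
  out <- tibble(gene_id = gene_models$gene_id, chrom = gene_models$chrom,
                compartment = comp)
  if (anyNA(out$compartment)) {
    inform(sprintf("%d gene(s) unassignable to a compartment; excluded",
                   sum(is.na(out$compartment))))
    out <- filter(out, !is.na(.data$compartment))
  }
  out
}

#' Resampling null for the tetraploid piN/piS excess
#'
#' Compares the concatenated piN/piS of the tetraploid gene set against a
#' null distribution of `n_resamples` diploid gene sets of `genes_per_set`
#' genes sampled without replacement (scaled down proportionally, with a
#' message, when the diploid pool is smaller).
#'
#' @param stats per-gene tibble from [codon_site_stats()].
#' @param partition tibble from [assign_ploidy()].
#' @param n_resamples number of null sets (default 200).
#' @param genes_per_set genes per null set (default 4000).
#' @param seed RNG seed.
#' @return List of class `surf_resample`: `observed` (tetraploid ratio),
#'   `null` (numeric vector), `quantile` (midrank position of the observed
#'   value in the null).
#' @export
resample_diploid_load <- function(stats, partition, n_resamples = 200,
                                  genes_per_set = 4000, seed = 1) {
  dip <- partition$gene_id[partition$compartment == "diploid"]
  tet <- partition$gene_id[partition$compartment == "tetraploid"]
  dip <- intersect(dip, stats$gene_id)
  tet <- intersect(tet, stats$gene_id)
  if (length(dip) < 10) abort("diploid gene pool too small to resample")
  if (genes_per_set > length(dip)) {
    genes_per_set <- max(2L, as.integer(length(dip) * 0.5))
    inform(sprintf("diploid pool smaller than requested; using sets of %d genes",
                   genes_per_set))
  }
  observed <- pi_n_pi_s(stats, genes = tet)$ratio
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(k) {
      pi_n_pi_s(stats, genes = sample(dip, genes_per_set))$ratio
    }, numeric(1))
  })
  q <- (sum(null < observed) + 0.5 * (1 + sum(null == observed))) /
    (length(null) + 1)
  structure(list(observed = observed, null = null, quantile = q,
                 genes_per_set = genes_per_set, n_tetraploid = length(tet)),
            class = "surf_resample")
}

#' @export
print.surf_resample <- function(x, ...) {
  cat(sprintf(
    "<surf_resample> observed tetraploid ratio %.4f | null of %d sets (%d genes): mean %.4f | quantile %.3f\n",
    x$observed, length(x$null), x$genes_per_set, mean(x$null), x$quantile))
  invisible(x)
}

#' GC-matched diploid vs tetraploid piN/piS contrast
#'
#' Computes GC content in fixed genomic windows separately for each
#' compartment, bins windows into GC quantile bins (the lowest bin marks the
#' low-recombination fraction), assigns genes to their window's bin, and
#' reports concatenated piN/piS per (compartment, GC bin) cell.
#'
#' @param stats per-gene tibble from [codon_site_stats()] (carries `gc3`).
#' @param partition tibble from [assign_ploidy()].
#' @param gene_models tibble from [load_gene_models()].
#' @param gc_window_mb window span for GC averaging, in Mb (default 4).
#' @param n_bins number of GC quantile bins per compartment (default 5, so
#'   the lowest bin is the bottom quintile).
#' @return Tibble per compartment and GC bin: `gc_bin` (1 = lowest GC),
#'   `lowest` flag, `n_genes`, `pi_n`, `pi_s`, `ratio`.
#' @export
gc_matched_contrast <- function(stats, partition, gene_models,
                                gc_window_mb = 4, n_bins = 5) {
  span <- gc_window_mb * 1e6
  df <- gene_models |>
    select("gene_id", "chrom", "start") |>
    inner_join(partition, by = c("gene_id", "chrom")) |>
    inner_join(stats, by = "gene_id") |>
    mutate(window = paste(.data$chrom, (.data$start - 1) %/% span))
  win_gc <- df |>
    group_by(.data$compartment, .data$window) |>
    summarise(win_gc = mean(.data$gc3, na.rm = TRUE), .groups = "drop") |>
    filter(is.finite(.data$win_gc)) |>
    group_by(.data$compartment) |>
    mutate(gc_bin = dplyr::ntile(.data$win_gc, n_bins)) |>
    ungroup()
  df |>
    inner_join(win_gc, by = c("compartment", "window")) |>
    group_by(.data$compartment, .data$gc_bin) |>
    summarise(
      n_genes = dplyr::n(),
      gc_mean = mean(.data$gc3, na.rm = TRUE),
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
      lowest = .data$gc_bin == 1
    )
}

#' Compare TE content between compartments
#'
#' Each transposable-element interval contributes its length divided by the
#' length of its chromosome (correcting for chromosome-size differences);
#' compartments are compared with a two-sided Mann-Whitney U test, with an
#' optional per-category breakdown.
#'
#' @param te_regions tibble from [read_region_set()] (the label column may
#'   carry a TE category as `"TE:<family>"`).
#' @param chrom_compartment tibble `chrom`, `compartment` (e.g. distinct
#'   rows of [assign_ploidy()] output).
#' @param chrom_lengths tibble `chrom`, `length`.
#' @return List of class `surf_te_test`: `per_te` tibble, `summary` per
#'   compartment, `test` (U statistic and p), and `by_category` when
#'   categories are present.
#' @export
te_compare <- function(te_regions, chrom_compartment, chrom_lengths) {
  per_te <- te_regions |>
    inner_join(chrom_compartment, by = "chrom") |>
    inner_join(chrom_lengths, by = "chrom") |>
    mutate(te_len = .data$end - .data$start,
           rel_len = .data$te_len / .data$length,
           category = sub("^TE:", "", .data$label))
  if (length(unique(per_te$compartment)) < 2) {
    abort("need TEs in both compartments")
  }
  tst <- wilcox.test(rel_len ~ compartment, data = per_te, exact = FALSE)
  by_cat <- NULL
  if (length(unique(per_te$category)) > 1) {
    by_cat <- per_te |>
      group_by(.data$category, .data$compartment) |>
      summarise(n = dplyr::n(), mean_rel_len = mean(.data$rel_len),
                .groups = "drop")
  }
  structure(list(
    per_te = per_te,
    summary = per_te |>
      group_by(.data$compartment) |>
      summarise(n = dplyr::n(), mean_rel_len = mean(.data$rel_len),
                median_rel_len = median(.data$rel_len), .groups = "drop"),
    test = tibble(statistic = unname(tst$statistic), p_value = tst$p.value),
    by_category = by_cat
  ), class = "surf_te_test")
}

#' @export
print.surf_te_test <- function(x, ...) {
  cat("<surf_te_test>\n")
  print(x$summary)
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n",
              x$test$statistic, x$test$p_value))
  invisible(x)
}
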