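# Validation experiments bundling the simulator and the analysis pipeline:
# replicated surfing runs and DFE-recovery trials. These back both the test
# suite and the reproduction script.

spearman_deme <- function(x) {
  suppressWarnings(cor(x, seq_along(x), method = "spearman"))
}

#' Replicated default-scenario surfing experiment
#'
#' Runs `n_reps` independent replicates of the default serial-founder
#' expansion, pushes each through the full analysis pipeline, and summarises
#' the expansion signatures per replicate: Spearman rank correlation of each
#' population metric with deme index, coefficients of variation of additive
#' and recessive load across demes, and the piN/piS of the low- versus
#' high-recombination gene classes (with the GC-matched compartment cells
#' accumulated over replicates).
#'
#' @param n_reps number of replicates (default 20).
#' @param seed base seed; replicate `i` uses `seed * 100 + i`.
#' @param config_fn function(seed) returning an [expansion_config()];
#'   defaults to the package defaults.
#' @return List: `reps` (one row per replicate: `rho_ho`, `rho_pinpis`,
#'   `rho_rec_missense`, `rho_rec_lof`, `rho_alpha`, `cv_additive`,
#'   `cv_recessive`, `low_recomb_ratio`, `high_recomb_ratio`), `cells`
#'   (pooled GC-matched contrast components per compartment x GC bin), and
#'   `fractions` (the per-signature replicate fractions).
#' @export
surfing_replicates <- function(n_reps = 20, seed = 1,
                               config_fn = function(s) expansion_config(seed = s)) {
  cells <- NULL
  reps <- purrr::map_dfr(seq_len(n_reps), function(i) {
    rs <- seed * 100 + i
    sim <- simulate_expansion(config_fn(rs))
    vd <- as_variant_data(sim)
    div <- vd$outgroup$samples[grepl("^og3_", vd$outgroup$samples)]
    if (!length(div)) div <- NULL
    res <- suppressWarnings(
      run_expansion_pipeline(vd, div_samples = div, seed = rs)
    )
    m <- res$metrics
    # metapopulation-wide per-gene stats for the recombination contrasts
    st <- bind_rows(lapply(res$per_pop, function(x) x$gene_stats)) |>
      group_by(.data$gene_id) |>
      summarise(across(c("syn_sites", "nonsyn_sites", "syn_diffs",
                         "nonsyn_diffs", "gc3"), sum), .groups = "drop") |>
      mutate(gc3 = .data$gc3 / length(res$per_pop))
    truth <- sim$genome$genes |>
      select("gene_id", "low_recomb", "compartment")
    st <- left_join(st, truth, by = "gene_id")
    rat <- function(df) {
      (sum(df$nonsyn_diffs) / sum(df$nonsyn_sites)) /
        (sum(df$syn_diffs) / sum(df$syn_sites))
    }
    part <- assign_ploidy(vd$gene_models)
    ct <- gc_matched_contrast(select(st, -"low_recomb", -"compartment"),
                              part, vd$gene_models,
                              gc_window_mb = 0.004, n_bins = 2)
    cells <<- bind_rows(cells, ct)
    cv <- function(x) sd(x) / mean(x)
    tibble(
      seed = rs,
      rho_ho = spearman_deme(m$ho),
      rho_pinpis = spearman_deme(m$pin_pis),
      rho_rec_missense = spearman_deme(m$recessive_missense),
      rho_rec_lof = spearman_deme(m$recessive_lof),
      rho_alpha = spearman_deme(m$alpha),
      cv_additive = cv(m$additive_missense),
      cv_recessive = cv(m$recessive_missense),
      low_recomb_ratio = rat(filter(st, .data$low_recomb)),
      high_recomb_ratio = rat(filter(st, !.data$low_recomb))
    )
  })
  pooled_cells <- cells |>
    group_by(.data$compartment, .data$gc_bin, .data$lowest) |>
    summarise(across(c("syn_sites", "nonsyn_sites", "syn_diffs",
                       "nonsyn_diffs"), sum), .groups = "drop") |>
    mutate(ratio = (.data$nonsyn_diffs / .data$nonsyn_sites) /
             (.data$syn_diffs / .data$syn_sites))
  list(
    reps = reps,
    cells = pooled_cells,
    fractions = tibble(
      ho_declining = mean(reps$rho_ho < 0),
      pinpis_increasing = mean(reps$rho_pinpis > 0),
      recessive_missense_increasing = mean(reps$rho_rec_missense > 0),
      recessive_lof_increasing = mean(reps$rho_rec_lof > 0, na.rm = TRUE),
      alpha_declining = mean(reps$rho_alpha < 0),
      cv_additive_lt_recessive = mean(reps$cv_additive < reps$cv_recessive),
      low_recomb_elevated = mean(reps$low_recomb_ratio >
                                   reps$high_recomb_ratio)
    )
  )
}

#' DFE parameter recovery experiment
#'
#' Samples SFS pairs from the Poisson random field model at a reference
#' parameter point (n = 20 haploids, theta 5000 per class, gamma shape 0.3
#' with mean scaled effect -1000, 2% beneficial mutations of mean effect 4)
#' and refits the generating GammaExpo model, recording how often the shape
#' is recovered within 0.1 and log10|mean_Sd| within 0.5.
#'
#' @param n_reps number of replicates (default 10).
#' @param seed base seed.
#' @return Tibble with one row per replicate: `shape_hat`, `mean_Sd_hat`,
#'   `p_b_hat`, `ok_shape`, `ok_mean_sd`.
#' @export
dfe_recovery_experiment <- function(n_reps = 10, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sfs <- sample_prf_sfs(20, theta_s = 5000, theta_n = 5000, shape = 0.3,
                          mean_Sd = -1000, p_b = 0.02, mean_Sb = 4,
                          seed = seed * 100 + r, L_syn = 1e6, L_nonsyn = 1e6)
    fit <- fit_gamma_expo(sfs, "GammaExpo", n_starts = 5, seed = seed + r,
                          fit_distortion = FALSE, fit_misorientation = FALSE)
    tibble(
      shape_hat = fit$params$shape,
      mean_Sd_hat = fit$params$mean_Sd,
      p_b_hat = fit$params$p_b,
      ok_shape = abs(fit$params$shape - 0.3) <= 0.1,
      ok_mean_sd = abs(log10(abs(fit$params$mean_Sd)) - 3) <= 0.5
    )
  })
}
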