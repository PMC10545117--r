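# Forward Wright-Fisher simulation of a 1-D serial-founder range expansion
# with a gamma DFE of partially recessive deleterious mutations, neutral
# synonymous sites, and diverged outgroup panels. The generator emits every
# input the analysis pipeline consumes, together with full truth tables.

#' Configuration for the expansion simulator
#'
#' Defaults describe the reference surfing scenario: ten demes founded
#' serially from a southern source (N = 500 diploids) by K = 10 founders
#' every 50 generations, with nearest-neighbour migration m = 0.01. The
#' mutation rate is the salmonid-scale 8e-9 /bp/generation multiplied by
#' `rescale` so that kilobase-scale genes accumulate realistic diversity in
#' a desk-scale run; deleterious selection coefficients come from a gamma
#' distribution with partial recessivity (h = 0.3), plus a small exponential
#' beneficial tail. Loss-of-function variants are modelled as the most
#' deleterious tail of the gamma (above `lof_quantile`). A quarter of the
#' genes sit on a residually tetraploid chromosome whose AT-rich half
#' recombines little, coupling GC3 to recombination as gBGC does in real
#' genomes.
#'
#' @param n_demes,N,K,T_found,m expansion geometry: deme count, deme size
#'   (diploids), founder count, generations between foundings, migration
#'   rate per generation between neighbours.
#' @param growth_rate per-generation growth factor of a newly founded deme
#'   until it reaches its carrying capacity (logistic-style regrowth after
#'   the founder bottleneck).
#' @param capacity_gradient fractional decline of deme carrying capacity
#'   from the source (capacity `N`) to the expansion front (capacity
#'   `N * (1 - capacity_gradient)`), linear in deme index. Emulates the
#'   persistently smaller habitats and effective sizes of recently
#'   colonized northern populations; 0 gives a uniform metapopulation.
#' @param burnin generations of source-deme burn-in before the expansion
#'   (default `2 * N`).
#' @param post_gens generations after the last founding.
#' @param n_genes,codons_per_gene genome size.
#' @param frac_tetraploid fraction of genes on the tetraploid chromosome.
#' @param mutation_rate per-bp per-generation rate before rescaling.
#' @param rescale mutation-rate rescaling factor recorded in the manifest.
#' @param dfe_shape,dfe_mean_s gamma DFE of deleterious s (fitness 1-s).
#' @param h_del,h_ben dominance of deleterious / beneficial mutations.
#' @param p_b,mean_s_b beneficial fraction and mean beneficial s.
#' @param lof_quantile gamma quantile above which a deleterious mutation is
#'   labelled LoF.
#' @param outgroup_divergence per-species substitution densities of the
#'   three outgroup panels.
#' @param omega_out acceptance probability of nonsynonymous substitutions
#'   on outgroup branches (their dN/dS).
#' @param n_outgroup_ind diploid individuals per outgroup species.
#' @param n_sample diploids sampled per deme at the end.
#' @param deme_spacing_km distance between adjacent demes (covariate).
#' @param seed integer seed; the whole run is deterministic given it.
#' @return List of class `surf_sim_config`.
#' @export
expansion_config <- function(n_demes = 10, N = 500, K = 10, T_found = 50,
                             m = 0.01, growth_rate = 1.15,
                             capacity_gradient = 0.7,
                             burnin = 2 * N, post_gens = 150,
                             n_genes = 120, codons_per_gene = 50,
                             frac_tetraploid = 0.25,
                             mutation_rate = 8e-9, rescale = 1000,
                             dfe_shape = 0.3, dfe_mean_s = 0.01,
                             h_del = 0.3, h_ben = 0.5,
                             p_b = 0.02, mean_s_b = 0.01,
                             lof_quantile = 0.6,
                             outgroup_divergence = c(0.02, 0.04, 0.06),
                             omega_out = 0.2, n_outgroup_ind = 5,
                             n_sample = 16, deme_spacing_km = 500,
                             seed = 1, neutral = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$K <= cfg$N, cfg$m >= 0, cfg$m <= 1, cfg$dfe_shape > 0,
            cfg$h_del >= 0, cfg$h_del <= 1, cfg$p_b >= 0, cfg$p_b < 1)
  structure(cfg, class = "surf_sim_config")
}

# genome layout: genes, reference CDS, mutational opportunity tables
build_sim_genome <- function(cfg) {
  tb <- codon_tables()
  n_tet <- round(cfg$n_genes * cfg$frac_tetraploid)
  n_dip <- cfg$n_genes - n_tet
  n1 <- ceiling(n_dip / 2)
  chrom <- c(rep("chr1", n1), rep("chr2", n_dip - n1), rep("chr31", n_tet))
  # GC3 targets: smooth gradient on diploid chromosomes; on the tetraploid
  # chromosome the first (low-recombination) half is AT-rich
  gc3_target <- c(
    seq(0.40, 0.75, length.out = n1),
    seq(0.40, 0.75, length.out = n_dip - n1),
    rep(c(0.33, 0.55), times = c(ceiling(n_tet / 2), floor(n_tet / 2)))
  )
  low_rec <- c(rep(FALSE, n_dip),
               rep(c(TRUE, FALSE), times = c(ceiling(n_tet / 2),
                                             floor(n_tet / 2))))
  gene_len <- 3L * cfg$codons_per_gene
  gap <- 300L
  genes <- tibble(
    gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
    chrom = chrom, strand = "+",
    gc3_target = gc3_target, low_recomb = low_rec,
    compartment = ifelse(chrom == "chr31", "tetraploid", "diploid")
  ) |>
    group_by(.data$chrom) |>
    mutate(start = gap + (dplyr::row_number() - 1L) * (gene_len + gap) + 1L,
           end = .data$start + gene_len - 1L) |>
    ungroup()

  # reference CDS: third-position GC follows the gene target; no stops
  ref_codons <- lapply(seq_len(cfg$n_genes), function(i) {
    p <- genes$gc3_target[i]
    k <- cfg$codons_per_gene
    b1 <- sample.int(4, k, replace = TRUE)
    b2 <- sample.int(4, k, replace = TRUE)
    b3 <- ifelse(runif(k) < p, sample(c(2L, 3L), k, replace = TRUE),
                 sample(c(1L, 4L), k, replace = TRUE))
    repeat {
      bad <- tb$is_stop[codon_index(b1 - 1L, b2 - 1L, b3 - 1L)]
      if (!any(bad)) break
      nb <- sum(bad)
      b1[bad] <- sample.int(4, nb, replace = TRUE)
      b2[bad] <- sample.int(4, nb, replace = TRUE)
      b3[bad] <- ifelse(runif(nb) < p, sample(c(2L, 3L), nb, replace = TRUE),
                        sample(c(1L, 4L), nb, replace = TRUE))
    }
    rbind(b1, b2, b3)
  })
  ref_base_idx <- unlist(lapply(ref_codons, function(m) as.integer(m)))
  L <- length(ref_base_idx)
  gene_of_pos <- rep(seq_len(cfg$n_genes), each = gene_len)

  # mutational opportunities: the three non-stop target bases per position
  pos_in_codon <- rep.int(1:3, L / 3)
  codon_of_pos <- rep(seq_len(L / 3), each = 3)
  ci_ref <- codon_index(ref_base_idx[pos_in_codon == 1][codon_of_pos] - 1L,
                        ref_base_idx[pos_in_codon == 2][codon_of_pos] - 1L,
                        ref_base_idx[pos_in_codon == 3][codon_of_pos] - 1L)
  alt_targets <- matrix(-1L, L, 3)
  alt_is_syn <- matrix(FALSE, L, 3)
  pow <- c(16L, 4L, 1L)[pos_in_codon]
  for (t in 1:3) {
    delta <- t # offset cycling through the 3 alternative bases
    alt_base <- ((ref_base_idx - 1L + delta) %% 4L) + 1L
    ci_alt <- ci_ref + (alt_base - ref_base_idx) * pow
    okd <- !tb$is_stop[ci_alt]
    alt_targets[okd, t] <- alt_base[okd] - 1L # 0-based for C++
    alt_is_syn[, t] <- tb$aa[ci_alt] == tb$aa[ci_ref] & okd
  }

  # crossover probability at each adjacent-gene boundary
  xover <- numeric(cfg$n_genes - 1)
  for (b in seq_len(cfg$n_genes - 1)) {
    if (genes$chrom[b] != genes$chrom[b + 1]) xover[b] <- 0.5
    else if (genes$low_recomb[b] && genes$low_recomb[b + 1]) xover[b] <- 1e-5
    else xover[b] <- 0.01
  }
  list(genes = genes, ref_base_idx = ref_base_idx, L = L,
       gene_of_pos = gene_of_pos, xover = xover,
       alt_targets = alt_targets, alt_is_syn = alt_is_syn,
       gene_len = gene_len, gap = gap)
}

#' Simulate a serial-founder range expansion
#'
#' Runs the individual-based Wright-Fisher simulation defined by an
#' [expansion_config()]: burn-in of the source deme, serial founding of the
#' remaining demes, selection with dominance, gene-scale recombination,
#' coding mutation with syn/nonsyn status taken from the reference codon
#' structure, and three diverged outgroup species generated by filtered
#' Poisson substitution from the ancestral sequence.
#'
#' @param cfg an [expansion_config()].
#' @return Object of class `surf_sim` carrying the genome layout, sampled
#'   genotypes in derived-dosage space, per-site truth (ancestral and
#'   derived bases, s, class, per-deme census frequencies), outgroup
#'   panels, population map, and the fixed-substitution log.
#' @export
simulate_expansion <- function(cfg) {
  stopifnot(inherits(cfg, "surf_sim_config"))
  genome <- withr::with_seed(cfg$seed, build_sim_genome(cfg))
  lof_thr <- qgamma(cfg$lof_quantile, shape = cfg$dfe_shape,
                    scale = cfg$dfe_mean_s / cfg$dfe_shape)
  capacity <- as.integer(round(cfg$N * (1 - cfg$capacity_gradient *
                                          (seq_len(cfg$n_demes) - 1) /
                                          max(cfg$n_demes - 1, 1))))
  res <- .wf_simulate(
    n_demes = cfg$n_demes, capacity = capacity, K = cfg$K,
    T_found = cfg$T_found,
    m = cfg$m, growth = cfg$growth_rate, burnin = cfg$burnin,
    post_gens = cfg$post_gens,
    gene_of_pos_r = genome$gene_of_pos - 1L, xover = genome$xover,
    alt_targets = genome$alt_targets, alt_is_syn = genome$alt_is_syn,
    gamma_shape = cfg$dfe_shape, gamma_mean = cfg$dfe_mean_s,
    p_b = cfg$p_b, mean_sb = cfg$mean_s_b, h_del = cfg$h_del,
    h_ben = cfg$h_ben, lof_thr = lof_thr, s_max = 0.95,
    mu = cfg$mutation_rate * cfg$rescale, n_sample = cfg$n_sample,
    purge_every = 20L, seed = cfg$seed, neutral = cfg$neutral
  )
  if (ncol(res$haps) == 0) abort("simulation produced no segregating sites")

  # genomic coordinates of coding-map indices
  cds_to_genomic <- function(idx) {
    gi <- genome$gene_of_pos[idx]
    offset <- idx - (gi - 1L) * genome$gene_len - 1L
    list(chrom = genome$genes$chrom[gi],
         pos = genome$genes$start[gi] + offset, gene = gi)
  }
  loc <- cds_to_genomic(res$pos)
  cls_name <- c("synonymous", "missense", "lof")
  sites <- tibble(
    chrom = loc$chrom, pos = loc$pos, cds_index = res$pos,
    gene_id = genome$genes$gene_id[loc$gene],
    ancestral_base = BASES[genome$ref_base_idx[res$pos]],
    derived_base = BASES[res$derived_base + 1L],
    s = res$s, effect = cls_name[res$cls + 1L]
  )
  fixed_loc <- cds_to_genomic(res$fixed$pos)
  fixed <- tibble(
    chrom = fixed_loc$chrom, pos = fixed_loc$pos, cds_index = res$fixed$pos,
    gene_id = genome$genes$gene_id[fixed_loc$gene],
    ancestral_base = BASES[genome$ref_base_idx[res$fixed$pos]],
    derived_base = BASES[res$fixed$derived_base + 1L],
    s = res$fixed$s, effect = cls_name[res$fixed$cls + 1L],
    generation = res$fixed$gen
  )
  hap <- res$haps
  n_ind <- nrow(hap) / 2
  geno <- hap[2 * seq_len(n_ind) - 1, , drop = FALSE] +
    hap[2 * seq_len(n_ind), , drop = FALSE]
  samples <- sprintf("d%02d_i%02d", res$sample_deme + 1L,
                     sequence(rep(cfg$n_sample, cfg$n_demes)))
  popmap <- tibble(
    sample = samples,
    population = sprintf("pop%02d", res$sample_deme + 1L),
    deme = res$sample_deme + 1L,
    distance_south = res$sample_deme * cfg$deme_spacing_km,
    distance_ocean = res$sample_deme * cfg$deme_spacing_km * 0.15
  )

  outgroups <- withr::with_seed(cfg$seed + 7L, {
    lapply(seq_along(cfg$outgroup_divergence), function(sp) {
      d <- cfg$outgroup_divergence[sp]
      cand <- which(runif(genome$L) < d)
      keep <- logical(length(cand))
      tgt <- integer(length(cand))
      for (q in seq_along(cand)) {
        p <- cand[q]
        okt <- which(genome$alt_targets[p, ] >= 0)
        if (!length(okt)) next
        t <- okt[sample.int(length(okt), 1)]
        accept <- genome$alt_is_syn[p, t] || runif(1) < cfg$omega_out
        if (accept) { keep[q] <- TRUE; tgt[q] <- genome$alt_targets[p, t] + 1L }
      }
      tibble(cds_index = cand[keep], base_idx = tgt[keep])
    })
  })

  structure(list(
    config = cfg, genome = genome, sites = sites, fixed = fixed,
    haps = hap, geno = geno, samples = samples, popmap = popmap,
    deme_freq = res$freq, outgroup_subs = outgroups,
    total_generations = res$total_gens,
    manifest = tibble(
      field = c("rescale_factor", "effective_mutation_rate", "total_generations",
                "segregating_sites", "fixed_substitutions"),
      value = c(cfg$rescale, cfg$mutation_rate * cfg$rescale, res$total_gens,
                nrow(sites), nrow(fixed))
    )
  ), class = "surf_sim")
}

#' @export
print.surf_sim <- function(x, ...) {
  cat(sprintf(
    "<surf_sim> %d demes x %d sampled diploids | %d segregating sites (%d syn / %d mis / %d lof) | %d fixed\n",
    x$config$n_demes, x$config$n_sample, nrow(x$sites),
    sum(x$sites$effect == "synonymous"), sum(x$sites$effect == "missense"),
    sum(x$sites$effect == "lof"), nrow(x$fixed)))
  invisible(x)
}

# full chromosome sequences (reference = ancestral + given substitutions)
sim_chrom_seqs <- function(sim, subs = NULL) {
  genome <- sim$genome
  chroms <- unique(genome$genes$chrom)
  base_by_pos <- lapply(chroms, function(ch) {
    len <- max(genome$genes$end[genome$genes$chrom == ch]) + genome$gap
    # deterministic filler keeps emitted FASTA stable across calls
    filler <- BASES[(seq_len(len) * 7L + 3L) %% 4L + 1L]
    filler
  })
  names(base_by_pos) <- chroms
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    idx <- ((i - 1L) * genome$gene_len + 1L):(i * genome$gene_len)
    base_by_pos[[g$chrom]][g$start:g$end] <- BASES[genome$ref_base_idx[idx]]
  }
  if (!is.null(subs) && nrow(subs)) {
    gi <- genome$gene_of_pos[subs$cds_index]
    ch <- genome$genes$chrom[gi]
    gp <- genome$genes$start[gi] + subs$cds_index -
      (gi - 1L) * genome$gene_len - 1L
    for (k in seq_len(nrow(subs))) {
      base_by_pos[[ch[k]]][gp[k]] <- BASES[subs$base_idx[k]]
    }
  }
  vapply(base_by_pos, paste, character(1), collapse = "")
}

#' Convert a simulation to the pipeline's variant-space inputs
#'
#' Produces what a variant-calling workflow would deliver: a reference
#' genome (the species consensus: ancestral sequence plus all substitutions
#' fixed during the run, with the reference allele at segregating sites
#' drawn from a haplotype-frequency-weighted coin, emulating an assembly
#' from one individual), a [surf_geno] in ref/alt space with effect
#' classes, gene models, and outgroup genotype panels covering focal SNPs
#' and outgroup-substituted positions.
#'
#' @param sim a `surf_sim`.
#' @return List: `geno`, `ref` (named chromosome sequences), `gene_models`,
#'   `outgroup` (a `surf_outgroup`), `truth` (site table with the true
#'   ancestral allele and `ref_is_derived` flag), `popmap`.
#' @export
as_variant_data <- function(sim) {
  cfg <- sim$config
  withr::with_seed(cfg$seed + 13L, {
    n_hap <- nrow(sim$haps)
    dfreq <- colSums(sim$haps) / n_hap
    ref_is_derived <- runif(length(dfreq)) < dfreq
    ref_al <- ifelse(ref_is_derived, sim$sites$derived_base,
                     sim$sites$ancestral_base)
    alt_al <- ifelse(ref_is_derived, sim$sites$ancestral_base,
                     sim$sites$derived_base)
    dos <- sim$geno
    dos[, ref_is_derived] <- 2L - dos[, ref_is_derived, drop = FALSE]
    sites <- tibble(
      chrom = sim$sites$chrom, pos = sim$sites$pos,
      ref = ref_al, alt = alt_al,
      effect = sim$sites$effect, gene_id = sim$sites$gene_id
    )
    g <- surf_geno(dos, sites, sim$samples)
    # reference genome: fixed substitutions + derived ref alleles
    ref_subs <- bind_rows(
      tibble(cds_index = sim$fixed$cds_index,
             base_idx = match(sim$fixed$derived_base, BASES)),
      tibble(cds_index = sim$sites$cds_index[ref_is_derived],
             base_idx = match(sim$sites$derived_base, BASES)[ref_is_derived])
    )
    ref <- sim_chrom_seqs(sim, ref_subs)

    gene_models <- sim$genome$genes |>
      mutate(
        transcript_id = paste0(.data$gene_id, ".t1"),
        cds = purrr::map2(.data$start, .data$end,
                          ~ tibble(start = .x, end = .y, phase = 0L)),
        cds_len = .data$end - .data$start + 1L,
        in_frame = TRUE
      ) |>
      select("gene_id", "transcript_id", "chrom", "strand", "cds",
             "cds_len", "start", "end", "in_frame")

    # outgroup panels: species base at focal SNPs and substituted positions
    og_sites_idx <- sort(unique(c(
      sim$sites$cds_index, sim$fixed$cds_index,
      unlist(lapply(sim$outgroup_subs, `[[`, "cds_index"))
    )))
    gi <- sim$genome$gene_of_pos[og_sites_idx]
    og_sites <- tibble(
      chrom = sim$genome$genes$chrom[gi],
      pos = sim$genome$genes$start[gi] + og_sites_idx -
        (gi - 1L) * sim$genome$gene_len - 1L
    )
    anc_base <- BASES[sim$genome$ref_base_idx[og_sites_idx]]
    n_sp <- length(sim$outgroup_subs)
    n_ind <- cfg$n_outgroup_ind
    a1 <- matrix(NA_character_, n_sp * n_ind, length(og_sites_idx))
    for (sp in seq_len(n_sp)) {
      sp_base <- anc_base
      subs <- sim$outgroup_subs[[sp]]
      hitq <- match(subs$cds_index, og_sites_idx)
      sp_base[hitq] <- BASES[subs$base_idx]
      rows <- (sp - 1) * n_ind + seq_len(n_ind)
      a1[rows, ] <- matrix(rep(sp_base, each = n_ind), nrow = n_ind)
    }
    miss <- matrix(runif(length(a1)) < 0.02, nrow(a1), ncol(a1))
    a1[miss] <- NA_character_
    outgroup <- new_outgroup_panel(
      a1, a1, og_sites,
      samples = sprintf("og%d_i%02d", rep(seq_len(n_sp), each = n_ind),
                        rep(seq_len(n_ind), n_sp))
    )
    truth <- sim$sites |> mutate(ref_is_derived = ref_is_derived)
    list(geno = g, ref = ref, gene_models = gene_models, outgroup = outgroup,
         truth = truth, popmap = sim$popmap)
  })
}

#' Sample an SFS pair directly from the PRF model
#'
#' Poisson draws around [expected_sfs()] expectations: the fast route to
#' DFE-recovery experiments without forward simulation.
#'
#' @inheritParams expected_sfs
#' @param seed RNG seed.
#' @param L_syn,L_nonsyn site totals recorded in the pair.
#' @param D_syn,D_nonsyn optional divergence counts.
#' @return A `surf_sfs`.
#' @export
sample_prf_sfs <- function(n, theta_s, theta_n, shape, mean_Sd, p_b = 0,
                           mean_Sb = 1, r = rep(1, n - 1), eps_anc = 0,
                           seed = 1, L_syn = NULL, L_nonsyn = NULL,
                           D_syn = NA_real_, D_nonsyn = NA_real_) {
  e <- expected_sfs(n, theta_s, theta_n, shape, mean_Sd, p_b, mean_Sb, r,
                    eps_anc)
  counts <- withr::with_seed(seed, {
    list(syn = rpois(n - 1, e$syn), nonsyn = rpois(n - 1, e$nonsyn))
  })
  if (is.null(L_syn)) L_syn <- max(sum(counts$syn) * 10, 1)
  if (is.null(L_nonsyn)) L_nonsyn <- max(sum(counts$nonsyn) * 10, 1)
  new_sfs_pair(n, counts$syn, counts$nonsyn, L_syn, L_nonsyn, D_syn, D_nonsyn)
}

#' Single-locus fixation trials of the simulator's selection scheme
#'
#' Runs `n_trials` Wright-Fisher trajectories of a new mutation (fitness
#' 1, 1-h*s, 1-s) and returns the realized fixation probability, for
#' checking the simulator against the diffusion prediction
#' [fixation_rel()].
#'
#' @param N diploid population size.
#' @param s selection coefficient (negative = beneficial in this scheme).
#' @param h dominance.
#' @param n_trials number of trajectories.
#' @param seed RNG seed.
#' @return One-row tibble: `fixed`, `trials`, `p_fix`.
#' @export
fixation_probability <- function(N, s, h = 0.5, n_trials = 1e5, seed = 1) {
  r <- .wf_fixation_trials(N, s, h, n_trials, seed)
  tibble(fixed = r[1], trials = r[2], p_fix = r[1] / r[2])
}

#' Write every pipeline input format for a simulated dataset
#'
#' Emits the focal VCF, outgroup VCF, reference FASTA, GFF3 gene models,
#' effect-class TSV, population map TSV, tetraploid BED, TE BED and truth
#' tables, and returns a manifest with MD5 checksums. Re-reading the VCF
#' through [read_variants()] reproduces the genotype matrix exactly.
#'
#' @param sim a `surf_sim`.
#' @param out_dir output directory (created if needed).
#' @return Tibble manifest: `file`, `md5`.
#' @export
emit_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vd <- as_variant_data(sim)
  paths <- c(
    vcf = file.path(out_dir, "focal.vcf"),
    outgroup_vcf = file.path(out_dir, "outgroup.vcf"),
    fasta = file.path(out_dir, "reference.fa"),
    gff = file.path(out_dir, "genes.gff3"),
    effects = file.path(out_dir, "effects.tsv"),
    popmap = file.path(out_dir, "popmap.tsv"),
    tetra_bed = file.path(out_dir, "tetraploid.bed"),
    te_bed = file.path(out_dir, "te.bed"),
    truth = file.path(out_dir, "truth_sites.tsv"),
    truth_fixed = file.path(out_dir, "truth_fixed.tsv")
  )
  write_variants_vcf(vd$geno, paths["vcf"])
  write_outgroup_vcf(vd$outgroup, vd$geno, paths["outgroup_vcf"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(vd$ref), paths["fasta"])
  write_sim_gff(vd$gene_models, paths["gff"])
  readr::write_tsv(
    vd$geno$sites |>
      select("chrom", "pos", "ref", "alt", class = "effect", "gene_id"),
    paths["effects"]
  )
  readr::write_tsv(vd$popmap |> select(-"deme"), paths["popmap"])
  tet <- sim$genome$genes |> filter(.data$compartment == "tetraploid")
  writeLines(sprintf("%s\t%d\t%d", "chr31", 0L,
                     max(tet$end) + sim$genome$gap), paths["tetra_bed"])
  te <- sim_te_regions(sim)
  writeLines(sprintf("%s\t%d\t%d\t%s", te$chrom, te$start, te$end, te$label),
             paths["te_bed"])
  readr::write_tsv(vd$truth, paths["truth"])
  readr::write_tsv(sim$fixed, paths["truth_fixed"])
  tibble(file = unname(paths), md5 = unname(tools::md5sum(paths)))
}

# outgroup VCF against the focal reference
write_outgroup_vcf <- function(outgroup, focal_geno, path) {
  key_f <- paste(focal_geno$sites$chrom, focal_geno$sites$pos)
  key_o <- paste(outgroup$sites$chrom, outgroup$sites$pos)
  at_focal <- match(key_o, key_f)
  # REF from focal where known; otherwise the modal outgroup base
  ref <- ifelse(!is.na(at_focal), focal_geno$sites$ref[at_focal], NA)
  for (j in which(is.na(ref))) {
    tab <- table(outgroup$a1[, j])
    ref[j] <- names(tab)[which.max(tab)]
  }
  gt_code <- function(a, ref_b, alt_b) {
    ifelse(is.na(a), ".", ifelse(a == ref_b, "0", "1"))
  }
  alt <- rep(".", length(ref))
  for (j in seq_along(ref)) {
    bs <- unique(c(outgroup$a1[, j], outgroup$a2[, j]))
    bs <- setdiff(bs[!is.na(bs)], ref[j])
    if (length(bs)) alt[j] <- bs[1]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", outgroup$samples), collapse = "\t")
  )
  gts <- vapply(seq_along(ref), function(j) {
    g1 <- gt_code(outgroup$a1[, j], ref[j], alt[j])
    g2 <- gt_code(outgroup$a2[, j], ref[j], alt[j])
    g1[g1 == "." | g2 == "."] <- "."
    g2[g1 == "."] <- "."
    paste(paste(g1, g2, sep = "/"), collapse = "\t")
  }, character(1))
  body <- paste(outgroup$sites$chrom, outgroup$sites$pos, ".", ref, alt,
                ".", "PASS", ".", "GT", gts, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_sim_gff <- function(gene_models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    lines <- c(
      lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom, g$start,
              g$end, g$strand, g$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", g$chrom,
              g$start, g$end, g$strand, g$transcript_id, g$gene_id),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s", g$chrom,
              g$start, g$end, g$strand, g$transcript_id, g$transcript_id)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

# synthetic TE annotation: denser, longer elements on the tetraploid chromosome
sim_te_regions <- function(sim) {
  withr::with_seed(sim$config$seed + 23L, {
    genes <- sim$genome$genes
    purrr::map_dfr(unique(genes$chrom), function(ch) {
      len <- max(genes$end[genes$chrom == ch]) + sim$genome$gap
      tetra <- ch == "chr31"
      n_te <- rpois(1, if (tetra) len / 2000 else len / 4000)
      if (n_te == 0) return(tibble())
      te_len <- pmax(50L, as.integer(stats::rexp(n_te,
                                                 1 / (if (tetra) 400 else 200))))
      st <- as.integer(runif(n_te, 0, len - te_len))
      fam <- sample(c("TE:DNA", "TE:LINE", "TE:LTR"), n_te, replace = TRUE)
      tibble(chrom = ch, start = st, end = st + te_len, label = fam)
    })
  })
}
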