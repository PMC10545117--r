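---
title: "Methods: quantifying expansion load and selection efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying expansion load and selection efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Populations at the front of a range expansion are founded serially by few
individuals. The repeated founder events inflate genetic drift, so weakly
deleterious variants can rise in frequency or fix by "allele surfing",
building up an *expansion load* that purifying selection cannot efficiently
remove. `surfload` implements the analysis chain used to detect this
process in population resequencing data — polarization against outgroups,
per-individual deleterious-allele counting, piN/piS along geographic and
genomic axes, and selection-efficacy estimation from the site frequency
spectrum (SFS) — together with a forward simulator that generates data with
the same statistical structure and known truth, so every stage can be
validated end to end.

# Models and procedures

## Polarization

At each biallelic SNP, the ancestral allele is the modal homozygous allele
of the outgroup panel, accepted only when (i) at least 90% of the
non-missing outgroup individuals are homozygous for it and (ii) it matches
one of the two focal alleles. Everything else is treated as missing and
excluded from load analyses. We interpret "90% of individuals" as 90% of
*non-missing* individuals and pool the outgroup species by default (a
per-species consensus is available through the `samples` argument of
`outgroup_consensus_cds()`); both choices matter only at sites with
substantial outgroup missingness or deep inter-species disagreement.

## Coding statistics

Site counting is Nei–Gojobori (1986) equal-weight counting: each codon
position contributes one site, split into synonymous and nonsynonymous
fractions by how many of its three single-base changes preserve the amino
acid, with changes to stop codons removed from the denominator. This
convention is stated explicitly so that the test oracles (exhaustive
enumeration of all nine changes per codon) are well defined. Diversity per
site uses the unbiased estimator `2 p (1-p) n/(n-1)`; ratios are
ratio-of-sums over concatenated gene sets, never means of per-gene ratios,
because per-gene piS in low-diversity genomes is dominated by zeros. For
the same reason genome-wide scans use windows of 4 Mb of *concatenated gene
space*. Codon columns containing missing data in any haplotype are excluded
alignment-wide from the diversity statistics, keeping site totals shared
across haplotypes; the SFS construction instead applies its own per-site
coverage rule (below), as its filters operate site by site.

GC3 — the GC fraction at third codon positions of the consensus sequence —
serves as the recombination proxy: long-term recombination drives GC-biased
gene conversion (gBGC), so GC3 tracks the recombination landscape. Genes
are sorted by ascending GC3 into equal-count bins (default 20,
configurable; the bin count behind the published analyses of this design is
not standardized). A filter to GC-conservative polymorphisms (A/T and C/G
pairs), which gBGC cannot distort, is provided as a robustness route.

## Load counting

For an effect class (missense, loss-of-function, or synonymous as a
negative control), each individual's additive (total) load is
`Ntotal = 2*Nhomo + Nhetero` derived alleles and its recessive (fixed) load
is `Nhomo`. Counts are raw per-individual numbers (not per-site rates) by
default, matching the way such counts are reported; a `per_site` option
exists for datasets with very unequal missingness. Sites where the derived
allele is fixed in every population are included — there is no segregation
requirement — and among-population differences are tested by one-way ANOVA
with Tukey HSD contrasts and an additional Bonferroni correction across
contrasts.

## SFS construction

Per population, coding alignments are filtered with the classical
alignment-cleaning rules: haplotype sequences with more than 50% missing
data are dropped (`gapN_seq`), genes need at least 6 complete codons
(`min_nb_codon`), internal stop codons outside a 20-codon terminal
tolerance zone disqualify a gene (`tolerance_zone`), and a site is used
only if at least 10 haplotypes are ungapped there (`gapN_site`). Sites are
polarized with the ancestral assignments and down-projected to a haploid
sample size of 8 by the *expected* hypergeometric projection — fractional
class counts, which keeps the construction deterministic rather than
resampling-based. Divergence is counted at monomorphic columns against an
outgroup consensus, position by position under the same NG86
classification; no transition/transversion correction is applied (the
divergences involved are small enough that multiple hits are negligible at
this scale, and the uncorrected counts keep the polymorphism and divergence
pipelines identical). Because a pooled multi-species consensus approximates
the focal ancestor — species-specific substitutions cancel out — divergence
is better counted against a single (typically the most diverged) outgroup
species, which is what the pipeline does by default in the packaged
experiments.

## The DFE likelihood

The distribution of fitness effects is estimated from the unfolded SFS pair
by Poisson random field maximum likelihood. With scaled coefficient
`S = 4*Ne*s` (negative deleterious), the sojourn density of a derived
allele is

    H(x; S) = (1 - exp(-S(1-x))) / (x (1-x) (1 - exp(-S)))

with neutral limit `1/x`, and the expected count in frequency class `i` of
`n` is the DFE-weighted integral of `H` against the binomial sampling
kernel. Synonymous classes are neutral and computed analytically
(`theta * r_i / i`). The DFE is "GammaExpo": a reflected gamma (shape,
mean `mean_Sd < 0`) plus an optional exponential beneficial tail of mass
`p_b`; "GammaZero" fixes `p_b = 0`. Nuisance parameters follow the
established design: class-specific distortion multipliers `r_i` (with
`r_1 = 1`) shared between synonymous and nonsynonymous spectra absorb
demography, linked selection and genotyping error, and a misorientation
probability `eps_anc` mixes class `i` with `n - i`.

One identifiability decision deserves emphasis: the per-site mutational
input is tied between classes, `theta_n / theta_s = L_nonsyn / L_syn`
(`tie_theta = TRUE`). The *absolute deficit* of nonsynonymous polymorphism
relative to its mutational opportunity is the main evidence for strongly
deleterious mass; leaving both thetas free discards it, and spectra of a
few hundred SNPs then collapse to degenerate corner solutions. An untied
variant remains available.

Numerics: the deleterious integral uses Gauss–Legendre quadrature on
log10|S| over [1e-4, 1e5] (160 nodes), the frequency integral a log panel
near zero plus a linear panel (220 + 64 nodes); DFE mass below |S| = 1e-4
is treated analytically as neutral and mass above the upper bound is
assigned the boundary integral. The normalization of the discretized DFE
is tested to 1e-8, and the class integrals against `stats::integrate` to
1e-6. Optimization is multi-start (default 5 dispersed starts under a
recorded seed) box-constrained quasi-Newton (`nlminb`); model comparison
between GammaZero and GammaExpo is reported by AIC, not enforced.

Selection efficacy uses the relative fixation probability
`u(S) = S / (1 - exp(-S))`, `u(0) = 1`:
`omega_NA = integral of phi(S) u(S) over S <= 0`,
`omega_A = dN/dS - omega_NA` and `alpha = omega_A / (dN/dS)` — exact
identities by construction. For per-population fits at desk scale the
packaged pipeline defaults to GammaZero with misorientation fixed at zero:
the beneficial fraction and eps are weakly identified from single-population
spectra of a few hundred SNPs, and the recovery experiments (below) fit
the full GammaExpo where the data actually carry that information.

## Residual tetraploidy and TE contrasts

Genes are assigned to the diploid or residually tetraploid compartment by
the salmonid chromosome rule (1–30 diploid, 31–38 tetraploid) or an
explicit BED. The tetraploid piN/piS is compared against a null of 200
resampled diploid sets of 4,000 genes (sampled without replacement; scaled
down proportionally on smaller gene sets, with a message). The GC-matched
contrast computes GC in fixed genomic windows separately per compartment,
bins windows into GC quantiles (lowest bin = bottom quintile by default,
configurable), and compares compartments within bins — isolating whether
recombination, not ploidy, drives any excess. TE content is compared as
per-element length divided by chromosome length, with a two-sided
Mann–Whitney test.

## Population statistics

Ho is the mean per-site heterozygote fraction; beta_ST follows the
Weir–Goudet allele-matching formulation with distinct draws within
populations (note this estimator is slightly negative when evaluated on
literally duplicated finite samples — its zero is defined at the parameter
level); Tajima's D uses the standard constants per 100-kb window with
population means over windows with at least 3 segregating sites; FST is the
multi-locus ratio-of-averages Weir–Cockerham (1984) estimator; LD decay
bins dosage-correlation r² by log-spaced distance; and the population tree
is neighbor joining on the FST matrix, rooted at the minimal-beta_ST
population (the most ancestral), with root-to-leaf branch-length sums as
the expansion-route proxy. Negative NJ branch lengths are clamped to zero
with a warning.

# The synthetic-data generator

`simulate_expansion()` is an individual-based Wright–Fisher simulator
(C++ core) of a 1-D stepping-stone expansion: the source deme (N = 500
diploids) burns in for 2N generations; every 50 generations the next of 10
demes is founded by K = 10 individuals from the current front and regrows
logistically (factor 1.15 per generation) toward its carrying capacity;
neighbouring demes exchange migrants at m = 0.01 per generation; 150
generations follow the last founding so spectra partially re-equilibrate
(rare-variant deficits refill quickly from new mutation while surfed
high-frequency excesses persist on the slower 1/(h s) timescale).
Carrying capacities decline linearly to 30% of the source by the front
(`capacity_gradient = 0.7`), reflecting the persistently smaller habitats
and effective sizes of recently colonized range-edge populations; with a
uniform metapopulation, selection efficacy re-equalizes within a few
hundred generations of regrowth and the efficacy cline decays — the
gradient keeps the front's long-term Ne genuinely lower, which is the
regime the analysis is designed to detect.

Mutations arise on a 120-gene coding map (50 codons each) at the salmonid
rate 8e-9 /bp/generation rescaled by 1000 so kilobase-scale genes
accumulate realistic diversity in minutes of computing; the rescaling
factor is recorded in the manifest. Synonymous or nonsynonymous status
comes from the actual codon structure of the reference sequence (mutations
creating stop codons are redrawn; premature stops are therefore absent by
construction and the internal-stop alignment filters are exercised with
constructed fixtures instead). Nonsynonymous selection coefficients are
gamma distributed (shape 0.3, mean s = 0.01, i.e. mean |S| = 20 at the
source size) with dominance h = 0.3 — deleterious mutations are partially
recessive, which is what separates the additive from the recessive load —
plus a 2% exponential beneficial tail (mean s = 0.01, h = 0.5).
Loss-of-function variants are modelled as the most deleterious gamma tail,
above the 60th percentile (threshold s around 0.004, |S| around 7 at the
source). The cut is deliberately milder than an "always lethal" reading of
LoF: a tail so severe that it can never drift to homozygosity would make
the recessive LoF load identically zero everywhere, whereas annotated LoF
sets in real data include many tolerated variants, and it is precisely the
surfable part of that tail that generates the homozygous-LoF gradient the
analysis measures.

Recombination acts between genes (crossover probability 0.01 between
adjacent genes, 0.5 across chromosome boundaries). A quarter of the genes
sit on a "tetraploid" chromosome; its AT-rich half (GC3 target 0.33)
recombines essentially not at all (1e-5), coupling GC3 to recombination
phenomenologically as gBGC does in real genomes — the generator does not
simulate gene conversion itself, it reproduces its footprint so that GC3
binning and GC-matched contrasts have signal. Diploid genes carry a smooth
GC3 gradient (0.40–0.75) along each chromosome. Tetrasomic inheritance is
*not* simulated; the tetraploid compartment differs only by recombination,
which is exactly the hypothesis (recombination, not ploidy) the contrast
machinery is meant to isolate.

Three outgroup "species" diverge from the ancestral sequence by filtered
Poisson substitution at densities 2%, 4% and 6% (nonsynonymous
substitutions accepted with probability 0.2, their dN/dS); panels of 5
diploid individuals per species are emitted with 2% missing genotypes.
The emitted reference genome is the species consensus — ancestral sequence
plus all substitutions fixed during the run — with the reference allele at
segregating sites drawn by a frequency-weighted coin, emulating an assembly
from one individual; polarization therefore has genuinely to flip a
fraction of sites. Sixteen diploids are sampled per deme.

What the generator does *not* emulate: linked neutral intergenic variation
(only coding positions mutate), gene conversion, mutation-rate and
recombination-rate heterogeneity beyond the two-class structure,
population structure within demes, and sequencing/genotyping error beyond
missingness. Passing the validation suite therefore shows the estimators
recover truth under the model's assumptions at desk scale — not that any
particular empirical dataset satisfies those assumptions.

# Validation experiments and problem sizes

`surfing_replicates()` runs 20 replicates of the default scenario through
the full pipeline (about half a minute each) and summarises, per replicate,
the Spearman correlation of each metric with deme index. The qualitative
expansion signatures asserted by the test suite are: heterozygosity
declining and recessive load (missense and LoF) increasing along the
expansion in at least 90% of replicates; piN/piS increasing and fitted
alpha declining in at least 80%; additive load varying less among demes
than recessive load; and, pooled over replicates, the low-recombination
gene class showing elevated piN/piS with the GC-matched contrast isolating
the tetraploid low-GC cell. `dfe_recovery_experiment()` checks parameter
recovery of the PRF machinery itself on directly sampled spectra (n = 20,
theta 5000 per class): gamma shape within 0.1 and log10|mean_Sd| within
0.5 in at least 8 of 10 replicates, fitted without the distortion nuisances
because the sampled data are undistorted (the distortion machinery is
exercised by its own likelihood-ratio test). The recovery experiment sizes
the synonymous panel to match the nonsynonymous one, as a designer of such
an experiment naturally would.

The per-population fits inside the pipeline use the GammaZero model and a
single outgroup species for divergence, as discussed above; both choices
are arguments, not constants.

# Known limitations

- The expansion signatures on piN/piS and alpha are weak relative to
  replicate-level stochasticity at desk scale: single replicates can show
  reversed clines, which is why the assertions are phrased over 20
  replicates.
- Frameshift handling in the SFS filters is nominal (the reconstruction
  never produces indels), and kappa-style multiple-hit corrections to
  divergence are not implemented; a hook exists in the sense that
  divergence counting is isolated in one function.
- The resampling null for the tetraploid contrast samples gene sets
  without replacement; with-replacement sampling gives marginally wider
  nulls but was not adopted.
- beta_ST-based rooting of the FST tree is a principled default, not the
  only defensible one; `fst_tree()` accepts an explicit root.
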