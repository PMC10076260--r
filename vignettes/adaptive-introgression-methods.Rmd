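---
title: "Detecting adaptive introgression between crop genepools: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive introgression between crop genepools: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
library(dplyr)
```

# The problem

Domesticated common bean comes in two deeply diverged genepools — Andean and
Mesoamerican — that hybridised after both were introduced into a new range.
When material from one genepool introgresses into the other and then rises
to high frequency because it carries an adaptive variant (say, a flowering
or photoperiod allele useful at high latitude), the signal is threefold: an
excess of foreign ancestry at the locus, a haplotype-frequency signature of
selection, and strong allele-frequency differentiation between the new range
and the centres of origin. `introscan` implements that whole analytical
chain on phased SNP panels, together with the diversity, linkage
disequilibrium (LD), genetic-load and quantitative-trait (QST–FST) analyses
that surround it, and a synthetic-panel generator so every stage can be
validated against known truth.

# Haplotype painting

Each recipient haplotype is modelled with a Li & Stephens copying model: the
hidden state is which donor haplotype is being copied. Between adjacent
sites `d` bp apart the chain switches to a uniformly chosen donor with
probability `1 - exp(-Ne * rho * d / N)` (N donors; the self-copy keeps its
`1/N` share of the switch mass), and the emitted allele matches the copied
donor with probability `1 - Mu`. Posterior copying probabilities come from a
scaled forward–backward pass (per-site normalisation constants rather than
log-sum-exp, which keeps the cost at `O(L*N)`; the tests verify the result
against exhaustive path enumeration to 1e-10). Missing alleles, on either
side, contribute a flat emission.

`Ne` (recombination scaling) and `Mu` (miscopy rate) are estimated per
accession with exactly 10 EM iterations over both haplotypes: the expected
switch count determines `Ne` through a monotone one-dimensional root find,
and the expected miscopy fraction gives `Mu` directly. Fully selfed lines
carry two identical haplotypes; the implementation detects this and computes
each distinct haplotype once.

No recombination map is assumed: genetic distance is physical distance times
a constant `rho` (default 1e-8 per bp), exposed in the configuration. Donor
haplotype posteriors are summed within the five donor races (`AM_M1`,
`AM_M2` Mesoamerican; `AM_A1`–`AM_A3` Andean), so per-SNP vectors over
groups still sum to one.

# Windows, genepool calls, blocks, masks

Per-SNP group probabilities are averaged within 10-kb non-overlapping
windows; a window is assigned to the group whose mean probability reaches
0.8, otherwise it is `unknown` (windows without SNPs are `unknown` too). We
read the threshold as applying to the window-mean probability — averaging is
the only combination the windowing construction supports.

Each accession's genepool is called from two criteria: (a) the overall
proportion of assigned windows that are Andean vs Mesoamerican, and (b) the
per-chromosome majority vote. The call is made only when both agree;
otherwise the accession is flagged ambiguous and excluded from group-level
statistics downstream (on two-chromosome synthetic panels, ties under
criterion (b) make this flag fairly common; with eleven chromosomes it is
rare).

Introgression blocks are maximal runs of windows assigned to the *other*
genepool, with runs separated by at most 50 kb joined (the gap may bridge
`unknown` or same-genepool windows, which do not count towards support) and
blocks supported by a single 10-kb window removed. Block coordinates span
the join, matching interval-merge semantics; per-accession length
distributions are summarised by the median because they are strongly
non-normal. Ancestry masks set an allele to missing wherever its window is
labelled with the other genepool or `unknown`, producing an Andean-masked
and a Mesoamerican-masked panel; masking is idempotent and the two masks
partition the observed alleles.

# Excess introgression and PAIL calling

At each SNP, each recipient haplotype inherits the genepool of its
containing window. With `n_and` Andean-called and `n_mes`
Mesoamerican-called accessions, the expected Andean fraction at a neutral
SNP is all Andean haplotypes plus half the Mesoamerican ones:

    F_A = (2 n_and + n_mes) / (2 (n_and + n_mes))
    F_M = (2 n_mes + n_and) / (2 (n_and + n_mes))

For the 71/43 split these give 0.811 and 0.688 after truncation to three
decimals — truncation, not rounding, reproduces the quoted values, and the
comparison is `>=` for both genepools. Unknown-window haplotypes stay in the
denominator. Flagged SNPs become 5-kb regions (`slop` 2500 bp, clipped at
chromosome ends), regions within 10 kb are merged, and only regions holding
at least three flagged SNPs survive.

A putative adaptive introgressed locus (PAIL) is a region with all three
evidence layers: excess introgression, a haplotype-cluster selection
signature, and an outlier FST window, intersected at the region level (any
overlap). Genes are attributed by interval overlap and classified as
selection-only, introgression-only, both, or PAIL.

# Selection scan

**Windowed FST.** Per-SNP Weir & Cockerham (1984) variance components are
summed within 10-kb windows, `sum(a) / sum(a+b+c)`; negative window values
are retained, and the window distribution is summarised by mean and IQR.

**Kinship.** On a panel thinned to one SNP per 250 kb, pairwise population
differentiation (ratio-of-sums Weir & Cockerham) is mapped to the Reynolds
scale `D = -log(1 - t)`, a neighbour-joining tree is built and
midpoint-rooted (no outgroup exists for two crop genepools, and midpoint
rooting is standard FLK practice), and the kinship matrix F holds shared
root-to-MRCA branch lengths. Negative NJ branch lengths are clamped to zero.
With fewer than three populations a star tree is used with a warning.

**FLK.** For allele frequencies `p` across populations, the ancestral
estimate is the kinship-weighted mean `p0 = (1'F⁻¹p)/(1'F⁻¹1)` and the
statistic is `(p - p0 1)' [p0 (1 - p0) F]⁻¹ (p - p0 1)`, chi-square with
`n_pop - 1` df under drift. With `F = c I` it reduces to the classical
Lewontin–Krakauer statistic (verified numerically), and under a
Balding–Nichols drift-only null its type-I error at 5% lands inside
[0.035, 0.065] in the acceptance checks.

**hapFLK-style statistic.** A fastPHASE-type haplotype-cluster HMM (K
clusters; per-site cluster allele frequencies and weights; a
distance-dependent jump probability tied across clusters, with the jump
intensity re-estimated each EM step) is fitted to all haplotypes jointly,
chromosomes independently. At each SNP the per-population cluster
frequencies (posterior occupancies) replace allele frequencies in an
FLK-type quadratic form summed over clusters. Because the likelihood is
multimodal the statistic is averaged over 20 independent EM fits by default.
EM starts are built as mirrored cluster pairs around the site frequency
(pairs share their weight column; an odd K adds a self-mirrored cluster at
0.5), which makes the statistic exactly invariant to swapping allele labels
— a property the tests assert. EM stops at 100 iterations or an absolute
log-likelihood change below 1e-4.

We read "20 expectation–maximisation cycles" as 20 independent fits whose
statistics are averaged (matching the averaging language and the standard
tool's `--nfit`); both the fit count and the per-fit iteration cap are
exposed as parameters, so the other reading (20 iterations within one fit)
is also available.

**K selection.** The cluster count is chosen by masked-imputation
cross-validation: on a panel thinned to ≥100 kb spacing, five replicate
copies each mask 10% of genotypes; for each K in {5, 10, 20, 30, 40, 50}
the model is fitted to the masked copy and hidden genotypes are imputed from
the fitted cluster posteriors; the K minimising the mean wrongly-imputed
proportion (Wp) wins.

**Scaling and regions.** Raw statistics are referred to a chi-square null by
robust moment matching: the effective df and scale solve the 2-by-2 system
matching the genome-wide median and 75th percentile to `s * chisq_d` (the
robust quantiles make the fit insensitive to a selected tail). SNPs with
`p < 1e-3` and Benjamini–Hochberg `FDR < 0.05` (the FDR method is our
choice; only the bound is prescribed) become 10-kb regions centred on the
SNP, merged within 5 kb. Two runs (K = 5 and K = K*) combine into the
extended set (union) and the restricted set (interval intersection, hence
contained in both runs' coverage), and only regions containing at least one
top-5% (or top-1%) FST window are retained.

# Diversity, private alleles, load

Per-site nucleotide diversity is `pi = 2 k (n - k) / (n (n - 1))` over `n`
non-missing alleles with `k` alternates; regional `theta_pi`/bp sums
per-site values over the region span, a 100-kb window track is emitted, and
sites below a minimum proportion of non-masked individuals (PIND) can be
excluded — the lever used to test the stability of masked-panel estimates.
Region classes (callable/coding/neutral) are plain interval inputs; the
package does not infer them.

Private variants segregate in one continental group and are absent in the
other (frequencies over non-missing alleles only); they are split at 5%
frequency and into synonymous vs non-synonymous. Genetic load counts
non-reference alleles per accession by effect class (dosage by default,
presence by flag; missing genotypes contribute zero) and forms
missense/synonymous and loss-of-function/synonymous ratios (NA when the
synonymous count is zero), compared between groups with two-sided Wilcoxon
rank-sum tests (exact for groups of at most 20 without ties).

# LD

Decay curves use the squared Pearson correlation between haplotype allele
indicators (MAF ≥ 0.1, pairs up to 5 Mb), binned by distance, with the
`r² = 0.2` crossing linearly interpolated between bin midpoints. The
inter-chromosomal scan thins deterministically to the first qualifying SNP
per 10-kb cell (reproducibility over random sampling), scores all
cross-chromosome pairs, keeps `r² ≥ 0.8`, clusters SNP pairs whose two sides
both lie within 100 kb, and keeps region pairs spanning ≥500 kb per side
(≥50 kb in the within-selection-regions variant). A pair is private to a
group when no other group links the same two regions — both sides must
overlap; one-sided overlap leaves it private.

# Traits: H², PS, QST

Broad-sense heritability uses ANOVA method-of-moments with genotype (and
environment, when present) as random effects, components truncated at zero
— closed-form and dependency-free, adequate for the balanced synthetic
designs; REML is a reasonable alternative for unbalanced field data.
Photoperiod sensitivity is the long-day/short-day ratio of days to
flowering, with never-flowering accessions flagged rather than scored. PC1
of standardised traits (missing values mean-imputed and counted) is oriented
to correlate positively with the first input trait.

QST uses the one-way decomposition on accession means:
`QST = s2_B / (s2_B + 2 s2_W)` by default, with a selfing variant
(`s2_B / (s2_B + s2_W)`) recommended for fully inbred lines — the
literature's convention for the study species is not fixed, so both are
implemented and the choice is a flag. The outlier test places the focal QST
in the empirical (`<=`) percentile of a high-heritability (H² > 0.65)
metabolite QST reference and of the per-SNP FST distribution; the
selection-candidate verdict fires at the 97.5th percentile of the
metabolite reference.

# The synthetic generator

`sim_config()` fixes the study conditions the test-suite runs under: two
genepools drawn from a Balding–Nichols model at `f = 0.4` (realising
inter-genepool FST ≈ 0.4), five races nested inside them with a second,
smaller `f = 0.05`, 60 donor accessions (12 per race), 40 fully selfed
recipients (Andean-major in the observed 71:43 proportion), two 5-Mb
chromosomes with 1500 SNPs each, admixture `m = 0.1` laid down `g = 20`
generations ago at `r = 1e-8` recombination per bp per generation, and a
1e-3 miscopy rate during copying so painting is non-degenerate. Ancestry
along a haplotype is a two-state Markov tract process (switch probability
`1 - exp(-g r d)` over `d` bp, state redrawn with minor-ancestry probability
`m`), so visible minor-ancestry tracts are exponential with mean
`1/(g r (1-m))` — about 5.6 Mb under the defaults, deliberately at the
chromosome scale so that block extraction, gap-joining and masking are
exercised with realistically long introgression blocks. Balding–Nichols
rather than a coalescent simulator gives direct control of FST with no
external dependency; the price is no realistic site-frequency spectrum or
LD decay within donor races, so passing tests speak to the pipeline's
inferential machinery, not to demographic realism. Engineered
adaptive-introgression loci overwrite the tract state of a chosen fraction
of recipients inside an interval, creating jointly the ancestry excess and
the local frequency shift the PAIL definition requires.

Traits follow `value = group_mean (var s2_B) + line (var s2_W) + replicate
noise (var s2_E)` with expected `H² = (s2_B + s2_W)/(s2_B + s2_W + s2_E)`;
defaults `2/1/1` with three replicates.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; VCF positions
  are shifted on read/write and BED needs no shift. Human-readable tables
  are 1-based inclusive where emitted.
* Missing genotypes are a real state, propagated (never imputed) by all
  statistics; frequency-type quantities use non-missing denominators.
* Monomorphic sites: NA in FLK; skipped in LD; zero in diversity; removed
  by the MAF filter.
* `chi2_scale()` refuses a degenerate statistic distribution (median ≤ 0 or
  IQR collapse) rather than returning meaningless p-values.
* Window labels break argmax ties by first group in sorted order; in
  practice the 0.8 threshold makes ties irrelevant.
* EM non-convergence in a hapFLK fit (non-finite likelihood) excludes that
  fit with a warning; all fits failing is an error.

# Problem sizes used by the test-suite

The shipped tests run the full chain at the generator defaults above
(3000 SNPs, 100 accessions). The painting accuracy and block-recovery
checks share one painted panel; the end-to-end PAIL recovery check repeats
the whole pipeline over ten seeds with an engineered locus at
Chr01:2.25–2.75 Mb (90% carrier fraction), using 5 EM fits per hapFLK run
and a 30-iteration cap — a scaled-down setting of the same machinery whose
defaults (20 fits, 100 iterations) are used for real analyses. Tract-length
calibration uses 200 haplotypes on 200-Mb chromosomes so that interior
tracts are effectively uncensored; QST calibration uses 100 seeds for
parameter recovery and 400 seeds (39 exchangeable references) for the
neutral outlier rate.

# Known limitations

* The painting model ignores LD within the donor panel beyond the copying
  process itself; co-ancestry summaries and the "unlinked" mixture mode of
  the original tool are out of scope.
* The hapFLK-style statistic is a faithful re-implementation of the idea,
  not a bit-for-bit port; its absolute values differ from the original
  software, which is why the chi-square rescaling step exists.
* Dating introgression events, GWAS, orthology/GO enrichment and
  environmental association are outside the package's remit.
* With two-chromosome panels the chromosome-majority criterion often ties,
  flagging more accessions ambiguous than a full genome would.
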