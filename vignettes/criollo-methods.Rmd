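---
title: "Methods: diversity scans and isotope traits for bean panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity scans and isotope traits for bean panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(criollo)
```

This vignette is the package's own account of what it computes, the
assumptions behind each statistic, the conventions and defaults that matter,
and what the synthetic validation does and does not establish about real
data.

## The setting

A diversity panel of predominantly self-pollinating common bean lines —
traditional landraces alongside participatory-bred (PPB) and conventional
varieties — is genotyped on a ~6K SNP array and phenotyped in low-nitrogen
field trials. Array data of this kind has three properties that shape every
method choice here: sites are biallelic and sparse (a few per 100 kb, not
resequencing density), lines are close to fully inbred (heterozygous calls
are rare), and allele frequencies are ascertainment-biased toward
intermediate values. The pipeline treats dosages (alternate-allele counts 0,
1, 2 per diploid line) as the fundamental observation and never requires
phase.

## Windowed diversity and Tajima's D

`site_pi()` is the unbiased pair-counting estimator
$\pi_{site} = 2x(n-x)/(n(n-1))$ with $x$ alternate alleles among $n$
non-missing chromosomes; per-site $n$ excludes missing calls. `windowed_pi()`
sums site values over non-overlapping tiles (default 1 Mb) and divides by
the *full window length in bp*. Dividing by window length rather than by the
number of assayed sites is deliberate: monomorphic positions count as zero
diversity implicitly, which is what puts array-panel values at the
$10^{-7}$–$10^{-6}$ per-bp scale and makes windows with different SNP
densities comparable. Windows containing no SNPs are omitted, and
genome-wide means (`genome_wide_summary()`) average over reported windows
only; whether empty windows are averaged as zero or omitted is a genuine
fork, and omission was chosen because an empty array window carries no
information about diversity, only about probe placement.

"Sliding" windows default to step = size (disjoint tiles) for both the 1 Mb
diversity windows and the 100 bp F~ST~ windows, matching how windowed scans
of this kind are conventionally tabulated; `step` is exposed for genuinely
overlapping scans, in which case the region caller's adjacency logic does
not apply.

`windowed_tajima_d()` computes, per window, the number of segregating sites
$S$, the mean pairwise difference $\hat k$ (site-pi summed over sites, in
site units), and
$D = (\hat k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard
constants from `tajima_constants()`. $D$ is undefined exactly when $S = 0$
and is excluded (never zero-filled) from genome-wide means. The chromosome
sample size feeding the constants is the modal non-missing chromosome count
across the window's sites — after `impute_missing()` this is simply twice
the sample count; the mode was preferred over the mean because it is stable
and integer-valued under scattered missingness.

Two caveats are documented rather than corrected. First, inbred panels
violate the random-mating sampling theory behind the $D$ variance constants,
so $D$ values are comparative indices between groups scanned identically,
not calibrated test statistics. Second, adjacent windows share linkage, so
group comparisons that treat windows as independent observations
(`welch_t_test()` on windowed values) inherit the usual autocorrelation
optimism; the test is provided in that form because that is how such
genome-wide group contrasts are conventionally reported.

## The diversity-ratio region caller

`call_high_diversity_regions()` flags windows where group A diversity
exceeds `ratio_threshold` (default 3) times group B diversity,
window-by-window on identical grids, merges qualifying windows that share a
boundary on the same chromosome, and keeps merged regions at least
`min_length` bp (default 25,000) long. With 1 Mb tiles the length rule never
filters; it is retained verbatim so the caller behaves sensibly at smaller
window sizes. A window with $\pi_B = 0$ qualifies iff $\pi_A > 0$ and its
ratio is reported as `Inf` — a zero-diversity denominator is the strongest
possible contrast, not a missing value. The comparison is window-by-window
(not region-aggregated) because the per-window ratio is what the region
tables of such scans list. Raising either threshold can only shrink the
called set (a property the tests verify), and re-calling on an already
merged result is a fixpoint.

## Weir–Cockerham F~ST~

`fst_site_components()` implements the 1984 two-population moment estimator
exactly as published: among-population ($a$), among-individual ($b$) and
within-individual ($c$) variance components from sample sizes, allele
frequencies and observed heterozygote frequencies. `windowed_fst()` reports
the "weighted" ratio-of-sums $\sum a / \sum(a+b+c)$ per window plus the mean
of per-site ratios; with 100 bp windows on array data nearly every window
holds one SNP, so weighted and per-site values coincide and the window
carries the SNP's position. Negative estimates are reported as computed —
clamping would bias any averaging done downstream. The outlier rule
(`call_fst_outliers()`) is a fixed threshold (default 0.5), not a p-value
procedure, so no multiple-testing correction applies; candidate windows
(`extract_candidate_windows()`) span 100 kb centred on the marker
(`[pos - 50000, pos + 50000)` in 0-based half-open coordinates), clipped at
the chromosome start, with optional gene-interval overlap from GFF3 input.

## Missing data

`read_vcf()` keeps biallelic SNPs with MAF > 0.01 (computed on non-missing
chromosomes) and missingness ≤ 0.2. `impute_missing()` replaces each missing
call with the site's modal non-missing dosage, ties broken toward the lower
dosage for determinism. At the <3% missingness typical of array panels the
choice of imputation rule is immaterial to windowed statistics; the modal
rule was chosen over statistical imputation because it is deterministic,
dependency-free and honest about its crudeness. All downstream statistics
also work on unimputed data by excluding missing calls per site.

## Isotope traits

`percent_ndfa()` is the 15N natural-abundance estimator
$100(\delta_{ref}-\delta_{fix})/(\delta_{ref}-B)$. Three conventions:

* The reference $\delta^{15}N$ is the mean over the environment's
  reference-line plots (`ndfa_table()` errors, naming the environment, if a
  trial lacks reference records) — the reference line is grown alongside the
  panel precisely so that it integrates the same soil N pool.
* $B$ — the $\delta^{15}N$ of beans whose entire N is fixed from the
  atmosphere — is a required configuration scalar
  (`isotope_config(b = ...)`), estimable from N-free growth-room records via
  `estimate_b_value()`. It is deliberately not hard-coded: $B$ is
  experiment-specific and publishing pipelines too often bury it.
* Estimates are not clamped to [0, 100]; an `out_of_range` flag is set
  instead, because clamping destroys the error structure that recovery
  diagnostics depend on.

An optional per-environment centring switch (`normalize = TRUE`) is exposed
but off by default; %Ndfa is invariant to a common shift of ref, fix and B,
so centring affects reporting only.

`carbon_discrimination()` converts seed $\delta^{13}C$ (‰) to
$\Delta^{13}C = (\delta_{air}-\delta_{plant})/(1+\delta_{plant})$ with
deltas as fractions, $\delta_{air} = -8$‰ by default and configurable. The
function is strictly decreasing in plant $\delta^{13}C$; lower
$\Delta^{13}C$ reads as higher water-use efficiency. At full precision the
classic $-28.2$‰ example evaluates to 20.79‰ (two-decimal presentations
often truncate to 20.7‰).

`pearson_matrix()` uses pairwise-complete observations with a minimum of 3
complete pairs per cell (sparser cells are `NA`, not zero). `gt_biplot()`
standardises traits, drops genotypes with missing cells (reported), and
returns scores plus loadings in the correlation-biplot convention
(eigenvectors scaled by component standard deviations), so acute/obtuse
angles between trait vectors track positive/negative correlations to the
extent that the first two components dominate.

## Structure and relatedness

Distances are allele-sharing p-distances on dosages: mean per-site
$|d_i - d_j|/2$ over jointly called sites. Substitution-model distances
(e.g. composite-likelihood nucleotide distances) are not identifiable from
biallelic array dosages, so no exact correspondence with trees built that
way on real data is claimed — topology-level agreement is what the p-distance
analogue supports. Neighbor joining is the classic agglomeration (via
`ape`); negative branch lengths, a known NJ artefact, are set to zero
with the deficit transferred to the adjacent sibling edge so local path
lengths are preserved. `bootstrap_support()` resamples site columns with
replacement (default 1000 replicates, seeded) and reports bipartition
frequencies. `genotype_pca()` mean-centres sites (mean-imputing missing
calls for the decomposition only) without variance scaling by default;
frequency scaling is exposed as an option because it changes how much weight
rare alleles get, which is a sensitivity question rather than a correctness
one.

## The synthetic generator: what it emulates, and its limits

`simulate_genotypes()` produces panels with the statistical structure the
analysis assumes, with complete truth records. Defaults mirror the study
conditions the pipeline targets: 72 inbred lines (30 landrace, 30 PPB, 12
admixed at 50/50), 5398 SNPs on 11 chromosomes of 50 Mbp, inbreeding
F = 0.98, ~2% missing calls, and 1084/5398 of sites planted below the
MAF 0.01 panel filter so the default panel filters to exactly 4314 SNPs.
Group frequencies are Balding–Nichols perturbations (drift parameter 0.02)
of a truncated-Beta(0.8, 0.8) ancestral frequency on [0.1, 0.9]; direct
frequency modelling was chosen over coalescent simulation because the scans
are validated against *planted* diversity ratios and frequency gaps, which
frequency models control exactly. The low drift parameter reflects that the
two groups are both domesticated Mesoamerican material separated by a few
decades of breeding, and it gives clean PCA/NJ separation without
manufacturing spurious selection signals.

Planted regions force landrace expected heterozygosity to `multiplier`
(default 5) times a PPB heterozygosity drawn from U[0.05, 0.09], on the same
side of 0.5, with at least 10 SNPs guaranteed per region. These defaults
come from a design-stage power analysis of the ratio caller: with ~10 SNPs
per window and 60 chromosomes per group, the log window-ratio has a standard
error near 0.3, so a true 5× contrast clears the 3× threshold with ~1.65
standard errors of margin (per-region sensitivity ≈ 0.95), while the
background log-ratio noise sits more than 4 standard errors below the
threshold across the ~550 windows of a genome — the operating point at which
the documented "sensitivity ≥ 0.9, ~0 false regions" behaviour is a design
property rather than luck. A multiplier of 5 is also the typical per-window
contrast such scans report in real landrace/improved comparisons. Requesting
a multiplier whose implied heterozygosity exceeds 0.5 is an error naming the
region. Planted outlier sites fix $|p_A - p_B|$ (default 0.9 at six sites),
which under near-complete inbreeding yields weighted F~ST~ well above the
0.5 cutoff; $\delta = 1$ gives exactly 1.

`simulate_neutral_panel()` draws alternate-allele counts from the neutral
site-frequency spectrum ($P(i) \propto 1/i$) over outbred diploids. Under
that law the pairwise and segregating-sites estimators of $\theta$ have
identical expectation, so genome-mean Tajima's *D* is zero up to Monte-Carlo
error — the analytic null used to validate the *D* scan.

`simulate_isotopes()` forward-models the natural-abundance design: reference
plots at $\delta^{15}N_{ref} = 3$‰, B = −2‰ (typical bean magnitudes;
both configurable), genotype-level true %Ndfa drawn per breeding group
(landrace 46.4, PPB 40.1, between-genotype SD 6 — the group contrast such
trials report), three replicate plots per genotype, six reference plots per
environment, and 0.2‰ measurement noise on each plot. The estimator then
inverts the truth exactly at zero noise, and at field noise the
per-genotype mean absolute error is ~2 %Ndfa points. Seed $\delta^{13}C$ is
generated by inverting the discrimination formula from a drawn true
$\Delta^{13}C$ (mean 18.5‰, SD 1‰), so discrimination recovery is exact at
zero noise by construction.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium and recombination
structure (sites are independent given frequencies), array genotyping error
modes (cluster-calling artefacts, probe failure), real pedigree relatedness
within groups (individuals are exchangeable draws), field spatial effects
and genotype × environment interaction in the isotope model, and the
lattice-design adjustment of trait means (the pipeline consumes trait means
produced by whatever mixed-model machinery the trial design requires).

## Problem sizes used in validation

The test suite and the acceptance script run the full pipeline on 20 seeded
replicates of the default 72 × 5398 panel (a few seconds each), exact
brute-force oracles on panels up to 10 × 50, 100-case random checks of the
Weir–Cockerham and Welch formulas against independently coded textbook
evaluations, additive-tree recovery up to 8 taxa, a 70-genotype isotope
trial, and a 20-sample × 2000-site neutral panel (~100 windows) for the
Tajima's *D* null. These sizes give every stochastic check a comfortable
margin relative to its tolerance while keeping a full validation run in the
minutes range on a single CPU.

## Known limitations

* Two-population F~ST~ only; no multi-group estimator, no haplotype
  statistics (EHH/iHS), no LD pruning.
* Tajima's *D* theory assumes outbred random mating; on inbred panels treat
  *D* as a comparative index.
* The diversity-ratio caller compares windows marginally; it does not model
  spatial autocorrelation along the chromosome.
* Admixture-proportion inference (STRUCTURE-style) is out of scope; the
  population map is an input, not an inference.
* The p-distance NJ tree is a relatedness summary, not a substitution-model
  phylogeny.
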