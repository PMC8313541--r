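---
title: "Models and methods behind hybridscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hybridscope dissects a collection of resequenced diploid genomes into pure
populations, clones, F1 hybrids, families and introgressed segments. The
design target is the situation found in east Asian mandarin citrus: a handful
of strongly differentiated ancestral populations, extensive interspecific F1
hybridization, clonal (apomictic) propagation that freezes hybrid genotypes in
place, and occasional multi-megabase introgression. This vignette explains
each statistic, the simulation model used to validate the stack, the default
parameters and the reasoning behind them, and the known limitations.

## The pairwise genomic distance D

For two diploids the package computes, over the sites callable and genotyped
in both samples,

$$D \;=\; 1 - \frac{\pi_1 + \pi_2}{4\,\pi_{12}},$$

where $\pi_1$ and $\pi_2$ are the two heterozygosities (fraction of included
sites heterozygous in each sample) and $\pi_{12}$ is the probability that one
allele drawn at random from each sample differs. Per site, with dosages
$a=g_1/2$ and $b=g_2/2$, the contribution to $\pi_{12}$ is $a(1-b)+b(1-a)$;
this with-replacement convention is what makes the two anchor values exact:

* clones: $\pi_{12} = \pi_1/2 = \pi_2/2$, so $D = 0$ identically;
* two unrelated members of one panmictic Hardy–Weinberg population:
  $E[\pi_1]=E[\pi_2]=E[\pi_{12}]=2pq$ per site, so $D = 0.5$;
* deeply diverged genomes: $\pi_{12}$ dominates and $D \to 1$.

Genome-wide D aggregates the $\pi$ *sums* over all included sites before
forming the ratio; it is not the mean of window values, which would weight
marker-poor windows equally with marker-rich ones. Windows with
$\pi_{12}=0$ are flagged undefined rather than given a number. Raw D can be
slightly negative for closely related pairs (shared haplotypes push
$\pi_{12}$ below $(\pi_1+\pi_2)/4$); the raw value is reported, with a
$[0,1]$-clamped companion used for distance-matrix consumers such as MDS.

## IBS, IBD and the coefficient of relatedness

In non-overlapping 200-kb windows the package counts IBS2 (joint genotype
AB|AB) and IBS0 (AA|BB) and forms the identity-by-state ratio
$\mathrm{IBSR} = \mathrm{IBS2}/(\mathrm{IBS2}+\mathrm{IBS0})$. Within one
population IBSR is independent of allele frequencies; its mean is 2/3 for
unrelated individuals under panmixia (per informative site the probability of
AB|AB is $(2pq)^2$ against $2(pq)^2$ for homozygous difference), and it is
exactly 1 whenever a haplotype is shared across the window because a shared
haplotype makes AA|BB impossible. Window IBD state follows the threshold
rule: IBSR < 0.95 gives IBD0; IBSR ≥ 0.95 with window D < 0.05 gives IBD2;
IBSR ≥ 0.95 with D > 0.05 gives IBD1. The rule leaves D exactly 0.05 open;
the package assigns IBD1, the conservative choice that avoids inflating clone
calls. Genome-wide fractions over classified windows give
$r = \tfrac12\,\mathrm{IBD1} + \mathrm{IBD2}$ (≈1 clones, ≈0.5
parent–offspring, ≈0.25 half-sibs, ≈0 unrelated).

Windows carry real information only when they contain joint genotypes; a
window with too few jointly genotyped sites is left undetermined rather than
classified. The cutoff (`min_informative`, default 50 jointly genotyped
callable sites per 200-kb window) is a package choice, exposed as
configuration. More fundamentally, the IBSR thresholds assume tens of
IBS-informative sites per window — see "Simulation scale" below.

## Interspecific phasing and haplotype sharing

Between two interspecific hybrids (or a hybrid and a putative parent) IBSR is
inflated by fixed species differences, so haplotypes are compared instead of
diploid genotypes. Phasing uses panels of representative accessions from the
two parental populations. The default rule is strict: a heterozygous site
resolves only in the diagnostic configuration, one allele absent from panel A
(allele count ≤ `tolerance`, default 0) and fixed in panel B, and vice versa.
A laxer `"present"` rule (allele assigned to the only panel where it occurs)
resolves more sites but mis-assigns alleles that segregate in both
populations and were missed by a finite panel; at the default drift levels it
mis-phases roughly 1 resolved site in 70–100, versus about 1 in 1000 for the
strict rule, which is why strict is the default. Phasing accuracy is limited
by panel size, not marker density: with three exemplars per side residual
errors sit near $10^{-3}$ per resolved site, and they vanish in the test
cohorts when every available founder is used as a panel member.

Two haplotype vectors are called identical in a window when their mismatch
rate over jointly resolved sites is below $2\times10^{-4}$, a threshold that
tolerates residual genotyping and phasing error. For parent–offspring
questions the package compares a phased haplotype against the candidate's
*diploid genotype* (`haplotype_consistency`): a site mismatches only when the
haplotype allele is absent from the candidate's genotype. Unlike
haplotype-to-haplotype identity this test is insensitive to crossovers in the
transmitted gamete — the candidate parent carries both of its haplotypes — so
a true parent is expected to be consistent in essentially every window, which
is exactly the signature used to call one accession the shared parent of a
half-sib family.

## Ancestry-informative markers and local ancestry

AIMs for a target population are biallelic SNVs homozygous for one allele in
every target exemplar and absent from all other populations' exemplars
(optionally after masking admixed exemplar segments). Because the two
mandarin subspecies are much less differentiated from each other than from
the other populations, a super-population (`MM` = MA ∪ MS) captures markers
fixed in the combined group relative to the rest; such sites are by
construction not member-population AIMs, so targets stay disjoint.

Local ancestry is assigned in non-overlapping windows of 500 AIMs in genome
order (never crossing a chromosome). For each unordered pair of ancestral
populations — heterozygous pairs and homozygous pairs alike — the window
log-likelihood sums, over AIMs, a binomial dosage model with genotyping-error
rate $\varepsilon$: the expected diagnostic-allele frequency is
$1-\varepsilon$, $1/2$ or $\varepsilon$ according to whether two, one or zero
haplotype ancestries match the AIM's target, and the observed dosage is
$\mathrm{Binomial}(2, q)$. Super-population AIMs match either member. The
call is the arg-max pair; a window is `Unknown` when any ancestral population
has fewer than 5 scored AIMs in it (super-population markers do not count
toward this minimum) or when the top-two log-likelihood margin falls below 2
log-units — a tie-break that prefers no call over a coin flip.
$\varepsilon = 0.01$ by default: large enough that a single discordant AIM
cannot veto a window, small enough that a heterozygous pair is preferred over
a homozygous call as soon as a few percent of AIMs show the second ancestry.
The likelihood form is this package's reconstruction (the windowed-AIM
approach itself is standard); its arg-max is validated against an exhaustive
scorer in the tests. Genome-wide admixture proportions weight each called
window's two haplotype labels equally; `Unknown` windows are excluded from
the denominator and reported as their own share.

Consecutive windows with identical calls merge into segments; runs shorter
than `min_windows` (default 2) are absorbed into agreeing flanks or set to
`Unknown` otherwise. This run-length cleanup is the deliberate alternative to
an HMM: it makes no linkage assumptions and keeps segment boundaries within
one window of the evidence.

## Fst, pseudo-diploids and the folded AFS

Differentiation uses the Weir–Cockerham two-level variance-components
estimator for biallelic sites, aggregated as a ratio of sums across sites
(the weighting vcftools uses). It is re-implemented here from the 1984
formulas for self-containment and is cross-checked in the tests against an
independently coded literal transcription. To compare populations observed
only as haplotypes inside hybrids (e.g. the wild-species haplotypes carried
by different hybrid families), extracted haplotypes are paired into
pseudo-diploids — genotype = sum of the two haplotype alleles, unresolved
sites missing — and the diploid estimator is applied unchanged.

The folded allele-frequency spectrum counts the minor allele over the $2n$
haplotypes of the selected samples, pooling counts $k$ and $2n-k$, using only
callable sites with no missing genotype and outside caller-supplied exclusion
intervals (e.g. admixed segments). A sexual panmictic population yields the
characteristic decaying spectrum; clonal lineages do not.

## Clone collapsing and MDS

Clonal groups (vegetative or apomictic propagation, D ≈ 0 up to somatic
mutation and genotyping error) are found by single-linkage grouping of pairs
with genome-wide D below a threshold (default 0.02 — clones in practice sit
one to two orders of magnitude below it, unrelated conspecifics near 0.5).
Each group is represented by its highest-depth member, ties broken by sample
id, and only representatives enter the MDS so clone clusters cannot distort
the projection.

Principal-coordinates analysis uses the classical Torgerson procedure
(`stats::cmdscale` on the clamped D matrix): double-centering of squared
distances, eigendecomposition, coordinates from the top positive eigenpairs.
Negative eigenvalues — D is not exactly Euclidean — are dropped with a logged
warning, matching `cmdscale`. Axis signs, arbitrary in any eigendecomposition,
are fixed by making each axis's largest-magnitude loading positive so runs are
bit-reproducible. Pure populations appear as corner clusters; F1 hybrids
project close to the midpoint of their parental clusters in the leading
coordinates because the "hybrid" direction (equidistance to both parents) is
orthogonal to the axes that separate populations.

## The synthetic-data generator

Every statistic above is validated on simulated cohorts with full ground
truth, generated by a deliberately simple model in which each ingredient has
a closed-form check:

* **Differentiated populations.** Each site draws an ancestral frequency $p$
  from a Beta density (default shape $(0.5, 0.5)$, a U-shaped spectrum
  resembling variants ascertained in a diverged panel), and each population
  draws its frequency from the Balding–Nichols distribution
  $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, so $F$ is
  the drift coefficient: $E=p$, $\mathrm{Var}=F\,p(1-p)$, and the
  Weir–Cockerham estimator between two populations with drift $F_i, F_j$
  targets approximately $(F_i+F_j)/2$.
* **Calibration.** The default coefficients $F = (\mathrm{RK}\,0.80,\,
  \mathrm{MA}\,0.54,\, \mathrm{MS}\,0.44,\, \mathrm{PU}\,0.84)$ solve the
  pairwise targets RK–MA ≈ 0.67, RK–PU ≈ 0.82, MS–MA ≈ 0.49 under that
  relation; the test suite verifies the realized values to ±0.05.
* **Pedigrees.** Founders are two independent Bernoulli haplotypes (HWE by
  construction). Meioses draw a Poisson number of crossovers per chromosome
  (default mean 1.3, the order of a compact plant linkage map of ~130 cM per
  chromosome) at uniform positions; ancestry labels and the identity of the
  transmitted parental haplotype propagate onto every gamete, giving exact
  truth tracks for local ancestry and IBD sharing. Clones copy their source
  and flip one allele at Bernoulli-selected sites (somatic mutation);
  introgressed founders carry donor-population alleles over declared
  intervals on one haplotype.
* **Conventions.** Positions are uniform, sorted, deduplicated; 1-based in
  the VCF site table, 0-based half-open in all windows and BED-like truth
  output.

### Simulation scale

The default genome is 9 chromosomes (the citrus karyotype) of 10 Mbp with
40,000 segregating sites each — 360,000 sites at 4 sites/kb. The density is
chosen so that a 200-kb window holds ~800 genotyped sites and a few tens of
heterozygous sites, comparable in information content to the windows of a
deep resequencing study; this matters because the IBSR ≥ 0.95 rule is a
count-based classifier, and below roughly 1 site/kb an unrelated pair shows
IBS0 = 0 windows by chance alone, inflating IBD1 and hence $r$. Chromosome
length, not density, is the free knob for runtime: full cohorts at the
default scale build in seconds. Experiments that estimate $r$ for half-sibs
use a longer genome (9 × 30 Mbp at the same density) and average several
pairs, because the realized shared-gamete fraction of a single half-sib pair
has standard deviation of order 0.1 on a 90-Mbp genome — a property of
recombination, not of the estimator.

### What the simulator does not emulate

No coalescent structure within populations (sites are exchangeable and
unlinked given the frequencies; LD exists only through pedigree
recombination), no mutation-rate or time calibration (so divergence-time
estimation is out of scope), no sequencing-error or read-level simulation, no
structural variants, and biallelic SNVs only. Passing tests therefore show
that the estimators recover the parameters of this generative model at
realistic information densities — not that any particular biological dataset
satisfies the model's assumptions. Statistics that depend on haplotype
structure beyond the pedigree (e.g. LD-based phasing) cannot be studied with
it, which is one reason the package phases interspecifically with panels
instead.

## Default parameters at a glance

| Parameter | Default | Units | Role |
|---|---|---|---|
| `bp_span` window | 200,000 | bp | D, heterozygosity, IBS/IBD profiles |
| heterozygosity window | configurable | callable sites | violin-style per-sample distributions |
| AIM window | 500 | AIMs | local-ancestry likelihood |
| min AIMs per population | 5 | AIMs/window | `Unknown` guard |
| $\varepsilon$ | 0.01 | — | genotyping-error rate in the dosage model |
| likelihood margin | 2 | log-units | tie-break to `Unknown` |
| IBSR threshold | 0.95 | — | IBD0 vs IBD1/2 |
| window-D threshold | 0.05 | — | IBD1 vs IBD2 (equality → IBD1) |
| haplotype mismatch | $2\times10^{-4}$ | per compared site | identity call |
| clone threshold | 0.02 | D | single-linkage clone grouping |
| `min_informative` | 50 | joint sites/window | undetermined guard |
| QUAL / DP / allele balance | 30 / 10 / [0.2, 0.8] | — | VCF ingestion filters |

The VCF filter defaults are standard hardened values for GATK-style calls;
every one of them is configuration, and filters whose fields are absent from
a VCF are skipped rather than guessed.

## Degenerate inputs and numerical choices

Windows with no usable site are flagged `NA`, never zero. Pairs with
$\pi_{12}=0$ have undefined D and are masked in the distance matrix. An
all-excluded AFS, an empty pedigree, a zero-sample VCF emission, dangling
pedigree references, drift coefficients outside (0, 1) and $\varepsilon$
outside (0, 0.5) are rejected with errors rather than propagated. Determinism
is part of the contract: one seed drives frequencies and all meioses, and
rerunning any pipeline configuration with the same seed reproduces
byte-identical tables (the manifest records md5 sums to make this checkable).

## Test problem sizes

The suite validates unit behavior on small constructed matrices, and
parameter recovery on: the default-scale cohorts described above (360k
sites, ~27 samples) for distances, phasing, AIMs and local ancestry; a
9 × 30 Mbp cohort (1.08M sites, 12 samples) for relatedness-coefficient
recovery; and a 100,000-site single-population cohort for the analytic
anchors, which is also what `scripts/acceptance.R` re-runs from scratch.
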