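# hybridscope

Hybrid, clone and local-ancestry inference from multi-sample diploid
genotypes.

Collections of resequenced genomes from clonally propagated perennial crops —
citrus is the motivating case — mix a few strongly differentiated ancestral
populations with interspecific F1 hybrids, half-sib families, apomictic
clones and occasional multi-megabase introgressed segments. hybridscope
implements the comparative-genomics stack used to resolve such collections:

* **Pairwise genomic distance** `D = 1 − (π₁ + π₂) / (4 π₁₂)`, where π₁, π₂
  are the two heterozygosities and π₁₂ the cross-sample allele mismatch
  probability: `D = 0` for clones, `0.5` for unrelated members of one
  panmictic population, `→ 1` for deeply divergent species. Computed per
  200-kb window and genome-wide, alongside windowed heterozygosity.
* **IBS/IBD relatedness**: window counts of shared heterozygotes (IBS2) and
  homozygous differences (IBS0), the ratio `IBSR = IBS2/(IBS2 + IBS0)`
  (mean 2/3 for unrelated pairs, 1 when a haplotype is shared), threshold
  classification into IBD0/1/2, and the coefficient of relatedness
  `r = ½·IBD1 + IBD2`.
* **Interspecific phasing** of hybrids against parental population panels,
  haplotype-identity calls at a 2×10⁻⁴ mismatch threshold, and
  haplotype-vs-genotype consistency for parentage detection.
* **Ancestry-informative markers** (fixed in a target population's
  exemplars, absent elsewhere, plus a super-population for weakly
  differentiated sister taxa) and **likelihood-based local ancestry** in
  500-AIM windows, with admixture proportions and merged ancestry segments.
* **Weir–Cockerham Fst** (ratio-of-sums across sites), including on
  pseudo-diploids built from extracted haplotypes, and the **folded
  allele-frequency spectrum**.
* **Clone-group collapsing** (single linkage on `D`) and **classical MDS**
  of the distance matrix.
* A **synthetic-data generator** — Balding–Nichols population drift,
  pedigrees with Poisson recombination, clones with somatic mutation,
  introgressed segments — that emits VCF plus complete ground-truth tracks,
  so the whole pipeline is testable end to end without any external data.

## Worked example

Simulate four differentiated populations (drift calibrated so pairwise Fst
spans ~0.49–0.82), an interspecific F1 and its somatic clone, then recover
the structure:

```r
library(hybridscope)

model <- population_model()   # 4 populations, 9 x 10 Mbp, 360,000 sites
ped <- pedigree(
  ped_founder("RK1", "RK"), ped_founder("RK2", "RK"), ped_founder("RK3", "RK"),
  ped_founder("MA1", "MA"), ped_founder("MA2", "MA"), ped_founder("MA3", "MA"),
  ped_founder("MS1", "MS"), ped_founder("MS2", "MS"),
  ped_founder("PU1", "PU"), ped_founder("PU2", "PU"), ped_founder("PU3", "PU"),
  ped_f1("HYB", "RK1", "MA1"),
  ped_clone("HYBc", "HYB", somatic_rate = 1e-5)
)
cohort <- build_cohort(model, ped, seed = 42)
vm <- cohort$matrix
vm
#> variant_matrix: 360000 sites x 13 samples (360000 callable sites, 0.00% missing)

frame <- make_windows(vm, "bp_span", 200000,
                      chrom_lengths = setNames(rep(1e7, 9), paste0("chr", 1:9)))

genomic_distance(pair_pi(vm, "HYB", "HYBc", frame))   # clones
#> pair_distance HYB vs HYBc: genome-wide D = 0.0000 over 360000 sites
genomic_distance(pair_pi(vm, "RK2", "RK3", frame))    # unrelated, same species
#> pair_distance RK2 vs RK3: genome-wide D = 0.5022 over 360000 sites
genomic_distance(pair_pi(vm, "RK1", "MA1", frame))    # different species
#> pair_distance RK1 vs MA1: genome-wide D = 0.8349 over 360000 sites

pair_ibd(vm, "RK1", "HYB", frame)                     # parent-offspring
#> pair_ibd RK1 vs HYB: IBD0/1/2 = 0.000/1.000/0.000, r = 0.500 (D = 0.454)

aims <- derive_aims(vm, list(RK = c("RK1","RK2","RK3"), MA = c("MA1","MA2","MA3"),
                             MS = c("MS1","MS2"),       PU = c("PU1","PU2","PU3")))
aims
#> aim_set: 30079 markers
#>   MA   MM   MS   PU   RK
#> 5048 2785 4776 8935 8535

window_ancestry(vm, "HYB", aims)
#> ancestry_track for HYB: 63 windows
#>      RK      MA      MS      PU Unknown
#>     0.5     0.5     0.0     0.0     0.0
```

Reading the numbers: the clone pair sits at `D ≈ 0` and the unrelated
conspecific pair at the panmictic anchor `D = 0.5`, while the two species are
separated at `D = 0.83`. The F1's relationship to its parent is pure IBD1
(`r = 0.5`, no window without a shared haplotype), and local ancestry calls
the hybrid heterozygous RK/MA in every informative window — a 50:50 admixture
profile.

The full pipeline (simulate → distances/heterozygosity → clones/MDS → AIMs →
local ancestry → IBD/relatedness → phasing/parentage → figures + manifest) is
one call:

```r
run_end_to_end(default_demo_config(), "demo_out")
```

or, from a shell, via the bundled CLI:

```sh
Rscript inst/cli/hybridscope run --demo --out demo_out
Rscript inst/cli/hybridscope run --config inst/extdata/example_config.yaml --out example_out
```

The demo cohort mirrors a resolved hybrid-species family: one
mandarin parent carrying a single 2.4-Mbp introgressed pummelo segment, six
interspecific F1 children by distinct wild mothers, and clones; the report
flags the shared parent by haplotype sharing in every child and collapses the
clone pairs.

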