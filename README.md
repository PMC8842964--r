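# pangotrace

Conservation genetics and forensic tracing of a local wildlife trade, built
around microsatellite and mitochondrial control-region data from
white-bellied pangolins (*Phataginus tricuspis*) of the Dahomey Gap — the
Togo–Benin–SW Nigeria savannah corridor whose endemic lineage feeds both
bushmeat and traditional-medicine markets.

The package is for conservation geneticists and wildlife-forensics
practitioners who have diploid microsatellite genotypes (allele-size calls)
with forest/market metadata, plus an aligned mtDNA fragment, and want to
answer: how much diversity and structure remain in the source populations;
can individual animals be distinguished (and re-identified across market
stalls); and can market individuals be assigned back to their source
forests when there is **no** usable population structure?

## What it computes

* **QC and data model** — replicate-consensus genotype calling (an allele
  must appear in ≥2 of 3 PCR replicates), a ≥75%-typed completeness
  filter, native and GenAlEx-style CSV dialects, aligned-FASTA input.
* **Diversity and structure** — per-locus `n`, `Na`, `Ho`, unbiased
  `He = (2n/(2n−1))(1 − Σp²)`, rarefied allelic richness
  `Ar(g) = Σ[1 − C(N−Nᵢ,g)/C(N,g)]`, HWE chi-square tests, Weir–Cockerham
  variance-component F-statistics with permutation significance, and the
  ≥7-samples-per-forest reference partition.
* **Forensic identity** — multilocus genotype matching (≥15 mutually typed
  loci), `pgen`/`psex`, the sample-size-corrected unbiased probability of
  identity and its full-sibling variant
  `PIsibs = 0.25 + 0.5Σp² + 0.5(Σp²)² − 0.25Σp⁴`, and the minimum locus
  count reaching `PIsibs < 0.01`.
* **Trade tracing** — generalized rarefaction of private-allele measures
  over population combinations (presence probability
  `Q = 1 − C(N−Nₐ,g)/C(N,g)`), plateau/exponential/decreasing curve
  classification with 50%/45% selection thresholds, cross-validation
  against observed private alleles, and screening of market genotypes.
* **mtDNA** — haplotype collapse with complete deletion, `h`, `Hd`, `π`,
  mismatch distribution and Harpending's raggedness, Tajima's `D`, Fu's
  `Fs` (Ewens sampling formula), Ramos-Onsins & Rozas' `R2`, coalescent
  null p-values conditioned on `S`, and nearest-reference K2P lineage
  assignment.
* **Isolation by distance** — Edwards' chord distances (population and
  individual level), great-circle geographic distances, Mantel
  permutation test.
* **Synthetic data** — a seeded Balding–Nichols generator with inbreeding,
  planted private alleles, market sampling from known sources, MCAR
  missingness, and a Kingman-coalescent sequence simulator; truth records
  make every stage testable end to end.

## Worked example

A fully synthetic study-scale run — 104 forest individuals in six
populations, 65 market individuals, 20 loci with seven planted private
alleles — through QC, diversity, identity and tracing:

```r
library(pangotrace)

sim <- simulate_dataset(simulation_config(seed = 42))
ds  <- filter_by_completeness(sim$dataset)
#> completeness filter (>= 0.75): retained 169, removed 0 samples

ls <- locus_summary(ds)
round(attr(ls, "means"), 3)
#>       n      Na      Ho      He      Ar     Fis
#> 159.800   6.000   0.531   0.698   5.997   0.240

part <- default_partitions(ds)           # forests with >= 7 samples
wc <- wc_f_statistics(ds, part)
c(FST = wc$fst, FIS = wc$fis)            # targets were 0.10 / 0.17
#> multilocus FST: 0.111  FIS: 0.169

ft <- allele_frequencies(ds)
unbiased_pi(ft)$total                    # P(two unrelated animals match)
#> uPI: 1.35e-18
pi_sibs(ft)$total                        # conservative sibling bound
#> PIsibs: 5.79e-08
attr(min_loci_curve(ft), "min_loci")     # loci needed for PIsibs < 0.01
#> 5

ftr <- allele_frequencies(ds, part)
sel <- select_tracing_loci(private_richness_curves(ftr),
                           observed_private_alleles(ftr))
sel
#>   locus allele population   trend
#> 1    L1   9011         P1 plateau
#> 2   L10   9106         P6 plateau
#> 3    L7   9074         P4 plateau

tr <- trace_individuals(ds, sel)
table(tr$verdict)
#>      traced untraceable
#>          19          46
head(tr[tr$verdict == "traced", c("sample_id", "source", "hits")], 3)
#>    sample_id source        hits
#> 1       M1_1     P4 L7:9074->P4
#> 6       M1_6     P4 L7:9074->P4
#> 9       M1_9     P1 L1:9011->P1
```

Reading the numbers: mean `Ho` (0.531) sits well below mean `He` (0.698) —
the heterozygote deficit produced by the generator's inbreeding knob, which
the Weir–Cockerham `FIS` recovers (0.169 vs the 0.17 target), while
pairwise differentiation recovers the `FST` knob (0.111 vs 0.10). The
identity statistics say any two animals are effectively distinguishable
(`uPI ≈ 1e−18`), and five loci already push the sibling-collision bound
under 1%. Three loci carry private alleles that both the rarefaction
curves (plateau above 50%) and the observed catalog support; screening the
65 market genotypes for them traces 19 animals to their source forests —
all correctly, as the truth record `sim$truth$market_sources` confirms.

The same chain runs as one call with per-stage reports and provenance
headers: `run_pipeline(run_config(seed = 1), out_dir = "reports")`.

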