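---
title: "Methods: conservation genetics and forensic tracing of a local wildlife trade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation genetics and forensic tracing of a local wildlife trade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

White-bellied pangolins (*Phataginus tricuspis*) of the Dahomey Gap — the
savannah corridor spanning Togo, Benin and southwestern Nigeria — form an
endemic mitochondrial lineage that is hunted for bushmeat and traditional
medicine. Samples reach wildlife markets hundreds of kilometres from their
source forests, and the conservation questions are forensic ones: do two
market items come from the same animal? Can a market individual be assigned
back to its forest of origin? How much diversity and structure is left in
the source populations?

`pangotrace` implements the analysis chain for this setting: diploid
microsatellite genotypes (20 loci, allele sizes) with population and
forest/market metadata, plus an aligned mitochondrial control-region
fragment. Because the defining feature of the system is the *absence* of
clear population structure, classical likelihood assignment is ineffective,
and the package centres on a rarefaction-and-cross-validation procedure
over population-private alleles.

# Data model and quality control

Genotypes live in a `geno_dataset`: two integer matrices of allele sizes
(canonically ordered, so `214/210` and `210/214` are the same unordered
pair), with missingness only at the whole-call level — half-typed calls are
rejected as malformed rather than silently imputed. Two CSV dialects are
read: a native wide `"a1/a2"` format and a GenAlEx-style two-columns-per-
locus format with `0` for missing.

Two quality rules reflect how such data are produced:

* **Replicate consensus** (`consensus_from_replicates()`): degraded samples
  are amplified in PCR triplicate; an allele is accepted only when present
  in at least two of the three replicates. Two qualifying alleles make a
  heterozygote, one a homozygote, none a missing call; three or more is a
  scoring conflict, flagged and set missing.
* **Completeness filter** (`filter_by_completeness()`): samples typed at
  fewer than 75% of loci (15 of 20) are removed before analysis. The filter
  is idempotent.

Aligned mtDNA arrives as FASTA restricted to `A,C,G,T,N,-`; alignment is an
input, never computed here.

# Diversity and structure

Per-locus summaries follow the standard population-genetics estimators:
observed heterozygosity; unbiased expected heterozygosity
$H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$; and allelic richness
by rarefaction,
$A_R(g) = \sum_i \left[1 - \binom{N-N_i}{g} \big/ \binom{N}{g}\right]$,
the expected allele count in a uniform subsample of $g$ gene copies. The
default $g$ is the smallest per-locus gene-copy count in the analysis set
(the FSTAT convention); because published "sample size" wordings are
ambiguous, $g$ is always overridable and reported alongside the summary.

Hardy–Weinberg deviation is tested with the genotype-count chi-square
against expectations from sample allele frequencies
($df = k(k-1)/2$ for $k$ alleles), matching the spreadsheet-tool convention
rather than an exact Guo–Thompson test; the exact test is future work.
F-statistics use the Weir–Cockerham variance components $(a, b, c)$, with
multi-locus estimates formed as ratios of summed components — never means
of per-locus ratios. Pairwise $\theta$ significance comes from permuting
individuals between the two groups (sizes preserved) with the $+1$
correction, $p = (\#\{\theta_\text{perm} \ge \theta_\text{obs}\}+1)/(B+1)$,
so $p = 0$ is unattainable. Reference partitions take forest populations
with at least 7 samples; market samples never enter reference partitions.
No multiple-testing correction is applied by default.

# Forensic identity

Two samples match when identical at every mutually typed locus, with at
least 15 mutually typed loci required so that missing data cannot
manufacture matches; match groups are transitive closures. The probability
that a genotype recurs by chance uses the single-encounter form
$p_\text{sex} = 1-(1-p_\text{gen})^{n-1}$, with $p_\text{gen}$ the product
of Hardy–Weinberg genotype probabilities at the sample's typed loci from
pooled frequencies (no inbreeding correction by default; that choice is
recorded in the output).

Probability-of-identity statistics are computed per locus and cumulated as
products: the sample-size-corrected (unbiased) PI
$$\widehat{PI} = \frac{n^3(2a_2^2 - a_4) - 2n^2(a_3 + 2a_2) + n(9a_2+2) - 6}
{(n-1)(n-2)(n-3)}, \qquad a_k = \sum_i p_i^k,$$
which converges to the classical $2(\sum p^2)^2 - \sum p^4$ as $n$ grows
(tested at $n = 5000$), and the sibling variant
$PI_\text{sibs} = 0.25 + 0.5 a_2 + 0.5 a_2^2 - 0.25 a_4$, which bounds the
collision probability for full siblings from above and therefore drives the
conservative "minimum loci" analysis: loci are ordered most-informative
first and the smallest count with cumulative $PI_\text{sibs} < 0.01$ is
reported.

# Tracing through private alleles

The tracing procedure works in four steps:

1. **Observed private alleles**: an allele seen in exactly one reference
   population (`observed_private_alleles()`).
2. **Rarefaction curves** (`private_richness_curves()`): for population
   subsets of size $K$ ($2..J$) and subsample sizes of $g = 2..7$
   individuals ($2g$ gene copies, the diploid convention), using the
   presence probability
   $Q = 1 - \binom{N-N_a}{g}\big/\binom{N}{g}$. Two measures are computed,
   because richness is the classical generalized-rarefaction output while
   the selection thresholds are expressed as percentages:
   * *private allelic richness*
     $\sum_a Q_{j,a}\prod_{j'\ne j}(1-Q_{j',a})$ — expected number of
     alleles present in population $j$'s subsample and absent from all
     others;
   * *private-allele frequency mass*
     $\sum_a \hat p_{j,a}\, Q_{j,a}\prod_{j'\ne j}(1-Q_{j',a})$ — the
     expected frequency, in population $j$, of alleles that appear private
     at that subsample size. This lives on $[0,1]$, rises to a plateau near
     $\hat p$ for truly private alleles, and decays terminally for shared
     ones, which is exactly the visual behaviour the selection rules read.
3. **Trend classification** (`classify_trend()`): with $v$ the final curve
   value and $\Delta$ the last increments — flat curves
   ($|\Delta_\text{last}| \le 0.05\, v$) are plateaus when $v \ge 50\%$;
   genuinely declining curves are discarded; accelerating curves are
   "exponential" when $v \ge 45\%$; everything else is rejected. Flatness
   is judged *before* the sign of the last increment: saturating curves end
   with a tiny negative drift that is a plateau, not a decline — with the
   opposite ordering no real curve would ever qualify. All thresholds are
   configurable.
4. **Cross-validation and screening**: a (locus, population) pair is
   retained only when the curve qualifies *and* the population has an
   observed private allele there; market genotypes are then screened for
   the retained alleles. All hits agreeing on one population give
   `traced`; conflicting hits give `ambiguous` (reported, never resolved
   silently); no hits give `untraceable`.

A caveat the package surfaces deliberately: alleles that are private *in
the sample* need not be private *in the populations*. Tracing through a
sample-private but truth-shared allele can mis-assign; with few reference
samples per forest this is the method's main failure mode, which is why
selection demands both the rarefaction signature and the observed catalog,
and why the synthetic-recovery guarantees below are stated for planted,
truly private alleles.

# Mitochondrial statistics

Sequences containing `N` are dropped, then every site with a gap or `N` in
any retained sequence (complete deletion). Haplotype diversity uses the
unbiased $\frac{n}{n-1}(1-\sum f_i^2)$; nucleotide diversity is the mean
pairwise per-site difference. The neutrality battery comprises Tajima's
$D$, Fu's $F_s$ (Ewens sampling formula with $\hat\theta = \hat\pi$;
unsigned Stirling numbers of the first kind are computed by the exact
recursion in log space, stable to $n$ well beyond 200), Ramos-Onsins &
Rozas' $R_2$ from singleton counts, and Harpending's raggedness
$r = \sum_{i=1}^{d+1}(x_i - x_{i-1})^2$ with $x_{d+1}=0$ — the leading
step off $x_0$ enters through the $i=1$ term and a trailing step to zero
closes the sum, a convention locked by worked fixtures (a single mismatch
class gives $r = 1$).

P-values condition on the observed $n$ and $S$: `coalescent_pvalues()`
simulates Kingman genealogies (exponential waiting times at rate
$\binom{k}{2}$), places exactly $S$ mutations uniformly on total branch
length under infinite sites, and scores lower tails for $D$, $F_s$ and
$R_2$ (upper tail for raggedness). $\theta$-conditioning is available as an
option. Lineage assignment deliberately replaces tree building with
nearest-reference mean K2P distance
($d = \tfrac12\ln\frac{1}{1-2P-Q} + \tfrac14\ln\frac{1}{1-2Q}$, pairwise
deletion of gap/`N` sites, saturation flagged infinite); the winning margin
is reported and ties are left unassigned (margin threshold default 0).

# Isolation by distance

Edwards' chord distance
$D(x,y) = \sqrt{1 - \tfrac1L \sum_l \sum_a \sqrt{p_{x,l,a}\,p_{y,l,a}}}$
averages over loci inside the square root (the common genetics-package
convention; variants exist, hence the formula is documented). Individual
level treats each animal as a 2-gene sample with frequencies $0, 0.5, 1$
and drops loci missing in either member pairwise. Geographic distances are
great-circle kilometres on a 6371-km sphere — coordinates are geographic,
so "Euclidean" plan distances are only an option for strict replication —
with population centres as member-coordinate centroids unless supplied.
The Mantel test correlates upper triangles and permutes rows and columns
of one matrix jointly, one-sided for positive association, $+1$-corrected.

# The synthetic generator

`simulate_dataset()` is a first-class module, not a fixture: it defines
the study conditions under which every recovery guarantee is stated.
Ancestral allele frequencies are flat-Dirichlet; population frequencies
follow the Balding–Nichols distribution
$\mathrm{Dir}\!\left(p_\text{anc}\tfrac{1-F}{F}\right)$, the simplest
frequency model with an interpretable $F_{ST}$ knob. Inbreeding is modelled
as per-individual autozygosity with probability $F_{IS}$ — one allele drawn
and duplicated — which reproduces the heterozygote deficit that motivates
the inbreeding estimates. Planted private alleles are inserted as labels
absent everywhere else, at a stated frequency with renormalisation. Market
individuals draw a source population from per-market mixture weights, then
a genotype from that population; the truth record keeps the source.
Missingness is MCAR. Microsatellite mutation (stepwise models) is *not*
simulated: datasets are single-generation draws, sufficient for every
statistic computed here, and a stated non-goal.

The default configuration emulates the study design: six forest
populations totalling 104 individuals (sizes 30/25/15/12/12/10, all at or
above the 7-sample partition floor), 65 market individuals over three
markets with uniform source weights, 20 loci with 6 ancestral alleles,
$F_{ST} = 0.10$ (the observed low-to-moderate differentiation range),
$F_{IS} = 0.17$ (the observed mean inbreeding), 5% missing calls, and
seven loci carrying private alleles at frequencies 0.30–0.50 in four
populations — mirroring the seven-locus, four-population tracing signature
of the real data. The coalescent default for the mtDNA stand-in is
$n = 126$, $S = 13$ over 432 sites, the scale of the control-region
fragment. What the generator does *not* emulate: null alleles, allelic
dropout beyond MCAR, linkage, mutation, admixed individuals, spatially
continuous structure. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated model, not robustness to
those artefacts in real data.

# Numerical choices and problem sizes

* Binomial-coefficient ratios are evaluated in log space (`lchoose`),
  exact for the enumeration-scale checks (tolerance $10^{-9}$ against
  exhaustive subsampling with $\le 8$ gene copies per population).
* Permutation p-values always use the $+1$ correction; random draws flow
  from one root seed through named per-stage substreams, making pipeline
  reports byte-identical across reruns.
* Degenerate inputs are flagged, not guessed: monomorphic loci in HWE
  tests, $S = 0$ in $D$/$R_2$, $S' \in \{0, 1\}$ in $F_s$ (signed
  infinity), K2P saturation (infinite), zero-variance Mantel matrices,
  empty reference groups.
* The test suite sizes its Monte-Carlo checks to run on one CPU in a few
  minutes: parameter recovery uses 50 replicates at $4 \times 30$
  individuals (accuracy $\pm 0.05$ on $F_{ST}$ and $F_{IS}$); null
  calibration uses a 999-draw null set scored against 2000 observed
  replicates for the coalescent tests, 600 Mantel and 400 FST permutation
  replicates at 99 permutations each, asserting empirical type-I error
  within $[0.03, 0.07]$ at $\alpha = 0.05$; the null mean of Tajima's $D$
  is checked over 10{,}000 coalescent draws.

# Known limitations

* Tracing power is bounded by reference sampling: sample-private alleles
  can mis-assign (see above), and markets sourced from unsampled forests
  are untraceable in principle.
* The HWE test is asymptotic; with many rare alleles its chi-square
  approximation is rough (flagged df reported so users can judge).
* The unbiased-PI correction needs $n \ge 4$ typed individuals per locus;
  smaller loci are excluded from the product with a warning.
* Lineage assignment is nearest-reference only; it does not quantify
  uncertainty beyond the distance margin, and tree building with bootstrap
  is out of scope.
* `Fs` uses $\hat\theta = \hat\pi$, the original definition; alternative
  estimators of $\theta$ would shift borderline p-values.
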