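---
title: "Methods: MHC microsatellite diversity, trio phasing and meiotic event calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MHC microsatellite diversity, trio phasing and meiotic event calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equimhc)
```

## The data model

`equimhc` analyses a panel of linked microsatellite loci — by default the
eleven intra-MHC markers on horse chromosome 20 — typed as two fragment
lengths (bp) per locus per individual. Allele identity is fragment length:
these markers are length polymorphisms, and no sequence-level identity is
attempted. A dataset (`mhc_data`) bundles the long-form genotype table, an
optional pedigree and the locus panel. Pair order within a genotype carries
no meaning, so pairs are canonicalized (sorted); a locus missing either
allele is wholly missing, and individuals missing a locus are excluded from
that locus's statistics only (pairwise deletion), which matches the
per-locus sample sizes that parentage-software outputs report.

The panel is the coordinate system. Loci are ordered by `map_index`, and
crossover breakpoints are always named by the flanking pair of informative
loci ("UM011–COR114") rather than base-pair positions, because the marker
map provides none. One genuinely open choice: the relative order of the
three class I loci (COR110, UMN-JH38, TAMU30593) is not pinned down by any
observable crossover in data of this design, so the default places UMN-JH38
second and the order stays configurable through `mhc_panel()`.

## Diversity statistics

All statistics are computed from the formulas rather than by calling the
legacy tools that popularized them, so every number is reproducible from
first principles:

* **Expected heterozygosity** uses Nei's small-sample correction,
  $\hat H_e = \frac{2n}{2n-1}\left(1 - \sum_a p_a^2\right)$, the estimator
  used by Cervus-style outputs.
* **PIC** is Botstein's form
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$; it is bounded above by
  $H_e$.
* **Fis** defaults to the ratio form $1 - H_o/H_e$, which is the relation
  the published per-locus tables this package mirrors satisfy exactly at
  two decimals. A small-sample corrected estimator (Nei–Chesser
  $1 - H_o/\hat H_s$ with $\hat H_s = \frac{n}{n-1}(1-\sum p^2 -
  H_o/2n)$) is reported alongside it in `locus_stats()`.
* **Null-allele frequency** is the Chakraborty estimator
  $(H_e - H_o)/(H_e + H_o)$; maximum-likelihood alternatives are
  deliberately not implemented, and negative values (heterozygote excess)
  are reported as such.
* **Allelic richness** is hypergeometric rarefaction
  $\sum_a \left[1 - \binom{N-N_a}{g}/\binom{N}{g}\right]$. The rarefaction
  size $g$ defaults, per locus, to the smallest gene count among the
  populations being compared — which is why the smallest population's AR
  equals its raw allele count (an integer), a pattern visible in published
  per-population tables.
* **Hardy–Weinberg** testing is the Guo–Thompson probability test
  conditional on allele counts. Genotype tables are fully enumerated when
  the table space is small (the recursion is attempted for few-allele,
  small-n cases and aborts at $10^5$ tables); otherwise the null is sampled
  by shuffling the gene vector, with the add-one p-value correction.
  Monomorphic loci return $p = 1$ with a `testable = FALSE` flag rather
  than `NA`, so tabulations never drop rows silently.
* **Linkage disequilibrium** is a genotypic G-test with a permutation
  null (one locus's genotypes permuted across individuals), which makes no
  phase assumption.
* **Allele-frequency homogeneity** across populations is a Pearson
  chi-square on gene counts with Bonferroni correction over the loci
  tested; the HWE family and the chi-square family are corrected
  separately.
* **Evanno ΔK** post-processes replicate log-likelihoods from an external
  admixture clustering run:
  $\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$.
  The MCMC clustering itself is a published tool and out of scope; zero
  replicate spread yields an infinite ΔK with a flag.

## Population structure

Nei identity averages $J_{xy}$, $J_x$, $J_y$ over loci before forming
$I = \bar J_{xy}/\sqrt{\bar J_x \bar J_y}$, with the unbiased
($\frac{2nJ-1}{2n-1}$) within-population correction by default, and
$D = -\ln I$. The unbiased identity of two very similar samples can exceed
1 (D slightly negative); values are reported raw rather than clamped, and
$I = 0$ flags $D = \infty$.

AMOVA partitions variance among groups, among individuals within groups
and within individuals. The squared distance between two gene copies at a
locus is the allele-mismatch indicator summed over loci — the codominant,
unweighted-genotypic convention (no repeat-size weighting; these data were
not analysed with stepwise-mutation distances). Variance components come
from equating mean squares; negative components are kept raw and truncated
to zero only for the percent-of-total (flagged). The ΦPT p-value permutes
individuals among groups, 999 permutations by default with the add-one
correction. Pairwise Fst is ΦPT from the two-population AMOVA — published
horse-population values of this kind come from that convention — with
Weir–Cockerham θ available behind a flag, and raw negative estimates kept
alongside the clamped value. With missing genotypes, sums of squares use
the individuals typed at each locus while the degrees of freedom use the
full individual count; this is adequate at the low missingness these
panels show.

## Trio phasing

Phasing is constraint-based, mirroring the manual trio-comparison
procedure used to assemble equine MHC haplotypes — algorithmized, with
zero guessing:

1. For each offspring locus, the two alleles are labelled
   maternal/paternal when Mendelian logic forces it; if both orientations
   are consistent the locus is ambiguous, if neither is it is a conflict.
   Conflicts are candidate meiotic events and are excluded from phasing
   but never discarded.
2. Parents accumulate phase from their transmissions. Homozygous loci are
   trivially phased. At heterozygous loci, transmissions that are mutually
   consistent (pairwise agree-or-complement) are merged in sorted
   offspring order; a transmission that mixes agreement and
   complementation with the others is a candidate recombinant and is set
   aside for event calling instead of being merged. When transmissions
   conflict, the maximum-conflict ones are dropped first (all of them on a
   tie), which isolates a single recombinant among several concordant
   siblings without guessing between two lone disagreeing ones.
3. Remaining ambiguous offspring loci are resolved only when the
   transmitting parent's haplotype is established and matches exactly one
   orientation (pool matching). The loop repeats to a fixpoint.

Processing order is sorted ids throughout, so the output is deterministic
and independent of input row order. Haplotype identity requires all panel
loci resolved; partially resolved haplotypes are tallied as unresolved and
never counted as distinct — with eleven linked loci, counting partial
haplotypes would conflate resolution with diversity.

An inherent limit worth stating: a parent with a single offspring is
phased *from* that transmission, so a crossover in that meiosis is
undetectable in principle. In a population where each mare has one foal
per season, dam-side events are therefore mostly invisible while
stallions, with many foals, are well phased — a detectability asymmetry
that itself predicts the observation that detected recombinant haplotypes
are of paternal origin.

## Meiotic event calling

`explain_transmission()` explains a transmitted haplotype against the
parent's two haplotypes with an explicit minimum-cost model: each
crossover breakpoint costs 2, each point event (conversion or indel) costs
1, within a search budget of at most 3 breakpoints plus 1 point event;
anything beyond is returned as `unexplained`, never silently dropped. The
model's tie-breaks are structural rather than ad hoc:

* A conversion is a tract of at most 2 panel loci copied from the
  homolog, *flanked on both sides* by same-haplotype context. An internal
  1–2 locus island is therefore read as a conversion (cost 1) rather than
  a double crossover (cost 4), but a single-locus switch at a terminal
  panel locus cannot be a conversion and is called recombination — with
  the alternative reading recorded in a tie flag.
* An indel must match *neither* parental allele and sit an exact multiple
  (≤ 3) of the locus repeat unit away from the mosaic-source allele.
  Offsets only readable from the homolog cost the extra breakpoints that
  source switch implies.
* Breakpoints are reported as the interval between the flanking
  informative loci; loci where the parental haplotypes agree never anchor
  a breakpoint and simply widen the interval.

The minimality of this search is not assumed: the test suite checks it
against exhaustive enumeration of all explanations on 6-locus panels
(1000 randomized cases) and against all $2^{11}$ mosaics of fully
informative haplotypes.

Event frequencies divide by the number of meioses — parent-offspring
pairs, two per full trio — the denominator under which the published
worked examples (3/24 = 12.5%, 6/86 ≈ 7%, 2/30 ≈ 6.7%, 11/24 ≈ 46%)
are all arithmetically consistent. Offspring-level,
transmission(haplotype)-level and breakpoint-level recombination counts
are reported separately because a single meiosis can carry several
breakpoints and published prose often mixes the three. The new-haplotype
ratio counts distinct fully resolved offspring haplotypes absent from the
parental-generation inventory, again per meiosis.

The duplication pattern — an offspring carrying both alleles of one
parent at a locus, neither matching the other parent — is emitted as a
conversion on the failing parent's transmission, matching how such
non-Mendelian patterns are interpreted in family studies of these
markers.

## The simulator and what passing tests mean

`simulate_mhc()` is a forward pedigree simulator whose defaults are the
study conditions the package targets: three populations with 49/16/19
founder dams, 8/4/4 founder sires and 43/12/15 offspring (so 86/24/30
meioses); per-locus founder allele counts fixed at the panel-wide counts
observed in that design (5–14 per locus); a founder haplotype pool of
twice the founder count per population, with 8% of the pool shared
between the two related populations; and event rates of the order the
design reports — crossover 0.008 per map interval per meiosis (≈ 8% of
meioses carry one), conversion 0.015 per meiosis, stepwise ±1-repeat-unit
indel 0.0175 per locus per meiosis (27 indels per 140 meioses over 11
loci gives that rate). Allele sizes live on a contiguous repeat-unit
lattice inside each locus's size range, so an indel usually recreates an
existing allele rather than a new one, as observed. Founder genotypes are
two independent uniform draws from the pool — Hardy–Weinberg by
construction. Events are planted independently per meiosis; crossover
interference is out of scope. Every meiosis runs in a counter-based RNG
substream, so datasets are reproducible from the seed and adding
offspring does not perturb earlier draws. The truth log is exhaustive —
replaying it reproduces every offspring genotype exactly, and the test
suite asserts this.

Recovery tests use a deliberately favourable design — one population,
many offspring per dam and sire, 14 near-uniform alleles per locus on a
widened size lattice — because event recovery is only a sharp test where
detectability is near-complete. Under those conditions the pipeline
recovers planted crossover, conversion and indel rates within binomial
95% confidence bounds over 2000 meioses, and recovers planted haplotypes
perfectly when event rates are zero. What such tests do *not* show: real
data have genotyping error (a single-locus mismatch fitting no rule is
reported `unexplained`, not attributed), null alleles, lower
informativeness, and single-offspring dams, all of which reduce detection
below the simulated ceiling; the study-shaped default config exhibits
that attenuation and is the honest setting for end-to-end demonstrations.

Problem sizes in the shipped tests (2000-meiosis recovery runs, 200+ loci
for the HWE calibration check, 250–1000 randomized oracle cases) were
chosen as the smallest sizes at which the binomial and enumeration bounds
being asserted are sharp.

## Numerical and interface choices

* Genepop export maps each observed allele size to a rank-based 3-digit
  code per locus (sorted ascending from 001), because bp sizes can exceed
  the format's 3-digit field; a JSON sidecar records the code-to-bp map
  and population labels, making the round trip exact.
* Permutation and Monte-Carlo p-values use the add-one correction and an
  explicit seed argument everywhere.
* Probability comparisons in the exact tests use a `1e-9` log-scale
  tolerance so ties in table probabilities are counted into the tail.
* Undefined statistics (zero typed individuals, single population for
  private alleles, zero meioses) return `NA` with a warning; "not
  testable" cases return flagged `p = 1` instead, as noted above.
* The published full-data reproduction targets (AMOVA percent, pairwise
  Fst, haplotype counts) require the study's genotype supplement; the
  package exercises those code paths end-to-end on study-shaped synthetic
  data and checks internal consistency, and will compute the published
  quantities directly when the real table is supplied through
  `read_genotypes()`/`read_pedigree()`.

## Known limitations

* No statistical (population-LD) phasing: individuals without informative
  relatives stay unphased by design.
* Fis and null-allele estimators are moment-based; likelihood-based
  refinements are out of scope.
* AMOVA treats missing data by per-locus exclusion with full-count
  degrees of freedom, which is slightly anticonservative at high
  missingness.
* The event cost model cannot distinguish a conversion from a double
  crossover spanning the same short tract, a terminal conversion from a
  terminal crossover, or a germline indel from a genotyping slippage
  artefact; ties and unexplained cases are flagged rather than decided.
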