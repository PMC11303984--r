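---
title: "Measuring genetic erosion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genetic erosion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erodiv)
```

## The problem

Whether crop domestication squeezed genetic diversity through a sudden
bottleneck or eroded it gradually over millennia is hard to decide from
extant material alone, and the few ancient samples that exist are too
sparse for population-based estimators such as π or Watterson's θ. This
package implements an individual-based alternative — the per-sample
proportion of private variants — together with chloroplast
haplotype-network phylogeography, and wraps both in a synthetic cohort
generator so the whole analysis chain can be exercised and validated
without consortium-scale sequencing data.

## The private-variant statistic

For each sample, over all retained variant sites,

$$\mathrm{PV\%} = 100 \cdot
  \frac{\#\text{private doubleton SNPs} + \#\text{private homozygous indels}}
       {\#\text{non-missing genotype calls}}.$$

An allele is a *private doubleton* when it is observed exactly twice
among all non-missing genotypes, both copies in a single homozygous
individual; a *private homozygous indel* is the same pattern at an indel
site. Heterozygous singletons are excluded: barley is a predominant
selfer, so isolated heterozygous calls mostly reflect somatic mutations,
mapping artefacts or sequencing error rather than transmitted variation.
The denominator counts the sample's non-missing calls over *all*
retained sites, not only sites that remain polymorphic after masking —
that makes the statistic comparable between samples with very different
missingness, which is the point of using it on ancient material.

Key behaviours, each enforced by tests:

* **Duplicates poison the statistic.** An accession genotyped twice has
  no private alleles at all, so duplicate pruning (IBS > 0.985,
  connected components, keep the copy with less missing data,
  lexicographic tie-break) runs before classification, and
  classification warns if identical genotype columns survive.
* **Depth robustness.** The singleton/doubleton status is *recomputed*
  after each minDP masking rather than frozen from the unmasked table:
  each minDP value is a genotype-calling regime of its own, and the
  report carries mean ± sd across the sweep (default minDP 2–5).
  Unknown depth passes the mask by default (a strict mode flips this),
  so depth-less records are usable.
* **Outlier calling.** z-scores use the sample standard deviation
  (n − 1); the modified Thompson Tau test runs iteratively at
  α = 0.05, removing the most extreme point while
  $|x-\bar x| > \tau s$ with
  $\tau = t_{\alpha/2,\,n-2}(n-1)/(\sqrt n\sqrt{n-2+t^2})$. Ancient
  samples are evaluated inside the domesticated pool (they cluster with
  domesticated accessions), while hybrid/feral accessions belong to
  neither reference group.

## Site and sample filters

Sites with more than 50 % missing calls are removed, as are sites whose
heterozygous fraction among non-missing calls is ≥ 5 % (strict ≥, so a
site at exactly 5.0 % is removed); a site with zero non-missing calls
falls under the missingness rule, never a division by zero. Both
thresholds are parameters of `filter_config()`. The het filter counts
any genotype with two distinct allele indices as heterozygous, including
multiallelic combinations — the minimal reading of a het call.

IBS is computed with flat weighting (every mutually non-missing site
weighs 1, no allele-frequency weighting): the per-site share is the
multiset intersection of the two genotypes' alleles divided by two,
which reduces to dosage algebra and lets the whole matrix be accumulated
from a handful of matrix cross-products instead of a loop over pairs. A
naive per-pair implementation serves as the oracle in the test suite.

## Diversity estimators with missing data

π and θ use pairwise deletion with a two-sequence minimum per site: a
column enters the computation iff at least two sequences carry an
unambiguous base there (gaps and IUPAC codes are missing). π averages
the per-site mean pairwise difference over included columns; θ counts
included segregating columns and divides by the harmonic number
$a_{n-1}$ and the included length. The number of sequences (not the
per-site valid count) is used for $a_{n-1}$ — at the missingness levels
of assembled organellar data the difference is negligible, and the
choice keeps θ a single per-group number; it is documented rather than
hidden. Haplotype diversity uses the small-sample correction
$H = \tfrac{N}{N-1}(1-\sum x_i^2)$. Allelic richness is the rarefaction
form $A(g) = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$ (each
haplotype counted as an allele); the rarefaction size defaults to the
smallest compared group's N, since sample-size correction is the reason
to use the statistic at all. The estimators are validated against
brute-force enumeration (all pairs for π, all subsamples for A(g)) and
against each other on neutral coalescent simulations, where π and θ
must agree in expectation.

## Haplotype networks

Scored sites keep columns whose minor state occurs in ≥ 2 samples —
single-sample states at assembled-consensus quality are not trustworthy.
Complete state vectors define haplotypes; a partial vector is assigned
iff compatible with exactly one existing haplotype at all its observed
positions and its missing fraction is below `max_missing` (default 0.5),
otherwise it stays unassigned rather than guessing.

The median-joining construction iterates: build the ε-relaxed minimum
spanning network (an edge survives iff its weight is within ε of the
single-linkage bottleneck between its endpoints; ε defaults to 0, the
most parsimonious network, and is exposed as a parameter); generate
per-position majority medians from node triples, branching over ties up
to a 1000-candidate cap so termination is guaranteed; add the median
that most reduces the spanning length; prune median vectors whose
removal does not increase it. Each addition strictly decreases an
integer length, so the loop terminates. On all small binary cases in the
test suite the resulting length equals the optimum found by exhaustive
Steiner-point enumeration.

Haplogroup labels are seed-based — the classic A/B/C/D-style
designations are curatorial, so the package takes a mapping from label
to haplotype and assigns every observed haplotype to the seed with the
smallest network path length, leaving ties unresolved. Divergence time
between haplotypes is $T=(d/L)/(2\mu)$; the substitution rate and the
compared fragment length are user inputs.

## Group-level analyses

"Variable in a group" means ≥ 2 distinct alleles among the group's
non-missing calls (a het carries both alleles) — the minimal reading of
a variable position. Diagnostic domestication sites require strict
inequalities (domesticated frequency > 0.95 *and* wild frequency
< 0.25, both over non-missing calls per group); the domestication score
counts carriage of ≥ 1 copy by default, with a homozygous-only flag,
because published scores do not state how het carriers were counted.
The clustering test uses the mean within-chromosome nearest-neighbour
distance of the specific sites against equal-size uniform draws from all
variable sites, with the empirical p-value
$(1+\#\{\text{null} \le \text{obs}\})/(n_{\text{draws}}+1)$; a mean
adjacent-gap statistic is available behind a flag. PCA encodes
alternate-allele dosage (most frequent non-reference allele at
multistate sites), imputes missing entries to the column mean and
applies Patterson scaling $\sqrt{p(1-p)}$ by default.

## The synthetic generator

`simulate_nuclear()` uses a pool-and-subsample model rather than a full
coalescent: the validation surface needs *controlled truth* — planted
private variants, planted linkage blocks, exact duplicates, a known
diversity gradient — not realistic genealogies, and a coalescent
backend could be slotted in behind the same interface later. Wild
samples draw from a high-diversity pool (per-site polymorphism
probability 0.35, frequencies uniform on 0.1–0.9); the domesticated
group keeps a retention fraction (default 0.4) of wild-polymorphic
sites plus its own derived alleles, a third of them laid out in ~20-site
physical blocks to exercise the clustering test. Genotypes are
homozygous except for a residual heterozygosity rate (default 0.01,
selfing); depth is negative-binomial (modern mean 20, ancient mean 2,
size 10) so minDP sweeps do real work; the ancient sample adds 40 %
random missingness and carries "eroded" variants (default 0.5 % of
sites) present in no extant sample — by construction these become
private doubletons. Six regions receive diversity multipliers that scale
both their region-restricted polymorphic sites and the Poisson rate of
planted per-sample private variants, so regional PV% and regional θ
co-vary by design. `scenario_erosion()` freezes the reference condition:
40 wild / 80 landraces / 30 cultivars / one ancient sample, 20,000
sites, two duplicate pairs.

In `exact_truth` mode all interfering noise is disabled and any
background allele that happens to land in a single carrier is given a
second homozygous carrier, so planted private-variant counts are
recovered *exactly* — this is what allows equality (not approximation)
tests of the classification chain.

What the generator does **not** emulate: linkage disequilibrium beyond
the planted blocks, genealogical correlation between sites, aDNA damage
patterns (deamination), reference bias, or realistic site-frequency
spectra. Passing tests therefore demonstrate the correctness of the
statistics and their implementation under controlled conditions, not
the power of the method on any particular real dataset.

## Numerical and scale choices

Problem sizes in the test suite are chosen to make sampling error small
relative to the planted effects while keeping runs desk-sized: the
power study uses 100 generator seeds of the 20,000-site scenario; the
null-calibration study uses 200 replicate p-values at 199 draws each
(the planted-block alternative uses 999 draws); estimator oracles run on
100 random alignments of ≤ 8 sequences × 50 sites. Positions are
1-based as in VCF; exclusion masks are 0-based half-open (BED) and
converted internally. Ties: duplicate pruning breaks missingness ties
lexicographically; haplogroup assignment leaves distance ties
unresolved; median generation enumerates state ties up to the candidate
cap. Degenerate inputs (zero comparable sites, zero valid calls, zero
variance, unreachable nodes) return NA sentinels with warnings rather
than silent numbers.

## Known limitations

* The IBS dosage algebra assumes diploid genotypes; polyploid calls are
  out of scope.
* Median-joining is a heuristic; optimality is verified only for the
  small binary cases the tests enumerate, and multistate medians use
  per-position majority with tie branching.
* θ from genotype matrices (`regional_theta_from_genotypes()`) treats
  individuals as units with a segregating-site count over all sites —
  adequate for comparing regions within one dataset, not calibrated as
  an absolute estimate.
* The generator's duplicate copies receive a small amount of extra
  missingness so that pruning is deterministic; exactly tied copies are
  resolved by sample id.
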