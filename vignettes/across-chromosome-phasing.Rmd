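---
title: "Across-chromosome phasing with windowed haplotype similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-chromosome phasing with windowed haplotype similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossphase)
```

## The problem

Within-chromosome phasing tools (Shapeit2, Eagle2, Beagle) separate a
diploid genome into two haplotypes per chromosome, but the labels of those
haplotypes are arbitrary on every chromosome: nothing says whether
"haplotype A" of chromosome 1 and "haplotype A" of chromosome 7 came from
the same parent. *Across-chromosome phasing* resolves exactly that — it
partitions the 2 × 22 autosomal haplotypes of a focal individual into two
genome-wide parental sets (without naming which set is maternal). This
matters for parent-of-origin effect analyses, pedigree reconstruction,
GWAS-by-proxy, and studies of assortative mating.

When parents or other first-degree relatives are genotyped, the problem is
easy. `crossphase` implements a method for the hard case: cohorts where the
focal individual has no close relatives, only the faint genome-wide traces
of distant common ancestry.

## The model

### Haploid windowed similarity

For a focal individual *f* and every other cohort member *i*, within a
chromosomal window *w*, the similarity of one focal haplotype *H* to one of
*i*'s haplotypes is

$$\hat\psi_w(H_f, A_i) = \sum_{k \in s}
  \left(\frac{(x_k^{H_f}-p_k)(x_k^{A_i}-p_k)}{p_k(1-p_k)}\right)^{1/5},$$

where the sum runs over *s*, the longest contiguous run of SNPs at which
the two haplotypes carry identical alleles, restricted to the SNPs where
the focal individual is heterozygous (the only phase-informative sites);
$p_k$ is the minor allele frequency and $x_k$ the 0/1 allele code (1 = the
minor allele). Because the run consists of identical alleles and codes are
minor-allele oriented, every term is non-negative and so is $\hat\psi$.
Matching on a rare allele contributes more than matching on a common one —
it is stronger evidence of co-ancestry — but the 1/5 exponent dampens that
excess so single rare-allele coincidences cannot dominate. Unlike an
average-based relatedness estimate, $\hat\psi$ is a *sum* over the run:
long identical stretches (the fingerprint of identity-by-descent) dominate
it, without any explicit IBD segment calling.

Each window then keeps, per partner, only the better of the partner's two
haplotypes, amplified by a square:

$$\hat\psi^*_w(H_f, i) = \max\{\hat\psi_w(H_f,A_i),\,\hat\psi_w(H_f,B_i)\}^2 .$$

Taking the within-window maximum makes the score invariant to the
partner's own phase labels and robust to the partner's switch errors; the
square stretches the contrast between background similarity and genuine
shared ancestry.

### Correlating windows

Stacking $\hat\psi^*_w(A_f,\cdot)$ and $\hat\psi^*_w(B_f,\cdot)$ over all
partners gives two profile vectors per window. If haplotype A of window
*g* and haplotype A of window *h* descend from the same parent, the same
partners (relatives of that parent's lineage) light up in both profiles.
The four Pearson correlations between the two windows' profile pairs are
combined into one signed score

$$\lambda_{g,h} = r(A_g,A_h) - r(A_g,B_h) - r(B_g,A_h) + r(B_g,B_h),$$

whose sign predicts whether the A haplotypes of the two windows share a
parent (+) or cross (−), and whose magnitude measures the evidence.
Relabelling either window's haplotypes flips the sign exactly.

### Windows from recombination hotspots

Windows must be long enough to contain informative runs but short enough
that a single within-chromosome switch error does not contaminate a whole
chromosome. Boundaries are placed at the strongest recombination hotspots —
the inter-anchor intervals of a genetic map with the highest cM/Mb ratio
(top 10 per chromosome by default) — subject to every window spanning at
least 25 cM. A candidate boundary is accepted in a left-to-right sweep only
if the window it closes is long enough, and a too-short terminal window is
merged into its neighbour. On the human genome with a sex-averaged
pedigree-based recombination map these defaults produce a few windows per
autosome (more on long chromosomes than short ones).

### Greedy merging

All windows start unassigned. The pair of windows with the largest
$|\lambda|$ (after adjustment, below) is merged first, fixing the second
window's orientation by the sign of $\lambda$; thereafter the unassigned
window with the largest $|\lambda|$ *against the merged group* is folded
in, where the group is represented by the element-wise sums of its members'
profile vectors aligned by their assigned orientations. Orientations are
never revisited. Because switch errors between two windows of the same
chromosome occur with probability below one half, a *negative* λ between
same-chromosome windows is partly discounted (×0.75 by default) before the
arg-max. Windows with no focal-heterozygous SNPs (or degenerate profiles)
are flagged uninformative and assigned arbitrarily.

### Evaluation: ACPA

With genotyped parents, each focal-heterozygous site where at least one
parent is homozygous reveals which parent transmitted each allele
(triple-heterozygous sites are excluded from scoring by default, so the
score does not depend on the parents' phasing quality). The
across-chromosome phasing accuracy (ACPA) is the percentage of resolved
sites whose slot-A allele traces to one single parent, under the one
genome-wide set↔parent mapping that maximises agreement. The genome-wide
score is therefore ≥ 50% (50% is the random-assignment expectation; 100%
is perfect), while individual chromosomes can score below 50% — a wholly
mis-phased chromosome scores 0 under the global mapping, as in the
four-chromosome worked example (100 + 88 + 100 + 0)/4 = 72%.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.05 | variant QC: minimum minor allele frequency |
| `hwe_p_min` | 5e-4 | variant QC: HWE χ² p-value must exceed this |
| `hotspots_per_chrom` | 10 | boundary candidates per chromosome |
| `min_span_cM` | 25 cM | minimum genetic window span |
| `pihat_max` | 0.33 | partner exclusion: genome-wide relatedness bound |
| `psi_exponent` | 1/5 | per-site damping in $\hat\psi$ |
| `psi_star_power` | 2 | amplification after the per-partner maximum |
| `same_chrom_penalty` | 0.75 | discount on negative same-chromosome λ |

The 0.33 relatedness bound removes parents, offspring and full siblings
from the partner set: parents would trivialise the problem and full
siblings are uninformative here (they inherit both haplotypes from the
same couple). Second-degree and more distant relatives remain — they are
the signal.

## The simulator, and what it does and does not emulate

`simulate_cohort()` generates founder haplotypes by independent Bernoulli
draws at per-SNP frequencies (uniform on [0.05, 0.5] by default), builds a
genetic map with planted recombination hotspots, transmits haplotypes
through meioses with Poisson crossovers (mean = genetic length / 100 cM,
no interference, positions uniform on the cM axis), and constructs, per
focal individual, a trio plus configurable distant relatives: 2nd degree
as an avuncular relative (another child of the focal's grandparents), 3rd
degree as a first cousin, 4th degree as a first cousin once removed,
alternating between the paternal and maternal side. Each individual's
per-chromosome slot order is then scrambled at random — exactly the
label-arbitrariness real within-chromosome phasing leaves behind — and
within-chromosome switch errors can be injected at a per-heterozygous-site
rate (each hit swaps the two haplotypes from that site to the chromosome
end). Optionally founders come from two populations with Balding–Nichols
allele-frequency divergence and the two parents of each focal individual
are drawn from different populations, emulating the parental-generation
stratification that is a second source of phasing signal.

Deliberate non-goals of the generator: linkage disequilibrium among
founders (available only as an optional mosaic-of-pool-haplotypes mode),
crossover interference, genotyping error, mutation, and realistic
demography. Under site-independence, background identical runs are shorter
than in real data while IBD-driven runs are map-length-driven, so the
simulated signal-to-background contrast is, if anything, conservative for
short windows; passing tests demonstrate the machinery and its scaling
behaviour, not the accuracy attainable on a real biobank-scale cohort.

## Numerical and design choices

* **Run definition.** The "longest contiguous run" is measured in number of
  focal-heterozygous sites after restriction; ties are broken by the larger
  run score, then by the leftmost start. Runs are found by a single linear
  scan (the tests check it against an exhaustive all-runs oracle).
* **Minor-allele orientation** is fixed at load time (code 1 = minor
  allele), so $p_k \le 0.5$ always refers to the minor allele and the
  $\hat\psi$ terms for identical alleles are non-negative by construction.
* **Missing data** are rejected at load: the longest-run logic is undefined
  across gaps. Unphased genotypes are a hard error naming the record.
* **The ψ\* power is 2.** The amplification exponent applied after the
  per-partner maximum is squared; it is exposed as `psi_star_power` for
  sensitivity analyses.
* **Group representation in the greedy merge** is the orientation-aligned
  element-wise *sum* of member profiles (mean would give identical Pearson
  correlations); λ against a group applies the same-chromosome discount
  when the candidate window shares a chromosome with any group member.
* **Ties** anywhere in the greedy arg-max are broken by the lowest window
  index, making the merge log reproducible bit for bit; per-focal
  computations are pure functions of their inputs, so focal individuals
  can be processed concurrently with identical results.
* **Degenerate inputs.** Pairs with a zero-variance profile have undefined
  λ and are skipped; windows without focal-het SNPs are flagged; a
  chromosome losing all SNPs in QC, or a focal individual with no eligible
  partners, is a hard error.
* **Interpolation.** Genetic positions are linearly interpolated in bp
  between map anchors and clamped at the map boundaries.

## Study conditions used by the test suite

The package's end-to-end accuracy checks run on a synthetic cohort chosen
to be a realistic, desk-scale version of a biobank experiment: 2,000
individuals, six chromosomes of 75 cM (75 Mb) with 4,200 SNPs each, twelve
hotspot-delimited windows genome-wide, and 36 focal trio offspring — 24
given one 2nd-degree and one 3rd-degree relative in the cohort and 12 given
only the 3rd-degree relative, so accuracy can be contrasted across
relatedness strata. On noise-free input the with-2nd-degree group reaches
median ACPA ≥ 95% with a sizeable fraction phased perfectly; injecting
switch errors at increasing rates (0, 1%, 4% per heterozygous site)
strictly degrades the mean, and the stratified means preserve the
with-relative ≥ without-relative ordering. The random-assignment baseline
(50%) and kinship expectations (parent–offspring π̂ ≈ 0.5, 2nd degree
≈ 0.25) are verified on separate simulations. Smaller window/SNP counts
than a real biobank keep each check reproducible on a single CPU.

## Known limitations

* Accuracy is bounded by the focal individual's *within*-chromosome phasing
  quality: a switch error inside a window corrupts that window's profile.
  The method neither detects nor corrects within-chromosome switch errors.
* Windows with no detectable shared ancestry on either parental side are
  oriented essentially at random; in small cohorts with few distant
  relatives this, not the algorithm, is the accuracy ceiling.
* The two parental sets are unlabeled — deciding which is maternal
  requires external information (e.g. chrX or mitochondrial data).
* Strong ancestry mixture within the partner set changes ψ̂ behaviour;
  cohorts should be reasonably homogeneous, or stratification should be
  treated as part of the signal (parents from different subpopulations).
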