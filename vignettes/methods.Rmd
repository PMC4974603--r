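---
title: "Blinded ancestry-label benchmarks: models, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blinded ancestry-label benchmarks: models, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixbench)
```

## The problem this package addresses

Claims that a binary group membership ("is this person a member of
community X?") can be read off genome-wide genotype data are common in
direct-to-consumer genetics, and are rarely exposed to a falsifiable test.
`admixbench` operationalizes one such test as a *blinded challenge*:
genotypes of self-reporting members and non-members are hybridized
forward in time for two generations, the terminal offspring are released
with identities, sexes, pedigree links and labels stripped, and any claimed
classifier can be scored against the hidden key. The package also ships the
companion population-genetic analysis used to ask whether the challenge is
even winnable in principle: supervised admixture estimation against a fixed
ancestral panel, a minimal-Euclidean-distance statistic between admixture
vectors, and a thresholded similarity graph over a simulated reference
cohort.

Two descent rules generate the hidden truth, matching the two legal/
religious definitions in actual use:

* **matrilineal rule (Halacha)** — an individual is labeled iff its strict
  maternal-line founder self-reported as labeled;
* **grandparent-threshold rule (Law of Return)** — an individual is labeled
  iff at least one (configurable: 1–4) of its four grandparents is deemed
  labeled.

Both rules are functions of pedigree topology and founder self-reports
only; genotypes never enter. That asymmetry is the entire point of the
benchmark: a genotype-based classifier is being asked to predict a quantity
that is, by construction, genealogical rather than genetic.

## The forward simulation

Generation 0 consists of `n_founders = 30` individuals (15 male, 15
female), half of whom carry the self-report label. Founders are randomly
paired male–female (monogamous, each used once); every pair has
`offspring_per_pair = 4` children whose sex is an independent fair coin.
From the 60 offspring a sex-balanced cohort of `cohort_size = 30` is drawn
uniformly without replacement and paired for the next round; the procedure
runs for `generations = 2` rounds, so the terminal generation again holds
60 individuals. "Thirty males and females" is read as 30 total; this is
the reading consistent with "thirty male and female offspring were randomly
paired" yielding 15 pairs, and a 60-total mode remains available through
`sim_config()`.

Recombination uses fixed **hotspot blocks**: markers are partitioned into
half-open blocks of `hotspot_spacing = 10,000` markers (0-based,
`[0, s), [s, 2s), ...`), restarting at every chromosome boundary because
inter-chromosomal assortment is biologically mandatory even though the
hotspot rule itself is index-based. A gamete copies, for each block
independently, one of the parent's two haplotypes chosen uniformly; there
is no within-block crossover, no genetic map, no interference and no
mutation. This makes a sharp, exhaustively checkable invariant — every
non-founder haplotype equals a parental haplotype block-by-block — which
the test suite uses as the simulator's oracle.

Real input genotypes are unphased; founders are phased by splitting
homozygotes deterministically and assigning the counted allele of each
heterozygous cell to haplotype 1 or 2 with an independent fair coin.
Missing founder cells must be imputed first (`impute_missing()`: two
Bernoulli draws at the pooled allele frequency, seeded and logged).
Since any valid phasing is block-consistent with the dosage data and the
simulator only ever copies whole haplotype blocks, the random phase
convention does not bias dosage-level statistics.

## Blinding and scoring

`blind()` releases, by default, the terminal generation only: dosages are
untouched, rows are permuted by a seeded permutation, ids are replaced by
sequential anonymized codes, and sex/parent columns are written as 0. The
private bundle retains the inverse map and the per-rule key. The
grandparent rule is defined only for generation ≥ 2 (otherwise grandparents
are outside the pedigree); in an all-generations key, earlier individuals
fall back to their matrilineal label and are flagged, because the challenge
itself only ever scores terminal offspring.

`score()` reports the confusion matrix, accuracy, sensitivity and
specificity per rule, with missing predictions excluded and counted. The
historically observed outcome class — a submission that identifies not a
single labeled individual — is exactly sensitivity 0.

## Synthetic data: what is emulated, and what is not

The real founder panels are not redistributable, so the package generates
its own world:

* **Ancestral allele frequencies** follow a Balding–Nichols model: per
  marker an ancestral frequency `p ~ Uniform(0.05, 0.95)`, then each of K
  component frequencies `~ Beta(p(1−fst)/fst, (1−p)(1−fst)/fst)`, so
  `E[f|p] = p` and `Var(f|p) = p(1−p)·fst`. Default `fst = 0.1` is a
  realistic continental-scale divergence; `fst = 0.2` is used in tests
  where well-separated components are needed.
* **Founders** draw each haplotype allele independently as
  `Bernoulli(q_i' F_l)` given a per-individual admixture vector — i.e.
  Hardy–Weinberg within individuals and linkage equilibrium across markers.
* **The simulated Israelite reference cohort** draws each of nine
  components independently and renormalizes to the simplex. The geographic
  admixture ranges the original construction used are unavailable; the
  shipped default (`israelite_spec()`) therefore parameterizes the four
  major components by their published cohort means ± SDs in percent —
  Mediterranean 57.7 ± 1.2, South West Asian 23.9 ± 0.6, Sub-Saharan
  African 9.4 ± 0.5, Northern European 3.2 ± 1.3 — as zero-truncated
  normals, and splits the residual 5.8% equally over the five unprinted
  minor components (1.16 each, SD 0.5, a deliberately documented fixed
  ratio that keeps normalization non-trivial). A uniform-range family is
  also provided since the original draw distribution is unstated; neither
  family is claimed to be "the" original.

What a green test on this world does **not** establish: real genotypes have
LD (our founders are in linkage equilibrium, so LD pruning removes little
from synthetic panels), missingness structure, array ascertainment bias,
and relatedness; and the ancestral panel here is generated, not the fixed
proprietary panel of any published pipeline. The benchmark logic, the
descent rules, the estimator contracts, and the distance analysis are
fully exercised; dataset-specific figures (e.g. a 531,315 → 226,836 marker
pruning outcome) are not reproducible and are not asserted anywhere.

## Supervised admixture and the distance graph

`estimate_admixture()` solves the simplex-constrained least-squares
problem

$$\hat q = \arg\min_{q \ge 0,\ \mathbf 1'q = 1}
  \sum_l \left(\tfrac{x_l}{2} - \textstyle\sum_k q_k F_{lk}\right)^2$$

with a primal active-set method: an equality-constrained KKT solve over the
free components, a blocking-constraint line step when a free component
would go negative, and a Lagrange-multiplier test to release active
components. The iterate objective is monotonically non-increasing (a
property test asserts the trace) and the method terminates finitely at the
exact KKT point, so results are deterministic — the reason least squares
was chosen over a binomial maximum likelihood, which the cited supervised
frameworks do not pin down anyway. Degenerate panels (duplicate frequency
columns) are rejected at construction with a 1e-12 column-distance guard.

The **admixture genomic distance** `d(q, P) = min_{m∈P} ‖q − q_m‖₂` is
point-to-set and deliberately not symmetric in its roles. The similarity
graph connects pairs with `d < τ`, strict inequality, default `τ = 0.075`
on the proportion scale (the same scale the distances are quoted on).
Population-level aggregates use the median member-wise `d` — a repo
convention, flagged as such, since no aggregate is defined in the source
analyses. Connected components and degrees come from igraph.

## Numerical and interface choices

* **Counted allele**: the first non-missing allele observed per marker in
  file order. Deterministic and frequency-free; PLINK's minor-allele
  convention is not assumed. A consequence: a `.ped` file does not store
  the counted allele, so write→read round trips are exact only up to
  per-marker allele orientation (a flipped marker complements dosages to
  2); read→write→read is bit-exact.
* **LD pruning** scans pairs within each window in index order and removes
  the *later-indexed* member of an offending pair (the conventional
  tie-break; the source text says only "one member"). Windows are
  re-scanned to convergence — whether the original made a single pass is
  unstated, and convergence makes the "no surviving hot pair" invariant
  unconditional. Markers with undefined r² (monomorphic, or < 2 complete
  pairs) are kept: undefined is not evidence of high LD.
* **Seeding**: every stochastic operation derives an independent substream
  from the root seed and an operation name (`derive_seed()`), so the order
  of unrelated calls cannot perturb results; all derived seeds stay below
  2³¹.
* **Percent vs proportion**: internal Q matrices are proportions;
  percentages appear only in reporting (`cohort_component_summary()`).
* **Config format**: component specs serialize as JSON (the environment
  ships no YAML parser); structure matches the documented spec table.

## Scaled-down test replications

Two property tests replicate distributional claims with reduced effort to
keep the default suite near one minute: the drift-unbiasedness check uses
40 replicate simulations at L = 200 (instead of 200 seeds at full size) and
the matriline-fraction symmetry check uses 60 replicates. The Mendelian
block oracle runs at full stated size (50 seeds, L = 30,000, spacing
10,000). The 3-SE allele-frequency conservation band is asserted in its
multiple-comparison form (≤ 1% of markers outside 3 SE) because with
hundreds of markers an all-within-3-SE assertion fails by chance for a
nontrivial fraction of seeds.

## Known limitations

* No genetic map, crossover interference, mutation, or X-specific
  inheritance (X markers are simply treated like autosomes if present;
  autosomal-only input is the intended use).
* Founders are simulated in linkage equilibrium, so the LD-pruning module
  is exercised by construction (planted correlated pairs, duplicated
  markers) rather than by realistic LD decay.
* The supervised estimator's equivalence to any specific published
  admixture pipeline is not claimed — only the stated contract: fixed
  K-component panel in, simplex vector out, deterministic.
* Binary labels only; fractional "membership scores" are out of scope by
  design.
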