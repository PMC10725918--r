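---
title: "Methods behind ssrpopgen: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ssrpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpopgen)
```

# Scope

`ssrpopgen` analyses diploid codominant microsatellite (SSR) genotypes —
the marker system still standard for clone identification and diversity
surveys in perennial crops and their wild relatives (olive, grapevine,
fruit trees). A typical study design it serves: a few hundred wild and
cultivated individuals scored at ~10 hyper-variable loci, with replicate
genotyping for error control, clone/synonymy detection before any
population-level statistic, and weak differentiation among groups.

Alleles are stored as absolute fragment lengths in base pairs (not
repeat counts), because downstream consumers — notably the TreeMix
microsatellite export, which summarises each group by the mean and SD of
absolute allele length — need lengths. Genotypes are unphased and kept
in canonical ascending order; a cell is either a complete pair or
missing, since SSR scoring produces pairs (half-calls are treated as
missing by upstream scoring software and are not representable here).

# The synthetic-data generator

Every stochastic claim in the test suite is validated against data from
`simulate_ssr_dataset()`, whose defaults are fixed to the study
conditions the package is aimed at:

* 8 wild populations of 30 diploid individuals plus a cultivated group
  of 60;
* 10 loci with 15–30 alleles each on a 2-bp ladder starting at 100 bp
  (hyper-variable dinucleotide repeats);
* within-population inbreeding $F_{IS} = 0.15$;
* weak differentiation, Balding–Nichols $F_{ST} = 0.02$ among wild
  populations (pairwise $G_{ST}$ in the 0.001–0.03 range);
* a cultivar group drawn from the same ancestral frequencies with a
  larger drift parameter (0.12), emulating the allele-poorer,
  bottlenecked profile of clonally propagated crops;
* 5 clonal copies differing from their source by 0–2 alleles;
* per-allele mis-scoring probability 0.0085 (one ladder step);
* 1% missing cells.

The Balding–Nichols model was chosen over coalescent simulation because
its closed-form moments make recovery checks analytic: population
frequencies are Dirichlet around ancestral frequencies $p$ with
concentration $p(1-F)/F$, so $\mathrm{Var}(p_s) = F p (1-p)$, and the
expected multilocus $G_{ST}$ for $k$ demes is
$F (1 - 1/k) / (1 - F/k)$, which the test suite verifies to within
±0.01 over 50 replicates. Genotypes are drawn with
$P(\text{hom}_i) = p_i^2 + F_{IS} p_i(1-p_i)$ and
$P(\text{het}_{ij}) = 2 p_i p_j (1 - F_{IS})$.

Scoring errors move an allele one motif step (±2 bp, reflected at the
ladder ends), the dominant real failure mode for dinucleotide SSRs;
allele dropout and null alleles are deliberately not modelled. The
generator also does not model mutation across generations, linkage, or
spatial structure. Passing tests therefore demonstrate correct
behaviour under drift-inbreeding-error structure, not robustness to
dropout, stutter artefacts or isolation by distance.

# Genotyping-error QC

`compare_replicates()` compares two independent genotyping runs. A
*reaction* is an (individual, locus) cell typed in both runs; it is
erroneous when the unordered pairs differ, and its allele-error count is
$2 - |\text{multiset intersection}|$, so $\{100,102\}$ vs $\{100,104\}$
is one allele error and disjoint pairs are two. Per-locus denominators
are the actually comparable reactions (cells missing in either run drop
out). Overall rates are totals-based: per reaction
$\sum e_r / \sum n$, per allele $\sum e_a / (2\sum n)$. This makes
$0 \le \text{rate}_\text{allele} \le \text{rate}_\text{reaction}$ a
structural invariant. `simulate_replicate_pair()` reconstructs a
replicate pair realising any published per-locus (reactions, errors)
table exactly, which is how the error-rate computation is validated
end-to-end against printed QC tables.

# Clones and contracted MLGs

The pairwise distance between individuals is the number of allele
differences summed over loci comparable in both (one unit = one allele
of difference). Missing loci are excluded pairwise, not imputed, and
the distance is left as an unscaled integer; a pair with no comparable
locus is undefined and excluded from the histogram. On complete data
the metric is a sum of per-locus metrics and satisfies the triangle
inequality.

Clonal groups are read off the distance histogram: genotyping error and
somatic mutation make true clones differ by a few alleles, producing a
small clump near zero separated by a valley from the unrelated-pair
mass. `suggest_threshold()` automates the visual rule. It does *not*
naively take the first local maximum/minimum, because low-distance
clumps hold only a handful of pairs and routinely contain internal
zero-count dips that a literal scan mistakes for the valley. Instead
the separating valley is located as the longest zero-count run between
the first non-zero distance and the histogram's main mode, and the
threshold is the distance just below it; for continuous histograms the
literal peak-then-minimum scan is the fallback, and a histogram that
rises monotonically into its main mode yields 0 with a warning. The
histogram itself is always reported so the user can override the
threshold — the choice is ultimately a judgement call.

Contraction links individuals at distance ≤ threshold and takes
connected components (single linkage), matching the transitive
"same clone" semantics of synonymy tables; the MLG count is therefore
monotone non-increasing in the threshold. Each MLG is represented by
its member with the fewest missing cells (ties: lexicographic ID), an
arbitrary but reproducible convention for "one sample per MLG"
deduplication before population statistics. Undefined distances never
link.

# Identity and informativeness statistics

Per locus, from pooled allele frequencies $p_i$:

$$PID = 2\left(\sum p_i^2\right)^2 - \sum p_i^4, \qquad
  PID_{sibs} = 0.25 + 0.5\sum p_i^2 + 0.5\left(\sum p_i^2\right)^2
  - 0.25\sum p_i^4,$$

and Botstein's $PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$.
Multilocus values are products over loci (independence assumption).
Both closed forms are tested to 1e-12 against brute-force enumeration
oracles — genotype-pair enumeration for PID, full parental-quadruple
enumeration for the sibling variant — across the entire 0.05-grid of
frequency vectors with up to six alleles.

The locus-resampling power analysis draws $k$ loci *with replacement*
(a drawn locus can repeat, and then its factor repeats in the product)
1,000 times for $k = 1..L-1$ and summarises the statistic per panel
size. For the MLG-count statistic, classes are exact genotype strings
over the drawn panel with missing kept as an explicit state — at
threshold 0 these are the strict MLGs, and the shortcut keeps 9,000
resamples tractable where repeated distance-matrix construction would
not be.

Identity statistics default to the clone-deduplicated input produced by
the pipeline (duplicated clones would bias the frequencies toward
themselves); computing them per group instead is a one-argument change.

# Diversity estimators

Per (group, locus): observed alleles $N_a$; effective alleles
$n_e = 1/\sum p_i^2$; observed heterozygosity $H_o$; unbiased gene
diversity $uH_e = \frac{2N}{2N-1}(1 - \sum p_i^2)$. Allelic richness
uses hypergeometric rarefaction to $g$ gene copies,
$AR(g) = \sum_a \left[1 - \binom{N-N_a}{g} / \binom{N}{g}\right]$
(computed with log-binomials), validated against exhaustive subsample
enumeration; the default $g$ is the smallest typed copy number across
the compared groups at each locus, so groups are compared at a common
standardised size. The allele accumulation curve applies the same
expectation at $2n$ copies for $n = 1..N$ individuals, capped per locus
at the observed copy number when data are missing.

$F_{IS}$ is aggregated as a ratio of sums across loci,
$1 - \sum_\ell H_o^{(\ell)} / \sum_\ell uH_e^{(\ell)}$ (robust to
low-diversity loci, unlike averaging per-locus ratios), with percentile
bootstrap CIs over loci (default 1,000 draws, seeded). With only ~10
loci as resampling units these CIs are approximate; measured coverage
at the default study conditions is ≈91% for a nominal 95% interval,
which is why the parameter-recovery check asks for ≥90%.

The Hardy–Weinberg test is a permutation test (statistic $|H_o - H_e|$,
gene copies shuffled among individuals within the population) rather
than an exact enumeration, which is impractical for loci with up to 30
alleles. Its reported p-value is valid but conservative because the
statistic is discrete; the returned `p_smooth` (randomized permutation
p-value) is exactly Uniform(0,1) under the null and is the quantity
used in calibration diagnostics.

# Differentiation

Per locus, within-group and total gene diversities use the Nei–Chesser
small-sample corrections (harmonic-mean sample size $\tilde n$, $k$
groups, $\bar H_o$ the mean observed heterozygosity):

$$\hat H_S = \frac{\tilde n}{\tilde n - 1}\left(1 -
  \overline{\textstyle\sum_a p_{sa}^2} - \frac{\bar H_o}{2\tilde n}\right),
\qquad
\hat H_T = 1 - \sum_a \bar p_a^2 + \frac{\hat H_S}{\tilde n k}
  - \frac{\bar H_o}{2 \tilde n k}.$$

Then $G_{ST} = (\hat H_T - \hat H_S)/\hat H_T$ (multilocus from summed
components, not a mean of ratios),
$G''_{ST} = k(\hat H_T - \hat H_S) / [(k\hat H_T - \hat H_S)(1 - \hat
H_S)]$ (from across-locus mean components) and Jost's
$D = \frac{k}{k-1}(\hat H_T - \hat H_S)/(1 - \hat H_S)$ per locus,
averaged across loci (a harmonic-mean alternative is exposed; the
arithmetic mean is the default because per-locus $D$ can be ≤ 0 at weak
differentiation, where a harmonic mean is undefined). $G''_{ST}$ and
$D$ are reported alongside $G_{ST}$ because hyper-variable markers keep
$H_S$ high and compress $G_{ST}$ toward zero even when groups share few
alleles.

The corrected estimators are unbiased, so they are *near* zero, not
identically zero, for finite identical groups; `correction = "none"`
exposes the raw plug-in definitions, which are exactly zero there —
both variants are reported where diagnosing a discrepancy matters.
Significance uses permutation of whole multilocus individuals among
groups (group sizes preserved, within-individual structure intact),
$p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$.

# Assignment testing

`cross_validate()` implements the Monte-Carlo protocol: per iteration,
a balanced training set (equal per-group size, default
`floor(prop × smallest group)`), a fresh random locus panel of the
requested size, model fitting on training individuals only, and
per-group accuracy on the held-out rest. Loci are redrawn every
iteration (the alternative — fixing one panel per size — confounds
panel identity with panel size).

The default classifier is the transparent allele-frequency likelihood
rule: assign to the group maximising
$\prod_\ell P(g_\ell \mid \text{HWE, training frequencies})$, with
unseen alleles given the pseudo-frequency $1/(2N)$ of that group-locus
training sample so log-likelihoods stay finite. A nearest-centroid
classifier in PCA space of the allele-dosage encoding (axes explaining
80% variance, capped at 20, fitted on training rows only) is the
second option, mirroring the common reduce-then-classify designs.
Kernel classifiers are out of scope: published accuracies under a
specific SVM are properties of data + classifier, while this package's
contract is the leak-free cross-validation protocol itself — which the
tests verify directly (held-out labels cannot influence the fitted
model; null two-group splits score 1/k; disjoint allele sets score 1).

# Clustering post-processing

`evanno_delta_k()` consumes replicate log-probability tables from
external Bayesian clustering and reports mean lnP per K (the first
model-selection criterion) plus
$\Delta K = |L(K+1) - 2L(K) + L(K-1)| / SD(L(K))$ on the replicate
means. ΔK is undefined at boundary K and where the replicate SD is
zero, and is invariant to adding a constant to all lnP values. The
clustering MCMC itself is out of scope — only its output table is
consumed, and group labels derived from membership matrices (e.g. the
50% rule via `membership_groups()`) are the user's upstream decision.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains QC → distances/contraction → one sample per
contracted MLG → (optional outgroup exclusion) → identity → diversity →
differentiation → rarefaction → TreeMix export, writing every stage as
TSV plus a JSON summary whose every value traces to a stage table. One
master seed determines all stochastic stages; reruns are byte-identical.
Outgroup individuals are excluded from structure-facing stages by
default, as extreme asymmetric sampling distorts frequency-based
statistics.

Test and validation problem sizes were chosen to make Monte-Carlo
checks sharp yet quick: 50 generator replicates for parameter recovery,
200 loci for HWE calibration, 200 bootstrap draws inside coverage
loops (1,000 remains the analysis default), 100 cross-validation
iterations split over 10 replicate simulations for the null-accuracy
check. The full suite runs in well under a minute.

# Known limitations

* Diploid codominant markers only; no polyploids, no dominant markers.
* No dropout/null-allele error modelling, and no maximum-likelihood
  decomposition of error types.
* No Weir–Cockerham variance-components F-statistics, no AMOVA, no
  $R_{ST}$.
* Bootstrap CIs over ~10 loci are approximate (slight undercoverage).
* The threshold heuristic assumes a clump-valley-mass histogram shape;
  continuous clonal gradients (e.g. extensive somatic variation) need a
  manual threshold.
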