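---
title: "Methods: ddRAD design and population-genomic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ddRAD design and population-genomic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradpop)
```

This vignette documents the statistical models, the numerical choices, and
the design decisions behind `ddradpop`. The package covers the analysis arc
of a reduced-representation population-genomic study of a diploid species:
choosing a restriction enzyme pair for double-digest RAD (ddRAD)
sequencing, quality-filtering the resulting SNP genotypes, quantifying
population differentiation, inferring ancestry structure, and visualising
relationships as networks. A synthetic-data generator with exposed ground
truth supports parameter-recovery testing of every stage.

## 1. In-silico double digestion

A restriction enzyme is modelled as an IUPAC recognition motif plus a
0-based top-strand cut offset (`restriction_enzyme()`). Only palindromic
motifs are accepted: for a palindromic site the bottom-strand recognition
coincides with the top strand, so a single forward scan finds every cut.
The nine catalogue enzymes (`enzyme_catalogue()`) are the common ddRAD
screening set: AvaII (G^GWCC), EcoRI (G^AATTC), MseI (T^TAA), MspI (C^CGG),
NlaIII (CATG^), PstI (CTGCA^G), SbfI (CCTGCA^GG), SphI (GCATG^C) and MluCI
(^AATT).

Cut positions are reported 0-based *between* bases: a cut at position $p$
separates bases $p$ and $p+1$ of the 1-based sequence. Ambiguity codes are
honoured in the motif only; any non-ACGT genome character (typically N in
assembly gaps) never matches, which avoids inventing cut sites inside gaps.

`double_digest()` merges the cut positions of the two enzymes per scaffold
into 0-based half-open fragments that exactly partition the scaffold; each
fragment records which enzyme produced its left and right boundary (scaffold
ends are `"terminus"`). When both enzymes cut at the same between-base
position the boundary is attributed to the first enzyme of the pair — an
arbitrary but deterministic convention that cannot change fragment
coordinates.

`count_selectable()` reports two counts for a size window
$[\ell_{\min}, \ell_{\max}]$ (inclusive):

* `in_window`: every fragment whose length falls in the window;
* `selectable`: in-window fragments flanked by cut sites of the *two
  different* enzymes — the ddRAD-selectable class, since only such
  fragments receive both adapters.

Both counts are always returned because published in-silico digest tables
are not always explicit about which definition they use. `rank_enzyme_pairs()`
sorts candidate pairs by `in_window` with a default 300–500 bp window, the
common size-selection range for ddRAD libraries.

## 2. Genotype container and quality control

`genotype_matrix()` holds an individuals × loci matrix of alternate-allele
dosages (0/1/2/NA) with locus coordinates and per-sample metadata.
`read_vcf()` keeps biallelic SNP records only and treats half-missing
genotypes (`./1`) as missing; `write_vcf()` round-trips the container.

Filtering mirrors standard RAD practice and is deliberately strict by
default:

* `filter_samples_by_call_rate(g, min_rate)` removes low-coverage samples
  first;
* `filter_loci(g, min_call_rate = 1, min_maf = 0.03)` removes loci typed in
  fewer than all remaining samples, then loci whose minor allele frequency
  (computed from allele counts among called genotypes) falls below 0.03.

The order matters — allele frequencies are recomputed on the post-call-rate
panel — and every step appends to an auditable `filter_report()` ledger.
`thin_one_per_scaffold()` reduces linkage for structure analyses by keeping
one SNP per scaffold (deterministic lowest-position rule by default).

## 3. Differentiation statistics

### Pairwise $F_{ST}$

`pairwise_fst()` computes, for each pair of populations, the among-group
fraction of allele-level variance from a two-level analysis of molecular
variance. Each diploid genotype contributes its two alleles; for a
biallelic locus with $m_p$ called alleles and allele frequency $\hat p_p$
in population $p$ (total $M$ alleles, pooled frequency $\bar p$):

$$SS_T = M \bar p (1 - \bar p), \qquad
  SS_W = \sum_p m_p \hat p_p (1 - \hat p_p),$$

with $MS_A = SS_T - SS_W$ (1 d.f.), $MS_W = SS_W / (M - 2)$, and
$n_c = M - (m_1^2 + m_2^2)/M$. Summing the variance components
$\sigma_a = (MS_A - MS_W)/n_c$ and $\sigma_w = MS_W$ over loci gives

$$F_{ST} = \Phi_{ST} = \frac{\sum_l \sigma_a^{(l)}}
  {\sum_l (\sigma_a^{(l)} + \sigma_w^{(l)})}.$$

This is the allele-level (haplotype) AMOVA treatment applied to genotypic
SNP data. The identity
$\sum_{i<j}(x_i - x_j)^2 = m \sum_i (x_i - \bar x)^2$ makes it exactly
equivalent to an AMOVA over pairwise allele mismatch distances, and its
expectation under the Balding–Nichols model is the divergence parameter
$F$ itself. We deliberately do *not* decompose squared distances between
*dosage* vectors: that statistic has expectation $2F/(1+F)$ (about 0.18 at
$F = 0.1$) and would not estimate $F_{ST}$ on its usual scale. Negative
estimates (sampling noise around zero differentiation) are reported as-is.
`method = "wc"` provides the Weir–Cockerham (1984) $\theta$ as an
alternative; the two agree closely on balanced designs.

Significance uses label permutations of individuals between the pair of
populations, with the add-one estimator
$p = (1 + \#\{F^{perm} \ge F^{obs}\})/(B + 1)$, which is never exactly
zero and keeps the test valid at finite $B$.

### Hierarchical AMOVA

`hierarchical_amova()` expands each individual into its two allele rows,
computes pairwise-complete squared mismatch distances scaled to the full
locus count, and partitions the total sum of squares into among-group,
among-population-within-group, and within-population components with the
usual unbalanced-design coefficients. The three $\Phi$ statistics each get
their own permutation scheme: individuals across everything
($\Phi_{ST}$), individuals across populations within groups
($\Phi_{SC}$), and whole populations across groups ($\Phi_{CT}$). With
`groups = NULL` the two-level decomposition is returned, and its
$\Phi_{ST}$ coincides exactly with `pairwise_fst()` on the same two
populations — an internal-consistency invariant the test suite checks.

### Individual distances

`individual_distance()` returns allele-mismatch dissimilarities
$d(i,j) = \sum_l |g_{il} - g_{jl}| / (2\, n_{ij})$ over the $n_{ij}$ loci
called in both individuals, so identical genotypes score 0 and opposite
homozygotes at every locus score 1. Pairs sharing no called locus are an
error rather than a silent zero.

## 4. Structure inference

### Genotype PCA

`snp_pca()` drops monomorphic loci, mean-imputes missing entries per locus,
centres by $2\hat p$ and scales by $\sqrt{2\hat p(1-\hat p)}$ (Patterson
normalisation), and takes the singular value decomposition. Variance
explained is each squared singular value's share of the total.

### Admixture model

`admixture_em_fit()` maximises the likelihood of the standard admixture
model — dosage $g_{il} \sim \mathrm{Binomial}(2, \theta_{il})$ with
$\theta_{il} = \sum_k q_{ik} p_{kl}$ — by expectation–maximisation over the
ancestry proportions $Q$ and cluster allele frequencies $P$. Missing
genotypes contribute nothing to the likelihood. EM is run from several
random initialisations (default 10) and the best likelihood wins; the
$K = 1$ solution is analytic. Numerical guards: $\theta$ and $P$ are
clamped to $[10^{-6}, 1 - 10^{-6}]$, and the reported log-likelihood
omits the constant $\log\binom{2}{g}$ term. The likelihood trace is
exposed, and monotonicity (up to a $10^{-9}$ relative tolerance for
round-off) is asserted in the tests. EM was chosen over variational
approximations because at these problem sizes exact maximum likelihood is
affordable and easier to verify.

### Choosing K

`choose_k()` scores each candidate $K$ by masked-entry cross-validation:
non-missing entries are partitioned into folds, each fold is masked in
turn, the model is refitted, and the held-out binomial deviance
$-2\sum [g \log\hat\theta + (2-g)\log(1-\hat\theta)]$ is averaged over
folds. The chosen $K$ minimises the mean deviance; ties break toward the
smaller (more parsimonious) $K$.

## 5. Networks

### Minimum spanning network

`minimum_spanning_network()` runs Kruskal's algorithm level by level: at
each distance value, *every* edge of that weight joining two components
(as they stood before the level) is kept. By the cut property this yields
exactly the union of all minimum spanning trees, so reticulations caused
by tied distances are retained instead of being broken arbitrarily.

### NeighborNet

`neighbor_net()` implements the Bryant–Moulton agglomeration: clusters are
linear chains whose two end taxa stay active; cluster pairs are selected by
the net-divergence-corrected average distance, the ends to link by the
analogous node-level criterion, and each link triggers the 3-point
reduction $d(u,\cdot) = \tfrac23 x + \tfrac13 y$,
$d(v,\cdot) = \tfrac13 y + \tfrac23 z$ collapsing a path $x\!-\!y\!-\!z$.
The surviving chain closes into a circular ordering; the weights of all
$n(n-1)/2$ splits compatible with that ordering are then estimated by
non-negative least squares against the input distances and splits below
`prune = 1e-8` are dropped.

One numerical subtlety deserves a note: when exactly three clusters
remain, the pair-selection criterion takes the same value
$-(D_{12}+D_{13}+D_{23})$ for all three pairs, so the "minimum" would be
decided by floating-point round-off. The implementation special-cases this
stage with a fixed convention, which makes the ordering deterministic and
matches the behaviour of independent implementations. On additive tree
metrics the recovered splits and weights equal the generating tree to
machine precision; `neighbor_joining()` (via `ape::nj`) provides the
tree-based cross-check.

A caveat for empirical matrices: the circular ordering of a NeighborNet on
non-additive data is a heuristic, and qualitative features of published
split-network figures (which taxa are adjacent, which terminal split is
largest) are not always recoverable from the distance matrix alone —
figures drawn from richer intermediate output can differ legitimately from
a network rebuilt from the published pairwise matrix. The package asserts
implementation-correctness properties (metric recovery, agreement of
induced distances) rather than figure-level folklore.

`write_splits_nexus()` / `read_splits_nexus()` round-trip the split system
in the Nexus SPLITS format used by splits-graph viewers;
`write_msn_graphml()` exports networks as GraphML.

## 6. Synthetic data with exposed truth

`sim_genotypes()` draws ancestral frequencies from $U(0.05, 0.95)$
(avoiding near-fixed loci that destabilise the Beta sampler), population
frequencies from the Balding–Nichols distribution
$p_{kl} \sim \mathrm{Beta}\!\big(p_l \tfrac{1-F}{F},\,
(1-p_l)\tfrac{1-F}{F}\big)$, and dosages from
$\mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$, with optional
missing-completely-at-random masking. The returned truth bundle
($p$ ancestral and per population, $Q$, $F$) lets tests measure recovery
rather than merely stability. The divergence parameter $F$ equals the
expected $F_{ST}$ against the ancestral pool, which is what the
variance-component estimator targets.

`sim_genome()` plants restriction motifs at chosen positions in random
background sequence and iteratively rewrites any accidental motif
occurrence elsewhere, so the planted sites are provably the only cut
sites. Its truth bundle includes a `fragments(e1, e2)` closure giving the
exact fragment-length ledger any correct digest must reproduce.

All simulator functions take a `seed` and restore the caller's RNG state,
so they are reproducible and side-effect-free. Default problem sizes in
the examples and tests (tens of individuals, hundreds to a thousand loci)
are the package's own choices, selected so that full parameter-recovery
checks complete in minutes on one CPU.

## 7. Limitations

* Only palindromic restriction enzymes are supported; nicking enzymes and
  non-palindromic recognition sites are out of scope.
* The digest simulator models complete digestion — no partial digests,
  no methylation sensitivity.
* $F_{ST}$ and AMOVA assume biallelic loci; the multi-allelic
  generalisation is not implemented.
* The admixture model treats loci as independent; linked loci should be
  thinned first (`thin_one_per_scaffold()`).
* NeighborNet's circular ordering is a greedy heuristic; only the split
  weights given the ordering are globally optimised (by NNLS).
* The Balding–Nichols simulator draws populations independently around a
  single ancestral pool; it does not model migration, admixture history,
  or linkage.
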