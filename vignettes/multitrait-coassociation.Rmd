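---
title: "From multi-trait GWAS to co-association networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-trait GWAS to co-association networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coassocnet)
```

## The problem this package addresses

Complex traits such as the fatty-acid composition of muscle fat are driven
by many loci, and a battery of related phenotypes measured on the same
animals carries information that no single-trait analysis exposes: loci
whose estimated effects co-vary across many traits point at shared
regulation. `coassocnet` implements that whole chain as reusable,
seed-reproducible components:

1. **Bayes-B GWAS** per trait, with contemporary-group fixed effects;
2. **1-Mb window summaries**: posterior share of genetic variance and a
   posterior probability of association (PPA) per window;
3. an **association weight matrix (AWM)**: posterior mean SNP effects of
   the SNPs in the key trait's top windows, across all traits;
4. **PCIT** filtering of the SNP-pair correlation matrix into a
   co-association network;
5. **density-scored complex detection** on that network;
6. **EASE-based term enrichment** for the genes under the selected
   windows.

Because the motivating study design (half-sib beef cattle families,
~1,800 offspring of ~150 sires genotyped on a dense SNP panel, 33
contemporary groups, 39 fatty-acid traits in two lipid fractions) has no
public data deposit, the package ships a synthetic-data generator that
emulates the statistical structure of such a design, and every stage is
tested against it.

## The Bayes-B model

For one trait, phenotypes are modeled as

$$y_i = b_{g(i)} + \sum_j x_{ij}\,\delta_j a_j + e_i,$$

with contemporary-group effects $b_g$ under a flat prior, centered
dosages $x_{ij} \in \{0,1,2\} - 2p_j$, indicator
$\delta_j \sim \mathrm{Bernoulli}(1-\pi)$, effect
$a_j \mid \sigma^2_j \sim N(0, \sigma^2_j)$, locus variance
$\sigma^2_j \sim$ scaled-inv-$\chi^2(\nu, S)$ and residual variance
scaled-inv-$\chi^2(\nu_e, S_e)$. The sampler updates $(\delta_j, a_j)$
jointly — $\delta_j$ is drawn from its full conditional with $a_j$
integrated out of the likelihood, then $a_j$ from its normal full
conditional when included — so no Metropolis tuning is needed and each
sweep is an exact Gibbs step on the augmented model. Centering by $2p_j$
makes a locus's additive-variance contribution exactly
$2p_j(1-p_j)a_j^2$ under linkage equilibrium, the quantity
`snp_variance()` computes.

Key tunables and defaults:

| parameter | default | meaning |
|---|---|---|
| `pi` | 0.99 | prior fraction of zero-effect SNPs; typical for dense panels where a few hundred loci matter. `default_pi(strategy = "markers-based")` sets it from a target count of nonzero SNPs. |
| `burn_in`, `chain_length` | 1,000 / 40,000 | the conventional chain lengths for this model class at full scale; tests and the demo configuration run shorter chains (hundreds to ~1,500 iterations), which the recovery tests show is ample at desk scale. |
| `nu`, `scale` | 4, derived | locus-variance prior; `scale` is derived from an assumed genetic fraction `h2_prior` (default 0.5) of the phenotypic variance spread over the expected $(1-\pi)\sum_j 2p_jq_j$: a weakly informative choice common in practice. |
| `thin` | 10 | stride at which effect vectors are stored for window posteriors; bounds memory at full scale. |

The chain is deterministic given `seed` (it uses R's RNG), which the
tests assert bit-for-bit.

## Window variance and PPA

SNPs map to windows by `floor(pos_bp / 1e6)`, labeled `"chrom_index"`
(chromosome 19 at 51.5 Mb is `"19_51"`). For each stored MCMC draw the
genetic value of window $w$ is $g_w = X_w a_w$ (centered dosages), and the
window's share is

$$f_w^{(t)} = \frac{\mathrm{Var}(g_w^{(t)})}{\sum_{w'} \mathrm{Var}(g_{w'}^{(t)})}.$$

Two deliberate choices live here. First, the numerator is the *genomic*
variance of the window component, so within-window LD is honored rather
than assuming independent loci (the independent-sum
$\sum 2p_jq_ja_j^2$ is available via `approx = TRUE`). Second, the
denominator is the **sum of within-window variances**, not the variance
of the genome-wide sum: with between-window LD the two differ, and only
the former makes shares a true decomposition that sums to exactly 1 at
every iteration — an invariant the tests check to $10^{-8}$. Iterations
in which every effect is zero contribute a share of 0 to every window.

The PPA of a window is the fraction of stored iterations in which its
share beats a threshold. No closed-form definition is universal; we use
the uniform expectation $1/\#\text{windows}$ (the window explains more
than an average window's share), with the threshold rule pluggable.
`top_windows()` ranks by PPA, breaking ties by posterior variance share
and then lexicographically — when many PPAs saturate at 1.00, ranking by
variance first is available via `by = "var_pct"`.

## AWM and PCIT

The AWM takes every SNP in the key trait's top `K = 20` windows (no
further filtering) and collects its posterior mean effect across all
traits, key trait first. Whether to standardize the columns before
correlating is not dictated by the method's sources; the default is
per-trait z-scoring, because traits measured in different units would
otherwise dominate the row correlations by scale alone. Raw mode is one
flag away, and the choice is surfaced prominently since it changes PCIT's
input. Rows with zero variance across traits (SNPs whose effect never
moved in any trait) have undefined correlations and are dropped with a
warning at the correlation step.

PCIT scans all $\binom{n}{3}$ trios. For trio $(x, y, z)$ it computes the
three first-order partial correlations, e.g.

$$r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},$$

forms the local tolerance $\varepsilon$ as the mean of
$|r_{\cdot\cdot \cdot}/r_{\cdot\cdot}|$ over the pairs with nonzero direct
correlation, and flags edge $(x,y)$ when
$|r_{xy}| \le \varepsilon |r_{xz}|$ and
$|r_{xy}| \le \varepsilon |r_{yz}|$ — the association is fully
explainable through $z$. Numerical edge rules, all chosen for
determinism and documented because the method's description leaves them
open: a zero direct correlation is skipped from the tolerance average
(an all-zero trio imposes no constraint); conditioning correlations of
magnitude 1 within $10^{-12}$ set the partial to 0 (maximally
explainable); ties eliminate (`<=`), switchable to strict `<`. Although
the trio-wise step is sometimes described as "third-order" partial
correlation in the applied literature, what trios yield mathematically is
the first-order partial above, and that is what is implemented. The fast
C++ scan is verified edge-for-edge against a brute-force R enumeration on
random matrices, and a 454-node input (the motivating study's size)
finishes in seconds.

## Complex detection and scoring

Vertex weighting and complex growth follow the MCODE scheme: a vertex is
weighted by the core number $k$ of the highest k-core of its closed
neighborhood times that core's density; complexes grow breadth-first from
the highest-weight unvisited seed, admitting neighbors whose weight
exceeds $(1 - \mathrm{vwp})$ of the seed's. Defaults are the plugin's
conventional `vwp = 0.2`, haircut on (degree-1 members removed), minimum
size 3, no fluff stage. A complex with $n$ nodes and $m$ induced edges
has density $m / \binom{n}{2}$ (self-loops excluded) and score
$\text{density} \times n$; reported complexes are disjoint and sorted by
score, then size, then seed id. Published MCODE tables occasionally print
scores inconsistent with the reported node/edge counts (plausibly scored
before pruning); this package always reports score, nodes and edges from
the same induced subgraph, and the tests recompute one from the other to
$10^{-12}$.

## Enrichment

Genes are pulled from selected windows by any-overlap of 1-based
inclusive intervals. For a list of $n$ genes of which $k$ carry a term
that annotates $K$ of $N$ background genes, the EASE score is the
one-sided Fisher upper tail evaluated at $k-1$: it equals
$P(X \ge k-1)$ for hypergeometric $X$, is never smaller than the plain
Fisher p (single-gene overlaps are pushed to $p = 1$), and is checked
against an exhaustive tail summation over a grid of small tables. Fold
enrichment is $(k/n)/(K/N)$; FDR is Benjamini–Hochberg. The background
defaults to all annotated genes in the supplied map, and is overridable —
enrichment services rarely disclose their exact per-run background, so
results are only comparable within one choice. Term clustering links
terms whose gene memberships agree at Cohen's kappa $\ge 0.5$
(single-linkage components; a simplification of multi-linkage annotation
clustering heuristics) and scores each cluster as $-\log_{10}$ of the
geometric mean of member p-values, computed in log space; 1.3 — geometric
mean p of 0.05 — marks significance.

## What the simulator emulates, and what it does not

`simulate_genotypes()` builds haplotypes as a first-order Markov chain
along each chromosome: marginal allele frequency drawn from `maf_range`,
adjacent-marker allele correlation $e^{-\lambda d}$ with distance $d$ in
bp. Offspring receive one recombined sire gamete (Haldane, 1 cM/Mb) and
one fresh population haplotype, giving paternal half-sib families;
contemporary groups are assigned uniformly and receive normal effects.
This is the simplest model that produces the two features the analysis
depends on: LD that spreads a QTL's signal across its 1-Mb window, and
family structure that inflates within-family genotype sharing (which the
tests verify exceeds between-family sharing).

`simulate_phenotypes()` draws a sparse architecture: `n_qtl` causal SNPs,
of which `n_major_qtl` sit in one window and are rescaled so that window
carries `qtl_variance_fraction` (default 30%, the order of magnitude the
largest windows reach in dense-panel cattle GWAS) of the per-window
variance decomposition — the same decomposition the window posteriors
estimate, so recovery tests compare like with like. Each QTL is shared
across all traits with probability `qtl_sharing`, acting through
per-trait loadings of ±1; otherwise it is private to one trait. Residual
variance is scaled from the realized genetic variance so the target
heritability holds essentially exactly, and the tests confirm recovery
within 0.05 at $n \ge 2000$.

Deliberately not modeled: realistic recombination maps or demography,
genotype error, residual correlations among traits (only *genetic*
sharing is simulated — the method detects co-association of genetic
effects, and adding residual correlation would not change what the SNP
effect profiles measure, but this remains an assumption to keep in mind
when porting conclusions to real data), and selection. Passing tests
therefore show the machinery is correct and the signal flow works at
realistic effect sizes; they do not certify performance on a real cattle
population.

Default scale is deliberately desk-sized (1,000 individuals, 3,000 SNPs
on 10 chromosomes of 10 Mb, 10 traits); the motivating full scale
(1,833 × 54k × 39) is a configuration choice. The bundled
`demo_run_config()` is smaller still (600 × 1,500 × 8, chains of 1,500)
and completes the whole pipeline in about a minute; the recovery test
suite uses 1,000 × 3,000 with chains of 1,200–1,500, sizes at which the
planted window is recovered reliably across seeds.

## Degenerate inputs and numerical conventions

* Monomorphic SNPs are flagged on read, never dropped; they carry no
  variance and the sampler skips them.
* Missing phenotypes exclude an individual from that trait's fit only;
  contemporary groups reduced below 2 members are dropped with a warning.
* Iterations with zero total genetic variance contribute zero shares
  (not NaN) to every window.
* An empty PCIT network exports as a valid empty file with a warning.
* Geometric means of p-values are computed in log space.
* Every stochastic stage takes a seed; the pipeline derives per-trait
  chain seeds from the master seed, and reruns are byte-identical.

## Known limitations

* The Bayes-B locus-variance prior is weakly informative and derived
  from a user-supplied guess of the genetic variance fraction; on data
  with very different architecture, `pi` and `h2_prior` deserve thought.
* PCIT's data-driven tolerance has no significance calibration; on
  profiles built from few traits the surviving edge set can be dense.
* The co-association contrast between QTL-window SNP pairs and background
  pairs is much weaker on *estimated* effect profiles than on true ones,
  for two structural reasons the test suite documents empirically. First,
  a sparse variable-selection estimator concentrates posterior credit on
  the causal marker itself, so a QTL's window-mates carry mostly noise
  rather than a shared profile. Second, under heavily shared architecture
  every trait is a mixture of a few genetic factors, and the estimated
  profile of a *null* SNP inherits its chance dosage correlation with
  those factors — identically in every trait — so background profiles are
  correlated through the same low-dimensional space as the signal. Both
  effects compress the edge-rate ratio between the two classes toward 1,
  and the end-to-end coherence check makes the measured ratio visible
  rather than assuming it.
* The DAVID-style clustering here is single-linkage on kappa, a
  simplification of the multiple-linkage heuristic used by annotation
  services; cluster membership can differ from theirs near the
  threshold.
* Windows are fixed, non-overlapping 1-Mb tiles; a QTL on a window
  boundary splits its signal between neighbors.
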