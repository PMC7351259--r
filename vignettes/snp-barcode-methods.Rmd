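---
title: "Methods: high-order SNP barcode search with a hybrid Taguchi-genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-order SNP barcode search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-SNP association tests miss combinations of loci whose joint genotype
state separates cases from controls even when no single locus does. An *SNP
barcode* of order $m$ fixes one genotype at each of $m$ distinct SNPs
(coded 1 = homozygous major, 2 = heterozygous, 3 = homozygous minor); a
sample *carries* the barcode iff it matches all $m$ genotypes. With $p$
SNPs there are $\binom{p}{m} 3^m$ candidate barcodes — 2925 at
$(p, m) = (26, 2)$ but over $10^9$ at $m = 7$ — so beyond low orders the
space must be searched, not enumerated. This package implements a hybrid
Taguchi-genetic algorithm (HTGA) for that search on case-control genotype
matrices, together with plain-GA, PSO and chaotic-PSO baselines, an
exhaustive oracle for low orders, and the odds-ratio statistics used to
validate hits.

## Fitness and encoding

A chromosome is an order-$m$ barcode: $m$ distinct SNP indices paired with
$m$ genotype codes. Slot $j$ (its SNP *and* its genotype) is the unit all
operators exchange, so the SNP-genotype coupling is never broken. Fitness
is the carrier-count difference

$$F(C) = \#\{\text{controls carrying } C\} - \#\{\text{cases carrying } C\},$$

which is maximized: large positive values flag putatively *protective*
combinations (odds ratio below 1). $F$ is antisymmetric under a
case/control label swap, so a risk-direction search needs no extra
machinery — swap the labels and run the same maximization.

## The search loop

One iteration of `run_htga()` (and `run_ga()`, which simply skips the
Taguchi step) performs, in fixed RNG order:

1. **Selection.** $M$ binary tournaments fill the mating pool: two members
   drawn uniformly (independently, so a member can play itself), the fitter
   wins, the first draw wins ties.
2. **Crossover.** The $M/2$ sequential mating-pool pairs cross with
   probability $p_c$ by uniform crossover — one bit per slot; where the bit
   is 1 the slot (SNP plus genotype) is swapped. A pair that does not cross
   passes into the offspring pool unchanged, so the pool always holds $M$
   chromosomes before refinement and every selected chromosome remains
   exposed to mutation.
3. **Taguchi refinement** (HTGA only). $\mathrm{round}(0.5\,M\,p_c)$
   refinements, each combining two distinct chromosomes drawn from the
   offspring pool; each adds one refined child to the pool.
4. **Mutation.** Every offspring-pool member mutates element-wise with rate
   $p_m$: a mutating SNP element is redrawn uniformly from the SNPs not in
   the barcode (kept when none is free), a mutating genotype element is
   redrawn uniformly from $\{1,2,3\}$.
5. **Replacement.** The next population is the best $M$ of parents plus
   offspring, preferring **distinct** chromosomes (see below); equal
   fitness is broken by a deterministic lexicographic barcode order, so
   results are reproducible and the best-so-far history is non-decreasing.

Termination is a fixed iteration count; there is no early stopping.

### Duplicate removal at replacement

Whether the population may contain duplicate chromosomes is a genuinely
open design point. We resolve it by removing duplicates during
replacement: the survivors are the top-$M$ *distinct* barcodes, with
duplicates only filling a shortfall. The motivation is diversity
preservation under strong elitism: if copies are allowed, the population
collapses within tens of iterations onto clones of one attractor, after
which only single mutants that immediately beat the incumbent can enter —
a regime in which the search reliably stalls on local optima of the
barcode landscape (the broad cluster of common-genotype combinations in
the packaged cohort is exactly such an attractor). With duplicate removal
the population remains a moving front of the 50 best distinct solutions
and the order-2 search recovers the exhaustive optimum from every seed we
test.

## The Taguchi operation

The refinement runs a two-level orthogonal-array experiment on the slots
of two parents. `orthogonal_array(k)` builds the canonical
$L_n(2^{n-1})$ array, $n = 2^k$: column $j$ corresponds to the bit-reversal
of $j$ over $k$ bits, and the entry for (0-based) run $i$ is
$1 + \mathrm{parity}(\mathrm{popcount}(i \wedge \mathrm{mask}_j))$. This
reproduces the standard L4/L8/L16 layouts, with every column balanced and
every column pair containing each level pair $n/4$ times.

For parents of order $m$, the smallest array with $n - 1 \ge m$ columns is
used and slot $j$ is assigned to column $j$. Each run composes a candidate
taking slot $j$ from parent 1 (level 1) or parent 2 (level 2), repairs
duplicate SNPs, and is scored by the signal-to-noise value
$\eta = \mathrm{sign}(y)\,y^2$ of its fitness $y$ (larger-the-better,
sign-preserving square). The effect of slot $j$ at level $l$ is the sum of
$\eta$ over the runs with that level; the predicted-optimal child takes
each slot from the level with the larger effect (ties to parent 1), is
repaired, evaluated, and returned as-is. Each refinement therefore costs
exactly $n + 1$ fitness evaluations.

**Known limitation.** When $m > k$ the $m$ columns of a $2^k$-run array
are necessarily linearly dependent over GF(2), so at least one slot is
aliased with an interaction of others (in L4, column 3 is the XOR of
columns 1 and 2). Because $\eta$ is a nonlinear transform of the response,
the aliased slot's effect estimate can then misrank its levels even for a
perfectly additive fitness: with slot-contribution pairs $(10,0)$,
$(10,0)$, $(0,1)$ at $m = 3$ the best selection has fitness 21 but the
predicted optimum returns 20. The refinement is exact whenever the used
columns form a full factorial (e.g. $m = 2$ on L4), and in Monte-Carlo
checks it recovers the brute-force argmax in roughly 85–100% of random
additive cases at $m \le 4$ depending on the weight distribution. It
should be read as a strong local-improvement heuristic — the role it plays
inside the GA — not as an exact slot optimizer.

## PSO and chaotic PSO baselines

The swarm baselines relax the discrete space to $\mathbb{R}^{2m}$: $m$
SNP coordinates in $[1, p]$ and $m$ genotype coordinates in $[1, 3]$.
Positions decode by rounding, clamping and duplicate repair before every
evaluation. Velocities follow the standard global-best update with
per-coordinate uniform $r_1, r_2$, clamped to half the coordinate range,
and are initialized uniformly within that clamp. PSO decreases the inertia
weight linearly from $w_{\max}$ to $w_{\min}$; CPSO modulates it with a
logistic-map sequence $z_{t+1} = 4 z_t (1 - z_t)$,
$w_t = w_{\min} + (w_{\max} - w_{\min}) z_t$, with $z_0$ drawn in $(0,1)$
avoiding the map's fixed and eventually-fixed points
$\{0, 0.25, 0.5, 0.75, 1\}$. The original study never describes how its
PSO/CPSO encoded barcodes, so this decoding is this package's own choice;
published PSO/CPSO rows are treated as data to recompute statistics from,
not as behavior to match.

## The cohort simulator

`generate_cohort()` rebuilds a case-control genotype matrix from
per-genotype counts: for each group and SNP independently it constructs
the exact multiset of genotype codes implied by the counts (rescaled to
the group size by largest-remainder rounding) and deals it to samples in a
seeded random permutation. Consequently:

* per-SNP per-group genotype counts are **exact**, not expected values, so
  single-SNP odds ratios recompute identically from the cohort;
* SNP columns are mutually independent — the simulator encodes **no
  linkage disequilibrium and no Hardy-Weinberg structure**, because the
  source table provides marginal counts only;
* the same master seed yields a bit-identical matrix; each (SNP, group)
  column uses its own deterministically derived child seed, so column
  streams never interact.

The packaged `snp_table()` carries the published counts for 26 SNPs in
eight growth factor-related genes, both groups already normalized to 5000.
The published normalization example for SNP 1 prints a 4418/569/13 control
split although exact proportional scaling of the printed raw counts
(2008/259/6 of 2273) gives 4417.07/569.73/13.20, i.e. 4417/570/13 under
any standard rounding; the packaged table keeps the published values
verbatim, and `normalize_genotype_counts()` implements largest-remainder
rounding (ties to the lower genotype code) for user-supplied counts.

Because the simulator reproduces marginal structure only, passing tests
demonstrate correct search and statistics machinery on
marginally-faithful, interaction-free data; they say nothing about
performance under LD, population stratification, genotyping error or
missingness, which real cohorts have and this generator deliberately does
not.

## Statistics

For a barcode's 2x2 table (cases/controls x carrier/non-carrier) the
package reports the odds ratio $(TP \times TN)/(FP \times FN)$, the Woolf
log-scale confidence interval
$\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/TP + 1/FP + 1/FN + 1/TN})$,
and the uncorrected Pearson chi-square p-value (1 df). The source tables
never name their interval or test; these two choices reproduce the
published 2-SNP row (OR 0.870, CI 0.79–0.95, p .003) and the single-SNP
rows at printed precision, and are adopted on that evidence. Any zero cell
(or zero margin) yields `NA`, reported as `N/A` — matching the published
treatment of reference rows — rather than a 0.5 continuity correction.
Single-SNP odds ratios compare genotype 2 or 3 carriers against the
genotype-1 reference. No multiple-testing correction is applied across
barcode orders, matching the source analysis; treat the p-values as
descriptive.

## Defaults and tunables

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 50 | population / swarm size $M$ |
| `iterations` | 1000 | fixed iteration budget $T$ |
| `p_c` | 0.3 | per-pair crossover probability |
| `p_m` | 0.05 | per-element mutation probability |
| `w_min`, `w_max` | 0.4, 0.9 | PSO/CPSO inertia-weight range |
| `c1`, `c2` | 2, 2 | cognitive / social learning factors |
| `n_per_group` | 5000 | simulated cases (= controls) |

These defaults are the study conditions of the method being reimplemented
and are what the acceptance checks run under. `exhaustive_search()` guards
its enumeration at $10^6$ candidates (orders up to 3 for 26 SNPs).

## Numerical and tie-break conventions

* Largest-remainder rounding in count normalization; ties to the lower
  genotype code.
* All "best barcode" ties break by the lexicographic order on (sorted SNP
  indices, then their genotype codes).
* Factor-effect ties in the Taguchi step take level 1 (parent 1).
* Duplicate-SNP repair scans slots left to right and redraws an offending
  slot's SNP uniformly from the SNPs currently unused in that barcode,
  keeping its genotype.
* Each search run consumes a single `set.seed(seed)` stream in the fixed
  order documented above; the simulator uses per-(SNP, group) child seeds.
* The hot carrier-counting kernel packs per-(SNP, genotype) indicators
  into bitsets once per cohort, making one evaluation $m$ AND-reductions
  plus popcounts; a pure-R double loop gives identical counts and serves
  as the oracle in the tests.

## Problem sizes exercised by the test suite

The suite validates the searches at the full study conditions on the
packaged cohort (5000 per group, $M = 50$, $T = 1000$): ten seeded HTGA
runs at order 2 against the exhaustive optimum, and ten paired HTGA/GA
runs at order 5 for the method comparison. Unit tests use smaller cohorts
(40–500 per group) and shorter runs, which are ample for the contracts
they check. Published carrier counts (orders 2–7) are used as direct
inputs for the statistics reproductions.

## Limitations

* Identified barcodes are associations on simulated, interaction-free
  data; nothing here supports causal or clinical interpretation.
* The Taguchi refinement is heuristic for $m > \log_2(\text{runs})$ (see
  above).
* The fitness targets the protective direction only; use the label-swap
  identity for risk-direction searches.
* Orders above 3 cannot be verified against the exhaustive oracle for 26
  SNPs; the order-5 comparison checks relative, not absolute, quality.
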