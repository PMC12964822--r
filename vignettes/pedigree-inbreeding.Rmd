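---
title: "Pedigree inbreeding coefficients: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree inbreeding coefficients: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Wright's inbreeding coefficient $F_i$ is the probability that the two
alleles of animal $i$ at a locus are identical by descent.  With the
numerator relationship matrix $\mathbf A$ and its factorization
$\mathbf A = \mathbf L \mathbf D \mathbf L'$ — $\mathbf L$ unit
lower-triangular holding the expected gene fraction each animal inherits
from each ancestor, $\mathbf D$ diagonal with the within-family
(Mendelian-sampling) variances
$d_i = \tfrac12 - \tfrac14 (F_{s_i} + F_{d_i})$ —

$$F_i = A_{ii} - 1 = \sum_{k} L_{ik}^2\, d_k - 1 .$$

**Metafounders.**  Every unknown parent slot is filled by a pseudo-animal
with self-relationship $\gamma$ ($A_{mm} = \gamma$, $F_m = \gamma - 1$,
$d_m = \gamma$), one per birth-year bin of the progeny, so every real
animal has exactly two parents and all algorithms share one uniform
recursion.  Distinct metafounders are unrelated.  With $\gamma = 0$ a
metafounder contributes nothing to any relationship, so the classical
unrelated-founder $F$ is reproduced exactly — this is asserted in the
test suite against an independent plain-R tabular oracle that knows
nothing about metafounders.

**LAP sorting.**  The longest ancestral path is $\mathrm{LAP}_i = 0$ for a
metafounder and $\max(\mathrm{LAP}_{s_i}, \mathrm{LAP}_{d_i}) + 1$
otherwise.  Sorting by ascending LAP puts metafounders first, parents
before progeny, and makes every equal-LAP block a set of animals with no
parent–offspring links among them — the unit of parallel work.  Ties are
broken by original record order (stable sort), which makes the
renumbering, and hence every downstream result, bit-reproducible.

## The algorithms

All six methods are exact and agree to $10^{-10}$ (absolute, double
precision); they differ in cost profile.

* **tabular** builds dense $\mathbf A$ row by row; it is the brute-force
  oracle and refuses pedigrees above `options(pedmi.oracle_cap = 5000)`
  (a ~200 MB dense-matrix memory contract) with an error rather than a
  silent truncation.
* **REC** is the memoized recursive kinship: each pair coefficient is
  computed once and stored in a hash map.
* **ML** (Meuwissen–Luo) traverses each animal's ancestors in descending
  identification order (a max-heap over pending indices), accumulating
  $\sum L^2 d$ on the fly.
* **SI** (Sargolzaei–Iwaisaki) does the same traversal in descending LAP
  order using per-LAP buckets; within a bucket animals are popped in
  ascending index, a deterministic tie-break.
* **I** (indirect) solves $\mathbf A^{-1}\mathbf y = \mathbf x$ per sire:
  backward substitution scatters $z$ from the sire's position to the start
  of a *reduced pedigree* (evaluated sires, their mates, all ancestors —
  equivalently, every animal with progeny, a set closed under parentage),
  then forward substitution runs densely from position 1 to $mip_s$, the
  highest-numbered mate; $F_j = y_{d_j}/2$.  One reduced pedigree is built
  once over all sires; each group redoes its own backward pass over reused
  buffers, and the forward-element counter adds $mip_s$ per group, the
  loop bound of the dense formulation.
* **MI** (modified indirect) replaces the backward pass by direct
  computation of the sire's sparse L-row (the SI bucket traversal), seeds
  a workspace with $y_k = d_k L_{s,k}$ over the sire's ancestors, and
  evaluates $y$ at each mate by a *flagged recursion*:
  $y_i = \tfrac12 (y_{s_i} + y_{d_i}) + d_i z_i$, computed at most once
  per animal.  Every flagged value equals $A_{i,s}$, an identity the test
  suite checks entry-by-entry against the tabular oracle.

### MI design choices

* **Seeding.**  The seed $d_i L_{s,i}$ is written into `y` but seed
  indices are *not* flagged; the recursion later adds the parent average
  on top of the stored seed (`y[i] += (y[s]+y[d])/2`).  This keeps the
  additive form of the recursion valid also for ancestors of the sire
  that are reached through a mate.  Metafounder seeds are final
  ($y_m = \gamma_m L_{s,m}$) and are flagged at seed time.
* **Sparse reset.**  Every written index goes on a touched list; after a
  group, exactly those entries are zeroed, so reset cost tracks the work
  done, not the pedigree size.  Tests assert the all-zero/all-false state
  by full scan and compare shared-workspace runs against fresh-workspace
  runs.
* **Explicit stack.**  The recursion is realized iteratively, so pedigree
  depth is bounded by memory, not the C stack (the contract supports
  depths far beyond any real pedigree).
* **Sire groups.**  Real animals are grouped by (LAP block, sire); a sire
  with progeny in several blocks forms one group per block and its L-row
  is recomputed per block — bounded memory and no cross-block coupling.
  Animals whose sire slot is a metafounder are grouped under that
  metafounder; with $\gamma = 0$ this is a cheap all-zero path.
* **Parallelism.**  Within a block, groups are partitioned into
  contiguous chunks across `workers` (OpenMP when available), each worker
  owning a private workspace.  A group reads only state finalized in
  earlier blocks and writes only the F of its own progeny, so the result
  is bitwise identical for any worker count — asserted for 1, 2 and 8
  workers on a 100,000-animal simulated pedigree.

## Cleaning rules and their defaults

Order is fixed: impute years → fix birth order → assign metafounders →
build.

* **Birth-year imputation**: a missing year becomes the birth year of the
  oldest progeny minus `interval` (default 3 years, a plausible dairy
  generation interval; configurable).  Chains of missing years resolve in
  reverse topological order, realized as a monotone fixpoint so that an
  imputed child year can still lower its parent's estimate.
* **Birth-order repair**: a parent recorded as born in the same year as or
  later than its progeny is set to unknown.  Severed links are counted
  per link, not per animal (the narrower reading of an ambiguous count);
  the operation is idempotent.
* **Metafounder policy**: one metafounder per occupied year bin
  (`bin_width_years = 1`), serving both parental roles; a sex-split
  variant (two per bin) is available as a flag since the original
  assignment protocol does not specify it.  $\gamma$ defaults to 0
  because no value is published for the reference pedigree and $\gamma=0$
  is the unique choice that reproduces classical founder F; per-bin
  $\gamma$ can be supplied when estimates exist.  Progeny without a
  resolvable year fall back to the earliest bin.

## The simulator

`simulate_pedigree()` emulates the factorial half-sib evaluation designs:
a base of 50,000 dams and 100 / 500 / 25,000 sires (plateau half-sib
family sizes 1000 / 200 / 4), generation sizes 100,000 growing by 50,000
per generation to a 300,000 plateau, each dam mated to two distinct
random sires per generation (one progeny per litter, forced census), the
oldest 50% of sires and 30% of dams replaced each generation by the
top-ranked young animals of the previous generation for a trait with
$h^2 = 0.3$, up to 35 generations — 10,000,000 animals beyond the base,
generated in about 10 s.

Deviations, chosen once and documented rather than tuned:

* **Selection criterion.**  The original study delegated replacement to a
  simulator's internal EBV; here the phenotype ($y = \mathrm{TBV} + e$,
  $\sigma^2_e = 1 - h^2$) is the selection proxy.  This changes which
  individual animals are selected, not the census, family-size or
  pedigree-depth structure that the F algorithms are evaluated on.
* **Mendelian-sampling variance.**  TBV draws use the non-inbred variance
  $h^2/2$; the parental-F correction would require running the F
  machinery inside every generation of a 10M-animal simulation for a
  quantity that only perturbs the selection ranking.
* **Litter size 1** is implied by the census arithmetic (50,000 dams × 2
  litters = 100,000 generation-1 animals) and exposed as a config field;
  the sex ratio (0.5, not stated in the design) assigns exactly half of
  each generation male so replacement is always feasible.
* "Oldest" replacement ties break by lowest identifier; recruitment is
  restricted to the immediately previous generation.

**What a green test establishes — and does not.**  The simulated censuses
match the published N column exactly, and all algorithms agree on the
simulated pedigrees.  The simulator does not reproduce genomic features
(markers, QTL, crossovers), realistic variance in family sizes, or
missing-ancestry patterns of field pedigrees; wall-clock superiority of
MI on specific hardware is out of scope, and only the *element-count*
dominance of MI over I (a hardware-independent proxy) is asserted.

## Numerical choices and degenerate inputs

* Double precision throughout; cross-algorithm tolerance $10^{-10}$
  absolute.
* Cycles in parentage are detected during LAP computation (Kahn's
  algorithm) and reported with a cycle member; an animal recorded as its
  own parent is rejected at parse time.
* Parents referenced but never listed are appended as founder records
  ("padding"), counted in an attribute.
* Empty pedigrees flow through every operation (header-only outputs).
* A metafounder filling *both* parent slots of a founder receives the
  whole gene-flow coefficient $L = 1$ (0.5 per slot); with sex-split
  metafounders each receives 0.5.  Both satisfy
  $\sum L^2 d = 1 + F$.

## Known limitations

* The dense tabular and REC oracles are capped (by option) and meant for
  validation, not production use.
* `inbreeding_MI_reference()` (plain R) is quadratic-ish and exists as an
  independent route for the tests.
* No assembly of $\mathbf A^{-1}$, no dominance or genomic relationship
  matrices, no estimation of $\gamma$ from genomic data.
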