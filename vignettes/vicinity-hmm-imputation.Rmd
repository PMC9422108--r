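---
title: "Vicinity-based haplotype-copying HMM imputation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vicinity-based haplotype-copying HMM imputation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicimpute)
```

## The model

`vicimpute` imputes the genotypes of untyped variants from a phased
reference haplotype panel under the Li–Stephens haplotype-copying model.
Each phased query haplotype is treated as a mosaic of the `N` reference
haplotypes: a hidden state sequence walks over the panel rows, staying on
the same row between adjacent variants with probability

$$p^{NR}_j = 1 - (N-1)\,p^{R}_j, \qquad
  p^{R}_j = \frac{1}{N}\left(1 - e^{-4 N_e \Delta R_j / N}\right),$$

where $\Delta R_j$ is the genetic distance in centimorgans between
variants $j-1$ and $j$ and $N_e$ is the effective population size. The
state at variant $j$ emits the panel allele with probability
$1-\varepsilon_{\text{allele}}$ and the opposite allele with probability
$\varepsilon_{\text{allele}}$ (default $10^{-4}$). Both the switch
probability and the emission error are shared across haplotypes, which is
what makes the per-step recursions collapsible to $O(N)$.

Two inference routes are provided per window:

* **Forward–backward**: the per-haplotype allele posterior at an untyped
  target $j$ is obtained by anchoring at the typed variant $k$ immediately
  left of the target and summing $F(k,a)\,B(k,a)$ over the states $a$ whose
  panel haplotype carries each allele at $j$. The pair $(k, k+1)$ are the
  typed variants closest to the target, and the product accounts for every
  typed variant in the window. The two parental copies' normalized allele
  probabilities $p$ and $q$ combine into genotype probabilities
  $P(0)=p_0q_0$, $P(1)=p_0q_1+p_1q_0$, $P(2)=p_1q_1$, a dosage
  $P(1)+2P(2)$, and an argmax hard call.
* **Viterbi**: the maximum-probability mosaic path is computed with the
  same transition structure (summation replaced by maximization) and traced
  back; the target allele is copied from the path's state at the typed
  variant nearest to the target in genetic distance (ties to the left).
  The genotype hard call is the sum of the two path alleles. A confidence
  score is attached by normalizing, over the two alleles, the maximum
  Viterbi variable among allele-consistent states; this is a reporting
  convention — the Viterbi call itself comes from the path, because near
  window edges the prefix-only Viterbi variables are close to uniform and
  would otherwise dominate the call.

### Boundaries

Windows start and end with uniform state distributions: the forward
recursion is initialized as $F(1,a) = \frac1N e_1(g_1,a)$ and the backward
recursion as $B(V,a)=\frac1N$. When a target lies outside the span of its
window's typed variants (a truncated window at a chromosome end), the
missing factor of the anchor product is exactly this uniform boundary: for
a right-truncated window the anchor is the last member, whose backward
variable is the uniform $1/N$; for a left-truncated window the anchor is
the first member, whose forward variable folds the uniform start. No
emission is ever evaluated at the target itself — untyped variants carry
no observation.

## Locality parameters

* `lw` — total window length in cM (the window spans `lw/2` on each side
  of its center). Default 0.3 cM. Accuracy rises steeply up to roughly
  0.3 cM and flattens beyond it on the package's benchmark, mirroring how
  linkage information decays with genetic distance.
* `lc2t` — the maximum target-to-center offset in cM (default 0.05). The
  default window is centered on the target (`offset = 0`); a fixed nonzero
  `offset` reproduces off-center sweeps. Balanced flanks use the LD on
  both sides of the target, which is why accuracy degrades as the offset
  grows.
* `ntag_max` — maximum typed variants per window (default 10000, i.e.
  effectively unbounded below 1 cM). Oversized windows are thinned by
  keeping every `ceiling(n/ntag_max)`-th member. The stated stride rule is
  dimensionally inverted when `n > ntag_max`; this package uses the only
  direction that reduces the count. The two typed variants flanking the
  target are always retained, since they anchor the target posterior —
  without forcing them the anchor itself could be subsampled away. The
  final count can therefore exceed the cap by at most two.
* `n_e` — effective population size (default $10^4$). **Units matter**:
  distances enter the switch probability in centimorgans, exactly as the
  model is parameterized here, so $4 N_e \Delta R / N$ is 100× larger than
  under a Morgan convention. `hmm_params(morgans = TRUE)` divides by 100
  for users who want the classical scaling. The per-cM switch rate is
  approximately $4 N_e / N$, so sensible values of `n_e` scale with the
  panel size: for a production-scale regime (thousands of haplotypes, tag
  spacing of ~0.001 cM) $10^4$ is appropriate, while the 200-haplotype
  synthetic benchmark uses `n_e = 50`, giving mosaic segments of about
  1 cM (see below).
* `profile = "validation"` on `locality_config()` selects the tighter
  tuple `(lw, n_e, lc2t, ntag) = (0.5, 10^3, 0.02, 1000)` for held-out
  validation runs.

## Numerical strategy

Forward, backward and Viterbi values shrink multiplicatively and underflow
doubles after a few thousand steps. Two domains are implemented:

* **Scaled linear** (default, C++): after each DP column, if the column
  maximum leaves the band $[10^{-30}, 10^{30}]$, the column is multiplied
  by an integer power of the scaling factor $e^{0.2}$ and the exponent is
  accumulated; logs are reconstructed exactly on output. Results are
  invariant (to $10^{-9}$ relative) to the band and the factor; the band
  choice only controls how often rescaling triggers.
* **Log domain** (pure R): every value is a logarithm; overflow is
  impossible but each step pays for exp/log calls. The two domains agree
  to $10^{-6}$ relative on all outputs and the log route doubles as an
  independent numerical cross-check in the test suite.

The factorized $O(N)$-per-step recursion used throughout is
$\sum_b \tau_j(b\to a) F(j-1,b) = (p^{NR}_j - p^{R}_j)F(j-1,a) +
p^{R}_j \sum_b F(j-1,b)$ — note the $-p^R$ correction that keeps the self
state from being counted twice; it is verified against the naive
$O(N^2)$ transition-matrix recursion to $10^{-12}$ relative and against
exhaustive path enumeration to $10^{-9}$.

Viterbi ties are broken deterministically: the self-transition wins exact
ties against a recombination, and the lowest state index wins among equal
maxima. With duplicated panel rows the maximizing path is not unique; any
returned path attains the maximal probability.

## Haplotype block clustering

Over short stretches the number of distinct local haplotypes grows much
more slowly than the panel size. `cluster_blocks()` groups haplotypes with
identical allele strings within consecutive 10-variant blocks
(`block_len`), and the Viterbi recursion can run at cluster level: at
block entry each cluster takes the maximum of its members' values, inside
the block clusters act as states, and at block exit each member inherits
its cluster's value. The inheritance step makes this an upper-bound
approximation — a member whose own value was lower leaves the block with
its cluster's maximum, so the clustered path score can only overestimate
the exact one. It is exact whenever cluster membership persists across
block boundaries (e.g. rows duplicated over the whole window), which the
test suite verifies, and the discrepancy on adversarial panels is measured
by direct comparison against the unclustered engine. Because of this bias
the package defaults to exact (unclustered) inference; clustering is an
opt-in speed optimization (`hmm_params(cluster = TRUE)`).

## The synthetic benchmark generator

The generator mirrors the inference model exactly, which makes
parameter-matched recovery a clean end-to-end oracle:

* panel columns are independent Bernoulli draws with per-site frequencies
  from `freq_range` (default 0.02–0.5, a spectrum dominated by common
  variants); an optional founder mode (`n_founders`) builds the panel from
  few recombined founder haplotypes to induce panel LD;
* each query haplotype starts on a uniform panel row and, between
  consecutive sites, switches to a uniformly chosen *different* row with
  probability $(N-1)p^R(\Delta R)$ — the model's own transition kernel —
  and the copied allele flips with probability `eps_sim` (default
  $10^{-4}$);
* every `typed_every`-th site (default 10) is observed, the rest are
  imputation targets; the full haplotypes, genotypes and mosaic paths are
  returned as truth.

The standard benchmark is 200 haplotypes × 2000 sites at 1 kb spacing and
1 cM/Mb (a 2 Mb / 2 cM region) with `n_e = 50`, chosen so that the per-cM
switch rate $4 n_e/N$ is 1 and mosaic segments average ~1 cM — a few
recombinations per simulated haplotype, the regime in which window length
trades off against accuracy. On this benchmark, forward–backward hard
calls on common variants (panel MAF > 0.05) exceed 0.95 concordance when
the window spans the region, and mean accuracy is non-decreasing across
windows of 0.1, 0.3 and 1 cM.

What the generator deliberately does **not** emulate: coalescent
genealogies (panel rows are exchangeable, with no shared ancestry unless
the founder knob is used), population structure and panel–query ancestry
mismatch, genotyping and phasing errors with realistic error modes,
multi-allelic sites and indels, and variable recombination maps (the map
is piecewise-constant). Passing the recovery tests therefore demonstrates
correctness of the inference machinery under the model's own assumptions,
not real-data accuracy; on real panels the model is misspecified and
accuracy is an empirical question.

## Evaluation metrics

`genotype_concordance()` is the fraction of individuals whose imputed hard
call equals the known genotype; `non_ref_concordance()` restricts the
count to individuals whose known genotype is non-reference and is reported
as missing when no such individual exists. MAF strata are computed from
the reference panel (not the truth set) with boundaries 0.005 / 0.01 /
0.05; boundary values join the higher-MAF stratum. Precision–recall
curves pool all calls (rather than averaging per-variant curves), score
each call by its called genotype's probability, treat non-reference hard
calls as positive predictions, and sweep a descending threshold.

## Degenerate inputs and edge rules

* Both allele scores zero at a target → the posterior falls back to
  (0.5, 0.5) with a warning.
* A target with no typed variant inside its window is an "isolated
  target": it is skipped, logged in the per-target table, and never aborts
  the run.
* Monomorphic target columns put all mass on the panel's only allele.
* Genotype hard-call ties resolve to the lowest genotype index; FB
  per-haplotype hard alleles use a 0.5 threshold with ties to the
  reference allele.
* Positions outside the genetic map are clamped to the terminal marker's
  cumulative cM, so flanking regions carry zero recombination probability
  — a conservative choice, since the alternative (extrapolation) can
  produce negative or runaway distances.

## Problem sizes used by the tests

The enumeration oracle covers 200 random instances with up to 6 haplotypes
and 8 typed variants (every one of the up to $6^8$ paths evaluated);
factorized-vs-naive equivalence covers 100 instances up to 50×50; the
generative-recovery run uses the standard 200×2000 benchmark with 10
diploid queries (20 haplotypes) at three window lengths plus a full-region
window. These sizes were chosen to exercise every code path at full
coverage while keeping a complete test run to a couple of minutes on one
core.

## Known limitations

* Rare variants (MAF < 1%) are imputed poorly at small windows — rare
  haplotypes need longer stretches to be resolved. Extending `lw` helps at
  linear cost in time and memory.
* Windows are recomputed from scratch per target; neighboring windows
  overlap heavily and the DP arrays could in principle be shared, but that
  reuse is deliberately out of scope here.
* The engine is strictly per-haplotype on pre-phased input; unphased
  genotype-likelihood input and diploid joint inference are not supported.
* No parameter fitting (e.g. Baum–Welch) is included; `n_e` and
  `eps_allele` are user-set.
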