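---
title: "Detecting environmentally driven edges in microbial association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting environmentally driven edges in microbial association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Co-occurrence networks inferred from microbial abundance time series are not
ecological interaction networks. An edge between two taxa can reflect a true
ecological interaction, a shared (or opposite) response to an environmental
factor, or chance. Edges of the second kind — *environmentally driven* or
indirect edges — are a major interpretation hazard: two plankton taxa that
both bloom in summer will co-occur strongly without ever interacting.

This package detects such edges inside *environmental triplets*: a pair of
taxa $v, w$ and an environmental factor $f$ such that all three pairwise
edges $v\!-\!w$, $v\!-\!f$, $w\!-\!f$ are present in the network. Four
classifiers operate on each triplet, and a combination rule turns per-triplet
flags into per-edge removal decisions.

## The four classifiers

**Sign pattern (SP).** With association signs $s_{vw}, s_{vf}, s_{wf} \in
\{+,-\}$, the microbial edge is flagged when the product of the three signs
is positive (an even number of negative signs). If both taxa respond the
same way (or both oppositely) to the factor, their association is consistent
with pure environmental driving. Four of the eight sign combinations are
flagged.

**Overlap (OL).** Association windows are half-open sample intervals
$[b, b+d)$. The overlap of the microbial window with both taxon–factor
windows is

$$O = 100\,\frac{\min(e_{vw}, e_{vf}, e_{wf}) - \max(b_{vw}, b_{vf}, b_{wf})}
{e_{vw}-b_{vw}},$$

with $e = b + d$; $O$ can be negative (disjoint windows) and is not clipped.
A triplet is flagged when $O$ strictly exceeds the threshold (default 60%):
an environmentally driven association should be aligned in time with both
taxon–factor associations.

**Interaction information (II).** Series are discretized (below), and

$$\mathrm{II} = \mathrm{CMI}(v;w \mid f) - \mathrm{MI}(v;w),$$

with the plug-in entropy estimators in nats,
$\mathrm{MI} = S(v) + S(w) - S(v,w)$ and
$\mathrm{CMI} = S(v,f) + S(w,f) - S(v,w,f) - S(f)$. Negative II means the
dependence between the taxa largely disappears once the factor is known —
an indirect dependency somewhere in the triplet. Significance is a
parameter-free permutation test: because MI does not involve $f$, the
significance of II equals that of the CMI, so the factor series is permuted
(default 1000 times), the CMI recomputed, and
$p = (c+1)/(\text{iterations}+1)$ where $c$ counts permutations whose CMI
is at least as small as the observed one (ties count). The II flag requires
*both* II < 0 and $p \le \alpha$ (default 0.05); negativity alone can be
selected with `ii_ignore_significance`. No multiple-testing correction is
applied across triplets — the $\alpha$ is per-triplet, and the intersection
combination already makes removal conservative.

**Data processing inequality (DPI).** If $v$ and $w$ interact only through
$f$, then $\mathrm{MI}(v;w) \le \min\{\mathrm{MI}(v;f),
\mathrm{MI}(w;f)\}$. The triplet is flagged when the microbial edge carries
the smallest MI; ties count as smallest, matching the inequality.

## Combination semantics

Under the default **intersection** rule, a triplet flags its microbial edge
only when *all* selected methods flag it within that same triplet, and the
edge is removed when at least one of its triplets flags it. Edges outside
any triplet, and all taxon–factor edges, are always kept. The prose
"all methods must agree, and at least one triplet must indicate the edge"
also admits a weaker reading in which each method may be satisfied by a
*different* triplet; that semantics is available via
`agree_across_triplets = TRUE`. The per-triplet reading is the default
because the methods are defined on a triplet, so "agreement" most naturally
means agreement about the same evidence. `union` and `single` combinations
are provided for benchmarking; by construction
intersection-removed ⊆ single-method-removed ⊆ union-removed.

## Equal-width discretization

A series of length $n$ is binned into $|B| = \lfloor\sqrt{n}\rfloor$
equal-width ranges with label
$v_d = \lceil (v - v_{\min})\,|B| / \text{denom} \rceil$, where
$\text{denom} = v_{\max}$ for non-negative series and
$v_{\max} - v_{\min}$ otherwise. Two deliberate quirks of the method's
reference formulation are preserved:

* for non-negative series the denominator is $v_{\max}$, not the range, so
  bins are only genuinely equal-width when $v_{\min} = 0$; the arguably
  intended range denominator is available via `range_denominator = TRUE`;
* the minimum always maps to label 0, so up to $|B|+1$ labels occur. Labels
  only enter the estimators through equality, so no remapping is done —
  remapping would silently change MI values.

Tiny negative MI/CMI values from floating point are clamped to zero
(tolerance 1e-12); the plug-in estimates are analytically non-negative.
Missing values are not supported inside the estimators: vectors must be
complete. Constant series cannot be discretized and are rejected.

## The community simulator

`simulate_community()` provides ground truth for benchmarking. It integrates
a generalized Lotka–Volterra system

$$\frac{dy}{dt} = y\,\bigl(b(t) + A\,y\bigr)$$

with `deSolve::lsoda` (the standard stiff/non-stiff switching integrator;
`rtol = atol = 1e-6`). Defaults, which are also the benchmark conditions:

* **50 taxa**, sampled at $t = 0, 0.5, \dots, 49.5$ months — 100 samples;
* **topology**: a Klemm–Eguíluz growth process (modular and scale-free:
  new nodes attach to all active nodes, attachments rewire with probability
  0.1, actives deactivate with probability inversely proportional to
  degree; seed clique 5), subsampled to interaction probability 0.01 —
  about 12 interacting pairs among the 1225 possible;
* **coefficients**: 30% of off-diagonal taxon–taxon coefficients positive,
  magnitudes $U(0.2, 0.8)$ (mirroring the environmental-coupling ranges;
  the reference model fixes signs and sparsity but not magnitudes), all
  self-interactions $-0.5$;
* **external factor**: $\varepsilon(t) = \mathrm{round}(\sin(-2\pi t/12),
  3)$ — a seasonal sinusoid — acting through per-taxon Gaussian niche
  responses $g = g_{\max}^2 \exp(-(\epsilon_{opt}-\varepsilon)^2 /
  2\sigma^2)$ with $g_{\max}, \sigma \sim U(0.3, 1)$ and $\epsilon_{opt}
  \sim U(-1, 1)$. The squared amplitude $g_{\max}^2$ follows the method's
  reference formulation; it may well be intended as plain $g_{\max}$, so
  `gmax_squared = FALSE` switches to the unsquared amplitude;
* **internal factor**: an extra gLV state (initial value 0.001, niche
  constants $g_{\max} = 0.8$, $\epsilon_{opt} = 0.5$, $\sigma = 0.5$) whose
  column couples it to the taxa — half positively, half negatively,
  magnitudes $U(0.2,0.8)$ — and whose row is zero off-diagonal (no feedback
  from the community). Its self-limitation is set to the common $-0.5$
  diagonal, a package choice where the reference model is silent;
* **initial abundances**: a random broken-stick partition of the unit
  interval (gaps between sorted uniforms) — uneven, strictly positive,
  summing to 1.

**Stability guard.** A reciprocal mutualistic pair with coefficient product
above the self-limitation bound $(-0.5)^2$ has no positive equilibrium:
abundances diverge in finite time and the integrator stalls. With
$U(0.2,0.8)$ magnitudes roughly one such pair is expected per matrix, so
the generator rescales any $(+,+)$ reciprocal pair to keep its product at
$0.9 \times 0.25$, preserving signs and the coefficient ratio. This is the
one place the magnitude distribution is touched, and it is what makes the
default configuration integrable across seeds.

Negative states are clipped to zero at output. Ground truth is the set of
taxon pairs with a nonzero off-diagonal coefficient in either direction.
`add_poisson_noise()` replaces each cell by a Poisson draw with
$\lambda = \text{scale} \times \text{value}$, divided back by the scale.
The reference procedure corresponds to `scale = 1`; note that at gLV
abundance magnitudes (order 1) this is very aggressive noise — for
count-like output choose a scale near the sequencing depth.

## The stand-in association constructor

Association networks of this kind are typically inferred with eLSA. That
tool is not re-implemented here; `construct_network()` is a deliberately
simplified
zero-delay local-similarity scorer: series are standardized by median and
unscaled MAD, and for each taxon–taxon and taxon–factor pair the score is
$\max_{[i,j]} \bigl|\sum_t x_t y_t\bigr| / n$ over contiguous windows, with
ties broken by earliest start, then longest duration, then positive sign.
The maximizing window supplies the edge's association start and duration
(which is what the overlap method consumes). p-values come from a pure
permutation test, $p = (\#\{s_{perm} \ge s_{obs}\}+1)/(P+1)$ with $P = 2000$
by default, and Bonferroni q-values from `stats::p.adjust`.

Two consequences are worth stating plainly:

* benchmark edge counts differ from those of eLSA-based pipelines — the
  stand-in is not eLSA, and no claim of equivalence is made;
* a pure permutation p-value cannot go below $1/(P+1) = 1/2001$, so a
  Bonferroni-corrected threshold of 0.001 over ~1300 tests is unattainable
  by construction (eLSA's theoretical p-values go far lower). The
  constructor keeps the strict defaults for imported data, but
  `run_benchmark()` defaults to `q_threshold = 1`, filtering on the raw
  permutation p alone.

For pairs that can no longer reach the significance threshold the
permutation count is terminated early; their exact p-value is never used
(they are dropped, and each kept pair's Bonferroni q depends only on its
own p). Kept pairs always complete the full permutation run. Within one
network construction the permutation streams are consumed sequentially
from the caller's seed, so results are exactly reproducible.

## Benchmark and evaluation conventions

In all confusion accounting the "positive" class is the *false
association*: a network edge absent from the ground-truth interaction set.
TP = false association removed, FP = true interaction removed, and
TPR/TNR/FPR/PPV/ACC follow from $P = TP+FN$, $N = TN+FP$. PPV with nothing
removed is reported as `NA` rather than 0 or 1. Benchmark summaries report
per-method medians and standard deviations across replicates; medians are
computed per metric independently, so summary rows need not be consistent
with each other the way a single replicate is.

The random-removal null model is multivariate hypergeometric: removing $n$
of $N = N_{neg} + N_{pos}$ edges uniformly at random,
$P(k_{neg}, k_{pos}) = \binom{N_{neg}}{k_{neg}} \binom{N_{pos}}{k_{pos}} /
\binom{N}{n}$, evaluated in log space; `tail_probability()` sums the exact
upper tail of the negative-removal count.

**Problem sizes.** The package's own validation uses 50 replicates of the
default 50-taxon, 100-sample configuration for the benchmark (a few minutes
on one core), 2000 construction permutations, and 1000 II permutations per
triplet. The acceptance script reproduces the same sizes.

## What the synthetic benchmark does and does not show

The generator emulates a strongly seasonal community: one shared external
driver, one internal factor, sparse true interactions. It does not emulate
compositionality (closure to relative abundance), sequencing-depth
variation beyond simple Poisson noise, zero inflation, taxonomic
misassignment, or time-delayed interactions. Passing benchmarks therefore
demonstrate that the classifiers remove environmentally induced edges under
known, idealized driving — not that they are calibrated on real survey
data. On the real-data side, the methods require that the relevant factors
were actually measured; unmeasured drivers leave their indirect edges
undetected.

## Numerical and design notes

* Edge windows are 0-based, half-open `[start, start + duration)`; the end
  is `start + duration`, which makes the overlap formula unambiguous.
* A score of exactly 0 carries no sign and is rejected at load time; the
  constructor likewise drops zero-score pairs.
* The Jaccard index uses presence `> 0` (configurable threshold) and
  defines 0/0 as 0 — all-absent taxa are filtered upstream in any
  reasonable pipeline.
* Node kinds come from an explicit two-column node table rather than an
  id-prefix heuristic: mixed taxon/factor networks make name-based
  inference fragile.
* Permutations resample the factor vector uniformly without replacement;
  no block or seasonal permutation is offered. For strongly autocorrelated
  series a uniform permutation null is anticonservative — a known
  limitation of this family of tests.
* Klemm–Eguíluz free parameters (clique size 5, rewiring 0.1) are package
  choices; the benchmark conditions name the algorithm but fix no
  parameters for it.

## Known limitations

Triplets capture only first-order indirectness; taxon-mediated triplets
and higher-order (quadruplet+) DPI are out of scope. The plug-in MI
estimator with $\lfloor\sqrt{n}\rfloor$ bins is biased upward in the
3-dimensional CMI at these sample sizes; the permutation test calibrates
the decision, but reported II magnitudes should not be over-interpreted.
Alternative MI estimators (k-NN, shrinkage) and part mutual information
are deliberately not implemented.
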