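---
title: "Selecting multi-drug combinations as multiplicity-constrained hitting sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting multi-drug combinations as multiplicity-constrained hitting sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multihit)
```

## The model

A drug-response screen reports, for each compound and each cell line, a
response value (for NCI60-style data, a log10 GI50). After thresholding, the
screen becomes a bipartite graph: compounds are *drug vertices*, cell lines
are *classes*, and a class's neighborhood $N(u)$ is the set of compounds that
respond strongly against it. A combination therapy is a drug set $H$; it
*hits* a class once for every member of $N(u)$ it contains.

The model generalizes the plain hitting-set question in two directions. Each
class $u$ carries a minimum hit count $\alpha(u)$ and a maximum $\beta(u)$
(possibly unbounded), and the combination size is capped at $k$:

$$\exists\, H \subseteq V,\ |H| \le k:\quad \alpha(u) \le |H \cap N(u)| \le \beta(u)\ \ \forall u.$$

$\alpha$ expresses redundancy ("hit every melanoma line at least twice"),
$\beta$ expresses selectivity ("never hit a non-target line": $\beta = 0$).
The maximum class degree $d = \max_u |N(u)|$ is treated as a structural
constant of the dataset; it is always recomputed from the member sets and
never trusted from input. The problem is NP-complete already for $d = 2$,
but it is fixed-parameter tractable in $(k, \alpha_{\max})$ for constant
$d$, which is what makes exact solving practical: after polynomial-time
data reduction the residual instance has size bounded by a function of the
parameters alone, $O(\alpha\, d\, k^d)$.

Two objectives are supported, mirroring how such screens are used. The
primary objective minimizes $|H|$ subject to the bounds and the budget. The
secondary objective fixes $|H| = k$ exactly and maximizes the total number
of hits on classes *without* a maximum — the natural "hit the targets as
hard as possible" refinement once the minimum achievable size is known.
Hits are counted with multiplicity (a class hit twice contributes two), as
a direct reading of "number of hits".

## Preprocessing a screen

`resolve_duplicates()` collapses replicate records per (compound, line) pair
by keeping the measurement from the highest assay concentration. Ties in
concentration keep the last-read record and warn; this is an arbitrary but
deterministic choice, and when tied records carry equal values (the common
case, re-exported data) the downstream binary matrix is unaffected.

`zscore_rows()` standardizes each compound's row independently over its
non-missing entries. Two decisions here were genuinely open:

* **Axis.** Scores are computed per compound, not globally: the question
  asked of each compound is "against which lines is *this* compound
  unusually effective relative to its own profile?". A global
  transformation would conflate potency differences between compounds with
  selectivity within a compound. The axis is isolated in this one function,
  so the alternative is a one-line change.
* **SD flavor.** The population SD (divide by $n$) is used. With ~60
  columns the numerical difference from the sample SD is negligible, but
  the population form has the convenient exact property that a single
  outlier among $n$ otherwise-equal values scores $z = \sqrt{n-1}$, so a
  2-SD threshold is reachable exactly when $n \ge t^2 + 1$ — the worked
  case below. The sample-SD variant would shift this boundary by one.

Rows with fewer than two observations or zero variance carry no usable
signal; they become all-missing and are reported, rather than silently
producing $\pm\infty$ or `NaN`.

`binarize()` thresholds at $t$ SD units, $t = 2$ by default and strict
("more than $t$ standard deviations"); missing values always threshold to
0 — an unmeasured pair is never treated as a hit. Raising $t$ can only
remove edges (monotonicity), which the tests assert.

The worked case: a row with one unit response and nine zeros has mean 0.1
and population SD 0.3, so the outlier scores $z = 0.9 / 0.3 = 3.0$ and
becomes an edge at $t = 2$:

```{r zscore}
m <- response_matrix(matrix(c(1, rep(0, 9)), 1, 10,
  dimnames = list("NSC1", paste0("L", 1:10))
))
zscore_rows(m)[1, 1:3]
```

Input values are assumed to be on a logarithmic scale already (NCI60 GI50
exports are log10 molar); `log10_transform()` is available (and exposed as
`--log10` in the CLI) for raw positive values, mapping non-positive values
to missing.

`build_instance()` then takes one class per cell line with the thresholded
column as members, and `alpha`/`beta` from a `constraint_spec()` — a
mapping of lines to named groups plus per-group bounds. The exact bounds of
any targeting experiment are user inputs, not package constants. Classes
with $\beta = 0$ and empty classes are kept at this stage: removal is the
kernelizer's job, and a class demanding more hits than it has members is a
data problem that `validate_instance()` reports by name.

## Data reduction

`kernelize()` applies five reductions to a global fixpoint. Soundness for
the variants with finite $\beta$ required care; where a rule is only proven
for unbounded classes it is guarded accordingly.

1. **Basic cleanup.** Zero-degree drugs; empty classes with
   $\alpha = 0$ (empty with $\alpha > 0$ certifies a No-instance); drugs
   adjacent only to $\alpha = 0$, unbounded classes. Classes with
   $\beta = 0$ forbid every member: those drugs are deleted everywhere,
   then the class itself.
2. **Forcing.** A class with $\alpha(u) = |N(u)| \ge 1$ needs all its
   members; each is moved into the solution, decrementing $k$, the
   $\alpha$ of every incident class (floor 0) and every finite $\beta$. A
   finite $\beta$ hitting $-1$, or $k < 0$, certifies No. When forcing
   leaves a class with $\alpha = \beta = 0$ it is *saturated*: its
   remaining members may never be selected and are purged like a
   $\beta = 0$ class.
3. **Satisfied classes.** $\alpha = 0$ with unbounded $\beta$ constrains
   nothing. The unbounded guard matters: an $\alpha = 0$, $\beta = 1$
   class still constrains.
4. **Domination.** If $N(v) \subseteq N(u)$ and $\alpha(v) \ge \alpha(u)$,
   any solution hits $u$ at least $\alpha(v) \ge \alpha(u)$ times, so $u$
   is redundant — provided $\beta(u)$ is unbounded, since deletion may
   only discard a lower bound. Identical twins collapse onto the
   lexicographically smallest id.
5. **High-occurrence cores.** If many classes with the same requirement
   $a$ share a common core $S$ of $j$ drugs, solutions are eventually
   forced to take their hits inside $S$. Concretely, with thresholds
   $B(d) = 1$, $T(j) = k \cdot B(j+1)$, $B(j) = T(j) + 1$: each solution
   vertex outside $S$ can serve at most $B(j+1)$ classes of the family
   (inductively, from the level above), so once the family exceeds
   $T(j) = k \cdot B(j+1)$, some class must be hit entirely within $S$ —
   and then every class containing $S$ is hit $\ge a$ times provided
   $a \le |S|$; if $a > |S| = j$ the family is unsatisfiable and the
   instance is a No-instance. The family is replaced by the single class
   $(S, a)$. Families are grouped per $\alpha$-value before counting:
   replacing a mixed family with its maximum $\alpha$ is not obviously
   sound, and the per-value grouping costs only a constant factor
   $\alpha_{\max}$ in the kernel bound. Candidate cores are enumerated as
   $j$-subsets of actual neighborhoods (at most $m \cdot 2^d$ of them) —
   for any other subset the family is empty. A matching-based detection of
   maximal flower collections exists as an optimization but is not needed
   for correctness, and is not implemented.

Rules 1–3 run to a fixpoint before rule 5, which runs level by level from
$j = d-1$ down to 1, re-running rules 1–3 after each level. The
zero-budget guard ($k = 0$ with outstanding requirements certifies No) is
part of the consistency scan; besides being required for correctness it
also makes the threshold $T(j) = 0$ degenerate case unreachable.

For Yes-instances this yields at most $\alpha_{\max} \cdot k \cdot B(1)$
classes with $B(1) = O(k^{d-1})$, i.e. the $O(\alpha\, d\, k^d)$ total-size
guarantee; the test suite checks the concrete bound on every random
Yes-instance rather than the asymptotic claim.

Every change is logged as a replayable trace event (`forced_drug`,
`deleted_drug` with its reason, class deletions, `class_replacement` with
fresh namespaced `K#` ids). `lift_solution()` re-adds the forced drugs to
a kernel solution and re-verifies against the original instance, so a
kernel optimum plus the forced set is an original optimum.

```{r flower}
flower <- hs_instance(c("v0", "w1", "w2", "w3"), list(
  list(id = "p1", members = c("v0", "w1"), alpha = 1),
  list(id = "p2", members = c("v0", "w2"), alpha = 1),
  list(id = "p3", members = c("v0", "w3"), alpha = 1)
), k = 1)
kernelize(flower)
```

## Exact search

`solve_min_size()` is a complete branch-and-bound: branch on an unsatisfied
class of maximum deficit, trying each still-selectable member (at most $d$
branches per node, depth at most $k$ — the classic $d^k$ search tree), with
three prunes: the budget; saturation of any finite $\beta$; and a lower
bound given by summing deficits over a greedily packed set of
member-disjoint unsatisfied classes. By default the instance is kernelized
first. Among optima the lexicographically smallest drug-id set is returned,
via a second include-first scan at the optimal size — determinism the tests
rely on, since the model itself fixes no ordering.

`solve_max_hits()` searches selections of size exactly $k$ with the same
deficit/saturation pruning plus an optimistic score bound (the $k - |H|$
largest remaining per-drug scores). It deliberately runs on the *full*
instance: the reductions are entitled to delete $\alpha = 0$ unbounded
classes and the drugs adjacent only to them, but those are precisely the
classes whose hits this objective counts, so solving the kernel could
change the objective value. `use_kernel` is therefore a documented no-op
for this objective.

`export_ilp()` writes the equivalent integer program in CPLEX LP format —
one binary per drug, a $\ge$ row per requirement, a $\le$ row per finite
$\beta$, and the budget (or exact-size) row — with a sidecar TSV mapping
the sanitized variable names back to drug ids. The internal search is the
reference implementation; the export exists for interoperability with
external solvers, and the tests verify the exported text independently (an
in-package LP parser plus exhaustive enumeration, and GLPK's `glpsol` when
present on the PATH).

A `node_limit` can cap the search; hitting it yields an explicit
`"undecided"` verdict, never a silent wrong answer. Infeasibility, by
contrast, is an ordinary answer (exit code 1 in the CLI), not an error.

## Synthetic data: what it emulates, and what it does not

`random_instance()` draws class neighborhoods uniformly (degree $1..d$),
requirements from `alpha_range` clipped to the degree, and `beta` per mode
(`all_unbounded`, `mixed` with finite caps on half the classes, or
`targeting` with $\beta = 0$ off-target classes). `planted_instance()`
first plants a solution set and gives every class at least $\alpha$ planted
members, guaranteeing a Yes-instance at the planted budget.
`screen_matrix()` emits long-format records — including lower-concentration
decoy replicates, so the duplicate-resolution rule is load-bearing — with a
known intended post-threshold truth.

The screen generator's defaults encode the regime in which a 2-SD
threshold demonstrably works: 6 compounds by 15 lines, each compound with
exactly one responsive line shifted by 5 SD over unit noise, no
missingness. This is a deliberate, analyzed choice rather than a neutral
one. Row-wise z-scoring is self-normalizing: with $n$ columns the largest
attainable $|z|$ is $\sqrt{n-1}$, a strong outlier inflates the row SD and
thereby shields moderate noise from the threshold, and the miss/false-call
tradeoff is optimized near $n \approx 15$ (misses dominate below, noise
exceedances above — at $n = 60$ a pure-noise row exceeds a 2-SD row
threshold far too often for exact recovery). Two co-responsive lines
among 10–15 depress each other's scores to the threshold boundary, which
is why the recovery demonstration designates one hit per compound; the
per-cell Bernoulli mode (`hit_probability`) exists for distributional
tests. What the generator does *not* emulate: dose–response structure,
correlated compound families, panel-structured cell-line similarity, and
heavy-tailed assay noise. Passing the recovery tests therefore shows the
pipeline is implemented correctly, not that 2-SD thresholding recovers
truth on real screens, where the miss/false-call analysis above applies
with real effect sizes.

All generators seed R's Mersenne-Twister explicitly per call and restore
the caller's RNG state, so fixtures are byte-reproducible and generation
never perturbs user code.

## Numerical and degenerate-input choices

* Unbounded $\beta$ is `Inf` in memory and the JSON literal `null` on
  disk; no arithmetic is ever performed on it beyond comparison.
* Identifiers are opaque strings; every output (solutions, serialized
  instances, LP variables) is sorted lexicographically, so equal inputs
  give byte-identical outputs.
* Empty instances are legal everywhere: the empty set is their optimum.
* `validate_instance()` returns violations instead of raising, so a
  screening pipeline can report all data problems at once; solvers answer
  No on such instances regardless.
* The brute-force oracles refuse instances above 22 drugs — they exist to
  verify, not to solve.

## Problem sizes in the test suite

The randomized suites use 500 instances with up to 12 drugs, 15 classes,
$d \le 4$, $\alpha \le 3$, $k \le 4$, mixing unbounded and finite
$\beta$ — small enough for the exhaustive oracle to stay trustworthy and
fast, large enough to exercise every rule (the flower rule additionally
gets dedicated fixtures, since its thresholds rarely trip at these sizes
with $k \ge 2$). Planted recovery runs 100 draws; pipeline recovery runs
the committed screen configuration. `scripts/acceptance.R` re-derives the
same quantities from scratch under any seed.

## Known limitations

* Rules 4–5 skip classes with finite $\beta$; the extension of the
  kernel bound to the bounded-above variant is stated in the literature
  without a modified proof, and the conservative guard keeps every
  implemented transformation individually answer-preserving. Kernels of
  heavily $\beta$-constrained instances are therefore correct but not
  size-bounded by the formula above.
* The maximum-hits search does not use the kernel (see above), so very
  large instances benefit from reduction only under the min-size
  objective.
* Weighted drugs, drug–drug incompatibilities, and approximation modes
  are out of scope.
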