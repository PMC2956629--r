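# multihit

Exact selection of multi-drug combinations from cell-line response screens,
modeled as a hitting-set problem with per-line hit multiplicities.

## The problem

A screen such as the NCI60 panel reports a response value (log10 GI50) for
each compound against each cell line. After z-scoring each compound's
profile and thresholding at *t* standard deviations, the screen becomes a
bipartite graph: a compound is connected to every cell line it hits
strongly. Choosing a combination therapy is then a hitting-set question,
generalized so that each cell line *u* carries a minimum hit count α(u)
("hit every target line at least twice") and a maximum β(u) ("never hit a
non-target line": β = 0), with the combination size capped at *k*:

> find H ⊆ V, |H| ≤ k, with α(u) ≤ |H ∩ N(u)| ≤ β(u) for every class u,

where N(u) ⊆ V is line *u*'s set of responsive compounds, |N(u)| ≤ d. The
problem is NP-complete but fixed-parameter tractable in (k, α_max) for
constant d: polynomial-time reduction rules shrink any instance to an
equivalent kernel of size O(α·d·k^d), which an exact solver then finishes.

The package is aimed at computational biologists and methods researchers
working with drug-response panels who want *provably optimal* combinations
under targeting constraints, rather than greedy or annealed estimates. It
provides:

* the screen pipeline — duplicate resolution by highest assay
  concentration, row-wise population-SD z-scoring, strict t-SD
  thresholding (`resolve_duplicates()`, `zscore_rows()`, `binarize()`,
  `build_instance()`),
* the five-rule kernelization with a replayable trace and solution lifting
  (`kernelize()`, `lift_solution()`),
* complete branch-and-bound solvers for the two objectives — minimum
  combination size, and fixed size maximizing hits on unconstrained lines
  (`solve_min_size()`, `solve_max_hits()`),
* a CPLEX LP format exporter for external MIP solvers (`export_ilp()`),
* brute-force oracles and seeded synthetic generators used throughout the
  tests (`brute_min_size()`, `random_instance()`, `screen_matrix()`, ...),
* a command-line front end (`exec/multihit`; subcommands `threshold`,
  `kernelize`, `solve`, `generate`, `oracle`).

## Worked example

Generate a small synthetic screen (6 compounds × 15 lines, each compound
with one strongly responsive line), threshold it at 2 SD, require every
responding line to be hit at least once, and solve:

```r
library(multihit)

sc <- screen_matrix(generator_config(seed = 1))
b  <- binarize(zscore_rows(resolve_duplicates(sc$records)), t = 2)
spec <- constraint_spec(
  group_of = setNames(ifelse(colSums(b) > 0, "target", "spare"), colnames(b)),
  bounds   = list(target = c(1, Inf), spare = c(0, Inf))
)
inst <- build_instance(b, spec, k = 6)
inst
#> (alpha,beta,d)-hitting-set instance: 6 drugs, 15 classes, d = 1, k = 6
#>   alpha range [0, 1]; 0 class(es) with finite beta

sol <- solve_min_size(inst)
sol
#> hitting-set solution: {NSC001, NSC002, NSC003, NSC004, NSC005, NSC006} size 6, feasible, secondary score 6
sol$hits[sol$hits > 0]
#> LINE01 LINE02 LINE04 LINE07 LINE09 LINE13
#>      1      1      1      1      1      1
```

Each compound here hits a different line (d = 1), so the optimum needs all
six drugs — the solver proves that rather than assumes it. The reduction
machinery is more visible on structured instances, e.g. the three-petal
flower whose shared core is forced at budget 1:

```r
flower <- hs_instance(c("v0", "w1", "w2", "w3"), list(
  list(id = "p1", members = c("v0", "w1"), alpha = 1),
  list(id = "p2", members = c("v0", "w2"), alpha = 1),
  list(id = "p3", members = c("v0", "w3"), alpha = 1)
), k = 1)
kernelize(flower)
#> kernelization: ok; 4 -> 0 drugs, 3 -> 0 classes, residual k = 0, 6 event(s)
solve_min_size(flower)
#> hitting-set solution: {v0} size 1, feasible, secondary score 3
```

Targeting constraints (α/β per named group of cell lines) are supplied as
two TSV files on the command line:

```sh
multihit threshold --matrix gi50.csv --format wide --t 2 \
  --groups lines.tsv --bounds-file bounds.tsv --k 10 --out instance.json
multihit solve --instance instance.json --objective min-size --out solution.json
```

Exit status 1 with an `"infeasible"` verdict in the output JSON means the
constraints admit no combination within the budget — an answer, not an
error.

See the vignette (`vignettes/multihit-methods.Rmd`) for the model, the
reduction rules and their guards, and the design decisions behind the
preprocessing defaults.

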