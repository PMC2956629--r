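## Shared fixtures and generators for the test suite. Everything is built in
## code; nothing is read from disk.

## Triangle: three drugs, three pairwise classes, all alpha = 1. Minimum
## hitting sets are the three 2-subsets.
make_triangle <- function(k = 2, alpha = 1, beta = Inf) {
  hs_instance(c("v1", "v2", "v3"), list(
    list(id = "c1", members = c("v1", "v2"), alpha = alpha, beta = beta),
    list(id = "c2", members = c("v2", "v3"), alpha = alpha, beta = beta),
    list(id = "c3", members = c("v1", "v3"), alpha = alpha, beta = beta)
  ), k = k)
}

## Flower: three petals sharing the core drug v0; with k = 1 the
## high-occurrence rule collapses the petals and Rule 1 forces v0.
make_flower <- function(k = 1) {
  hs_instance(c("v0", "w1", "w2", "w3"), list(
    list(id = "p1", members = c("v0", "w1"), alpha = 1),
    list(id = "p2", members = c("v0", "w2"), alpha = 1),
    list(id = "p3", members = c("v0", "w3"), alpha = 1)
  ), k = k)
}

## Fixture for the maximum-hits objective: v2 hits both target classes and
## the unconstrained class f, for a total score of 3 at k = 1.
make_maxhits <- function(k = 1) {
  hs_instance(c("v1", "v2", "v3", "v4"), list(
    list(id = "t1", members = c("v1", "v2"), alpha = 1),
    list(id = "t2", members = c("v2", "v3"), alpha = 1),
    list(id = "f", members = c("v2", "v4"), alpha = 0)
  ), k = k)
}

## One random instance with per-draw structural parameters inside the
## documented envelope (n <= 12 drugs, m <= 15 classes, d <= 4, alpha <= 3,
## k <= 4). beta_mode NULL alternates unbounded and mixed draws.
suite_instance <- function(seed, beta_mode = NULL) {
  if (is.null(beta_mode)) {
    beta_mode <- if (seed %% 2 == 0) "all_unbounded" else "mixed"
  }
  params <- multihit:::with_seed(seed * 7 + 1, {
    list(
      n_drugs = sample(4:12, 1), n_classes = sample(3:15, 1),
      d = sample(1:4, 1), k = sample(1:4, 1)
    )
  })
  random_instance(generator_config(
    seed = seed,
    n_drugs = params$n_drugs, n_classes = params$n_classes, d = params$d,
    alpha_range = 0:3, beta_mode = beta_mode, k = params$k
  ))
}

## Straight-line re-implementation of the feasibility definition, kept
## deliberately naive as an in-test oracle.
direct_feasible <- function(inst, selected, k = inst$k) {
  if (length(unique(selected)) > k) return(FALSE)
  for (cl in inst$classes) {
    h <- length(intersect(unique(selected), cl$members))
    if (h < cl$alpha) return(FALSE)
    if (is.finite(cl$beta) && h > cl$beta) return(FALSE)
  }
  TRUE
}

## Instance equality up to class order (ids, members, bounds, budget).
same_instance <- function(a, b) {
  norm <- function(x) {
    list(
      drugs = sort(x$drugs),
      classes = lapply(x$classes[order(names(x$classes))], function(cl) {
        list(id = cl$id, members = sort(cl$members), alpha = cl$alpha, beta = cl$beta)
      }),
      k = x$k
    )
  }
  identical(norm(a), norm(b))
}
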