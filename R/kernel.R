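#' Pigeonhole thresholds for the high-occurrence reduction
#'
#' The high-occurrence (flower) rule replaces large families of classes that
#' share a common core S by a single class on S. The replacement is sound
#' once the family exceeds `T(j)`, where `j = |S|`: each hitting-set vertex
#' outside S can serve at most `B(j+1)` classes of the family (a bound
#' inherited from the next level up), so with more than `k * B(j+1)` classes
#' some class must be hit entirely inside S. The recurrence is
#' `B(d) = 1`, `T(j) = k * B(j+1)`, `B(j) = T(j) + 1`, which yields the
#' `O(alpha * d * k^d)` kernel size guarantee.
#'
#' @param k hitting-set budget.
#' @param d maximum class degree.
#' @return list with integer vectors `B` and `T`, indexed `1..d`.
#' @export
kernel_params <- function(k, d) {
  d <- max(1L, as.integer(d))
  B <- numeric(d)
  Tj <- numeric(d)
  B[d] <- 1
  Tj[d] <- k * 1 # unused level, kept for completeness of the recurrence
  if (d >= 2L) {
    for (j in seq(d - 1L, 1L)) {
      Tj[j] <- k * B[j + 1L]
      B[j] <- Tj[j] + 1
    }
  }
  list(B = B, T = Tj)
}

## ---------------------------------------------------------------------------
## Internal reduction state: a mutable-by-copy record threaded through rules.
## ---------------------------------------------------------------------------

kstate_new <- function(inst, k = inst$k) {
  list(
    drugs = inst$drugs,
    cls = inst$classes,
    k = k,
    original_k = k,
    events = list(),
    forced = character(),
    infeasible = NULL,
    nseq = 0L # counter for replacement class ids
  )
}

kstate_instance <- function(st) {
  hs_instance(st$drugs, unname(st$cls), k = max(st$k, 0))
}

kev <- function(st, type, ...) {
  st$events[[length(st$events) + 1L]] <- c(list(type = type), list(...))
  st
}

kfail <- function(st, reason) {
  st$infeasible <- reason
  st
}

## membership index: class ids containing drug v
classes_of <- function(st, v) {
  names(st$cls)[vapply(st$cls, function(cl) v %in% cl$members, logical(1))]
}

delete_drug_everywhere <- function(st, v, reason) {
  for (id in names(st$cls)) {
    st$cls[[id]]$members <- setdiff(st$cls[[id]]$members, v)
  }
  st$drugs <- setdiff(st$drugs, v)
  kev(st, "deleted_drug", drug = v, reason = reason)
}

delete_class <- function(st, id, type = "deleted_satisfied_class", ...) {
  st$cls[[id]] <- NULL
  kev(st, type, class = id, ...)
}

## Saturated class under finite beta: alpha == 0 and beta == 0 after forced
## picks. None of its remaining members may ever be selected, so they are
## removed globally, then the class goes.
purge_saturated <- function(st, id) {
  for (v in st$cls[[id]]$members) {
    st <- delete_drug_everywhere(st, v, reason = "forbidden-by-beta0")
    if (!is.null(st$infeasible)) return(st)
  }
  delete_class(st, id)
}

## consistency scan: conditions that certify a No-instance
kstate_check <- function(st) {
  if (!is.null(st$infeasible)) return(st)
  if (st$k < 0) return(kfail(st, "budget exhausted by forced drugs"))
  if (st$k == 0 && any(vapply(st$cls, function(cl) cl$alpha > 0, logical(1)))) {
    return(kfail(st, "positive hit requirements remain but the budget is zero"))
  }
  for (cl in st$cls) {
    if (is.finite(cl$beta) && cl$alpha > cl$beta) {
      return(kfail(st, sprintf("class %s: alpha exceeds beta", cl$id)))
    }
    if (cl$alpha > length(cl$members)) {
      return(kfail(st, sprintf(
        "class %s requires %g hits but has only %d members",
        cl$id, cl$alpha, length(cl$members)
      )))
    }
  }
  st
}

## ---------------------------------------------------------------------------
## Basic practical reduction: zero-degree drugs, trivially satisfied empty
## classes, drugs adjacent only to zero-requirement unconstrained classes,
## and beta = 0 classes (whose members are forbidden everywhere).
## ---------------------------------------------------------------------------

basic_reduce_st <- function(st) {
  repeat {
    st <- kstate_check(st)
    if (!is.null(st$infeasible)) return(st)
    changed <- FALSE

    for (id in names(st$cls)) {
      cl <- st$cls[[id]]
      if (length(cl$members) == 0L) {
        if (cl$alpha > 0) {
          return(kfail(st, sprintf("class %s has no members but requires hits", id)))
        }
        st <- delete_class(st, id)
        changed <- TRUE
      }
    }
    if (changed) next

    beta0 <- names(st$cls)[vapply(st$cls, function(cl) {
      is.finite(cl$beta) && cl$beta == 0
    }, logical(1))]
    if (length(beta0)) {
      id <- beta0[1L]
      if (st$cls[[id]]$alpha > 0) {
        return(kfail(st, sprintf("class %s: alpha exceeds beta", id)))
      }
      st <- purge_saturated(st, id)
      if (!is.null(st$infeasible)) return(st)
      next
    }

    deg <- structure(numeric(length(st$drugs)), names = st$drugs)
    only_zero <- structure(rep(TRUE, length(st$drugs)), names = st$drugs)
    for (cl in st$cls) {
      deg[cl$members] <- deg[cl$members] + 1
      if (cl$alpha > 0 || is.finite(cl$beta)) only_zero[cl$members] <- FALSE
    }
    for (v in st$drugs) {
      if (deg[[v]] == 0) {
        st <- delete_drug_everywhere(st, v, reason = "zero-degree")
        changed <- TRUE
      } else if (only_zero[[v]]) {
        st <- delete_drug_everywhere(st, v, reason = "only-zero-requirement")
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  st
}

## ---------------------------------------------------------------------------
## Rule 1: a class whose requirement equals its degree forces all members.
## Forcing one drug at a time keeps the bookkeeping simple; the class stays
## eligible (alpha and degree drop together) until exhausted.
## ---------------------------------------------------------------------------

rule1_st <- function(st) {
  repeat {
    st <- kstate_check(st)
    if (!is.null(st$infeasible)) return(st)
    tight <- names(st$cls)[vapply(st$cls, function(cl) {
      cl$alpha >= 1 && cl$alpha == length(cl$members)
    }, logical(1))]
    if (length(tight) == 0L) return(st)
    u <- tight[1L]
    v <- sort(st$cls[[u]]$members)[1L]

    st$k <- st$k - 1
    st$forced <- c(st$forced, v)
    st <- kev(st, "forced_drug", drug = v, k_decrement = 1)
    if (st$k < 0) return(kfail(st, "budget exhausted by forced drugs"))

    saturated <- character()
    for (id in names(st$cls)) {
      cl <- st$cls[[id]]
      if (!(v %in% cl$members)) next
      cl$members <- setdiff(cl$members, v)
      cl$alpha <- max(cl$alpha - 1, 0)
      if (is.finite(cl$beta)) {
        cl$beta <- cl$beta - 1
        if (cl$beta < 0) {
          return(kfail(st, sprintf("forced drug %s violates beta of class %s", v, id)))
        }
      }
      st$cls[[id]] <- cl
      if (is.finite(cl$beta) && cl$beta == 0) saturated <- c(saturated, id)
    }
    st$drugs <- setdiff(st$drugs, v)

    for (id in saturated) {
      if (is.null(st$cls[[id]])) next
      if (st$cls[[id]]$alpha > 0) {
        return(kfail(st, sprintf("class %s saturated before meeting its requirement", id)))
      }
      st <- purge_saturated(st, id)
      if (!is.null(st$infeasible)) return(st)
    }

    if (!is.null(st$cls[[u]]) && length(st$cls[[u]]$members) == 0L &&
        st$cls[[u]]$alpha == 0) {
      st <- delete_class(st, u)
    }
  }
}

## Rule 2: alpha = 0 with no upper bound constrains nothing.
rule2_st <- function(st) {
  for (id in names(st$cls)) {
    cl <- st$cls[[id]]
    if (cl$alpha == 0 && !is.finite(cl$beta)) st <- delete_class(st, id)
  }
  st
}

## Rule 3: a class u with unbounded beta whose neighborhood contains that of
## a class v with alpha(v) >= alpha(u) is implied by v. Exact twins (equal
## members and alpha, both unbounded) collapse onto the lexicographically
## smallest id.
rule3_st <- function(st) {
  repeat {
    ids <- sort(names(st$cls))
    deleted <- FALSE
    for (u in ids) {
      cu <- st$cls[[u]]
      if (is.null(cu) || is.finite(cu$beta)) next
      for (v in ids) {
        if (u == v) next
        cv <- st$cls[[v]]
        if (is.null(cv)) next
        if (all(cv$members %in% cu$members) && cv$alpha >= cu$alpha) {
          twin <- setequal(cv$members, cu$members) && cv$alpha == cu$alpha &&
            !is.finite(cv$beta)
          if (twin && u < v) next # keep the smaller id of an identical pair
          st <- delete_class(st, u, type = "deleted_dominated_class", dominating = v)
          deleted <- TRUE
          break
        }
      }
      if (deleted) break
    }
    if (!deleted) return(st)
  }
}

rules123_st <- function(st, order = c(1L, 2L, 3L)) {
  repeat {
    if (!is.null(st$infeasible)) return(st)
    before <- length(st$events)
    st <- basic_reduce_st(st)
    if (!is.null(st$infeasible)) return(st)
    for (r in order) {
      st <- switch(r, rule1_st(st), rule2_st(st), rule3_st(st))
      if (!is.null(st$infeasible)) return(st)
    }
    if (length(st$events) == before) return(st)
  }
}

## ---------------------------------------------------------------------------
## Rules 4-5: the high-occurrence (flower) reduction. For each level j from
## d-1 down to 1 and each requirement value a, any family F_a(S) of more than
## T(j) unbounded classes with alpha = a whose neighborhoods share a j-subset
## S is replaced by the single class (S, alpha = a). Candidate cores S are
## drawn from subsets of actual neighborhoods (F_a(S) is empty otherwise).
## ---------------------------------------------------------------------------

high_occurrence_st <- function(st) {
  d <- max(c(1L, vapply(st$cls, function(cl) length(cl$members), integer(1))))
  if (d < 2L) return(st)
  for (j in seq(d - 1L, 1L)) {
    repeat {
      st <- kstate_check(st)
      if (!is.null(st$infeasible)) return(st)
      params <- kernel_params(st$k, d)
      elig <- Filter(function(cl) cl$alpha >= 1 && !is.finite(cl$beta), st$cls)
      if (length(elig) == 0L) break
      changed <- FALSE
      for (a in sort(unique(vapply(elig, `[[`, numeric(1), "alpha")))) {
        fam <- Filter(function(cl) cl$alpha == a, elig)
        cand <- unique(unlist(lapply(fam, function(cl) {
          if (length(cl$members) < j) return(character())
          apply(utils::combn(sort(cl$members), j), 2L, paste, collapse = "\r")
        })))
        for (key in sort(cand)) {
          S <- strsplit(key, "\r", fixed = TRUE)[[1L]]
          hit_ids <- names(fam)[vapply(fam, function(cl) all(S %in% cl$members), logical(1))]
          if (length(hit_ids) > params$T[j]) {
            if (a > j) {
              return(kfail(st, sprintf(
                "%d classes with alpha = %g share the %d-drug core {%s}: hits must come from the core, which is too small",
                length(hit_ids), a, j, paste(S, collapse = ", ")
              )))
            }
            st$nseq <- st$nseq + 1L
            new_id <- sprintf("K#%03d", st$nseq)
            for (id in hit_ids) st$cls[[id]] <- NULL
            st$cls[[new_id]] <- list(id = new_id, members = S, alpha = a, beta = Inf)
            st <- kev(st, "class_replacement",
              new_class = new_id, members = S, alpha = a, replaced = hit_ids
            )
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
      if (!changed) break
    }
    st <- rules123_st(st)
    if (!is.null(st$infeasible)) return(st)
  }
  st
}

## ---------------------------------------------------------------------------
## Exported operations
## ---------------------------------------------------------------------------

finish_kernel <- function(st, original) {
  structure(
    list(
      instance = kstate_instance(st),
      original = original,
      trace = list(
        events = st$events,
        forced = st$forced,
        residual_k = st$k,
        original_k = st$original_k
      ),
      status = if (is.null(st$infeasible)) "ok" else "infeasible",
      reason = st$infeasible,
      residual_k = st$k
    ),
    class = "hs_kernel"
  )
}

run_rule <- function(inst, k, fn) {
  st <- kstate_new(inst, k)
  finish_kernel(fn(st), inst)
}

#' Individual reduction rules
#'
#' Single reduction passes, mainly useful for inspection; [kernelize()] runs
#' them in the sound order to a global fixpoint. Each returns an `hs_kernel`
#' with the reduced instance, the event trace, and a status of `"ok"` or
#' `"infeasible"` (a certified No-instance is a verdict, not an error).
#'
#' * `basic_reduce()`: removes zero-degree drugs, empty classes with no
#'   requirement (empty with `alpha > 0` certifies a No-instance), drugs
#'   adjacent only to `alpha = 0`, unbounded classes, and `beta = 0` classes
#'   together with their (forbidden) members.
#' * `rule1_forced()`: a class with `alpha = |N(u)| >= 1` forces all its
#'   members into the solution; bounds of incident classes and the budget are
#'   decremented accordingly.
#' * `rule2_satisfied()`: drops classes with `alpha = 0` and unbounded `beta`.
#' * `rule3_dominated()`: drops an unbounded-beta class whose neighborhood
#'   contains that of a class with an equal or stricter requirement.
#' * `high_occurrence_reduce()`: the flower rule; see [kernel_params()].
#'
#' @param inst an `hs_instance`.
#' @param k budget (defaults to `inst$k`).
#' @return an `hs_kernel` object.
#' @name reduction_rules
NULL

#' @rdname reduction_rules
#' @export
basic_reduce <- function(inst, k = inst$k) run_rule(inst, k, basic_reduce_st)

#' @rdname reduction_rules
#' @export
rule1_forced <- function(inst, k = inst$k) run_rule(inst, k, rule1_st)

#' @rdname reduction_rules
#' @export
rule2_satisfied <- function(inst, k = inst$k) run_rule(inst, k, rule2_st)

#' @rdname reduction_rules
#' @export
rule3_dominated <- function(inst, k = inst$k) run_rule(inst, k, rule3_dominated_wrap)

rule3_dominated_wrap <- function(st) rule3_st(st)

#' @rdname reduction_rules
#' @export
high_occurrence_reduce <- function(inst, k = inst$k) run_rule(inst, k, high_occurrence_st)

#' Kernelize an instance
#'
#' Applies the basic reduction and Rules 1-3 to a fixpoint, then alternates
#' the high-occurrence reduction with Rules 1-3 until nothing changes. The
#' result is an equivalent instance (same Yes/No answer for the residual
#' budget) whose size is bounded by a function of `alpha`, `k` and `d` alone,
#' together with a replayable trace from which solutions on the kernel are
#' lifted back to the original instance.
#'
#' @param inst a validated `hs_instance`.
#' @param k budget (defaults to `inst$k`).
#' @param rule_order internal: the order in which Rules 1-3 are tried within
#'   each fixpoint round; the final verdict does not depend on it.
#' @return an `hs_kernel`: list with `instance` (the kernel), `original`,
#'   `trace` (`events`, `forced`, `residual_k`, `original_k`), `status`
#'   (`"ok"` or `"infeasible"`), `reason`, `residual_k`.
#' @examples
#' flower <- hs_instance(
#'   drugs = c("v0", "w1", "w2", "w3"),
#'   classes = list(
#'     list(id = "p1", members = c("v0", "w1"), alpha = 1),
#'     list(id = "p2", members = c("v0", "w2"), alpha = 1),
#'     list(id = "p3", members = c("v0", "w3"), alpha = 1)
#'   ),
#'   k = 1
#' )
#' kern <- kernelize(flower)
#' kern$trace$forced # the shared core drug is forced
#' @export
kernelize <- function(inst, k = inst$k, rule_order = c(1L, 2L, 3L)) {
  st <- kstate_new(inst, k)
  st <- rules123_st(st, order = rule_order)
  repeat {
    if (!is.null(st$infeasible)) break
    before <- length(st$events)
    st <- high_occurrence_st(st)
    if (!is.null(st$infeasible)) break
    st <- rules123_st(st, order = rule_order)
    if (length(st$events) == before) break
  }
  finish_kernel(st, inst)
}

#' Lift a kernel solution back to the original instance
#'
#' A feasible solution of the kernel, together with the drugs forced during
#' reduction, is a solution of the original instance with its original
#' budget. Feasibility is re-verified against the original instance.
#'
#' @param solution an `hs_solution` feasible for `kernel$instance` (with the
#'   residual budget).
#' @param kernel an `hs_kernel` as returned by [kernelize()].
#' @return an `hs_solution` evaluated on the original instance.
#' @export
lift_solution <- function(solution, kernel) {
  stopifnot(inherits(kernel, "hs_kernel"))
  if (!isTRUE(solution$feasible)) {
    stop("cannot lift an infeasible kernel solution")
  }
  check_feasible(
    kernel$original,
    union(solution$selected, kernel$trace$forced),
    k = kernel$trace$original_k
  )
}

#' @export
print.hs_kernel <- function(x, ...) {
  cat(sprintf(
    "kernelization: %s; %d -> %d drugs, %d -> %d classes, residual k = %g, %d event(s)\n",
    x$status,
    length(x$original$drugs), length(x$instance$drugs),
    length(x$original$classes), length(x$instance$classes),
    x$residual_k, length(x$trace$events)
  ))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Write a kernelization trace as JSON lines
#'
#' One replayable event object per line, followed by no terminator record;
#' `residual_k` and the forced-drug list live in the companion solution JSON.
#'
#' @param kernel an `hs_kernel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(kernel, path) {
  lines <- vapply(kernel$trace$events, function(ev) {
    jsonlite::toJSON(ev, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
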