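#' Solver configuration
#'
#' @param objective `"min_size"` (smallest feasible hitting set within the
#'   budget) or `"max_hits"` (among feasible sets of size exactly `k`,
#'   maximize total hits on classes with unbounded beta).
#' @param k budget; required for `"max_hits"`, defaults to the instance budget
#'   for `"min_size"`.
#' @param use_kernel kernelize before searching (min-size only; the
#'   maximum-hits objective counts hits on exactly the classes the
#'   kernelization is entitled to discard, so its search always runs on the
#'   full instance).
#' @param node_limit optional cap on search-tree nodes; exceeding it yields an
#'   explicit `"undecided"` verdict rather than a silent wrong answer.
#' @return a `solve_config` list.
#' @export
solve_config <- function(objective = c("min_size", "max_hits"), k = NULL,
                         use_kernel = TRUE, node_limit = NULL) {
  objective <- match.arg(objective)
  if (objective == "max_hits" && is.null(k)) {
    stop("the max-hits objective requires an explicit hitting-set size k")
  }
  list(objective = objective, k = k, use_kernel = use_kernel, node_limit = node_limit)
}

## ---------------------------------------------------------------------------
## Shared search machinery. Instances are compiled to indexed vectors once.
## ---------------------------------------------------------------------------

compile_instance <- function(inst) {
  drugs <- sort(inst$drugs)
  M <- incidence_matrix(inst)[, drugs, drop = FALSE]
  list(
    drugs = drugs,
    n = length(drugs),
    m = length(inst$classes),
    M = M,
    members = lapply(inst$classes, function(cl) match(sort(cl$members), drugs)),
    alphas = class_alphas(inst),
    betas = class_betas(inst),
    degree = colSums(M),
    wub = if (nrow(M)) colSums(M[!is.finite(class_betas(inst)), , drop = FALSE])
          else numeric(length(drugs))
  )
}

## Admissible lower bound on additional drugs needed: greedily pack classes
## with positive deficit whose member sets are pairwise disjoint (ignoring
## already selected drugs) and sum their deficits.
deficit_lower_bound <- function(ci, hits, sel_mask) {
  defs <- ci$alphas - hits
  open <- which(defs > 0)
  if (length(open) == 0L) return(0)
  used <- logical(ci$n)
  lb <- 0
  for (u in open[order(-defs[open])]) {
    mem <- ci$members[[u]]
    mem <- mem[!sel_mask[mem]]
    if (length(mem) < defs[u]) return(Inf) # cannot ever be satisfied
    if (!any(used[mem])) {
      lb <- lb + defs[u]
      used[mem] <- TRUE
    }
  }
  lb
}

## Complete branch-and-bound for the minimum size: branch on an unsatisfied
## class of maximum deficit, trying each selectable member (at most d
## branches per level, depth at most k).
bb_min_size <- function(ci, k, node_limit = NULL) {
  best <- Inf
  nodes <- 0L
  limited <- FALSE

  recurse <- function(sel_mask, hits, depth) {
    nodes <<- nodes + 1L
    if (!is.null(node_limit) && nodes > node_limit) {
      limited <<- TRUE
      return(invisible(NULL))
    }
    fin <- is.finite(ci$betas)
    if (any(hits[fin] > ci$betas[fin])) return(invisible(NULL))
    lb <- deficit_lower_bound(ci, hits, sel_mask)
    if (depth + lb >= best || depth + lb > k) return(invisible(NULL))
    if (lb == 0) { # all requirements met
      best <<- depth
      return(invisible(NULL))
    }
    defs <- ci$alphas - hits
    u <- which.max(defs)
    cand <- ci$members[[u]]
    cand <- cand[!sel_mask[cand]]
    ## a selectable member must not push a saturated class over its beta
    cand <- cand[vapply(cand, function(v) {
      touched <- which(ci$M[, v])
      all(hits[touched] + 1 <= ci$betas[touched])
    }, logical(1))]
    if (length(cand) == 0L) return(invisible(NULL))
    cand <- cand[order(-ci$degree[cand], ci$drugs[cand])]
    for (v in cand) {
      sel_mask[v] <- TRUE
      recurse(sel_mask, hits + ci$M[, v], depth + 1L)
      sel_mask[v] <- FALSE
      if (limited) return(invisible(NULL))
    }
    invisible(NULL)
  }

  hits0 <- if (ci$m) numeric(ci$m) else numeric(0)
  recurse(logical(ci$n), hits0, 0L)
  list(size = best, limited = limited)
}

## Lexicographically smallest feasible selection of size exactly s:
## include-first depth-first search over sorted drugs with the same pruning.
lex_search_size <- function(ci, s, require_score = NULL) {
  result <- NULL
  fin <- is.finite(ci$betas)

  recurse <- function(i, sel, hits, score) {
    if (!is.null(result)) return(invisible(NULL))
    nsel <- length(sel)
    if (nsel == s) {
      if (all(hits >= ci$alphas) && all(hits[fin] <= ci$betas[fin]) &&
          (is.null(require_score) || score == require_score)) {
        result <<- sel
      }
      return(invisible(NULL))
    }
    if (i > ci$n || nsel + (ci$n - i + 1L) < s) return(invisible(NULL))
    sel_mask <- logical(ci$n)
    sel_mask[sel] <- TRUE
    lb <- deficit_lower_bound(ci, hits, sel_mask)
    if (nsel + lb > s) return(invisible(NULL))
    if (!is.null(require_score)) {
      rem <- setdiff(seq(i, ci$n), sel)
      take <- min(s - nsel, length(rem))
      opt <- score + sum(sort(ci$wub[rem], decreasing = TRUE)[seq_len(take)])
      if (opt < require_score) return(invisible(NULL))
    }
    ## include drug i if no finite beta blocks it
    touched <- which(ci$M[, i])
    if (all(hits[touched] + 1 <= ci$betas[touched])) {
      recurse(i + 1L, c(sel, i), hits + ci$M[, i], score + ci$wub[i])
    }
    recurse(i + 1L, sel, hits, score)
    invisible(NULL)
  }

  hits0 <- if (ci$m) numeric(ci$m) else numeric(0)
  recurse(1L, integer(0), hits0, 0)
  result
}

#' Solve for the minimum-size hitting set
#'
#' Complete branch-and-bound search for a smallest drug set within the budget
#' that meets every class's `alpha` and `beta` bounds. By default the
#' instance is kernelized first and the kernel solution lifted back. Among
#' optima, the lexicographically smallest selected drug-id set is returned.
#'
#' @param inst a validated `hs_instance`.
#' @param k budget (defaults to `inst$k`).
#' @param use_kernel reduce with [kernelize()] before searching.
#' @param node_limit optional search-node cap; when exceeded the verdict is
#'   `"undecided"`.
#' @return an `hs_solution`; its `verdict` is `"feasible"` (optimal),
#'   `"infeasible"`, or `"undecided"`.
#' @examples
#' inst <- hs_instance(c("v1", "v2", "v3"), list(
#'   list(id = "c1", members = c("v1", "v2"), alpha = 1),
#'   list(id = "c2", members = c("v2", "v3"), alpha = 1),
#'   list(id = "c3", members = c("v1", "v3"), alpha = 1)
#' ), k = 2)
#' solve_min_size(inst)
#' @export
solve_min_size <- function(inst, k = inst$k, use_kernel = TRUE, node_limit = NULL) {
  if (use_kernel) {
    kern <- kernelize(inst, k)
    if (kern$status == "infeasible") return(infeasible_solution(kern$reason))
    inner <- solve_min_size(kern$instance,
      k = kern$residual_k,
      use_kernel = FALSE, node_limit = node_limit
    )
    if (!inner$feasible) return(inner)
    return(lift_solution(inner, kern))
  }
  ci <- compile_instance(inst)
  bb <- bb_min_size(ci, k, node_limit)
  if (bb$limited) {
    sol <- infeasible_solution("node limit exceeded")
    sol$verdict <- "undecided"
    return(sol)
  }
  if (!is.finite(bb$size) || bb$size > k) return(infeasible_solution())
  sel <- lex_search_size(ci, bb$size)
  check_feasible(inst, ci$drugs[sel], k = k)
}

#' Solve for the maximum-hits set of fixed size
#'
#' Among feasible selections of size exactly `k`, maximizes the total number
#' of hits on classes with unbounded `beta` (hits counted with multiplicity).
#' The search is complete, with budget/deficit pruning and an optimistic
#' bound given by the `k` largest remaining per-drug scores. Runs on the full
#' instance: the secondary objective counts hits on classes that the
#' kernelization may legitimately remove, so reduction is not applied here.
#'
#' @param inst a validated `hs_instance`.
#' @param k required hitting-set size (exact).
#' @param node_limit unused reserve for interface symmetry.
#' @return an `hs_solution` with `secondary_score` the attained optimum, or
#'   an infeasible verdict when no size-`k` selection meets the bounds.
#' @export
solve_max_hits <- function(inst, k, node_limit = NULL) {
  if (missing(k) || is.null(k)) stop("max-hits objective requires an explicit k")
  ci <- compile_instance(inst)
  if (k > ci$n) return(infeasible_solution("k exceeds the number of drugs"))
  fin <- is.finite(ci$betas)

  best <- -Inf
  found <- FALSE
  recurse <- function(i, sel, hits, score) {
    nsel <- length(sel)
    if (nsel == k) {
      if (all(hits >= ci$alphas) && all(hits[fin] <= ci$betas[fin])) {
        found <<- TRUE
        if (score > best) best <<- score
      }
      return(invisible(NULL))
    }
    if (i > ci$n || nsel + (ci$n - i + 1L) < k) return(invisible(NULL))
    sel_mask <- logical(ci$n)
    sel_mask[sel] <- TRUE
    lb <- deficit_lower_bound(ci, hits, sel_mask)
    if (nsel + lb > k) return(invisible(NULL))
    rem <- seq(i, ci$n)
    take <- min(k - nsel, length(rem))
    opt <- score + sum(sort(ci$wub[rem], decreasing = TRUE)[seq_len(take)])
    if (found && opt < best) return(invisible(NULL))
    touched <- which(ci$M[, i])
    if (all(hits[touched] + 1 <= ci$betas[touched])) {
      recurse(i + 1L, c(sel, i), hits + ci$M[, i], score + ci$wub[i])
    }
    recurse(i + 1L, sel, hits, score)
    invisible(NULL)
  }
  hits0 <- if (ci$m) numeric(ci$m) else numeric(0)
  recurse(1L, integer(0), hits0, 0)

  if (!found) return(infeasible_solution())
  sel <- lex_search_size(ci, k, require_score = best)
  check_feasible(inst, ci$drugs[sel], k = k)
}

## ---------------------------------------------------------------------------
## CPLEX LP format export
## ---------------------------------------------------------------------------

#' Export an instance as a CPLEX LP format integer program
#'
#' One binary variable per drug. Every class with `alpha >= 1` contributes a
#' `>=` constraint over its members, every class with finite `beta` a `<=`
#' constraint. For the minimum-size objective the model minimizes the number
#' of selected drugs subject to the budget; for maximum-hits the size is
#' fixed by an equality and the objective maximizes hits on unbounded-beta
#' classes (each drug weighted by the number of such classes containing it).
#' Variable names are `x1..xn` over lexicographically sorted drug ids; the
#' sidecar map makes the renaming round-trippable.
#'
#' @param inst a validated `hs_instance`.
#' @param objective `"min_size"` or `"max_hits"`.
#' @param k budget (min-size) or exact size (max-hits); defaults to `inst$k`.
#' @return an `hs_ilp`: list with `model` (character vector of LP lines),
#'   `map` (data.frame `variable`, `drug`), `objective`, `k`.
#' @seealso [write_ilp()] to write the `.lp` file and sidecar TSV.
#' @export
export_ilp <- function(inst, objective = c("min_size", "max_hits"), k = inst$k) {
  objective <- match.arg(objective)
  ci <- compile_instance(inst)
  vars <- if (ci$n) paste0("x", seq_len(ci$n)) else character()
  lines <- c("\\ (alpha,beta,d)-hitting-set model")

  obj_terms <- if (objective == "min_size") {
    vars
  } else {
    w <- ci$wub
    paste0(ifelse(w == 0, "0 ", paste0(w, " ")), vars)
  }
  lines <- c(
    lines,
    if (objective == "min_size") "Minimize" else "Maximize",
    paste0(" obj: ", if (length(obj_terms)) paste(obj_terms, collapse = " + ") else "0"),
    "Subject To"
  )

  cons <- character()
  idx <- 0L
  for (u in seq_along(ci$members)) {
    mem <- ci$members[[u]]
    lhs <- paste(vars[mem], collapse = " + ")
    if (ci$alphas[u] >= 1) {
      idx <- idx + 1L
      cons <- c(cons, sprintf(" c%d_min: %s >= %g", u, lhs, ci$alphas[u]))
    }
    if (is.finite(ci$betas[u]) && length(mem)) {
      idx <- idx + 1L
      cons <- c(cons, sprintf(" c%d_max: %s <= %g", u, lhs, ci$betas[u]))
    }
  }
  size_lhs <- paste(vars, collapse = " + ")
  if (length(vars)) {
    cons <- c(cons, if (objective == "min_size") {
      sprintf(" budget: %s <= %g", size_lhs, k)
    } else {
      sprintf(" size: %s = %g", size_lhs, k)
    })
  }
  lines <- c(lines, cons, "Binary", paste0(" ", paste(vars, collapse = " ")), "End")

  structure(
    list(
      model = lines,
      map = data.frame(variable = vars, drug = ci$drugs, stringsAsFactors = FALSE),
      objective = objective,
      k = k
    ),
    class = "hs_ilp"
  )
}

#' Write an exported model to disk
#'
#' @param ilp an `hs_ilp` from [export_ilp()].
#' @param path path of the `.lp` file; the variable-name sidecar is written
#'   next to it with extension `.vars.tsv`.
#' @return `path`, invisibly.
#' @export
write_ilp <- function(ilp, path) {
  writeLines(ilp$model, path)
  utils::write.table(ilp$map,
    file = paste0(sub("\\.lp$", "", path), ".vars.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

## ---------------------------------------------------------------------------
## Independent LP-format reader + enumerator, used to verify that the
## exported text faithfully encodes the instance without an external solver.
## ---------------------------------------------------------------------------

parse_lp_text <- function(lines) {
  lines <- trimws(lines[!grepl("^\\\\", lines)])
  lines <- lines[nzchar(lines)]
  section <- NULL
  sense <- NULL
  obj <- character()
  cons <- character()
  bins <- character()
  for (ln in lines) {
    low <- tolower(ln)
    if (low %in% c("minimize", "maximize", "subject to", "binary", "end", "st", "s.t.")) {
      section <- low
      if (low %in% c("minimize", "maximize")) sense <- low
      next
    }
    if (is.null(section)) stop("LP parse: content before a section header")
    if (section %in% c("minimize", "maximize")) obj <- c(obj, ln)
    if (section %in% c("subject to", "st", "s.t.")) cons <- c(cons, ln)
    if (section == "binary") bins <- c(bins, strsplit(ln, "\\s+")[[1]])
  }
  parse_terms <- function(expr) {
    expr <- sub("^[A-Za-z0-9_#]+:", "", expr)
    terms <- strsplit(gsub("\\+", " + ", expr), "\\s+\\+\\s+")[[1]]
    terms <- trimws(terms[nzchar(trimws(terms))])
    out <- list()
    for (tm in terms) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 1L) {
        if (grepl("^[0-9.]+$", parts)) next # bare constant (e.g. empty objective)
        out[[parts]] <- (out[[parts]] %||% 0) + 1
      } else {
        out[[parts[2]]] <- (out[[parts[2]]] %||% 0) + as.numeric(parts[1])
      }
    }
    out
  }
  con_list <- lapply(cons, function(cn) {
    mm <- regmatches(cn, regexec("^(.*?)(<=|>=|=)\\s*(-?[0-9.]+)$", cn))[[1]]
    if (length(mm) != 4L) stop("LP parse: bad constraint: ", cn)
    list(terms = parse_terms(mm[2]), op = mm[3], rhs = as.numeric(mm[4]))
  })
  list(
    sense = sense,
    objective = parse_terms(paste(obj, collapse = " ")),
    constraints = con_list,
    binaries = sort(unique(bins[nzchar(bins)]))
  )
}

## Exhaustive 0/1 enumeration of a parsed LP (<= 22 binaries).
solve_lp_exhaustive <- function(parsed) {
  vars <- parsed$binaries
  n <- length(vars)
  if (n > 22L) stop("exhaustive LP check guard: more than 22 binaries")
  coef_vec <- function(terms) {
    v <- structure(numeric(n), names = vars)
    for (nm in names(terms)) v[nm] <- terms[[nm]]
    v
  }
  obj <- coef_vec(parsed$objective)
  A <- do.call(rbind, c(
    lapply(parsed$constraints, function(cn) coef_vec(cn$terms)),
    list(matrix(numeric(0), 0, n))
  ))
  ops <- vapply(parsed$constraints, `[[`, character(1), "op")
  rhs <- vapply(parsed$constraints, `[[`, numeric(1), "rhs")
  best <- NULL
  for (code in 0:(2^n - 1)) {
    x <- as.numeric(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
    lhs <- if (nrow(A)) as.vector(A %*% x) else numeric(0)
    ok <- all(ifelse(ops == "<=", lhs <= rhs, ifelse(ops == ">=", lhs >= rhs, lhs == rhs)))
    if (!ok) next
    val <- sum(obj * x)
    if (is.null(best) ||
        (parsed$sense == "minimize" && val < best) ||
        (parsed$sense == "maximize" && val > best)) {
      best <- val
    }
  }
  if (is.null(best)) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}
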