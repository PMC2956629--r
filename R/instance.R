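#' Construct an (alpha,beta,d)-hitting-set instance
#'
#' An instance is a bipartite model of a thresholded drug screen: one vertex
#' per drug (compound) and one class per cell line. A class carries the set of
#' drugs it responds to (its neighborhood, at most `d` members), a minimum
#' required hit count `alpha`, and a maximum allowed hit count `beta`
#' (`Inf` for "no maximum"). A selection of at most `k` drugs is sought that
#' hits every class at least `alpha` and at most `beta` times.
#'
#' `beta = Inf` is the distinguished "unbounded" value; it serializes to the
#' JSON literal `null` (see [write_instance()]). The maximum class degree `d`
#' is always recomputed from the member sets, never taken from input.
#'
#' @param drugs character vector of drug identifiers (duplicates are an error
#'   reported by [validate_instance()]).
#' @param classes list of class records; each a list with elements `id`
#'   (character scalar), `members` (character vector of drug ids), `alpha`
#'   (non-negative integer), and `beta` (non-negative integer or `Inf`,
#'   default `Inf`).
#' @param k non-negative integer budget on the hitting-set size.
#' @return an object of class `hs_instance` with elements `drugs`, `classes`
#'   (named by class id), `k`, and recomputed `d`.
#' @seealso [validate_instance()], [check_feasible()], [kernelize()],
#'   [solve_min_size()]
#' @examples
#' inst <- hs_instance(
#'   drugs = c("v1", "v2", "v3"),
#'   classes = list(
#'     list(id = "c1", members = c("v1", "v2"), alpha = 1),
#'     list(id = "c2", members = c("v2", "v3"), alpha = 1),
#'     list(id = "c3", members = c("v1", "v3"), alpha = 1)
#'   ),
#'   k = 2
#' )
#' validate_instance(inst)
#' @export
hs_instance <- function(drugs, classes = list(), k = 0L) {
  drugs <- as.character(drugs)
  cls <- lapply(classes, function(cl) {
    if (is.null(cl$id)) stop("every class needs an 'id'")
    list(
      id = as.character(cl$id),
      members = as.character(cl$members %||% character()),
      alpha = as.numeric(cl$alpha %||% 0),
      beta = as.numeric(cl$beta %||% Inf)
    )
  })
  names(cls) <- vapply(cls, `[[`, character(1), "id")
  inst <- structure(
    list(drugs = drugs, classes = cls, k = as.numeric(k), d = 0),
    class = "hs_instance"
  )
  inst$d <- instance_degree(inst)
  inst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

instance_degree <- function(inst) {
  if (length(inst$classes) == 0L) return(0L)
  max(vapply(inst$classes, function(cl) length(cl$members), integer(1)))
}

class_alphas <- function(inst) {
  vapply(inst$classes, `[[`, numeric(1), "alpha")
}

class_betas <- function(inst) {
  vapply(inst$classes, `[[`, numeric(1), "beta")
}

#' Logical incidence matrix of an instance
#'
#' Rows are classes (in declaration order), columns drugs (in declaration
#' order); entry is TRUE where the drug is a member of the class.
#' @param inst an `hs_instance`.
#' @return logical matrix with dimnames (class ids, drug ids).
#' @keywords internal
incidence_matrix <- function(inst) {
  m <- length(inst$classes)
  n <- length(inst$drugs)
  M <- matrix(FALSE, m, n, dimnames = list(names(inst$classes), inst$drugs))
  for (cl in inst$classes) M[cl$id, intersect(cl$members, inst$drugs)] <- TRUE
  M
}

#' Validate an instance
#'
#' Returns a character vector of violation descriptions, empty when the
#' instance is well formed. Checked: duplicate drug or class identifiers,
#' members referencing undeclared drugs, duplicate members within a class,
#' negative or non-integral `alpha`/`beta`/`k`, `alpha > beta` for finite
#' `beta`, and classes demanding more hits than they have members
#' (`alpha > |N(u)|`), which makes the instance immediately infeasible and is
#' surfaced here rather than silently answered "No" by the solvers.
#'
#' @param inst an `hs_instance`.
#' @return character vector of human-readable violations (empty if valid).
#' @export
validate_instance <- function(inst) {
  stopifnot(inherits(inst, "hs_instance"))
  v <- character()
  dup <- unique(inst$drugs[duplicated(inst$drugs)])
  if (length(dup)) v <- c(v, paste0("duplicate drug id: ", dup))
  ids <- vapply(inst$classes, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) v <- c(v, paste0("duplicate class id: ", dup))
  if (is.na(inst$k) || inst$k < 0 || inst$k != floor(inst$k)) {
    v <- c(v, sprintf("budget k must be a non-negative integer, got %s", inst$k))
  }
  for (cl in inst$classes) {
    if (anyDuplicated(cl$members)) {
      v <- c(v, sprintf("class %s has duplicate members", cl$id))
    }
    unknown <- setdiff(cl$members, inst$drugs)
    if (length(unknown)) {
      v <- c(v, sprintf(
        "class %s references undeclared drug(s): %s",
        cl$id, paste(unknown, collapse = ", ")
      ))
    }
    if (is.na(cl$alpha) || cl$alpha < 0 || cl$alpha != floor(cl$alpha)) {
      v <- c(v, sprintf("class %s: alpha must be a non-negative integer", cl$id))
    }
    if (is.na(cl$beta) || cl$beta < 0 ||
        (is.finite(cl$beta) && cl$beta != floor(cl$beta))) {
      v <- c(v, sprintf("class %s: beta must be a non-negative integer or Inf", cl$id))
    } else if (is.finite(cl$beta) && cl$alpha > cl$beta) {
      v <- c(v, sprintf("class %s: alpha (%g) exceeds beta (%g)", cl$id, cl$alpha, cl$beta))
    }
    if (cl$alpha > length(unique(intersect(cl$members, inst$drugs)))) {
      v <- c(v, sprintf(
        "class %s demands %g hits but has only %d members (infeasible)",
        cl$id, cl$alpha, length(unique(intersect(cl$members, inst$drugs)))
      ))
    }
  }
  v
}

#' Count hits per class for a drug selection
#'
#' @param inst an `hs_instance`.
#' @param selected character vector of selected drug ids (a subset of
#'   `inst$drugs`; anything else is an error).
#' @return named integer vector, one entry per class: `|selected n N(u)|`.
#' @export
count_hits <- function(inst, selected) {
  selected <- as.character(selected)
  unknown <- setdiff(selected, inst$drugs)
  if (length(unknown)) {
    stop("selection contains undeclared drug(s): ", paste(unknown, collapse = ", "))
  }
  selected <- unique(selected)
  h <- vapply(inst$classes, function(cl) {
    sum(cl$members %in% selected)
  }, integer(1))
  if (length(h) == 0L) h <- structure(integer(0), names = character(0))
  h
}

#' Check feasibility of a drug selection
#'
#' Builds a full solution record: per-class hit counts, feasibility (size
#' within budget and every class between its `alpha` and `beta`), and the
#' secondary score used by the maximum-hits objective (total hits on classes
#' with unbounded `beta`).
#'
#' @param inst an `hs_instance`.
#' @param selected character vector of selected drug ids.
#' @param k budget to check against; defaults to `inst$k`.
#' @return an `hs_solution`: list with `selected` (sorted), `hits`, `feasible`,
#'   `size`, `secondary_score`, `verdict`.
#' @export
check_feasible <- function(inst, selected, k = inst$k) {
  hits <- count_hits(inst, selected)
  selected <- sort(unique(as.character(selected)))
  alphas <- class_alphas(inst)
  betas <- class_betas(inst)
  ok <- length(selected) <= k &&
    all(hits >= alphas) && all(hits[is.finite(betas)] <= betas[is.finite(betas)])
  new_solution(
    selected = selected,
    hits = hits,
    feasible = ok,
    secondary_score = sum(hits[!is.finite(betas)]),
    verdict = if (ok) "feasible" else "infeasible"
  )
}

new_solution <- function(selected, hits, feasible, secondary_score,
                         verdict = if (feasible) "feasible" else "infeasible") {
  structure(
    list(
      selected = selected,
      hits = hits,
      feasible = feasible,
      size = length(selected),
      secondary_score = as.numeric(secondary_score),
      verdict = verdict
    ),
    class = "hs_solution"
  )
}

infeasible_solution <- function(reason = "infeasible") {
  structure(
    list(
      selected = character(), hits = NULL, feasible = FALSE, size = NA_integer_,
      secondary_score = NA_real_, verdict = "infeasible", reason = reason
    ),
    class = "hs_solution"
  )
}

#' @export
print.hs_instance <- function(x, ...) {
  cat(sprintf(
    "(alpha,beta,d)-hitting-set instance: %d drugs, %d classes, d = %d, k = %g\n",
    length(x$drugs), length(x$classes), x$d, x$k
  ))
  betas <- class_betas(x)
  if (length(betas)) {
    cat(sprintf(
      "  alpha range [%g, %g]; %d class(es) with finite beta\n",
      min(class_alphas(x)), max(class_alphas(x)), sum(is.finite(betas))
    ))
  }
  invisible(x)
}

#' @export
print.hs_solution <- function(x, ...) {
  if (identical(x$verdict, "infeasible") && length(x$selected) == 0L) {
    cat("hitting-set solution: INFEASIBLE",
        if (!is.null(x$reason)) paste0(" (", x$reason, ")") else "", "\n", sep = "")
  } else {
    cat(sprintf(
      "hitting-set solution: {%s} size %d, %s, secondary score %g\n",
      paste(x$selected, collapse = ", "), x$size, x$verdict, x$secondary_score
    ))
  }
  invisible(x)
}
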