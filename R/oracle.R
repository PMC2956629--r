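#' Brute-force reference solvers
#'
#' Exhaustive-enumeration oracles used as an independent reference for the
#' branch-and-bound solvers and the kernelization. Enumeration is in
#' size-then-lexicographic order over sorted drug ids, so the first feasible
#' subset found is also the deterministic representative optimum. Guarded to
#' at most 22 drugs; these functions exist for verification on small
#' instances, not for production solving.
#'
#' @param inst an `hs_instance`.
#' @param k budget (defaults to `inst$k`).
#' @return `brute_min_size()`: list with `status` ("optimal"/"infeasible"),
#'   `size`, and `selected` (lexicographically first optimum).
#' @name brute_oracle
NULL

oracle_guard <- function(inst) {
  if (length(inst$drugs) > 22L) {
    stop("brute-force oracle guard: instance has more than 22 drugs")
  }
}

oracle_setup <- function(inst) {
  drugs <- sort(inst$drugs)
  M <- incidence_matrix(inst)[, drugs, drop = FALSE]
  list(
    drugs = drugs,
    M = M * 1,
    alphas = class_alphas(inst),
    betas = class_betas(inst),
    wub = if (nrow(M)) colSums((M * 1)[!is.finite(class_betas(inst)), , drop = FALSE])
          else numeric(ncol(M))
  )
}

## indicator matrix (n x n_candidates) for all size-s subsets, lex order
subset_indicators <- function(n, s) {
  if (s == 0L) return(matrix(0, n, 1))
  combos <- utils::combn(n, s)
  ind <- matrix(0, n, ncol(combos))
  ind[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = s))] <- 1
  ind
}

feasible_columns <- function(su, ind) {
  if (nrow(su$M) == 0L) return(rep(TRUE, ncol(ind)))
  H <- su$M %*% ind
  lo <- colSums(H < su$alphas) == 0
  fin <- is.finite(su$betas)
  hi <- if (any(fin)) colSums(H[fin, , drop = FALSE] > su$betas[fin]) == 0
        else rep(TRUE, ncol(ind))
  lo & hi
}

#' @rdname brute_oracle
#' @export
brute_min_size <- function(inst, k = inst$k) {
  oracle_guard(inst)
  su <- oracle_setup(inst)
  n <- length(su$drugs)
  for (s in 0:min(k, n)) {
    ind <- subset_indicators(n, s)
    feas <- feasible_columns(su, ind)
    if (any(feas)) {
      j <- which(feas)[1L]
      return(list(status = "optimal", size = s, selected = su$drugs[ind[, j] > 0]))
    }
  }
  list(status = "infeasible", size = NA_integer_, selected = NULL)
}

#' @rdname brute_oracle
#' @return `brute_max_hits()`: list with `status`, `score` (maximum total hits
#'   on unbounded-beta classes over feasible selections of size exactly `k`),
#'   and `selected`.
#' @export
brute_max_hits <- function(inst, k) {
  oracle_guard(inst)
  su <- oracle_setup(inst)
  n <- length(su$drugs)
  if (k > n) return(list(status = "infeasible", score = NA_real_, selected = NULL))
  ind <- subset_indicators(n, k)
  feas <- feasible_columns(su, ind)
  if (!any(feas)) return(list(status = "infeasible", score = NA_real_, selected = NULL))
  scores <- as.vector(su$wub %*% ind)
  scores[!feas] <- -Inf
  j <- which(scores == max(scores))[1L]
  list(status = "optimal", score = max(scores), selected = su$drugs[ind[, j] > 0])
}

#' @rdname brute_oracle
#' @return `enumerate_optimal()`: list of all minimum-size feasible
#'   selections (each a sorted character vector), in lexicographic order;
#'   empty list when infeasible.
#' @export
enumerate_optimal <- function(inst, k = inst$k) {
  oracle_guard(inst)
  opt <- brute_min_size(inst, k)
  if (opt$status != "optimal") return(list())
  su <- oracle_setup(inst)
  n <- length(su$drugs)
  ind <- subset_indicators(n, opt$size)
  feas <- feasible_columns(su, ind)
  lapply(which(feas), function(j) su$drugs[ind[, j] > 0])
}
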