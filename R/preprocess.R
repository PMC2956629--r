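#' Construct a response matrix
#'
#' A compounds-by-cell-lines matrix of real-valued responses on a logarithmic
#' scale (NCI60-style GI50 exports are log10 molar). Missing measurements are
#' `NA` and are never read as numbers downstream.
#'
#' @param values numeric matrix (compounds in rows, cell lines in columns).
#' @param compounds,lines identifiers; default to the dimnames of `values`.
#' @return an `hs_response` object (a classed numeric matrix).
#' @export
response_matrix <- function(values, compounds = rownames(values),
                            lines = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(compounds) || is.null(lines)) {
    stop("compound and cell-line identifiers are required")
  }
  if (anyDuplicated(compounds)) stop("duplicate compound identifiers")
  if (anyDuplicated(lines)) stop("duplicate cell-line identifiers")
  dimnames(values) <- list(as.character(compounds), as.character(lines))
  structure(values, class = c("hs_response", "matrix"))
}

#' Collapse replicate screen records to one value per compound/cell-line pair
#'
#' Screen exports carry one record per experiment; where several records
#' exist for the same compound and cell line, the value from the experiment
#' with the highest compound concentration is kept. Concentration ties keep
#' the last-read record and emit a warning naming the pair. Pairs with no
#' record are missing (`NA`).
#'
#' @param records data.frame with columns `compound`, `cell_line`,
#'   `concentration`, `value` (extra columns are ignored). Non-numeric
#'   concentrations or values are an error naming the offending record.
#' @return an `hs_response` matrix; rows and columns follow first appearance
#'   order in `records`.
#' @export
resolve_duplicates <- function(records) {
  req <- c("compound", "cell_line", "concentration", "value")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "))
  }
  conc <- suppressWarnings(as.numeric(records$concentration))
  val <- suppressWarnings(as.numeric(records$value))
  bad <- which(is.na(conc) | is.na(val))
  if (length(bad)) {
    stop(sprintf(
      "non-numeric concentration or value in record %d (%s / %s)",
      bad[1], records$compound[bad[1]], records$cell_line[bad[1]]
    ))
  }
  compounds <- unique(as.character(records$compound))
  lines <- unique(as.character(records$cell_line))
  m <- matrix(NA_real_, length(compounds), length(lines),
    dimnames = list(compounds, lines)
  )
  kept_conc <- m
  ties <- character()
  for (i in seq_len(nrow(records))) {
    co <- as.character(records$compound[i])
    li <- as.character(records$cell_line[i])
    prev <- kept_conc[co, li]
    if (is.na(prev) || conc[i] > prev) {
      m[co, li] <- val[i]
      kept_conc[co, li] <- conc[i]
    } else if (conc[i] == prev) {
      m[co, li] <- val[i] # last-read record wins on a tie
      ties <- c(ties, paste0(co, "/", li))
    }
  }
  if (length(ties)) {
    warning(
      "concentration tie(s), last-read record kept: ",
      paste(unique(ties), collapse = ", ")
    )
  }
  response_matrix(m)
}

#' Row-wise z-transformation
#'
#' Each compound's responses are standardized independently over its
#' non-missing entries: `(x - mean) / sd`, with the population standard
#' deviation (divide by n). Values are assumed to be on a logarithmic scale
#' already (see [log10_transform()]). Rows with fewer than two non-missing
#' entries or zero variance carry no usable signal and become all-missing,
#' with a warning naming them.
#'
#' @param m an `hs_response` matrix (or plain numeric matrix).
#' @return an `hs_response` matrix of z-scores.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  out <- m
  degenerate <- character()
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    obs <- !is.na(x)
    if (sum(obs) < 2L) {
      out[i, ] <- NA_real_
      degenerate <- c(degenerate, rownames(m)[i] %||% as.character(i))
      next
    }
    mu <- mean(x[obs])
    sdev <- sqrt(mean((x[obs] - mu)^2))
    if (sdev == 0) {
      out[i, ] <- NA_real_
      degenerate <- c(degenerate, rownames(m)[i] %||% as.character(i))
      next
    }
    out[i, obs] <- (x[obs] - mu) / sdev
  }
  if (length(degenerate)) {
    warning(
      "row(s) with fewer than 2 observations or zero variance set to missing: ",
      paste(degenerate, collapse = ", ")
    )
  }
  response_matrix(out,
    compounds = rownames(m) %||% paste0("r", seq_len(nrow(m))),
    lines = colnames(m) %||% paste0("c", seq_len(ncol(m)))
  )
}

#' Log10 transform of raw (non-logged) responses
#'
#' Applies `log10` to positive values; non-positive values cannot be
#' log-transformed and become missing.
#'
#' @param m numeric matrix of raw responses.
#' @return matrix on the log10 scale.
#' @export
log10_transform <- function(m) {
  m <- as.matrix(m)
  m[!is.na(m) & m <= 0] <- NA_real_
  log10(m)
}

#' Threshold z-scores into a binary response matrix
#'
#' A compound "hits" a cell line when its z-scored response exceeds `t`
#' standard deviations (strictly by default). Missing values threshold to 0
#' regardless.
#'
#' @param z z-scored `hs_response` matrix.
#' @param t positive threshold in standard-deviation units (default 2).
#' @param strict require strict exceedance (`> t`); otherwise `>= t`.
#' @return integer 0/1 matrix with the same dimnames.
#' @export
binarize <- function(z, t = 2, strict = TRUE) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0)
  z <- as.matrix(z)
  b <- if (strict) z > t else z >= t
  b[is.na(b)] <- FALSE
  mode(b) <- "integer"
  b
}

#' Per-group hit-count constraints for cell lines
#'
#' Assigns each cell line an `(alpha, beta)` pair via a named group: `alpha`
#' is the minimum number of selected drugs that must hit the line, `beta` the
#' maximum allowed (use `Inf` for no maximum). Targeting experiments are
#' expressed this way, e.g. target lines `(1, Inf)` and all others `(0, 0)`.
#'
#' @param group_of named character vector mapping cell line -> group label.
#' @param bounds named list mapping group label -> numeric `c(alpha, beta)`.
#' @param default_bounds bounds for lines without a group (default
#'   `c(1, Inf)`: every line must be hit at least once).
#' @return a `constraint_spec` list.
#' @export
constraint_spec <- function(group_of = character(), bounds = list(),
                            default_bounds = c(1, Inf)) {
  group_of <- vapply(group_of, as.character, character(1))
  missing_groups <- setdiff(unique(group_of), names(bounds))
  if (length(missing_groups)) {
    stop("group(s) without bounds: ", paste(missing_groups, collapse = ", "))
  }
  for (b in bounds) {
    if (length(b) != 2L || b[1] < 0 || b[2] < b[1]) {
      stop("each bounds entry must be c(alpha, beta) with 0 <= alpha <= beta")
    }
  }
  structure(
    list(group_of = group_of, bounds = bounds, default_bounds = default_bounds),
    class = "constraint_spec"
  )
}

line_bounds <- function(spec, line) {
  g <- spec$group_of[line]
  if (length(g) == 1L && !is.na(g)) spec$bounds[[g]] else spec$default_bounds
}

#' Build a hitting-set instance from a binary response matrix
#'
#' Compounds become drug vertices; each cell line becomes a class whose
#' members are the compounds with a 1 in its column, with `alpha`/`beta`
#' assigned from the constraint specification. Classes with `beta = 0` are
#' retained here (the kernelization removes them together with their
#' forbidden members), and all-zero columns with `alpha >= 1` are surfaced by
#' [validate_instance()] as infeasible rather than silently dropped.
#'
#' @param b 0/1 matrix (compounds x cell lines) from [binarize()].
#' @param spec a [constraint_spec()].
#' @param k hitting-set budget.
#' @return an `hs_instance`.
#' @export
build_instance <- function(b, spec = constraint_spec(), k) {
  b <- as.matrix(b)
  if (!all(b %in% c(0L, 1L))) stop("binary matrix expected (0/1 entries)")
  compounds <- rownames(b) %||% paste0("compound", seq_len(nrow(b)))
  lines <- colnames(b) %||% paste0("line", seq_len(ncol(b)))
  if (anyDuplicated(compounds)) stop("duplicate compound identifiers")
  if (anyDuplicated(lines)) stop("duplicate cell-line identifiers")
  classes <- lapply(seq_along(lines), function(j) {
    bd <- line_bounds(spec, lines[j])
    list(
      id = lines[j],
      members = compounds[b[, j] == 1L],
      alpha = bd[1],
      beta = bd[2]
    )
  })
  hs_instance(compounds, classes, k = k)
}
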