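#' Read and write instances as JSON
#'
#' The interchange schema is
#' `{"drugs": [...], "classes": [{"id", "members", "alpha", "beta"}], "k"}`
#' with `beta: null` denoting "no maximum" (`Inf` in memory). Writing imposes
#' canonical ordering (drugs and members sorted, classes by id) so identical
#' instances serialize byte-identically; reading preserves the file's
#' ordering.
#'
#' @param path JSON file path.
#' @param inst an `hs_instance`.
#' @return `read_instance()`: an `hs_instance`; `write_instance()`: `path`,
#'   invisibly.
#' @name instance_io
NULL

#' @rdname instance_io
#' @export
read_instance <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  faults <- character()
  if (is.null(doc$drugs)) faults <- c(faults, "$.drugs: missing")
  if (is.null(doc$k)) faults <- c(faults, "$.k: missing")
  classes <- lapply(seq_along(doc$classes), function(i) {
    cl <- doc$classes[[i]]
    where <- sprintf("$.classes[%d]", i)
    if (is.null(cl$id)) faults <<- c(faults, paste0(where, ".id: missing"))
    if (is.null(cl$alpha)) faults <<- c(faults, paste0(where, ".alpha: missing"))
    list(
      id = cl$id %||% sprintf("class%d", i),
      members = as.character(unlist(cl$members %||% list())),
      alpha = cl$alpha %||% 0,
      beta = if (is.null(cl$beta)) Inf else cl$beta
    )
  })
  if (length(faults)) stop("instance schema violation(s): ", paste(faults, collapse = "; "))
  inst <- hs_instance(as.character(unlist(doc$drugs)), classes, k = doc$k)
  bad <- validate_instance(inst)
  referential <- grep("undeclared drug", bad, value = TRUE)
  if (length(referential)) {
    stop("instance schema violation(s): ", paste(referential, collapse = "; "))
  }
  inst
}

#' @rdname instance_io
#' @export
write_instance <- function(inst, path) {
  cls <- inst$classes[order(names(inst$classes))]
  doc <- list(
    drugs = sort(inst$drugs),
    classes = lapply(unname(cls), function(cl) {
      list(
        id = jsonlite::unbox(cl$id),
        members = sort(cl$members),
        alpha = jsonlite::unbox(cl$alpha),
        beta = if (is.finite(cl$beta)) jsonlite::unbox(cl$beta) else NULL
      )
    }),
    k = jsonlite::unbox(inst$k)
  )
  writeLines(
    jsonlite::toJSON(doc, null = "null", digits = NA, pretty = TRUE),
    path
  )
  invisible(path)
}

#' Read a response matrix or long-format screen records
#'
#' Wide CSV: first column holds compound identifiers, the header row the
#' cell-line names; empty cells or `NA` are missing. Long TSV: columns
#' `compound`, `cell_line`, `concentration`, `value` for
#' [resolve_duplicates()]. Ragged rows and duplicate headers are errors that
#' name the offending line.
#'
#' @param path input file.
#' @param format `"wide"` or `"long"`.
#' @return wide: an `hs_response` matrix; long: a records data.frame.
#' @export
read_matrix <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    fields <- utils::count.fields(path, sep = ",", quote = "\"")
    if (length(unique(fields)) > 1L) {
      stop(sprintf(
        "ragged CSV: line %d has %d fields, expected %d",
        which(fields != fields[1])[1], fields[which(fields != fields[1])[1]], fields[1]
      ))
    }
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(names(df)[-1])) {
      stop("duplicate cell-line header(s): ",
           paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "))
    }
    vals <- as.matrix(df[, -1, drop = FALSE])
    mode(vals) <- "numeric"
    response_matrix(vals, compounds = df[[1]], lines = names(df)[-1])
  } else {
    fields <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(fields)) > 1L) {
      stop(sprintf("ragged TSV: line %d", which(fields != fields[1])[1]))
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    req <- c("compound", "cell_line", "concentration", "value")
    if (!all(req %in% names(df))) {
      stop("long TSV needs columns: ", paste(req, collapse = ", "))
    }
    df
  }
}

#' Read a constraint specification from its TSV pair
#'
#' The mapping file has columns `cell_line` and `group`; the bounds file has
#' `group`, `alpha`, `beta`, with `beta = "inf"` for no maximum.
#'
#' @param mapping_path,bounds_path TSV file paths.
#' @param default_bounds bounds applied to unmapped lines.
#' @return a [constraint_spec()].
#' @export
read_constraints <- function(mapping_path, bounds_path, default_bounds = c(1, Inf)) {
  map <- utils::read.delim(mapping_path, stringsAsFactors = FALSE)
  bnd <- utils::read.delim(bounds_path, stringsAsFactors = FALSE)
  if (!all(c("cell_line", "group") %in% names(map))) {
    stop("mapping file needs columns cell_line, group")
  }
  if (!all(c("group", "alpha", "beta") %in% names(bnd))) {
    stop("bounds file needs columns group, alpha, beta")
  }
  beta <- ifelse(tolower(trimws(bnd$beta)) %in% c("inf", "infinity"),
    Inf, suppressWarnings(as.numeric(bnd$beta))
  )
  if (anyNA(beta)) stop("unparseable beta in bounds file")
  bounds <- stats::setNames(
    lapply(seq_len(nrow(bnd)), function(i) c(bnd$alpha[i], beta[i])),
    bnd$group
  )
  constraint_spec(
    group_of = stats::setNames(map$group, map$cell_line),
    bounds = bounds,
    default_bounds = default_bounds
  )
}

#' Write a solution as JSON
#'
#' Schema: `{"selected": [...], "size", "objective", "hits": {...},
#' "verdict"}`; deterministic (selected drugs sorted).
#'
#' @param sol an `hs_solution`.
#' @param path output file.
#' @param objective optional objective label recorded in the file.
#' @return `path`, invisibly.
#' @export
write_solution <- function(sol, path, objective = NULL) {
  doc <- list(
    selected = sort(sol$selected),
    size = jsonlite::unbox(if (is.na(sol$size)) -1L else sol$size),
    objective = if (is.null(objective)) NULL else jsonlite::unbox(objective),
    secondary_score = jsonlite::unbox(sol$secondary_score),
    hits = if (is.null(sol$hits)) NULL else {
      lapply(as.list(sol$hits[order(names(sol$hits))]), jsonlite::unbox)
    },
    verdict = jsonlite::unbox(sol$verdict)
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  writeLines(jsonlite::toJSON(doc, null = "null", digits = NA, pretty = TRUE), path)
  invisible(path)
}
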