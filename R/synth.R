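#' Configuration for the synthetic generators
#'
#' One config object drives all three generators. Randomness uses R's
#' Mersenne-Twister stream, seeded explicitly per call and restored
#' afterwards, so generated structures are byte-identical for a given seed
#' across platforms.
#'
#' Instance-mode fields: `n_drugs`, `n_classes`, `d` (maximum class degree),
#' `alpha_range` (integer vector sampled uniformly, clipped to the class
#' degree), `beta_mode` (`"all_unbounded"`, `"mixed"`: unbounded with
#' probability 1/2 else `alpha` plus 0-2, or `"targeting"`: roughly half the
#' classes get their sampled `alpha >= 1` with unbounded `beta`, the rest
#' `alpha = 0, beta = 0`), `k`, `planted_size`.
#'
#' Screen-mode fields: `n_compounds`, `n_lines`, `hit_probability` (per-cell
#' probability of a designated hit; `NULL`, the default, designates exactly
#' one responsive line per compound - the regime in which a 2-SD z-threshold
#' recovers the truth reliably), `effect` (shift of hit cells in SD units),
#' `noise_sd`, `missing_rate`, `dup_fraction` (fraction of observed cells
#' that additionally receive a lower-concentration replicate record).
#'
#' @param seed integer seed (required).
#' @param n_drugs,n_classes,d,alpha_range,beta_mode,k,planted_size instance
#'   generator parameters.
#' @param n_compounds,n_lines,hit_probability,effect,noise_sd,missing_rate,dup_fraction
#'   screen generator parameters.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_drugs = 10L, n_classes = 12L, d = 3L,
                             alpha_range = 0:2,
                             beta_mode = c("all_unbounded", "mixed", "targeting"),
                             k = 4L, planted_size = NULL,
                             n_compounds = 6L, n_lines = 15L,
                             hit_probability = NULL, effect = 5, noise_sd = 1,
                             missing_rate = 0, dup_fraction = 0.2) {
  if (missing(seed)) stop("an explicit integer seed is required")
  beta_mode <- match.arg(beta_mode)
  if (!is.null(planted_size) && planted_size > n_drugs) {
    stop("planted_size cannot exceed n_drugs")
  }
  if (d < 1L) stop("d must be at least 1")
  structure(
    list(
      seed = as.integer(seed),
      n_drugs = n_drugs, n_classes = n_classes, d = d,
      alpha_range = alpha_range, beta_mode = beta_mode, k = k,
      planted_size = planted_size,
      n_compounds = n_compounds, n_lines = n_lines,
      hit_probability = hit_probability, effect = effect, noise_sd = noise_sd,
      missing_rate = missing_rate, dup_fraction = dup_fraction
    ),
    class = "generator_config"
  )
}

## sample() that never falls into the scalar-x "sample from 1:x" trap
resample <- function(x, n) x[sample.int(length(x), n)]

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a random instance
#'
#' Classes draw a degree uniformly from `1..d`, members without replacement
#' from the drugs, `alpha` uniformly from `alpha_range` clipped to the
#' degree, and `beta` according to `beta_mode`. Fully determined by the seed.
#'
#' @param cfg a [generator_config()].
#' @return an `hs_instance`.
#' @export
random_instance <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_drugs < 1L) stop("need at least one drug to build class member sets")
  with_seed(cfg$seed, {
    drugs <- sprintf("v%02d", seq_len(cfg$n_drugs))
    classes <- lapply(seq_len(cfg$n_classes), function(i) {
      deg <- sample.int(min(cfg$d, cfg$n_drugs), 1L)
      members <- sort(resample(drugs, deg))
      alpha <- min(resample(cfg$alpha_range, 1L), deg)
      beta <- switch(cfg$beta_mode,
        all_unbounded = Inf,
        mixed = if (stats::runif(1) < 0.5) Inf else alpha + resample(0:2, 1L),
        targeting = Inf # resolved below
      )
      cl <- list(id = sprintf("c%02d", i), members = members, alpha = alpha, beta = beta)
      if (cfg$beta_mode == "targeting") {
        if (stats::runif(1) < 0.5) {
          cl$alpha <- max(1, alpha) # target class: must be hit
        } else {
          cl$alpha <- 0
          cl$beta <- 0 # off-target class: must not be hit
        }
      }
      cl
    })
    hs_instance(drugs, classes, k = cfg$k)
  })
}

#' Generate an instance with a planted solution
#'
#' A planted drug set `P` of size `planted_size` is chosen first; every class
#' then receives at least `alpha` of its members from `P`, so `P` is feasible
#' and the instance is a Yes-instance for `k = planted_size`. All `beta` are
#' unbounded in planted mode.
#'
#' @param cfg a [generator_config()] with `planted_size` set.
#' @return list with `instance` (an `hs_instance` with `k = planted_size`)
#'   and `planted` (the planted drug set, sorted).
#' @export
planted_instance <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(cfg$planted_size)) stop("planted_size must be set")
  with_seed(cfg$seed, {
    drugs <- sprintf("v%02d", seq_len(cfg$n_drugs))
    planted <- sort(sample(drugs, cfg$planted_size))
    amax <- min(max(cfg$alpha_range), cfg$d, cfg$planted_size)
    classes <- lapply(seq_len(cfg$n_classes), function(i) {
      alpha <- min(resample(cfg$alpha_range, 1L), amax)
      if (alpha > cfg$planted_size) stop("alpha exceeds planted_size")
      deg <- resample(seq(max(alpha, 1L), cfg$d), 1L)
      from_p <- resample(planted, alpha)
      rest <- resample(setdiff(drugs, from_p), deg - alpha)
      list(
        id = sprintf("c%02d", i),
        members = sort(c(from_p, rest)), alpha = alpha, beta = Inf
      )
    })
    list(
      instance = hs_instance(drugs, classes, k = cfg$planted_size),
      planted = planted
    )
  })
}

#' Generate a screen-like set of response records with known truth
#'
#' Emulates a long-format GI50 export: baseline responses are normal with
#' mean 0 and SD `noise_sd`; designated hit cells are shifted upward by
#' `effect` (in SD units). Cells masked missing produce no record. A
#' `dup_fraction` of observed cells additionally receive a lower-concentration
#' replicate whose value carries no effect, so duplicate resolution by
#' highest concentration is genuinely exercised: keeping the wrong record
#' would lose the hit.
#'
#' @param cfg a [generator_config()].
#' @return list with `records` (data.frame `compound`, `cell_line`,
#'   `concentration`, `value`), `truth` (the intended 0/1 matrix after
#'   thresholding), and `cfg`.
#' @export
screen_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    compounds <- sprintf("NSC%03d", seq_len(cfg$n_compounds))
    lines <- sprintf("LINE%02d", seq_len(cfg$n_lines))
    truth <- matrix(0L, cfg$n_compounds, cfg$n_lines,
      dimnames = list(compounds, lines)
    )
    if (is.null(cfg$hit_probability)) {
      for (i in seq_len(cfg$n_compounds)) truth[i, sample.int(cfg$n_lines, 1L)] <- 1L
    } else {
      truth[] <- stats::rbinom(length(truth), 1L, cfg$hit_probability)
    }
    values <- matrix(
      stats::rnorm(length(truth), 0, cfg$noise_sd),
      cfg$n_compounds, cfg$n_lines
    ) + truth * cfg$effect
    observed <- matrix(
      stats::runif(length(truth)) >= cfg$missing_rate,
      cfg$n_compounds, cfg$n_lines
    )
    truth[!observed] <- 0L # a masked cell cannot become an edge

    idx <- which(observed, arr.ind = TRUE)
    records <- data.frame(
      compound = compounds[idx[, 1]],
      cell_line = lines[idx[, 2]],
      concentration = rep(100, nrow(idx)),
      value = values[idx],
      stringsAsFactors = FALSE
    )
    dup <- which(stats::runif(nrow(records)) < cfg$dup_fraction)
    if (length(dup)) {
      decoys <- data.frame(
        compound = records$compound[dup],
        cell_line = records$cell_line[dup],
        concentration = 50,
        value = stats::rnorm(length(dup), 0, cfg$noise_sd),
        stringsAsFactors = FALSE
      )
      records <- rbind(records, decoys)
    }
    list(records = records, truth = truth, cfg = cfg)
  })
}
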