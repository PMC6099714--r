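#' Damped atom-atom dispersion (EDas-type potential)
#'
#' Approximate dispersion energy from pairwise atom-atom potentials of the
#' form -f6(bR) C6/R^6 [- f8(bR) C8/R^8], with Tang-Toennies damping
#' f_n(x) = 1 - exp(-x) * sum_{k=0..n} x^k / k!. The damping removes the
#' unphysical short-range divergence of the bare dispersion series; beyond
#' the damping radius the potential recovers the -C6/R^6 asymptote. The
#' functional form and parameters are configuration: they are supplied per
#' unordered element pair, optionally with a geometric-mean combining rule
#' over per-element coefficients.
#'
#' @name das-dispersion
NULL

#' Tang-Toennies damping function
#'
#' `f_n(x) = 1 - exp(-x) * sum_{k=0..n} x^k/k!`, computed as the upper tail
#' of a Poisson distribution (`ppois(n, x, lower.tail = FALSE)`), which is
#' exact and stable for large `x`.
#'
#' @param n integer order (6 for the C6 term, 8 for the C8 term).
#' @param x numeric, `beta * R` (dimensionless).
#' @return numeric in \[0, 1\].
#' @export
tang_toennies <- function(n, x) {
  stats::ppois(n, x, lower.tail = FALSE)
}

#' Dispersion parameter table
#'
#' @param pairs `data.frame` with columns `elem1`, `elem2`, `c6`
#'   (kcal/mol*A^6, >= 0), optional `c8` (kcal/mol*A^8) and `beta`
#'   (1/A, > 0). Pairs are unordered.
#' @param fallback optional named list with per-element `c6` (named numeric)
#'   and scalar `beta` (and optionally per-element `c8`); element pairs
#'   absent from `pairs` then use geometric-mean combination
#'   `c6_ij = sqrt(c6_i * c6_j)`.
#' @return list with class `"dispersion_params"`.
#' @export
dispersion_params <- function(pairs = NULL, fallback = NULL) {
  if (!is.null(pairs)) {
    stopifnot(all(c("elem1", "elem2", "c6", "beta") %in% names(pairs)))
    if (any(pairs$c6 < 0)) stop("c6 must be non-negative")
    if (any(pairs$beta <= 0)) stop("damping beta must be positive")
    if (!"c8" %in% names(pairs)) pairs$c8 <- NA_real_
  }
  if (!is.null(fallback)) {
    stopifnot(is.numeric(fallback$c6), !is.null(names(fallback$c6)),
              is.numeric(fallback$beta), fallback$beta > 0)
    if (any(fallback$c6 < 0)) stop("fallback c6 must be non-negative")
  }
  structure(list(pairs = pairs, fallback = fallback),
            class = "dispersion_params")
}

.lookup_pair <- function(params, e1, e2) {
  p <- params$pairs
  if (!is.null(p)) {
    hit <- which((p$elem1 == e1 & p$elem2 == e2) |
                 (p$elem1 == e2 & p$elem2 == e1))
    if (length(hit) > 0L) {
      row <- p[hit[1L], ]
      return(list(c6 = row$c6, c8 = row$c8, beta = row$beta))
    }
  }
  fb <- params$fallback
  if (!is.null(fb) && all(c(e1, e2) %in% names(fb$c6))) {
    c8 <- NA_real_
    if (!is.null(fb$c8) && all(c(e1, e2) %in% names(fb$c8)))
      c8 <- sqrt(fb$c8[[e1]] * fb$c8[[e2]])
    return(list(c6 = sqrt(fb$c6[[e1]] * fb$c6[[e2]]), c8 = c8,
                beta = fb$beta))
  }
  stop("no dispersion parameters for element pair ", e1, "-", e2)
}

#' Damped atom-atom dispersion energy between two molecules
#'
#' @param coords_a,coords_b `data.frame`s with columns `element`, `x`, `y`,
#'   `z` (Angstrom), one row per atom.
#' @param params a [dispersion_params()] table.
#' @return energy in kcal/mol (always <= 0; tends to 0 as all
#'   inter-molecular distances grow).
#' @export
das_dispersion <- function(coords_a, coords_b, params) {
  stopifnot(inherits(params, "dispersion_params"))
  xa <- as.matrix(coords_a[, c("x", "y", "z")])
  xb <- as.matrix(coords_b[, c("x", "y", "z")])
  e <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    pp <- .lookup_pair(params, coords_a$element[i], coords_b$element[j])
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    e <- e - tang_toennies(6L, pp$beta * r) * pp$c6 / r^6
    if (!is.na(pp$c8))
      e <- e - tang_toennies(8L, pp$beta * r) * pp$c8 / r^8
  }
  e
}

#' Read or write dispersion parameters as YAML/JSON
#'
#' The on-disk form is a list with a `pairs` table (fields `elem1`, `elem2`,
#' `c6`, optional `c8`, `beta`) and an optional `fallback` block with
#' per-element `c6` and a scalar `beta`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a [dispersion_params()] object.
#' @export
read_dispersion_params <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  pairs <- if (!is.null(raw$pairs))
    as.data.frame(lapply(raw$pairs, unlist), stringsAsFactors = FALSE)
  fb <- raw$fallback
  if (!is.null(fb)) {
    fb$c6 <- unlist(fb$c6)
    fb$beta <- as.numeric(fb$beta)
    if (!is.null(fb$c8)) fb$c8 <- unlist(fb$c8)
  }
  dispersion_params(pairs = pairs, fallback = fb)
}

#' @rdname read_dispersion_params
#' @param params a [dispersion_params()] object.
#' @export
write_dispersion_params <- function(params, path) {
  out <- list()
  if (!is.null(params$pairs)) out$pairs <- params$pairs
  if (!is.null(params$fallback))
    out$fallback <- list(c6 = as.list(params$fallback$c6),
                         beta = params$fallback$beta,
                         c8 = if (!is.null(params$fallback$c8))
                           as.list(params$fallback$c8))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}
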