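#' Solvation-free-energy applicability screen
#'
#' Interaction-energy-only models of inhibitory activity neglect solvation,
#' so they are applicable only to ligand sets whose solvation free energies
#' are similar. The screen computes the sample standard deviation of
#' the ligands' continuum-solvent solvation free energies, compares it
#' against reference systems where the long-range composite model has known
#' performance, and supports re-evaluating the ranking statistics on a
#' reduced ligand set from which the solvation outliers are removed.
#'
#' @name solvation-screen
NULL

#' Sample standard deviation
#'
#' Standard deviation with the n-1 denominator, as used for the
#' solvation-free-energy spread of a ligand set.
#'
#' @param values numeric vector (kcal/mol), length >= 2.
#' @return standard deviation, kcal/mol.
#' @export
sample_sd <- function(values) {
  if (length(values) < 2L)
    stop("at least 2 values are required for a sample standard deviation")
  stats::sd(values)
}

#' Check solvation-record consistency
#'
#' The solvation free energy must equal the sum of its electrostatic and
#' non-electrostatic parts (within a printed-rounding tolerance), and for
#' this ligand class the non-electrostatic (cavitation-dominated) part is
#' non-negative.
#'
#' @param records `data.frame` with `ligand_id`, `dg_solv`, `dg_solv_el`,
#'   `dg_solv_nonel` (kcal/mol).
#' @param tol additivity tolerance, kcal/mol (default 0.15 for one-decimal
#'   printed data).
#' @param check_nonel_sign logical, also flag negative non-electrostatic
#'   parts.
#' @return `data.frame` of violations (`ligand_id`, `check`, `residual`);
#'   zero rows when consistent.
#' @export
validate_solvation <- function(records, tol = 0.15,
                               check_nonel_sign = TRUE) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    resid <- abs(records$dg_solv[i] -
                 (records$dg_solv_el[i] + records$dg_solv_nonel[i]))
    if (resid > tol)
      out[[length(out) + 1L]] <-
        data.frame(ligand_id = records$ligand_id[i],
                   check = "el + nonel additivity", residual = resid,
                   stringsAsFactors = FALSE)
    if (check_nonel_sign && records$dg_solv_nonel[i] < 0)
      out[[length(out) + 1L]] <-
        data.frame(ligand_id = records$ligand_id[i],
                   check = "non-electrostatic part negative",
                   residual = abs(records$dg_solv_nonel[i]),
                   stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(ligand_id = character(0), check = character(0),
                      residual = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Select a reduced ligand set by solvation-outlier removal
#'
#' Either removes an explicit list of ligands (the reproduction mode) or
#' applies the rule variant: remove the `k` ligands whose solvation free
#' energy is farthest from the set median. The explicit-list mode is the
#' default because outlier choice by eye is how reduced sets are reported;
#' the rule variant makes that choice algorithmic but is not guaranteed to
#' reproduce a hand-picked list.
#'
#' @param records solvation `data.frame` (`ligand_id`, `dg_solv`, ...).
#' @param exclusions character vector of ligand ids to drop, or
#'   `list(k = <int>)` for the median-distance rule.
#' @return list with `kept` (ligand ids), `excluded`, `sd_before`,
#'   `sd_after` (kcal/mol).
#' @export
select_reduced_set <- function(records, exclusions) {
  ids <- as.character(records$ligand_id)
  dg <- stats::setNames(records$dg_solv, ids)
  if (is.list(exclusions) && !is.null(exclusions$k)) {
    k <- as.integer(exclusions$k)
    dev <- abs(dg - stats::median(dg))
    ord <- order(-dev, names(dev))   # largest deviation first, id tie-break
    excl <- names(dev)[ord][seq_len(k)]
  } else {
    excl <- as.character(unlist(exclusions))
    unknown <- setdiff(excl, ids)
    if (length(unknown) > 0L)
      stop("exclusion list contains unknown ligand(s): ",
           paste(unknown, collapse = ", "))
  }
  kept <- setdiff(ids, excl)
  if (length(kept) < 3L)
    stop("over-exclusion: fewer than 3 ligands would remain")
  list(kept = kept, excluded = excl,
       sd_before = sample_sd(dg),
       sd_after = sample_sd(dg[kept]))
}

#' Packaged reference solvation-free-energy spreads
#'
#' Sample standard deviations of the ligand solvation free energies for
#' systems where the long-range composite model was previously benchmarked:
#' menin-MLL (18 inhibitors), FAAH (22) and TbPTR1 (6).
#'
#' @return named numeric vector, kcal/mol.
#' @export
reference_solvation_sds <- function() {
  ref <- eph_fixture("table4_reference_sds")
  ref <- ref[ref$system != "EphA2-ephrin A1", ]
  stats::setNames(ref$sd, ref$system)
}

#' Applicability verdict from the solvation-free-energy spread
#'
#' Computes the sample SD of the set's solvation free energies and compares
#' it with the reference systems: the spread is `"elevated"` (model
#' applicability doubtful) when it exceeds every reference value, otherwise
#' `"comparable"`.
#'
#' @param records solvation `data.frame`.
#' @param reference_sds named numeric vector of reference SDs (kcal/mol);
#'   defaults to [reference_solvation_sds()].
#' @return list with `sd`, `n`, `reference_sds`, `verdict`.
#' @export
applicability_index <- function(records,
                                reference_sds = reference_solvation_sds()) {
  sd_val <- sample_sd(records$dg_solv)
  list(sd = sd_val, n = nrow(records), reference_sds = reference_sds,
       verdict = if (sd_val > max(reference_sds)) "elevated"
                 else "comparable")
}

#' Screen by solvation and re-evaluate on the reduced set
#'
#' Runs [evaluate_model()] on the full ligand set and again on the reduced
#' set obtained from [select_reduced_set()], and reports per-column deltas.
#'
#' @param levels level table (`ligand_id` plus energy columns).
#' @param activities activity table (`ligand_id`, `pic50`).
#' @param solvation solvation table (`ligand_id`, `dg_solv`, ...).
#' @param exclusions as in [select_reduced_set()].
#' @return list with `full`, `reduced` (evaluation tables), `delta`
#'   (`column`, `delta_r`, `delta_npred`), `kept`, `excluded`,
#'   `sd_before`, `sd_after`.
#' @export
screen_and_reevaluate <- function(levels, activities, solvation,
                                  exclusions = character(0)) {
  ids_l <- as.character(levels$ligand_id)
  ids_a <- as.character(activities$ligand_id)
  ids_s <- as.character(solvation$ligand_id)
  orphan <- c(setdiff(ids_l, ids_a), setdiff(ids_a, ids_l),
              setdiff(ids_s, ids_a))
  if (length(orphan) > 0L)
    stop("tables do not share ligand IDs; orphan id(s): ",
         paste(unique(orphan), collapse = ", "))
  full <- evaluate_model(levels, activities)
  if (length(exclusions) == 0L) {
    sel <- list(kept = ids_l, excluded = character(0),
                sd_before = sample_sd(solvation$dg_solv),
                sd_after = sample_sd(solvation$dg_solv))
  } else {
    sel <- select_reduced_set(solvation, exclusions)
  }
  keep <- as.character(levels$ligand_id) %in% sel$kept
  reduced <- evaluate_model(levels[keep, , drop = FALSE],
                            activities[ids_a %in% sel$kept, , drop = FALSE])
  delta <- data.frame(column = full$column,
                      delta_r = reduced$r - full$r,
                      delta_npred = reduced$npred_percent -
                        full$npred_percent,
                      stringsAsFactors = FALSE)
  list(full = full, reduced = reduced, delta = delta,
       kept = sel$kept, excluded = sel$excluded,
       sd_before = sel$sd_before, sd_after = sel$sd_after)
}
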