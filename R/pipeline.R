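#' Run configuration for the scoring pipeline
#'
#' @param levels level table (`data.frame`) or path to a level CSV.
#' @param activities activity table or path.
#' @param solvation solvation table or path.
#' @param columns character vector of level columns to evaluate (default:
#'   all numeric columns of the level table).
#' @param exclusions ligand ids to drop for the reduced-set re-evaluation,
#'   or `list(k = <int>)` for the median-distance rule; `character(0)`
#'   disables the reduction.
#' @param tol rounding tolerance for consistency validation, kcal/mol.
#' @param out_dir optional output directory for the report bundle.
#' @return list with class `"run_config"`.
#' @export
run_config <- function(levels, activities, solvation,
                       columns = NULL,
                       exclusions = c("20", "7", "2", "18"),
                       tol = 0.15, out_dir = NULL) {
  load_tbl <- function(x, reader) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("input file does not exist: ", x)
      reader(x)
    } else x
  }
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(levels = load_tbl(levels, read_level_table),
                 activities = load_tbl(activities, read_activities),
                 solvation = load_tbl(solvation, read_solvation),
                 columns = columns, exclusions = exclusions,
                 tol = tol, out_dir = out_dir),
            class = "run_config")
}

#' Run the full evaluate / screen / re-evaluate pipeline
#'
#' Validates the ledger and solvation tables, evaluates every requested
#' score column on the full ligand set, runs the solvation applicability
#' screen, re-evaluates on the reduced set, and (when an output directory is
#' configured) writes a report bundle of CSV and plain-text tables.
#'
#' @param config a [run_config()].
#' @param verbose logical, log validation and tolerance decisions to
#'   standard error.
#' @return list with `evaluation` (full-set table), `screen` (as from
#'   [screen_and_reevaluate()]), `applicability`, `validation` (list of
#'   violation tables), `ok` (logical, no violations found).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  note <- function(...) if (verbose) message(...)
  levels <- config$levels
  if (!is.null(config$columns))
    levels <- levels[, c("ligand_id", config$columns), drop = FALSE]
  comp <- levels_to_components(config$levels)
  note("validating decomposition at tol = ", config$tol, " kcal/mol")
  v_dec <- validate_decomposition(comp, config$levels, tol = config$tol)
  v_sol <- validate_solvation(config$solvation, tol = config$tol)
  evaluation <- evaluate_model(levels, config$activities)
  screen <- screen_and_reevaluate(levels, config$activities,
                                  config$solvation, config$exclusions)
  appl <- applicability_index(config$solvation)
  note("solvation spread ", signif(appl$sd, 3), " kcal/mol (",
       appl$verdict, ")")
  out <- list(evaluation = evaluation, screen = screen,
              applicability = appl,
              validation = list(decomposition = v_dec, solvation = v_sol),
              ok = nrow(v_dec) == 0L && nrow(v_sol) == 0L)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(evaluation,
                    file.path(config$out_dir, "evaluation_full.csv"))
    write_table_csv(screen$reduced,
                    file.path(config$out_dir, "evaluation_reduced.csv"))
    writeLines(format_report(out),
               file.path(config$out_dir, "report.txt"))
  }
  out
}

#' Plain-text report of a pipeline result
#'
#' @param result list returned by [run_pipeline()].
#' @return character vector of report lines.
#' @export
format_report <- function(result) {
  fmt_eval <- function(df) {
    if (nrow(df) == 0L) return("  (no score columns)")
    sprintf("  %-18s R = %6.2f  Npred = %5.1f%% (%d/%d)  SE = %5.1f",
            df$column, df$r, df$npred_percent, df$n_pairs_concordant,
            df$n_pairs_total - df$n_pairs_excluded_ties, df$se)
  }
  appl <- result$applicability
  c("Full ligand set:", fmt_eval(result$evaluation),
    "",
    sprintf("Solvation spread: %.2f kcal/mol over %d ligands (%s; refs: %s)",
            appl$sd, appl$n, appl$verdict,
            paste(sprintf("%s %.1f", names(appl$reference_sds),
                          appl$reference_sds), collapse = ", ")),
    sprintf("Reduced set (%d kept, excluded: %s): SD %.2f -> %.2f kcal/mol",
            length(result$screen$kept),
            if (length(result$screen$excluded) == 0L) "none" else
              paste(result$screen$excluded, collapse = ", "),
            result$screen$sd_before, result$screen$sd_after),
    fmt_eval(result$screen$reduced))
}

#' Reproduce the packaged-study workflow
#'
#' Runs the full pipeline on the packaged tables with the published
#' exclusion list (ligands 20, 7, 2 and 18), the standard route to the
#' headline statistics of the analysis.
#'
#' @param out_dir optional report directory.
#' @param verbose logical.
#' @return as [run_pipeline()].
#' @export
reproduce_study <- function(out_dir = NULL, verbose = FALSE) {
  cfg <- run_config(levels = eph_fixture("table2_levels"),
                    activities = eph_fixture("table1_activities"),
                    solvation = eph_fixture("table3_solvation"),
                    exclusions = c("20", "7", "2", "18"),
                    out_dir = out_dir)
  run_pipeline(cfg, verbose = verbose)
}
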