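#' Ranking statistics for score columns against inhibitory activities
#'
#' Three statistics summarise how well one score column ranks a congeneric
#' inhibitor series against experimental pIC50 values:
#' \itemize{
#'   \item Pearson correlation R between raw score and pIC50, with
#'     orientation handling: columns where a higher score means greater
#'     predicted potency are sign-flipped, so a more negative R uniformly
#'     means a better ranking.
#'   \item Npred, the concordant-pair success rate: the percentage of
#'     unordered inhibitor pairs whose predicted stability ordering agrees
#'     with the experimental activity ordering. Pairs with exactly equal
#'     experimental pIC50 are excluded from the denominator; pairs the score
#'     cannot order (exact predicted ties) count as failures.
#'   \item SE, the standard error of estimate of the least-squares fit of
#'     the energy on pIC50, `sqrt(SS_res / (n - 2))`, in kcal/mol for
#'     energy-like columns.
#' }
#'
#' @name ranking-stats
NULL

#' Construct a score column
#'
#' @param name column label.
#' @param values named numeric vector, ligand id -> score.
#' @param orientation `"lower_is_better"` (energies: more negative = more
#'   potent) or `"higher_is_better"` (most empirical scoring functions).
#' @return list with class `"score_column"`.
#' @export
score_column <- function(name, values,
                         orientation = c("lower_is_better",
                                         "higher_is_better")) {
  orientation <- match.arg(orientation)
  if (is.null(names(values)))
    stop("score values must be named by ligand id")
  if (any(!is.finite(values)))
    stop("score values must be finite")
  structure(list(name = name, values = values, orientation = orientation),
            class = "score_column")
}

# align a score column with activities; returns list(s, a) in matching order
.align_scores <- function(scores, activities) {
  stopifnot(inherits(scores, "score_column"))
  ids <- as.character(activities$ligand_id)
  miss <- setdiff(ids, names(scores$values))
  if (length(miss) > 0L)
    stop("score column '", scores$name, "' lacks ligand(s): ",
         paste(miss, collapse = ", "))
  list(s = unname(scores$values[ids]), a = activities$pic50, ids = ids)
}

#' Pearson correlation of a score column with activities
#'
#' @param scores a [score_column()].
#' @param activities `data.frame` with `ligand_id` and `pic50`.
#' @return Pearson R; negated for `higher_is_better` columns so that a more
#'   negative value always indicates a better ranking.
#' @export
pearson_r <- function(scores, activities) {
  al <- .align_scores(scores, activities)
  if (length(al$s) < 3L) stop("at least 3 ligands are required")
  if (stats::var(al$s) == 0 || stats::var(al$a) == 0)
    stop("degenerate column: zero variance")
  r <- stats::cor(al$s, al$a)
  if (scores$orientation == "higher_is_better") r <- -r
  r
}

#' Concordant-pair success rate (Npred)
#'
#' Enumerates all unordered ligand pairs. Pairs with exactly equal pIC50 are
#' excluded from the denominator. After normalising the score to
#' lower-is-better, a pair is concordant when the lower (better) score
#' belongs to the ligand with the higher pIC50; exact predicted-score ties
#' are counted as non-concordant.
#'
#' @inheritParams pearson_r
#' @return list with `npred_percent`, `n_pairs_total`,
#'   `n_pairs_excluded_ties`, `n_pairs_concordant`.
#' @export
npred <- function(scores, activities) {
  al <- .align_scores(scores, activities)
  n <- length(al$s)
  if (n < 2L) stop("at least 2 ligands are required")
  s <- if (scores$orientation == "higher_is_better") -al$s else al$s
  a <- al$a
  total <- 0L; excluded <- 0L; concordant <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    total <- total + 1L
    if (a[i] == a[j]) { excluded <- excluded + 1L; next }
    if (sign(s[i] - s[j]) == -sign(a[i] - a[j]))
      concordant <- concordant + 1L
  }
  list(npred_percent = 100 * concordant / (total - excluded),
       n_pairs_total = total,
       n_pairs_excluded_ties = excluded,
       n_pairs_concordant = concordant)
}

#' Standard error of estimate of an energy-activity regression
#'
#' Ordinary least squares with the energy as dependent variable and pIC50 as
#' regressor; `se = sqrt(SS_res / (n - 2))`, reported in the units of the
#' score (kcal/mol for energies).
#'
#' @inheritParams pearson_r
#' @return standard error of estimate.
#' @export
standard_error_estimate <- function(scores, activities) {
  al <- .align_scores(scores, activities)
  if (length(al$s) < 3L) stop("at least 3 ligands are required")
  if (stats::var(al$a) == 0) stop("degenerate activities: zero variance")
  fit <- stats::lm(al$s ~ al$a)
  sqrt(sum(stats::resid(fit)^2) / (length(al$s) - 2L))
}

#' Evaluate a set of score columns against activities
#'
#' Applies [pearson_r()], [npred()] and [standard_error_estimate()] to each
#' column. A level table (as from [compose_levels_all()] or
#' [eph_fixture()]`("table2_levels")`) may be passed directly: each level
#' column becomes an energy-like, lower-is-better score column.
#'
#' @param columns a named list of [score_column()]s, or a `data.frame` with
#'   `ligand_id` plus numeric score columns (treated as lower-is-better
#'   energies).
#' @param activities `data.frame` with `ligand_id` and `pic50`.
#' @param se logical, compute the standard error of estimate (disable for
#'   dimensionless columns).
#' @return `data.frame`, one row per column ordered by column name, with
#'   `column`, `r`, `r_squared`, `npred_percent`, `n_pairs_total`,
#'   `n_pairs_excluded_ties`, `n_pairs_concordant`, `se`.
#' @export
evaluate_model <- function(columns, activities, se = TRUE) {
  if (is.data.frame(columns)) {
    num <- setdiff(names(columns)[vapply(columns, is.numeric, TRUE)],
                   "ligand_id")
    columns <- stats::setNames(lapply(num, function(cn)
      score_column(cn, stats::setNames(columns[[cn]],
                                       as.character(columns$ligand_id)),
                   orientation = "lower_is_better")), num)
  }
  if (length(columns) == 0L)
    return(data.frame(column = character(0), r = numeric(0),
                      r_squared = numeric(0), npred_percent = numeric(0),
                      n_pairs_total = integer(0),
                      n_pairs_excluded_ties = integer(0),
                      n_pairs_concordant = integer(0), se = numeric(0),
                      stringsAsFactors = FALSE))
  nm <- sort(names(columns))
  rows <- lapply(nm, function(cn) {
    sc <- columns[[cn]]
    r <- pearson_r(sc, activities)
    np <- npred(sc, activities)
    data.frame(column = cn, r = r, r_squared = r^2,
               npred_percent = np$npred_percent,
               n_pairs_total = np$n_pairs_total,
               n_pairs_excluded_ties = np$n_pairs_excluded_ties,
               n_pairs_concordant = np$n_pairs_concordant,
               se = if (se) standard_error_estimate(sc, activities)
                    else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
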