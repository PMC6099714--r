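#' HVPT interaction-energy ledger
#'
#' The hybrid variation-perturbation theory (HVPT) scheme partitions the
#' second-order Moller-Plesset interaction energy of a receptor-ligand
#' complex into multipole electrostatic, penetration, exchange,
#' delocalization and correlation components, arranged in levels of
#' increasing computational cost:
#'
#' \deqn{E_{EL,MTP}^{(10)} \rightarrow E_{EL}^{(10)} \rightarrow E^{(10)}
#'       \rightarrow E_{SCF} \rightarrow E_{MP2}}
#'
#' Each level adds one component to the previous one. An approximate
#' dispersion term (EDas, from fitted atom-atom potentials) can replace the
#' expensive correlation term, giving the long-range composite
#' \eqn{E_{EL,MTP}^{(10)} + E_{Das}}. All energies are in kcal/mol.
#'
#' @name hvpt-ledger
NULL

.hvpt_components <- c("eel_mtp", "eel_pen", "eex", "edel", "ecorr", "edas")
.hvpt_levels <- c("eel_mtp10", "eel10", "e10", "escf", "emp2",
                  "eelmtp_plus_edas")

#' Construct a table of per-residue-group HVPT components
#'
#' Builds and validates the component table that feeds [compose_levels()].
#' One row holds the interaction-energy components between one ligand and one
#' residue group of the binding-site model.
#'
#' @param ligand_id character, ligand identifiers (recycled if length 1).
#' @param residue_group character, residue-group labels (e.g. `"Arg103"`,
#'   `"Cys70-Cys188"`).
#' @param eel_mtp,eel_pen,eex,edel,ecorr numeric, energy components in
#'   kcal/mol: multipole electrostatic, electrostatic penetration, exchange
#'   repulsion, delocalization and correlation.
#' @param edas numeric or `NA`, approximate dispersion (kcal/mol); optional
#'   per record.
#' @return A `data.frame` with class `"hvpt_terms"`.
#' @seealso [compose_levels()], [validate_decomposition()]
#' @export
hvpt_terms <- function(ligand_id, residue_group, eel_mtp, eel_pen, eex,
                       edel, ecorr, edas = NA_real_) {
  if (length(ligand_id) == 0L) edas <- numeric(0)
  df <- data.frame(ligand_id = as.character(ligand_id),
                   residue_group = as.character(residue_group),
                   eel_mtp = as.numeric(eel_mtp),
                   eel_pen = as.numeric(eel_pen),
                   eex = as.numeric(eex),
                   edel = as.numeric(edel),
                   ecorr = as.numeric(ecorr),
                   edas = as.numeric(edas),
                   stringsAsFactors = FALSE)
  class(df) <- c("hvpt_terms", "data.frame")
  df
}

#' @rdname hvpt_terms
#' @param x a data.frame with the component columns.
#' @export
as_hvpt_terms <- function(x) {
  need <- c("ligand_id", "residue_group", "eel_mtp", "eel_pen", "eex",
            "edel", "ecorr")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("missing component field(s): ", paste(miss, collapse = ", "))
  if (!"edas" %in% names(x)) x$edas <- NA_real_
  hvpt_terms(x$ligand_id, x$residue_group, x$eel_mtp, x$eel_pen, x$eex,
             x$edel, x$ecorr, x$edas)
}

#' Default residue grouping of the EphA2 binding-site model
#'
#' The six-residue binding-site model groups the disulfide-bonded cysteines
#' and the sequence-adjacent Val/Met pair into dimers; the charged Arg103 and
#' the aromatic Phe108 interact as single residues.
#'
#' @return Named list mapping group label to the residues it contains.
#' @export
binding_site_groups <- function() {
  list("Arg103" = "Arg103",
       "Cys70-Cys188" = c("Cys70", "Cys188"),
       "Val72-Met73" = c("Val72", "Met73"),
       "Phe108" = "Phe108")
}

#' Compose HVPT theory-level totals from components
#'
#' Sums the per-residue-group components of a single ligand and accumulates
#' them into the consecutive theory levels:
#' \itemize{
#'   \item `eel_mtp10` = sum of `eel_mtp`
#'   \item `eel10` = `eel_mtp10` + total penetration
#'   \item `e10` = `eel10` + total exchange (first-order Heitler-London)
#'   \item `escf` = `e10` + total delocalization
#'   \item `emp2` = `escf` + total correlation
#'   \item `eelmtp_plus_edas` = `eel_mtp10` + total approximate dispersion
#'     (only when every record carries `edas`)
#' }
#'
#' @param terms an [hvpt_terms()] table for exactly one ligand.
#' @return One-row `data.frame` with `ligand_id` and the six level columns
#'   (kcal/mol).
#' @examples
#' t20 <- hvpt_terms("20", "total", eel_mtp = -89.2, eel_pen = -12.1,
#'                   eex = 34.8, edel = -17.0, ecorr = -19.2)
#' compose_levels(t20)
#' @export
compose_levels <- function(terms) {
  terms <- as_hvpt_terms(terms)
  if (nrow(terms) == 0L)
    stop("at least one component record is required")
  ids <- unique(terms$ligand_id)
  if (length(ids) != 1L)
    stop("mixed ligand IDs in component table: ",
         paste(ids, collapse = ", "))
  for (f in c("eel_mtp", "eel_pen", "eex", "edel", "ecorr"))
    if (anyNA(terms[[f]]))
      stop("missing component field: ", f)
  eel_mtp10 <- sum(terms$eel_mtp)
  eel10 <- eel_mtp10 + sum(terms$eel_pen)
  e10 <- eel10 + sum(terms$eex)
  escf <- e10 + sum(terms$edel)
  emp2 <- escf + sum(terms$ecorr)
  eelmtp_plus_edas <- if (anyNA(terms$edas)) NA_real_ else
    eel_mtp10 + sum(terms$edas)
  data.frame(ligand_id = ids, eel_mtp10 = eel_mtp10, eel10 = eel10,
             e10 = e10, escf = escf, emp2 = emp2,
             eelmtp_plus_edas = eelmtp_plus_edas,
             stringsAsFactors = FALSE)
}

#' Compose levels for every ligand in a component table
#'
#' @param terms an [hvpt_terms()] table, any number of ligands.
#' @return `data.frame` with one row per ligand, ordered as first seen.
#' @export
compose_levels_all <- function(terms) {
  terms <- as_hvpt_terms(terms)
  ids <- unique(terms$ligand_id)
  out <- lapply(ids, function(id)
    compose_levels(terms[terms$ligand_id == id, , drop = FALSE]))
  do.call(rbind, out)
}

#' Recover components from printed level totals
#'
#' The published energy tables print only the level totals per ligand.
#' Successive subtraction of adjacent levels recovers one total component of
#' each kind: penetration = `eel10 - eel_mtp10`, exchange = `e10 - eel10`,
#' delocalization = `escf - e10`, correlation = `emp2 - escf`, and the
#' approximate dispersion = `eelmtp_plus_edas - eel_mtp10`.
#'
#' @param levels a level table (`ligand_id` plus the six level columns).
#' @param residue_group label for the single pseudo-group holding the ligand
#'   totals (default `"total"`).
#' @return An [hvpt_terms()] table with one row per ligand.
#' @export
levels_to_components <- function(levels, residue_group = "total") {
  need <- c("ligand_id", "eel_mtp10", "eel10", "e10", "escf", "emp2")
  miss <- setdiff(need, names(levels))
  if (length(miss) > 0L)
    stop("missing level column(s): ", paste(miss, collapse = ", "))
  edas <- if ("eelmtp_plus_edas" %in% names(levels))
    levels$eelmtp_plus_edas - levels$eel_mtp10 else NA_real_
  hvpt_terms(levels$ligand_id, residue_group,
             eel_mtp = levels$eel_mtp10,
             eel_pen = levels$eel10 - levels$eel_mtp10,
             eex = levels$e10 - levels$eel10,
             edel = levels$escf - levels$e10,
             ecorr = levels$emp2 - levels$escf,
             edas = edas)
}

#' Aggregate one component or level over residue groups
#'
#' Returns the per-residue-group contribution to one raw component or one
#' composed theory level for a single ligand. The map values always sum to
#' the corresponding ligand total, so the dominant group (for the inhibitors
#' studied here, the charged Arg103) can be read off as the largest absolute
#' contribution.
#'
#' @param terms an [hvpt_terms()] table for one ligand.
#' @param component one of the raw fields (`"eel_mtp"`, `"eel_pen"`,
#'   `"eex"`, `"edel"`, `"ecorr"`, `"edas"`) or composed levels
#'   (`"eel_mtp10"`, `"eel10"`, `"e10"`, `"escf"`, `"emp2"`,
#'   `"eelmtp_plus_edas"`).
#' @return Named numeric vector, one entry per residue group (kcal/mol).
#' @export
aggregate_residue_contributions <- function(terms, component) {
  valid <- c(.hvpt_components, .hvpt_levels)
  if (!is.character(component) || length(component) != 1L ||
      !component %in% valid)
    stop("unknown component '", component, "'; valid names: ",
         paste(valid, collapse = ", "))
  terms <- as_hvpt_terms(terms)
  if (nrow(terms) == 0L) {
    out <- numeric(0)
    names(out) <- character(0)
    return(out)
  }
  ids <- unique(terms$ligand_id)
  if (length(ids) != 1L)
    stop("mixed ligand IDs in component table: ",
         paste(ids, collapse = ", "))
  per_row <- switch(component,
    eel_mtp10 = terms$eel_mtp,
    eel10 = terms$eel_mtp + terms$eel_pen,
    e10 = terms$eel_mtp + terms$eel_pen + terms$eex,
    escf = terms$eel_mtp + terms$eel_pen + terms$eex + terms$edel,
    emp2 = terms$eel_mtp + terms$eel_pen + terms$eex + terms$edel +
      terms$ecorr,
    eelmtp_plus_edas = terms$eel_mtp + terms$edas,
    terms[[component]])
  tapply(per_row, terms$residue_group, sum)[unique(terms$residue_group)]
}

#' Check sign and bookkeeping invariants of an HVPT decomposition
#'
#' Verifies the physically mandated component signs (exchange repulsion
#' non-negative; penetration, delocalization and correlation non-positive)
#' and, when a level table is supplied, the additive composition of every
#' level. Violations are reported, never silently corrected.
#'
#' @param terms an [hvpt_terms()] table (one or many ligands).
#' @param levels optional level table to check against the recomposed
#'   totals.
#' @param tol numeric tolerance in kcal/mol. Use the default `0` for exact
#'   (unrounded) data; `0.15` absorbs accumulation of one-decimal printed
#'   values over the at most three terms separating adjacent levels.
#' @return `data.frame` with columns `ligand_id`, `check`, `residual`;
#'   zero rows when the data are consistent.
#' @export
validate_decomposition <- function(terms, levels = NULL, tol = 0) {
  terms <- as_hvpt_terms(terms)
  rep <- list()
  flag <- function(id, check, residual)
    rep[[length(rep) + 1L]] <<- data.frame(ligand_id = id, check = check,
                                           residual = residual,
                                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(terms))) {
    row <- terms[i, ]
    if (row$eex < -tol)
      flag(row$ligand_id, paste0("exchange repulsion negative (",
                                 row$residue_group, ")"), abs(row$eex))
    for (f in c("eel_pen", "edel", "ecorr"))
      if (!is.na(row[[f]]) && row[[f]] > tol)
        flag(row$ligand_id, paste0(f, " positive (", row$residue_group, ")"),
             row[[f]])
  }
  if (!is.null(levels)) {
    composed <- compose_levels_all(terms)
    for (i in seq_len(nrow(levels))) {
      id <- levels$ligand_id[i]
      comp <- composed[composed$ligand_id == id, , drop = FALSE]
      if (nrow(comp) == 0L) {
        flag(id, "no components for ligand", NA_real_)
        next
      }
      for (lv in .hvpt_levels) {
        if (!lv %in% names(levels)) next
        a <- levels[[lv]][i]
        b <- comp[[lv]]
        if (is.na(a) || is.na(b)) next
        if (abs(a - b) > tol)
          flag(id, paste0(toupper(lv), " residual"), abs(a - b))
      }
    }
  }
  if (length(rep) == 0L)
    return(data.frame(ligand_id = character(0), check = character(0),
                      residual = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rep)
}
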