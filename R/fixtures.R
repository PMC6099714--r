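#' Packaged study tables
#'
#' The complete numerical record of the EphA2-ephrin A1 inhibitor study is
#' packaged as plain-text CSV at printed precision: the activity table
#' (15 lithocholic-acid amino-acid conjugates with pIC50), the
#' interaction-energy table (six theory-level totals per ligand, kcal/mol),
#' the solvation table (solvation free energy with its electrostatic and
#' non-electrostatic parts) and the cross-system reference table of
#' solvation-free-energy spreads.
#'
#' @param name one of `"table1_activities"`, `"table2_levels"`,
#'   `"table3_solvation"`, `"table4_reference_sds"`.
#' @return `data.frame` with `ligand_id` as character (where applicable)
#'   and a `printed_digits` attribute giving the precision of the stored
#'   values.
#' @examples
#' act <- eph_fixture("table1_activities")
#' act[act$ligand_id == "20", ]
#' @export
eph_fixture <- function(name) {
  valid <- c("table1_activities", "table2_levels", "table3_solvation",
             "table4_reference_sds")
  if (!name %in% valid)
    stop("unknown fixture '", name, "'; available: ",
         paste(valid, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "ephscore", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = if (name != "table4_reference_sds")
                          c(ligand_id = "character") else NA)
  attr(df, "printed_digits") <-
    switch(name, table1_activities = 2L, 1L)
  df
}

#' Read / write the canonical CSV dialects
#'
#' Plain UTF-8 CSV with a decimal point and a header row; energies in
#' kcal/mol. `read_energy_terms()` expects
#' `ligand_id,residue_group,eel_mtp,eel_pen,eex,edel,ecorr,edas`;
#' `read_level_table()` expects
#' `ligand_id,eel_mtp10,eel10,e10,escf,emp2,eelmtp_plus_edas`;
#' `read_activities()` expects `ligand_id,label,pic50`;
#' `read_solvation()` expects `ligand_id,dg_solv,dg_solv_el,dg_solv_nonel`.
#'
#' @param path CSV file path.
#' @return typed `data.frame`.
#' @export
read_energy_terms <- function(path) {
  as_hvpt_terms(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c(ligand_id = "character")))
}

#' @rdname read_energy_terms
#' @export
read_level_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ligand_id = "character"))
  need <- c("ligand_id", "eel_mtp10", "eel10", "e10", "escf", "emp2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing level column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_energy_terms
#' @export
read_activities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ligand_id = "character"))
  stopifnot(all(c("ligand_id", "pic50") %in% names(df)))
  if (anyDuplicated(df$ligand_id))
    stop("duplicate ligand_id in activity table")
  if (any(df$pic50 <= 0)) stop("pIC50 values must be positive")
  df
}

#' @rdname read_energy_terms
#' @export
read_solvation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ligand_id = "character"))
  stopifnot(all(c("ligand_id", "dg_solv", "dg_solv_el",
                  "dg_solv_nonel") %in% names(df)))
  df
}

#' @rdname read_energy_terms
#' @param x `data.frame` to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
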