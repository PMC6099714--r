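#' Long-range composite score of a ligand-binding site complex
#'
#' Evaluates the two long-range terms of the composite score for one ligand
#' against a binding-site model: the multipole electrostatic energy
#' ([mtp_electrostatics()]) and the damped atom-atom dispersion
#' ([das_dispersion()]), reported per residue group and as totals. The total
#' `eel_mtp + edas` is the long-range composite used to rank inhibitors and
#' feeds the HVPT ledger as the `eelmtp_plus_edas` source.
#'
#' @param ligand list of [multipole_site()]s for the ligand.
#' @param binding_site named list of residues, each a list of
#'   [multipole_site()]s.
#' @param params a [dispersion_params()] table.
#' @param grouping named list mapping residue-group label to the residue
#'   names it contains (default: each residue its own group). Every residue
#'   must belong to exactly one group.
#' @param max_inverse_power truncation order for the electrostatics.
#' @return `data.frame` with columns `residue_group`, `eel_mtp`, `edas`
#'   (kcal/mol) and attribute `"totals"` (named numeric with `eel_mtp`,
#'   `edas`, `eelmtp_plus_edas`).
#' @export
score_complex <- function(ligand, binding_site, params,
                          grouping = NULL, max_inverse_power = 4L) {
  stopifnot(is.list(binding_site), !is.null(names(binding_site)))
  if (is.null(grouping))
    grouping <- stats::setNames(as.list(names(binding_site)),
                                names(binding_site))
  members <- unlist(grouping, use.names = FALSE)
  dup <- unique(members[duplicated(members)])
  if (length(dup) > 0L)
    stop("residue(s) assigned to more than one group: ",
         paste(dup, collapse = ", "))
  miss <- setdiff(members, names(binding_site))
  if (length(miss) > 0L)
    stop("grouping refers to unknown residue(s): ",
         paste(miss, collapse = ", "))
  sites_to_coords <- function(sites)
    data.frame(element = vapply(sites, `[[`, "", "element"),
               x = vapply(sites, function(s) s$xyz[1L], 0),
               y = vapply(sites, function(s) s$xyz[2L], 0),
               z = vapply(sites, function(s) s$xyz[3L], 0),
               stringsAsFactors = FALSE)
  lig_coords <- sites_to_coords(ligand)
  rows <- lapply(names(grouping), function(g) {
    eel <- 0; edas <- 0
    for (res in grouping[[g]]) {
      eel <- eel + mtp_electrostatics(ligand, binding_site[[res]],
                                      max_inverse_power = max_inverse_power)
      edas <- edas + das_dispersion(lig_coords,
                                    sites_to_coords(binding_site[[res]]),
                                    params)
    }
    data.frame(residue_group = g, eel_mtp = eel, edas = edas,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- c(eel_mtp = sum(out$eel_mtp), edas = sum(out$edas))
  attr(out, "totals") <- c(tot,
                           eelmtp_plus_edas = unname(tot["eel_mtp"] +
                                                     tot["edas"]))
  out
}
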