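#' Synthetic congeneric-series generator
#'
#' Generates ligand series with the statistical structure the scoring
#' analysis assumes: per-residue-group HVPT components whose signs are
#' physically constrained, one dominant charged residue group carrying most
#' of the electrostatic binding energy, activities linearly related to the
#' total MP2-level energy at a controllable correlation strength, and
#' solvation free energies with a controllable spread. Everything is
#' reproducible from a single seed (Mersenne-Twister).
#'
#' @name synthetic-data
NULL

#' Specification of a synthetic congeneric series
#'
#' @param n_ligands number of ligands.
#' @param residue_groups `data.frame` with columns `name` and
#'   `charge_class` (`"charged"` or `"neutral"`); default mirrors the
#'   four-group binding-site model with a single charged arginine-like
#'   group.
#' @param dominant_group name of the group that dominates the electrostatic
#'   energy; must be one of `residue_groups$name`.
#' @param target_r target population Pearson correlation between the
#'   MP2-level total energy and pIC50; in (-1, 0) since lower energy means
#'   higher activity.
#' @param activity_range numeric length-2, the pIC50 interval the noiseless
#'   affine map spans.
#' @param solvation_sd standard deviation of the generated solvation free
#'   energies, kcal/mol (>= 0).
#' @param seed integer RNG seed.
#' @return list with class `"series_spec"`.
#' @export
series_spec <- function(n_ligands = 15L,
                        residue_groups = data.frame(
                          name = c("Arg103", "Cys70-Cys188",
                                   "Val72-Met73", "Phe108"),
                          charge_class = c("charged", "neutral",
                                           "neutral", "neutral"),
                          stringsAsFactors = FALSE),
                        dominant_group = "Arg103",
                        target_r = -0.7,
                        activity_range = c(4.0, 5.7),
                        solvation_sd = 3.0,
                        seed = 1L) {
  if (!dominant_group %in% residue_groups$name)
    stop("dominant_group must be one of the residue groups")
  if (!(target_r > -1 && target_r < 0))
    stop("target_r must lie strictly inside (-1, 0)")
  if (solvation_sd < 0) stop("solvation_sd must be non-negative")
  if (n_ligands < 3L) stop("n_ligands must be at least 3")
  structure(list(n_ligands = as.integer(n_ligands),
                 residue_groups = residue_groups,
                 dominant_group = dominant_group,
                 target_r = target_r,
                 activity_range = sort(as.numeric(activity_range)),
                 solvation_sd = solvation_sd,
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic congeneric series
#'
#' Draws per-ligand, per-group HVPT components such that the dominant
#' charged group carries >= 70 percent of the total first-order
#' electrostatic energy in expectation and every sign constraint holds
#' exactly; maps the MP2-level totals affinely onto the activity range and
#' adds Gaussian noise calibrated (against the realised energy spread) so
#' the expected Pearson correlation equals `target_r`; and draws solvation
#' free energies with standard deviation `solvation_sd`, split into
#' electrostatic and non-electrostatic parts that sum exactly.
#'
#' @param spec a [series_spec()].
#' @param tie_pair logical, force one pair of ligands to share an exactly
#'   equal pIC50 (mirrors the one experimental tie of the study series).
#' @return list with `terms` ([hvpt_terms()] table), `activities`
#'   (`ligand_id`, `label`, `pic50`), `solvation` (`ligand_id`, `dg_solv`,
#'   `dg_solv_el`, `dg_solv_nonel`) and `metadata` (rng, seed, spec).
#' @export
generate_series <- function(spec, tie_pair = FALSE) {
  stopifnot(inherits(spec, "series_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  n <- spec$n_ligands
  groups <- spec$residue_groups
  ids <- sprintf("L%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    for (g in seq_len(nrow(groups))) {
      dominant <- groups$name[g] == spec$dominant_group
      if (dominant) {
        eel_mtp <- -stats::runif(1, 60, 110)
        eel_pen <- -stats::runif(1, 5, 15)
        eex <- stats::runif(1, 20, 40)
        edel <- -stats::runif(1, 10, 20)
        ecorr <- -stats::runif(1, 12, 25)
        edas <- -stats::runif(1, 15, 30)
      } else {
        eel_mtp <- -stats::runif(1, 0.5, 4)
        eel_pen <- -stats::runif(1, 0.2, 1)
        eex <- stats::runif(1, 1, 5)
        edel <- -stats::runif(1, 0.5, 2)
        ecorr <- -stats::runif(1, 1, 4)
        edas <- -stats::runif(1, 2, 6)
      }
      rows[[length(rows) + 1L]] <-
        hvpt_terms(ids[i], groups$name[g], eel_mtp, eel_pen, eex, edel,
                   ecorr, edas)
    }
  }
  terms <- do.call(rbind, rows)
  class(terms) <- c("hvpt_terms", "data.frame")
  levels <- compose_levels_all(terms)
  emp2 <- levels$emp2
  sd_e <- stats::sd(emp2)
  if (sd_e == 0) stop("degenerate series: zero energy variance")
  # affine map: most negative energy -> top of the activity range
  rng <- spec$activity_range
  b <- (rng[1] - rng[2]) / (max(emp2) - min(emp2))
  a <- rng[2] - b * min(emp2)
  r <- spec$target_r
  sigma_eps <- abs(b) * sd_e * sqrt(1 / r^2 - 1)
  pic50 <- a + b * emp2 + stats::rnorm(n, 0, sigma_eps)
  if (tie_pair && n >= 2L) pic50[2L] <- pic50[1L]
  if (any(pic50 <= 0))
    stop("infeasible target_r / activity range: nonpositive pIC50 drawn")
  activities <- data.frame(ligand_id = ids,
                           label = sprintf("syn-%02d", seq_len(n)),
                           pic50 = pic50, stringsAsFactors = FALSE)
  dg <- stats::rnorm(n, -67, 1)
  dg <- if (spec$solvation_sd == 0 || stats::sd(dg) == 0) rep(-67, n) else
    -67 + (dg - mean(dg)) / stats::sd(dg) * spec$solvation_sd
  nonel <- stats::runif(n, 5, 8)
  solvation <- data.frame(ligand_id = ids, dg_solv = dg,
                          dg_solv_el = dg - nonel, dg_solv_nonel = nonel,
                          stringsAsFactors = FALSE)
  list(terms = terms, activities = activities, solvation = solvation,
       metadata = list(rng = "Mersenne-Twister", seed = spec$seed,
                       spec = spec))
}

#' Study-shaped series preset
#'
#' A [series_spec()] sized like the study series: 15 ligands, the four-group
#' binding-site model, one forced activity tie, target correlation -0.7 and
#' a 3.0 kcal/mol solvation spread.
#'
#' @param seed integer seed.
#' @return list as from [generate_series()].
#' @export
generate_study_shape_series <- function(seed = 1L) {
  generate_series(series_spec(n_ligands = 15L, seed = seed),
                  tie_pair = TRUE)
}

#' Generate a toy ligand-binding site complex
#'
#' Builds non-overlapping random geometries with atomic multipoles for the
#' physics core: a small ligand (net charge -1, like the carboxylate-bearing
#' inhibitors) surrounded by `n_residues` residues of which exactly one
#' carries a net +1 charge (arginine-like); all other residues are neutral.
#' Quadrupoles are trace-corrected by construction; dispersion parameters
#' use a per-element C6 table with geometric-mean combination.
#'
#' @param n_atoms_ligand number of ligand atoms (>= 1).
#' @param n_residues number of binding-site residues (>= 1).
#' @param seed integer seed.
#' @param residue_distance numeric length-2, min/max distance of residue
#'   centers from the ligand center, Angstrom.
#' @return list with `ligand` (multipole sites), `residues` (named list of
#'   site lists; the first, `"RES1"`, is the charged one), `grouping`,
#'   `dispersion` ([dispersion_params()]) and `metadata`.
#' @export
generate_toy_complex <- function(n_atoms_ligand = 5L, n_residues = 4L,
                                 seed = 1L,
                                 residue_distance = c(3.5, 6)) {
  stopifnot(n_atoms_ligand >= 1L, n_residues >= 1L)
  set.seed(seed, kind = "Mersenne-Twister")
  elements <- c("C", "N", "O", "H")
  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  make_sites <- function(n_atoms, center, net_charge) {
    pos <- t(vapply(seq_len(n_atoms), function(i)
      center + rand_unit() * stats::runif(1, 0, 1.2), numeric(3)))
    q <- stats::rnorm(n_atoms, 0, 0.3)
    q <- q - mean(q) + net_charge / n_atoms
    lapply(seq_len(n_atoms), function(i) {
      mu <- stats::rnorm(3, 0, 0.1)
      M <- matrix(stats::rnorm(9, 0, 0.05), 3, 3)
      multipole_site(sample(elements, 1L), pos[i, ], q = q[i], mu = mu,
                     theta = traceless_quadrupole(M %*% t(M)))
    })
  }
  ligand <- make_sites(n_atoms_ligand, c(0, 0, 0), -1)
  directions <- lapply(seq_len(n_residues), function(i) rand_unit())
  residues <- stats::setNames(lapply(seq_len(n_residues), function(i) {
    center <- directions[[i]] *
      stats::runif(1, residue_distance[1], residue_distance[2])
    make_sites(sample(2:4, 1L), center,
               net_charge = if (i == 1L) 1 else 0)
  }), sprintf("RES%d", seq_len(n_residues)))
  c6 <- c(C = 24, N = 19, O = 14, H = 3)   # kcal/mol * A^6, order-of-magnitude
  disp <- dispersion_params(fallback = list(c6 = c6, beta = 3.0))
  grouping <- stats::setNames(as.list(names(residues)), names(residues))
  list(ligand = ligand, residues = residues, grouping = grouping,
       dispersion = disp,
       metadata = list(rng = "Mersenne-Twister", seed = seed))
}
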