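#' Molecular geometry and multipole input/output
#'
#' Readers and writers for the plain-text formats the physics core consumes:
#' XYZ geometries, PDB coordinate records, and a JSON schema for atomic
#' multipole sets (`{sites: [{element, xyz, q, mu, theta, omega?}]}`).
#'
#' @name geometry-io
NULL

#' Read / write an XYZ geometry
#'
#' @param path file path.
#' @return `data.frame` with columns `element`, `x`, `y`, `z` (Angstrom);
#'   the comment line is kept as attribute `"comment"`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  body <- lines[seq(3L, 2L + n)]
  parts <- strsplit(trimws(body), "\\s+")
  out <- data.frame(element = vapply(parts, `[[`, "", 1L),
                    x = as.numeric(vapply(parts, `[[`, "", 2L)),
                    y = as.numeric(vapply(parts, `[[`, "", 3L)),
                    z = as.numeric(vapply(parts, `[[`, "", 4L)),
                    stringsAsFactors = FALSE)
  attr(out, "comment") <- lines[2L]
  out
}

#' @rdname read_xyz
#' @param coords `data.frame` with columns `element`, `x`, `y`, `z`.
#' @param comment comment line.
#' @export
write_xyz <- function(coords, path, comment = "") {
  lines <- c(nrow(coords), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", coords$element,
                     coords$x, coords$y, coords$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read ATOM/HETATM coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()` returning the atom table in the
#' package's coordinate dialect, with 1-based residue numbering as in the
#' PDB standard.
#'
#' @param path PDB file path.
#' @return `data.frame` with columns `element`, `x`, `y`, `z`, `resid`,
#'   `resno`, `chain`.
#' @export
read_pdb_coords <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1L, 1L)
  data.frame(element = trimws(elem), x = at$x, y = at$y, z = at$z,
             resid = at$resid, resno = at$resno, chain = at$chain,
             stringsAsFactors = FALSE)
}

#' Read / write atomic multipole sites as JSON
#'
#' Schema: `{"sites": [{"element": "O", "xyz": [..], "q": -0.8,
#' "mu": [..], "theta": [[..]x3], "omega": [[[..]]]? }, ...]}`. Omitted
#' moments default to zero; `omega` may be absent.
#'
#' @param path JSON file path.
#' @return list of [multipole_site()]s.
#' @export
read_multipole_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw$sites, function(s) {
    theta <- if (is.null(s$theta)) matrix(0, 3, 3) else
      matrix(unlist(s$theta), 3, 3, byrow = TRUE)
    omega <- if (is.null(s$omega)) NULL else
      aperm(array(unlist(s$omega), c(3, 3, 3)), c(3, 2, 1))
    multipole_site(s$element, unlist(s$xyz),
                   q = if (is.null(s$q)) 0 else s$q,
                   mu = if (is.null(s$mu)) c(0, 0, 0) else unlist(s$mu),
                   theta = theta, omega = omega)
  })
}

#' @rdname read_multipole_json
#' @param sites list of [multipole_site()]s.
#' @export
write_multipole_json <- function(sites, path) {
  out <- list(sites = lapply(sites, function(s) {
    rec <- list(element = s$element, xyz = s$xyz, q = s$q, mu = s$mu,
                theta = lapply(1:3, function(i) s$theta[i, ]))
    if (!is.null(s$omega))
      rec$omega <- lapply(1:3, function(i)
        lapply(1:3, function(j) s$omega[i, j, ]))
    rec
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
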