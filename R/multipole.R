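#' Long-range multipole electrostatics
#'
#' The multipole electrostatic term of the binding energy is evaluated from
#' atom-centered multipole expansions (charge, dipole, traceless quadrupole
#' and optionally traceless octopole per site), truncated so that only
#' interaction terms with an overall distance dependence of R^-1 ... R^-4
#' are retained: charge-charge (R^-1), charge-dipole (R^-2), dipole-dipole
#' and charge-quadrupole (R^-3), dipole-quadrupole and charge-octopole
#' (R^-4). Quadrupole-quadrupole and higher terms decay as R^-5 or faster
#' and are outside the truncation.
#'
#' Energies are in kcal/mol with positions in Angstrom and moments in e,
#' e*A, e*A^2, e*A^3 (Buckingham traceless convention). The Coulomb
#' constant is fixed at 332.06 kcal/mol*A/e^2.
#'
#' @name multipole-electrostatics
NULL

#' Coulomb constant, kcal/mol * Angstrom / e^2
#' @export
COULOMB_KCAL <- 332.06

.trace_tol <- 1e-9

#' Construct an atomic multipole site
#'
#' @param element element symbol.
#' @param xyz numeric length-3 position, Angstrom.
#' @param q numeric charge, e.
#' @param mu numeric length-3 dipole, e*A.
#' @param theta 3x3 symmetric traceless quadrupole, e*A^2 (Buckingham
#'   convention; see [traceless_quadrupole()]).
#' @param omega optional 3x3x3 symmetric traceless octopole, e*A^3.
#' @return list with class `"multipole_site"`.
#' @export
multipole_site <- function(element, xyz, q = 0, mu = c(0, 0, 0),
                           theta = matrix(0, 3, 3), omega = NULL) {
  xyz <- as.numeric(xyz); mu <- as.numeric(mu)
  stopifnot(length(xyz) == 3L, length(mu) == 3L,
            is.matrix(theta), all(dim(theta) == c(3L, 3L)))
  if (abs(sum(diag(theta))) > .trace_tol)
    stop("quadrupole is not traceless (trace = ", sum(diag(theta)), ")")
  if (max(abs(theta - t(theta))) > .trace_tol)
    stop("quadrupole is not symmetric")
  if (!is.null(omega)) {
    stopifnot(is.array(omega), all(dim(omega) == c(3L, 3L, 3L)))
    for (g in 1:3) {
      if (abs(sum(diag(omega[, , g]))) > .trace_tol ||
          abs(sum(sapply(1:3, function(a) omega[a, g, a]))) > .trace_tol ||
          abs(sum(sapply(1:3, function(a) omega[g, a, a]))) > .trace_tol)
        stop("octopole is not traceless over all index pairs")
    }
  }
  structure(list(element = as.character(element), xyz = xyz, q = q,
                 mu = mu, theta = theta, omega = omega),
            class = "multipole_site")
}

#' Traceless (Buckingham) quadrupole from a primitive second moment
#'
#' For a primitive second moment `S[a,b] = sum_i q_i r_a r_b` the Buckingham
#' quadrupole is `Theta = (3 S - tr(S) I) / 2`.
#'
#' @param S 3x3 primitive second-moment matrix, e*A^2.
#' @return 3x3 traceless symmetric matrix.
#' @export
traceless_quadrupole <- function(S) {
  S <- (S + t(S)) / 2
  (3 * S - sum(diag(S)) * diag(3)) / 2
}

#' Traceless octopole from a primitive third moment
#'
#' For `P[a,b,c] = sum_i q_i r_a r_b r_c` the Buckingham octopole is
#' `Omega[a,b,c] = (5 P[a,b,c] - t_a d_bc - t_b d_ca - t_c d_ab) / 2` with
#' `t_a = sum_b P[a,b,b]` the contraction of the primitive moment.
#'
#' @param P 3x3x3 primitive third-moment array, e*A^3.
#' @return 3x3x3 traceless symmetric array.
#' @export
traceless_octopole <- function(P) {
  P <- (P + aperm(P, c(2, 1, 3)) + aperm(P, c(3, 2, 1)) +
        aperm(P, c(1, 3, 2)) + aperm(P, c(2, 3, 1)) +
        aperm(P, c(3, 1, 2))) / 6
  t_vec <- sapply(1:3, function(a) sum(diag(P[a, , ])))
  Om <- array(0, c(3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (g in 1:3)
    Om[a, b, g] <- (5 * P[a, b, g] -
                    t_vec[a] * (b == g) - t_vec[b] * (g == a) -
                    t_vec[g] * (a == b)) / 2
  Om
}

#' Multipole expansion of a point-charge cluster about a center
#'
#' Builds a single [multipole_site()] carrying the charge, dipole,
#' traceless quadrupole and traceless octopole of a cloud of point charges,
#' referred to `center`. Used both for constructing test systems and for
#' the finite-difference oracles that validate [mtp_electrostatics()].
#'
#' @param charges numeric vector of charges, e.
#' @param positions n x 3 matrix of positions, Angstrom.
#' @param center numeric length-3 expansion center.
#' @param element element label for the site.
#' @return A `multipole_site`.
#' @export
expand_point_charges <- function(charges, positions, center = c(0, 0, 0),
                                 element = "X") {
  positions <- as.matrix(positions)
  r <- sweep(positions, 2, center)
  q <- sum(charges)
  mu <- colSums(charges * r)
  S <- t(r) %*% (charges * r)
  P <- array(0, c(3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (g in 1:3)
    P[a, b, g] <- sum(charges * r[, a] * r[, b] * r[, g])
  multipole_site(element, center, q = q, mu = mu,
                 theta = traceless_quadrupole(S),
                 omega = traceless_octopole(P))
}

# interaction tensors T^(n) = grad^n (1/R), derivatives wrt the position of
# the second site; Rvec points from site a to site b
.t_tensors <- function(Rvec) {
  r2 <- sum(Rvec^2); r <- sqrt(r2)
  T0 <- 1 / r
  T1 <- -Rvec / r^3
  T2 <- (3 * outer(Rvec, Rvec) - r2 * diag(3)) / r^5
  T3 <- array(0, c(3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (g in 1:3)
    T3[a, b, g] <- -(15 * Rvec[a] * Rvec[b] * Rvec[g] -
                     3 * r2 * (Rvec[a] * (b == g) + Rvec[b] * (g == a) +
                               Rvec[g] * (a == b))) / r^7
  list(T0 = T0, T1 = T1, T2 = T2, T3 = T3)
}

.pair_mtp_energy <- function(sa, sb, max_inverse_power,
                             include_charge_octopole = TRUE) {
  Rvec <- sb$xyz - sa$xyz
  tt <- .t_tensors(Rvec)
  e <- 0
  if (max_inverse_power >= 1L)
    e <- e + sa$q * tt$T0 * sb$q
  if (max_inverse_power >= 2L)
    e <- e + sa$q * sum(tt$T1 * sb$mu) - sum(sa$mu * tt$T1) * sb$q
  if (max_inverse_power >= 3L)
    e <- e - sum(sa$mu * (tt$T2 %*% sb$mu)) +
      (sa$q * sum(tt$T2 * sb$theta) + sum(sa$theta * tt$T2) * sb$q) / 3
  if (max_inverse_power >= 4L) {
    mu_theta <- 0
    for (a in 1:3)
      mu_theta <- mu_theta - sum(sa$mu[a] * tt$T3[a, , ] * sb$theta) / 3
    for (g in 1:3)
      mu_theta <- mu_theta + sum(sa$theta * tt$T3[, , g]) * sb$mu[g] / 3
    e <- e + mu_theta
    if (include_charge_octopole) {
      if (!is.null(sb$omega)) e <- e + sa$q * sum(tt$T3 * sb$omega) / 15
      if (!is.null(sa$omega)) e <- e - sum(sa$omega * tt$T3) * sb$q / 15
    }
  }
  e
}

#' Multipole electrostatic interaction energy between two molecules
#'
#' Sums, over all inter-molecular site pairs, the multipole-multipole
#' interaction terms whose overall distance dependence is R^-1 up to
#' R^-`max_inverse_power`. The result is symmetric under exchange of the
#' two molecules and reduces exactly to Coulomb's law for charge-only
#' sites.
#'
#' @param sites_a,sites_b lists of [multipole_site()]s, one per molecule.
#' @param max_inverse_power integer in 1..4, the truncation order.
#' @param include_charge_octopole logical, include the charge-octopole
#'   R^-4 cross term (requires octopoles on the sites); the dipole-
#'   quadrupole R^-4 term is always included at order 4.
#' @return energy in kcal/mol.
#' @examples
#' a <- list(multipole_site("X", c(0, 0, 0), q = 1))
#' b <- list(multipole_site("X", c(3.32, 0, 0), q = -1))
#' mtp_electrostatics(a, b)   # ~ -100 kcal/mol
#' @export
mtp_electrostatics <- function(sites_a, sites_b, max_inverse_power = 4L,
                               include_charge_octopole = TRUE) {
  if (!is.numeric(max_inverse_power) || length(max_inverse_power) != 1L ||
      !(max_inverse_power %in% 1:4))
    stop("max_inverse_power must be one of 1, 2, 3, 4")
  max_inverse_power <- as.integer(max_inverse_power)
  e <- 0
  for (sa in sites_a) for (sb in sites_b) {
    if (sum((sa$xyz - sb$xyz)^2) < 1e-16)
      stop("coincident sites across the two molecules at (",
           paste(signif(sa$xyz, 6), collapse = ", "), ")")
    e <- e + .pair_mtp_energy(sa, sb, max_inverse_power,
                              include_charge_octopole)
  }
  COULOMB_KCAL * e
}

#' Rigidly rotate a list of multipole sites
#'
#' Rotates positions, dipoles, quadrupoles and octopoles with the same
#' rotation matrix about `center`; used e.g. to verify rotational
#' invariance of the interaction energies.
#'
#' @param sites list of [multipole_site()]s.
#' @param R 3x3 rotation matrix.
#' @param center length-3 rotation center.
#' @return rotated list of sites.
#' @export
rotate_multipole_sites <- function(sites, R, center = c(0, 0, 0)) {
  lapply(sites, function(s) {
    om <- s$omega
    if (!is.null(om)) {
      out <- array(0, c(3, 3, 3))
      for (a in 1:3) for (b in 1:3) for (g in 1:3)
        for (i in 1:3) for (j in 1:3) for (k in 1:3)
          out[a, b, g] <- out[a, b, g] +
            R[a, i] * R[b, j] * R[g, k] * om[i, j, k]
      om <- out
    }
    multipole_site(s$element,
                   as.numeric(R %*% (s$xyz - center)) + center,
                   q = s$q,
                   mu = as.numeric(R %*% s$mu),
                   theta = R %*% s$theta %*% t(R),
                   omega = om)
  })
}
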