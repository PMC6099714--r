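# independent reference implementations used as oracles

# direct pairwise Coulomb sum over two point-charge clouds (kcal/mol)
coulomb_oracle <- function(qa, xa, qb, xb) {
  e <- 0
  for (i in seq_along(qa)) for (j in seq_along(qb))
    e <- e + qa[i] * qb[j] / sqrt(sum((xa[i, ] - xb[j, ])^2))
  332.06 * e
}

# explicit double-loop damped dispersion reference
das_oracle <- function(coords_a, coords_b, c6_tab, beta) {
  f <- function(n, x) 1 - exp(-x) * sum(x^seq(0, n) / factorial(seq(0, n)))
  e <- 0
  for (i in seq_len(nrow(coords_a))) for (j in seq_len(nrow(coords_b))) {
    r <- sqrt(sum((as.numeric(coords_a[i, c("x", "y", "z")]) -
                   as.numeric(coords_b[j, c("x", "y", "z")]))^2))
    c6 <- sqrt(c6_tab[[coords_a$element[i]]] * c6_tab[[coords_b$element[j]]])
    e <- e - f(6, beta * r) * c6 / r^6
  }
  e
}

# random rotation matrix from QR decomposition
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

fixture_activities <- function() eph_fixture("table1_activities")
fixture_levels <- function() eph_fixture("table2_levels")
fixture_solvation <- function() eph_fixture("table3_solvation")
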