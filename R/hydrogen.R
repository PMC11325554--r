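#' Hydrogen-like ground state on a radial grid
#'
#' Reduced radial wave function `u0(r) = 2 Z^{3/2} r exp(-Z r)` of the 1s
#' state, together with the grid and the exact energy `-Z^2/2`.
#'
#' @param Z Nuclear charge (default 1).
#' @param n Number of radial points (default 20000).
#' @param rmax Outer radius in bohr (default `40 / Z`).
#' @return List with `r`, `u0`, `energy`, `Z`.
#' @export
hydrogen_radial_ground <- function(Z = 1, n = 20000L, rmax = NULL) {
  stopifnot(Z >= 1)
  if (is.null(rmax)) rmax <- 40 / Z
  h <- rmax / n
  r <- h * seq_len(n)
  u0 <- 2 * Z^1.5 * r * exp(-Z * r)
  list(r = r, u0 = u0, energy = -Z^2 / 2, Z = Z, h = h)
}

#' Hydrogen-like polarizability via radial Dalgarno--Lewis
#'
#' Solves the first-order perturbation equation in the `l = 1` channel,
#' `(-u''/2 + (1/r^2 - Z/r - E0) u1) = -(1/sqrt(3)) r u0`,
#' with a tridiagonal finite-difference scheme, and forms
#' `alpha = (2/sqrt(3)) int r u0 u1 dr`.  For `Z = 1` the exact value is
#' 4.5 bohr^3.
#'
#' @inheritParams hydrogen_radial_ground
#' @return `alpha` in bohr^3.
#' @examples
#' hydrogen_alpha_dalgarno_lewis()  # ~4.5
#' @export
hydrogen_alpha_dalgarno_lewis <- function(Z = 1, n = 20000L, rmax = NULL) {
  g <- hydrogen_radial_ground(Z, n, rmax)
  r <- g$r; h <- g$h
  v <- 1 / r^2 - g$Z / r - g$energy
  d <- 1 / h^2 + v
  e <- rep(-1 / (2 * h^2), length(r) - 1)
  rhs <- -(1 / sqrt(3)) * r * g$u0
  u1 <- thomas_solve(d, e, rhs)
  -(2 / sqrt(3)) * trapz_uniform(r * g$u0 * u1, h)
}

#' Discrete (bound-to-bound) share of the hydrogen polarizability
#'
#' Sums the second-order contributions of the discrete `np` Rydberg series
#' using the closed-form 1s -> np oscillator strengths
#' `f_n = 2^8 n^5 (n-1)^(2n-4) / (3 (n+1)^(2n+4))`, giving
#' `alpha_disc = sum_n f_n / (E_n - E_1)^2`.  The remainder of the exact
#' `alpha = 4.5` is carried by the photoionization continuum (about 20%).
#'
#' @param nmax Highest principal quantum number included (default 2000).
#' @return List with `alpha_discrete`, `alpha_exact`, `continuum_share`.
#' @export
hydrogen_continuum_share <- function(nmax = 2000L) {
  n <- as.numeric(seq(2L, nmax))
  # logs for numerical stability at large n
  logf <- 8 * log(2) + 5 * log(n) + (2 * n - 4) * log(n - 1) -
    log(3) - (2 * n + 4) * log(n + 1)
  f <- exp(logf)
  dE <- 0.5 * (1 - 1 / n^2)
  alpha_disc <- sum(f / dE^2)
  list(alpha_discrete = alpha_disc, alpha_exact = 4.5,
       continuum_share = 1 - alpha_disc / 4.5)
}
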