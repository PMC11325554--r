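#' Slater--Kirkwood dispersion coefficient
#'
#' Dipole--dipole dispersion coefficient between atoms A and B from their
#' static polarizabilities and effective electron numbers:
#' \deqn{C_6^{AB} = \frac{3}{2}\,
#'   \frac{\alpha_A \alpha_B}{\sqrt{\alpha_A/N_A} + \sqrt{\alpha_B/N_B}}}
#' (atomic units).  This is the dipole specialization of the general
#' multipole combination rule, equivalent to an Unsoeld average-excitation
#' treatment with characteristic frequencies
#' `omega_X = sqrt(N_X / alpha_X)` inserted in the Casimir--Polder/London
#' formula.  For `A = B` it reduces to
#' `C6 = (3/4) sqrt(N) alpha^(3/2)`.
#'
#' @param alpha_A,alpha_B Static polarizabilities (bohr^3).
#' @param n_A,n_B Effective electron numbers.
#' @return `C6` in hartree bohr^6.
#' @examples
#' slater_kirkwood_c6(1.38, 1.38, 1.74, 1.74)
#' @export
slater_kirkwood_c6 <- function(alpha_A, alpha_B, n_A = NULL, n_B = NULL) {
  if (is.null(n_A) || is.null(n_B)) stop("effective electron numbers required")
  if (any(c(alpha_A, alpha_B, n_A, n_B) <= 0)) {
    stop("all inputs must be positive")
  }
  1.5 * alpha_A * alpha_B / (sqrt(alpha_A / n_A) + sqrt(alpha_B / n_B))
}

#' Quantum-Drude-oscillator dynamic polarizability
#'
#' Single-pole (Lorentzian) dynamic dipole polarizability on the imaginary
#' frequency axis: `alpha(i omega) = alpha0 / (1 + (omega/omega_eff)^2)`.
#' Exact for a quantum Drude oscillator, for which a two-state response
#' model holds.
#'
#' @param alpha0 Static polarizability (bohr^3).
#' @param omega_eff Effective (characteristic) frequency (hartree).
#' @param omega Imaginary frequency grid (hartree); may be a vector.
#' @return `alpha(i omega)`, same length as `omega`.
#' @export
qdo_dynamic_alpha <- function(alpha0, omega_eff, omega) {
  stopifnot(alpha0 > 0, omega_eff > 0)
  alpha0 / (1 + (omega / omega_eff)^2)
}

#' Effective frequency from static polarizability and C6
#'
#' Inverts the London relation `C6 = (3/4) omega_eff alpha0^2` of the
#' quantum Drude oscillator: `omega_eff = 4 C6 / (3 alpha0^2)`.  The pair
#' (`alpha0`, `omega_eff`) then reproduces `C6` through the Casimir--Polder
#' integral of [qdo_dynamic_alpha()].
#'
#' @param alpha0 Static polarizability (bohr^3).
#' @param C6_AA Homoatomic dispersion coefficient (hartree bohr^6).
#' @return `omega_eff` in hartree.
#' @examples
#' omega_eff_from(1, 0.75)  # 1
#' @export
omega_eff_from <- function(alpha0, C6_AA) {
  stopifnot(alpha0 > 0, C6_AA > 0)
  4 * C6_AA / (3 * alpha0^2)
}

#' Casimir--Polder integral for two Lorentzian polarizabilities
#'
#' `C6 = (3/pi) int_0^inf alpha_A(i w) alpha_B(i w) dw`, evaluated by
#' Gauss--Legendre quadrature under the rational substitution
#' `w = w0 (1 + x) / (1 - x)`.  For two quantum Drude oscillators this
#' reproduces the London formula exactly (to quadrature accuracy ~1e-12).
#'
#' @param alpha0_A,alpha0_B Static polarizabilities.
#' @param omega_A,omega_B Effective frequencies.
#' @param n Number of quadrature nodes (default 80).
#' @param w0 Substitution scale (default geometric mean of the frequencies).
#' @return `C6` in hartree bohr^6.
#' @export
casimir_polder_c6 <- function(alpha0_A, omega_A, alpha0_B, omega_B,
                              n = 80L, w0 = NULL) {
  if (is.null(w0)) w0 <- sqrt(omega_A * omega_B)
  gl <- pracma::gaussLegendre(n, -1, 1)
  w <- w0 * (1 + gl$x) / (1 - gl$x)
  dw <- 2 * w0 / (1 - gl$x)^2
  f <- qdo_dynamic_alpha(alpha0_A, omega_A, w) *
    qdo_dynamic_alpha(alpha0_B, omega_B, w)
  (3 / pi) * sum(gl$w * f * dw)
}

#' Volume rescaling of the C6 coefficient
#'
#' Scaling of the dispersion coefficient of an atom in a molecule with its
#' Hirshfeld volume ratio `v = V_eff / V_free`:
#' `C6_aim = C6_free * v^p` with `p = 2`.  The exponent follows from the
#' four-dimensional law (`alpha` scaling as `v^(4/3)`) combined with the
#' Slater--Kirkwood relation `C6` proportional to `sqrt(N_eff) alpha^(3/2)`
#' at a constant effective electron number:
#' `(4/3) * (3/2) = 2`.
#'
#' @param C6_free Free-atom coefficient (hartree bohr^6).
#' @param v_ratio Hirshfeld volume ratio, `> 0`.
#' @param p Scaling exponent (default 2).
#' @return Rescaled `C6`.
#' @examples
#' c6_rescale(6.38, 0.5)  # C6/4
#' @export
c6_rescale <- function(C6_free, v_ratio, p = 2) {
  if (any(v_ratio <= 0)) stop("v_ratio must be positive")
  C6_free * v_ratio^p
}
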