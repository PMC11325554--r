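#' Soft-wall confinement specification and potential
#'
#' A spherical soft-wall confining potential used to emulate the
#' compression an atom experiences inside a molecule:
#' \deqn{V_c(r) = \frac{S}{1 + e^{-(r - r_0)/\gamma}}}
#' a sigmoid wall of height `S` (hartree) centred at the confinement
#' radius `r0` (bohr) with softness `gamma` (bohr).  Inside the cavity
#' (`r << r0`) the wall's influence is exponentially negligible; beyond
#' `r0` the potential rises smoothly and saturates at `S`, so the
#' long-range form of the total potential stays qualitatively that of a
#' free atom (a finite barrier, not a divergent wall).  Increasing `S`
#' raises and steepens the wall at `r = r0` (slope `S / (4 gamma)`).
#'
#' @param r0 Confinement radius (bohr), `> 0`.
#' @param S Wall stiffness/height (hartree), default 4.
#' @param gamma_soft Wall softness (bohr), default 0.1.
#' @param field_strength Finite-difference field probe (a.u.), default 0.01.
#' @return An object of class `confinement_spec`.
#' @export
confinement_spec <- function(r0, S = 4, gamma_soft = 0.1,
                             field_strength = 0.01) {
  if (!is.numeric(r0) || r0 <= 0) stop("r0 must be positive")
  if (S <= 0 || gamma_soft <= 0 || field_strength <= 0) {
    stop("S, gamma_soft and field_strength must be positive")
  }
  structure(list(r0 = r0, S = S, gamma_soft = gamma_soft,
                 field_strength = field_strength),
            class = "confinement_spec")
}

#' @rdname confinement_spec
#' @param r Radial coordinate(s), bohr, `>= 0`.
#' @param spec A `confinement_spec`.
#' @export
confinement_potential <- function(r, spec) {
  if (!inherits(spec, "confinement_spec")) {
    stop("spec must be a confinement_spec")
  }
  if (any(r < 0)) stop("r must be non-negative")
  spec$S / (1 + exp(-(r - spec$r0) / spec$gamma_soft))
}

#' Backend contract for confinement scans
#'
#' [confinement_scan()] drives any electronic-structure backend that can
#' solve an atom with (a) an added spherical one-body potential and (b) a
#' finite uniform field, returning ground-state dipoles and an
#' [rdm_set()].  A backend is a function
#' `backend(element, potential, field)` -> `list(dipole = <z-dipole a.u.>,
#' rdms = <rdm_set or NULL>)`, where `potential` is a function of `r`
#' (or `NULL` for the free atom) and `field` the z-field strength in a.u.
#' ([onecenter_backend()] wires the package's own correlated atomic solver
#' into this contract; [qdo_backend()] provides an inexpensive isotropic
#' Drude-oscillator mock used in tests.)
#'
#' @param element Element symbol understood by the backend.
#' @param r0_values Confinement radii to scan (bohr); `Inf` rows are
#'   evaluated as the free atom.
#' @param spec A [confinement_spec()] carrying `S`, `gamma_soft`, and the
#'   finite-field probe strength (its `r0` is ignored in favour of
#'   `r0_values`).
#' @param backend Backend function (see Details).
#' @return Data frame with one row per `r0`: `r0`, `alpha`, `R2`, `L2`,
#'   `R4_over_alpha`, `L4_over_alpha`, the percentage deviations
#'   `dev_R4_pct`, `dev_L4_pct` from the free-atom row, and `error`
#'   (message for failed rows).
#' @export
confinement_scan <- function(element, r0_values, spec, backend) {
  stopifnot(inherits(spec, "confinement_spec"), is.function(backend))
  E <- spec$field_strength
  run_one <- function(r0) {
    pot <- if (is.infinite(r0)) NULL else {
      sp <- confinement_spec(r0, spec$S, spec$gamma_soft, E)
      function(r) confinement_potential(r, sp)
    }
    up <- backend(element, pot, +E)
    dn <- backend(element, pot, -E)
    z0 <- backend(element, pot, 0)
    alpha <- (up$dipole - dn$dipole) / (2 * E)
    R2 <- L2 <- NA_real_
    if (!is.null(z0$rdms)) {
      cs <- correlated_size(z0$rdms)
      R2 <- cs$R2
      L2 <- cs$R2_uncorrelated
    }
    data.frame(r0 = r0, alpha = alpha, R2 = R2, L2 = L2,
               R4_over_alpha = R2^2 / alpha, L4_over_alpha = L2^2 / alpha,
               error = NA_character_)
  }
  rows <- lapply(r0_values, function(r0) {
    tryCatch(run_one(r0), error = function(e) {
      data.frame(r0 = r0, alpha = NA_real_, R2 = NA_real_, L2 = NA_real_,
                 R4_over_alpha = NA_real_, L4_over_alpha = NA_real_,
                 error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  free <- run_one(Inf)
  out$dev_R4_pct <- 100 * (out$R4_over_alpha / free$R4_over_alpha - 1)
  out$dev_L4_pct <- 100 * (out$L4_over_alpha / free$L4_over_alpha - 1)
  out
}

#' @rdname confinement_scan
#' @export
onecenter_backend <- function(element, potential, field) {
  ab <- atomic_basis(element)
  ints <- onecenter_one_electron(ab$basis, ab$Z, extra_potential = potential)
  h_extra <- if (is.null(ints$Vextra)) NULL else ints$Vextra
  hf <- if (field != 0) {
    fe <- field * ints$z
    if (is.null(h_extra)) fe else h_extra + fe
  } else h_extra
  st <- atomic_state_from_ints(ab, ints, h_extra = hf)
  # physical dipole of the electron cloud: mu_z = -<sum_i z_i>; with the
  # interaction +field * z this makes alpha = d mu / d field positive
  list(dipole = -unname(st$dipole["z"]), rdms = st$rdms)
}

#' @rdname confinement_scan
#' @param alpha0,omega0 Free-oscillator parameters of the mock backend.
#' @export
qdo_backend <- function(alpha0 = 1.5, omega0 = 0.5) {
  # isotropic Drude-oscillator mock: a soft wall of curvature k_w(r0)
  # stiffens the oscillator; exact alpha and exact Gaussian moments
  function(element, potential, field) {
    mu <- 1 / (alpha0 * omega0^2)        # so that free alpha = alpha0
    kw <- if (is.null(potential)) 0 else {
      # effective harmonic stiffening: second derivative of the wall
      # averaged over the free ground-state density (crude but monotone)
      sd0 <- sqrt(1 / (2 * mu * omega0))
      r <- seq(1e-4, 12 * sd0, length.out = 2001)
      w <- r^2 * exp(-mu * omega0 * r^2)
      h <- r[2] - r[1]
      v2 <- diff(diff(potential(r))) / h^2
      sum(w[2:2000] * v2) / sum(w)
    }
    om <- sqrt(omega0^2 + max(kw, 0) / mu)
    al <- 1 / (mu * om^2)
    d <- al * field
    l2 <- 1 / (2 * mu * om)
    # one-particle Gaussian RDM set in a 1-orbital "basis"
    rd <- rdm_set(matrix(1, 1, 1), array(0, dim = rep(1, 4)),
                  matrix(0, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                  matrix(l2, 1, 1), matrix(l2, 1, 1), matrix(l2, 1, 1),
                  n_electrons = 1L)
    list(dipole = d, rdms = rd)
  }
}
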