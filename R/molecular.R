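#' Atoms-in-molecules site list
#'
#' Builds the per-atom site table used by the molecular polarizability
#' models: element, position (bohr), Hirshfeld volume ratio, free-atom
#' reference polarizability and C6, and the derived in-molecule (TS43)
#' polarizability and Gaussian width.
#'
#' @param elements Character vector of element symbols.
#' @param positions `n x 3` matrix of positions in bohr.
#' @param v_ratio Numeric vector of Hirshfeld volume ratios
#'   (`V_eff / V_free`), all `> 0`.
#' @return Data frame of class `aim_sites` with columns `element`, `x`,
#'   `y`, `z`, `v_ratio`, `alpha_free`, `c6_free`, `alpha_ts`,
#'   `alpha_ts43`, `sigma`.
#' @export
aim_sites <- function(elements, positions, v_ratio) {
  positions <- as.matrix(positions)
  n <- length(elements)
  if (n < 1L) stop("at least one site is required")
  if (nrow(positions) != n || ncol(positions) != 3L) {
    stop("positions must be an n x 3 matrix matching 'elements'")
  }
  if (length(v_ratio) != n) stop("v_ratio must match the number of sites")
  if (any(!is.finite(v_ratio)) || any(v_ratio <= 0)) {
    stop("volume ratios must be positive and finite")
  }
  alpha_free <- ref_lookup(elements, "alpha")
  c6_free <- ref_lookup(elements, "c6")
  alpha_ts <- alpha_free * v_ratio
  alpha_ts43 <- alpha_free * v_ratio^(4 / 3)
  df <- data.frame(element = elements,
                   x = positions[, 1], y = positions[, 2], z = positions[, 3],
                   v_ratio = v_ratio,
                   alpha_free = alpha_free, c6_free = c6_free,
                   alpha_ts = alpha_ts, alpha_ts43 = alpha_ts43,
                   sigma = sigma_from_alpha(alpha_ts43),
                   stringsAsFactors = FALSE)
  class(df) <- c("aim_sites", class(df))
  df
}

#' Polarizability tensor object
#'
#' Wraps a symmetric 3x3 dipole polarizability tensor (bohr^3) with its
#' isotropic average and eigenvalue anisotropy.
#'
#' @param matrix Symmetric 3x3 matrix (bohr^3).
#' @return Object of class `polarizability_tensor` with elements `matrix`,
#'   `iso` (trace/3) and `delta_aniso`.
#' @export
polarizability_tensor <- function(matrix) {
  if (!is.matrix(matrix) || any(dim(matrix) != 3L)) {
    stop("a 3 x 3 matrix is required")
  }
  if (max(abs(matrix - t(matrix))) > 1e-10 * max(1, max(abs(matrix)))) {
    stop("polarizability tensor must be symmetric")
  }
  m <- 0.5 * (matrix + t(matrix))
  structure(list(matrix = m, iso = sum(diag(m)) / 3,
                 delta_aniso = anisotropy(m)),
            class = "polarizability_tensor")
}

#' @export
print.polarizability_tensor <- function(x, ...) {
  cat(sprintf("<polarizability tensor> iso = %.4f bohr^3, anisotropy = %.4f bohr^3\n",
              x$iso, x$delta_aniso))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Tensor anisotropy
#'
#' Eigenvalue-based anisotropy invariant
#' `sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / 2)`; zero exactly for an
#' isotropic tensor and invariant under rotations.
#'
#' @param tensor Symmetric 3x3 matrix (or `polarizability_tensor`).
#' @return Non-negative scalar (bohr^3).
#' @export
anisotropy <- function(tensor) {
  if (inherits(tensor, "polarizability_tensor")) tensor <- tensor$matrix
  if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor)))) {
    stop("anisotropy is defined for symmetric tensors")
  }
  l <- eigen(0.5 * (tensor + t(tensor)), symmetric = TRUE,
             only.values = TRUE)$values
  sqrt(max(((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) / 2, 0))
}

#' TS and TS43 molecular polarizability
#'
#' Additive atoms-in-molecules models: the molecular isotropic
#' polarizability is the sum of free-atom values rescaled by the Hirshfeld
#' volume ratio, either linearly (`ts`, the classical
#' volume-proportionality) or with the 4/3 power prescribed by the
#' four-dimensional scaling law (`ts43`).  The returned tensor is
#' isotropic by construction.
#'
#' @param sites An [aim_sites()] table.
#' @return A [polarizability_tensor()].
#' @export
ts_alpha <- function(sites) {
  stopifnot(inherits(sites, "aim_sites"))
  polarizability_tensor(diag(3) * sum(sites$alpha_ts))
}

#' @rdname ts_alpha
#' @export
ts43_alpha <- function(sites) {
  stopifnot(inherits(sites, "aim_sites"))
  polarizability_tensor(diag(3) * sum(sites$alpha_ts43))
}

#' Gaussian width from an atom-in-molecule polarizability
#'
#' Mayer prescription for the width of the Gaussian charge distribution
#' representing a polarizable site:
#' `sigma = (sqrt(2/pi) * alpha / 3)^(1/3)` (bohr), strictly increasing
#' in `alpha`.
#'
#' @param alpha Atom-in-molecule polarizability (bohr^3).
#' @return `sigma` in bohr.
#' @examples
#' sigma_from_alpha(1)  # ~0.6430
#' @export
sigma_from_alpha <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  (sqrt(2 / pi) * alpha / 3)^(1 / 3)
}

#' Combined interaction width of two Gaussian sites
#'
#' Quadrature combination `sigma_jk = sqrt(sigma_j^2 + sigma_k^2)` arising
#' from the convolution of the two Gaussian charge distributions; symmetric
#' in its arguments and reducing to `sigma_j` when the partner width
#' vanishes.
#'
#' @param sigma_j,sigma_k Site widths (bohr), positive.
#' @return Combined width (bohr).
#' @export
combine_sigma <- function(sigma_j, sigma_k) {
  if (any(sigma_j < 0) || any(sigma_k < 0)) stop("widths must be non-negative")
  sqrt(sigma_j^2 + sigma_k^2)
}

#' Gaussian-damped dipole interaction tensor
#'
#' Dipole--dipole interaction tensor of two unit Gaussian charge
#' distributions with combined width `sigma_jk`,
#' `T = grad grad' erf(zeta)/r` with `zeta = r / sigma_jk`:
#' \deqn{T_{ab} = \frac{3 r_a r_b - r^2 \delta_{ab}}{r^5}
#'   \left(\mathrm{erf}(\zeta) - \frac{2\zeta}{\sqrt{\pi}} e^{-\zeta^2}\right)
#'   - \frac{4}{\sqrt{\pi}} \frac{\zeta^3 e^{-\zeta^2}}{r^5}\, r_a r_b / 1}
#' It reduces to the bare point-dipole tensor `(3 rr^T - r^2 I)/r^5` at
#' separations much larger than `sigma_jk` and stays finite as `r -> 0`,
#' which removes the polarization catastrophe of overlapping sites.
#'
#' @param r_vec Length-3 separation vector (bohr).
#' @param sigma_jk Combined Gaussian width (bohr); `Inf` or `bare = TRUE`
#'   gives the bare point-dipole tensor.
#' @param bare If `TRUE`, return the undamped point-dipole tensor.
#' @return 3x3 symmetric tensor (bohr^-3).
#' @export
dipole_tensor_gaussian <- function(r_vec, sigma_jk, bare = FALSE) {
  stopifnot(length(r_vec) == 3L, all(is.finite(r_vec)))
  r2 <- sum(r_vec^2)
  if (bare || is.infinite(sigma_jk)) {
    if (r2 == 0) stop("bare dipole tensor diverges at zero separation")
    r <- sqrt(r2)
    return((3 * tcrossprod(r_vec) - r2 * diag(3)) / r^5)
  }
  if (r2 == 0) {
    # r -> 0 limit of the damped tensor: -(4/(3 sqrt(pi))) sigma^-3 I
    return(diag(3) * (-4 / (3 * sqrt(pi) * sigma_jk^3)))
  }
  r <- sqrt(r2)
  zeta <- r / sigma_jk
  damp1 <- erf_base(zeta) - 2 * zeta * exp(-zeta^2) / sqrt(pi)
  extra <- 4 * zeta^3 * exp(-zeta^2) / sqrt(pi)
  (3 * tcrossprod(r_vec) - r2 * diag(3)) / r^5 * damp1 -
    extra * tcrossprod(r_vec) / r^5
}

erf_base <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Self-consistent screening of atoms-in-molecules polarizabilities
#'
#' Solves the coupled dipole equations
#' `abar_j = alpha_j (I + sum_{k != j} T_jk abar_k)` (with `T_jk` the
#' dipole-field tensor of [dipole_tensor_gaussian()]) for all site tensors
#' simultaneously via one dense `3N x 3N` linear solve: with
#' `B = A^{-1} - T` (block-diagonal `A` of local site polarizabilities,
#' `T` the Gaussian-damped dipole-field tensor with zero self-blocks), the
#' screened site tensor is the block-row sum of `B^{-1}` and the molecular
#' tensor is the sum of all screened site tensors.  The local
#' polarizabilities are the TS43 (4/3-power volume-rescaled) values, so the
#' model reduces to TS43 when all sites decouple.
#'
#' @param sites An [aim_sites()] table.
#' @param bare_t If `TRUE` use undamped point-dipole tensors (useful for
#'   closed-form dimer checks); default uses Gaussian damping.
#' @return List of class `screened_system`: `sites`, `screened_tensors`
#'   (list of 3x3 per site), `molecular_tensor`
#'   ([polarizability_tensor()]), `solver_residual`.
#' @export
scs_screen <- function(sites, bare_t = FALSE) {
  stopifnot(inherits(sites, "aim_sites"))
  n <- nrow(sites)
  pos <- as.matrix(sites[, c("x", "y", "z")])
  alpha_loc <- sites$alpha_ts43
  B <- matrix(0, 3 * n, 3 * n)
  Tfull <- matrix(0, 3 * n, 3 * n)
  for (j in seq_len(n)) {
    idx <- (3 * (j - 1) + 1):(3 * j)
    B[idx, idx] <- diag(3) / alpha_loc[j]
    for (k in seq_len(n)) {
      if (k == j) next
      kdx <- (3 * (k - 1) + 1):(3 * k)
      Tjk <- dipole_tensor_gaussian(pos[j, ] - pos[k, ],
                                    combine_sigma(sites$sigma[j],
                                                  sites$sigma[k]),
                                    bare = bare_t)
      B[idx, kdx] <- -Tjk    # dipole-field convention: B = A^-1 - T
      Tfull[idx, kdx] <- Tjk
    }
  }
  rc <- rcond(B)
  if (!is.finite(rc) || rc < 1e-14) {
    stop("screening system is numerically singular ",
         "(reciprocal condition number ", format(rc), "); ",
         "overlapping or unphysical site polarizabilities")
  }
  E <- do.call(rbind, replicate(n, diag(3), simplify = FALSE))  # stacked I
  X <- solve(B, E)                     # X_j = sum_k (B^-1)_{jk}
  screened <- lapply(seq_len(n), function(j) {
    idx <- (3 * (j - 1) + 1):(3 * j)
    X[idx, , drop = FALSE]
  })
  # fixed-point residual of abar_j = alpha_j (I + sum_k T_jk abar_k)
  resid <- 0
  for (j in seq_len(n)) {
    idx <- (3 * (j - 1) + 1):(3 * j)
    rhs <- diag(3)
    for (k in seq_len(n)) {
      if (k == j) next
      kdx <- (3 * (k - 1) + 1):(3 * k)
      rhs <- rhs + Tfull[idx, kdx] %*% screened[[k]]
    }
    resid <- max(resid, max(abs(screened[[j]] - alpha_loc[j] * rhs)))
  }
  mol <- Reduce(`+`, screened)
  mol <- 0.5 * (mol + t(mol))
  structure(list(sites = sites, screened_tensors = screened,
                 molecular_tensor = polarizability_tensor(mol),
                 solver_residual = resid),
            class = "screened_system")
}

#' @export
print.screened_system <- function(x, ...) {
  cat("<screened system> ", nrow(x$sites), " sites, residual ",
      format(x$solver_residual, digits = 3), "\n", sep = "")
  print(x$molecular_tensor)
  invisible(x)
}

#' Molecular polarizability by model name
#'
#' Convenience dispatcher over [ts_alpha()], [ts43_alpha()] and
#' [scs_screen()].
#'
#' @param sites An [aim_sites()] table.
#' @param method `"ts"`, `"ts43"` or `"scs43"`.
#' @param bare_t Passed to [scs_screen()].
#' @return A [polarizability_tensor()].
#' @export
molecular_alpha <- function(sites, method = c("ts43", "ts", "scs43"),
                            bare_t = FALSE) {
  method <- match.arg(method)
  switch(method,
    ts = ts_alpha(sites),
    ts43 = ts43_alpha(sites),
    scs43 = scs_screen(sites, bare_t = bare_t)$molecular_tensor)
}

#' Pairwise dispersion energy
#'
#' Sum of damped pairwise dipole--dipole dispersion terms
#' `E = -sum_{A<B} f_damp(R_AB) C6_AB / R_AB^6`, with per-pair C6 obtained
#' from the volume-rescaled atomic coefficients ([c6_rescale()], exponent
#' 2) combined through the Slater--Kirkwood rule with the embedded
#' effective electron numbers.  The damping function is supplied by the
#' caller; the default applies no damping.
#'
#' @param sites An [aim_sites()] table.
#' @param damping Function of distance (bohr) returning a factor in
#'   `[0, 1]`; default `function(r) 1`.
#' @return Dispersion energy in hartree (non-positive for non-negative
#'   damping).
#' @export
ts_dispersion_energy <- function(sites, damping = function(r) 1) {
  stopifnot(inherits(sites, "aim_sites"))
  n <- nrow(sites)
  if (n < 2L) return(0)
  ne <- effective_electrons()
  i <- match(sites$element, ne$element)
  if (any(is.na(i))) {
    stop("no effective electron data for element(s): ",
         paste(unique(sites$element[is.na(i)]), collapse = ", "))
  }
  neff <- ne$n_eff[i]
  alpha_aim <- sites$alpha_ts43
  c6_aim <- c6_rescale(sites$c6_free, sites$v_ratio)
  # consistent effective frequencies from the rescaled atomic pairs
  pos <- as.matrix(sites[, c("x", "y", "z")])
  E <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      Rab <- sqrt(sum((pos[a, ] - pos[b, ])^2))
      c6ab <- slater_kirkwood_c6(alpha_aim[a], alpha_aim[b],
                                 neff[a], neff[b])
      E <- E - damping(Rab) * c6ab / Rab^6
    }
  }
  E
}
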