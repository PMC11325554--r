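# Restricted Hartree-Fock and integral transformation for the one-center
# atomic backend.

sym_orth <- function(S) {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) {
    stop("overlap matrix is near-singular (min eigenvalue ",
         format(min(es$values)), "); basis is linearly dependent")
  }
  es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
}

#' Restricted Hartree--Fock for a closed-shell atom
#'
#' Plain Roothaan iterations with generalized-eigenvalue diagonalization
#' through symmetric orthogonalization; adequate for spherically symmetric
#' closed-shell atoms where SCF convergence is benign.
#'
#' @param ints One-electron integrals from [onecenter_one_electron()].
#' @param eri ERI tensor from [onecenter_eri()].
#' @param nocc Number of doubly occupied spatial orbitals.
#' @param h_extra Optional extra one-electron operator matrix added to the
#'   core Hamiltonian (confining potential, finite field, ...).
#' @param maxiter,tol SCF control parameters.
#' @return List `energy`, `eps` (orbital energies), `C` (MO coefficients),
#'   `converged`.
#' @export
rhf_atom <- function(ints, eri, nocc, h_extra = NULL,
                     maxiter = 200L, tol = 1e-10) {
  H <- ints$T + ints$V
  if (!is.null(h_extra)) H <- H + h_extra
  n <- nrow(H)
  X <- sym_orth(ints$S)
  eig_in_oao <- function(F) {
    Ft <- t(X) %*% F %*% X
    es <- eigen(0.5 * (Ft + t(Ft)), symmetric = TRUE)
    ord <- order(es$values)              # eigen() sorts decreasing
    list(eps = es$values[ord], C = X %*% es$vectors[, ord, drop = FALSE])
  }
  sol <- eig_in_oao(H)
  Em <- matrix(eri, n * n, n * n)          # (pq | rs) as [pq, rs]
  Ex <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)  # (pr | qs) as [pq, rs]
  Eold <- 0; conv <- FALSE; E <- NA_real_
  for (it in seq_len(maxiter)) {
    Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
    P <- 2 * tcrossprod(Cocc)
    J <- matrix(Em %*% as.vector(P), n, n)
    K <- matrix(Ex %*% as.vector(P), n, n)
    F <- H + J - 0.5 * K
    E <- 0.5 * sum(P * (H + F))
    if (abs(E - Eold) < tol && it > 3) { conv <- TRUE; break }
    Eold <- E
    sol <- eig_in_oao(F)
  }
  list(energy = E, eps = sol$eps, C = sol$C, converged = conv)
}

# AO -> MO transform of the chemist-order ERI tensor
mo_transform_eri <- function(eri, C) {
  n <- nrow(C)
  t1 <- matrix(C, n, n)
  v <- eri
  # transform one index at a time: (pqrs) with p fastest (column-major)
  for (pass in 1:4) {
    m <- matrix(v, n, n^3)               # first index x rest
    v <- array(crossprod(t1, m), dim = rep(n, 4))
    v <- aperm(v, c(2, 3, 4, 1))         # rotate so next index comes first
  }
  v
}

mo_rotate <- function(M, C) crossprod(C, M %*% C)
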