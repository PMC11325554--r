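# shared test helpers: random rotations, tiny RDM fixtures built in code

rand_rotation <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(M)) * sign(det(qr.Q(qr(M))))
}

# hydrogen-like 1s RDM set in a 1-orbital basis: <r^2> = 3/Z^2, Gamma = 0
hydrogen_rdm_fixture <- function(Z = 1) {
  rdm_set(gamma = matrix(1, 1, 1),
          Gamma = array(0, dim = rep(1, 4)),
          x = matrix(0, 1, 1), y = matrix(0, 1, 1), z = matrix(0, 1, 1),
          xx = matrix(1 / Z^2, 1, 1), yy = matrix(1 / Z^2, 1, 1),
          zz = matrix(1 / Z^2, 1, 1),
          n_electrons = 1L)
}

# closed-shell two-electron determinant in a 2-orbital basis with both
# electrons in orbital 1; mean-field (Hartree-Fock) RDMs:
#   gamma = diag(2, 0),  Gamma[p,q,r,s] = g_pq g_rs - 1/2 g_ps g_rq
determinant_rdm_fixture <- function(x01 = 0.3, x2_diag = c(1.0, 2.5)) {
  g <- diag(c(2, 0))
  G <- array(0, dim = rep(2, 4))
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    G[p, q, r, s] <- g[p, q] * g[r, s] - 0.5 * g[p, s] * g[r, q]
  }
  xm <- matrix(c(0, x01, x01, 0), 2, 2)
  z0 <- matrix(0, 2, 2)
  rdm_set(g, G, xm, z0, z0,
          diag(x2_diag), diag(x2_diag), diag(x2_diag),
          n_electrons = 2L)
}
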