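# one-center integral engine and correlated atomic solver

test_that("primitive one-electron integrals match Gaussian closed forms", {
  for (l in 0:3) {
    a <- c(8.092, 0.1133)[1 + l %% 2]
    b <- onecenter_basis(list(gauss_shell(l, a)))
    ii <- onecenter_one_electron(b, Z = 1)
    expect_equal(ii$S[1, 1], 1, tolerance = 1e-12)
    expect_equal(ii$T[1, 1], a * (2 * l + 3) / 2, tolerance = 1e-12)
    expect_equal(ii$V[1, 1], -sqrt(2 * a) * gamma(l + 1) / gamma(l + 1.5),
                 tolerance = 1e-11)
    expect_equal(ii$xx[1, 1] + ii$yy[1, 1] + ii$zz[1, 1],
                 (l + 1.5) / (2 * a), tolerance = 1e-12)
  }
})

test_that("s-type repulsion integrals match the one-center closed form", {
  b <- onecenter_basis(list(gauss_shell(0, 0.8), gauss_shell(0, 1.7)))
  V <- onecenter_eri(b)
  exact <- function(a1, a2) {
    nrm <- function(a) sqrt(2 * (2 * a)^1.5 / gamma(1.5)) / sqrt(4 * pi)
    2 * pi^2.5 / ((2 * a1) * (2 * a2) * sqrt(2 * a1 + 2 * a2)) *
      nrm(a1)^2 * nrm(a2)^2
  }
  expect_equal(V[1, 1, 2, 2], exact(0.8, 1.7), tolerance = 1e-9)
  expect_equal(V[1, 1, 1, 1], exact(0.8, 0.8), tolerance = 1e-9)
  # chemist-order permutation symmetry
  expect_equal(V[1, 2, 2, 1], V[2, 1, 1, 2], tolerance = 1e-12)
})

test_that("the real spherical harmonics are orthonormal", {
  g <- ang_grid()
  lm <- expand.grid(l = 0:3, m = -3:3)
  lm <- lm[abs(lm$m) <= lm$l, ]
  M <- sapply(seq_len(nrow(lm)),
              function(i) as.vector(real_sph(lm$l[i], lm$m[i], g)))
  Gm <- t(M * as.vector(g$W)) %*% M
  expect_lt(max(abs(Gm - diag(nrow(lm)))), 1e-12)
})

test_that("the helium solver hits its mean-field and correlated anchors", {
  st <- atomic_state("He")
  # published aug-tz restricted Hartree-Fock value
  expect_equal(st$e_hf, -2.861153, tolerance = 1e-4)
  # two-electron CISD == full CI in the basis
  expect_equal(st$e_total, -2.900598, tolerance = 1e-5)
  # spherical symmetry: zero dipole, isotropic second moments
  expect_lt(max(abs(st$dipole)), 1e-8)
  cs <- correlated_size(st$rdms)
  expect_equal(3 * sum(st$rdms$gamma * st$rdms$xx), cs$R2_uncorrelated,
               tolerance = 1e-8)
})

test_that("a finite field polarizes the helium atom by its CI polarizability", {
  ab <- atomic_basis("He")
  ints <- onecenter_one_electron(ab$basis, ab$Z)
  E <- 0.01
  up <- atomic_state("He", h_extra = +E * ints$z)
  dn <- atomic_state("He", h_extra = -E * ints$z)
  # the interaction +E z displaces the (negative) electrons towards -z, so
  # the physical dipole response is -d<z>/dE
  alpha_ff <- -(up$dipole["z"] - dn$dipole["z"]) / (2 * E)
  # correlated helium polarizability in a finite basis: near the reference
  # 1.38 a.u. but below it (basis-set truncation)
  expect_gt(alpha_ff, 1.15)
  expect_lt(alpha_ff, 1.45)
  # energy drops quadratically in the field
  expect_lt(up$e_total, -2.900)
  expect_equal(up$e_total, dn$e_total, tolerance = 1e-8)
})
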