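# atoms-in-molecules polarizability models

test_that("TS and TS43 are volume-weighted sums of free-atom values", {
  one <- aim_sites("He", matrix(0, 1, 3), 1)
  expect_equal(ts_alpha(one)$matrix, diag(3) * 1.38)
  two <- aim_sites(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, 5)), c(1, 1))
  expect_equal(ts_alpha(two)$iso, 2 * 1.38)
  expect_equal(ts43_alpha(two)$iso, ts_alpha(two)$iso)  # exponent moot at v=1
  # linear weight and 4/3-power weight
  s <- aim_sites("Ne", matrix(0, 1, 3), 0.8)
  expect_equal(ts_alpha(s)$iso, 2.67 * 0.8)
  expect_equal(ts43_alpha(s)$iso, 2.67 * 0.8^(4 / 3))
  # convexity around v = 1
  lo <- aim_sites("C", matrix(0, 1, 3), 0.8)
  hi <- aim_sites("C", matrix(0, 1, 3), 1.2)
  expect_lt(ts43_alpha(lo)$iso, ts_alpha(lo)$iso)
  expect_gt(ts43_alpha(hi)$iso, ts_alpha(hi)$iso)
  expect_error(aim_sites("Xx", matrix(0, 1, 3), 1), "no reference data")
  expect_error(aim_sites(character(0), matrix(0, 0, 3), numeric(0)),
               "at least one site")
})

test_that("Gaussian widths follow the cube-root prescription", {
  expect_equal(sigma_from_alpha(1), (sqrt(2 / pi) / 3)^(1 / 3))
  expect_equal(sigma_from_alpha(8), 2 * sigma_from_alpha(1))
  a <- sort(stats::runif(20, 0.1, 30))
  expect_true(all(diff(sigma_from_alpha(a)) > 0))
  expect_equal(combine_sigma(1, 1), sqrt(2))
  expect_equal(combine_sigma(0.3, 0.7), combine_sigma(0.7, 0.3))
  expect_equal(combine_sigma(0.5, 0), 0.5)
})

test_that("the damped dipole tensor interpolates bare and finite limits", {
  r <- c(1.2, -0.7, 2.0)
  sig <- 0.6
  far <- r * (20 * sig / sqrt(sum(r^2)))   # |far| = 20 sigma
  Td <- dipole_tensor_gaussian(far, sig)
  Tb <- dipole_tensor_gaussian(far, sig, bare = TRUE)
  expect_lt(max(abs(Td - Tb)) / max(abs(Tb)), 1e-10)
  expect_equal(sum(diag(Tb)), 0, tolerance = 1e-12)   # harmonic identity
  near <- dipole_tensor_gaussian(c(0, 0, 0), sig)
  expect_true(all(is.finite(near)))
  expect_error(dipole_tensor_gaussian(c(0, 0, 0), sig, bare = TRUE),
               "diverges")
  # symmetry
  Tm <- dipole_tensor_gaussian(r, sig)
  expect_lt(max(abs(Tm - t(Tm))), 1e-14)
})

test_that("screening reproduces the two-point-dipole closed form", {
  for (r in c(3, 5, 10, 25, 50)) {
    s <- aim_sites(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, r)), c(1, 1))
    a <- s$alpha_ts43[1]
    sys <- scs_screen(s, bare_t = TRUE)
    ev <- diag(sys$molecular_tensor$matrix)
    expect_equal(ev[3], 2 * a / (1 - 2 * a / r^3), tolerance = 1e-8)
    expect_equal(ev[1], 2 * a / (1 + a / r^3), tolerance = 1e-8)
    expect_equal(ev[2], ev[1], tolerance = 1e-10)
    expect_lt(sys$solver_residual, 1e-10)
  }
})

test_that("a single site passes through the screen unchanged", {
  s <- aim_sites("N", matrix(1.5, 1, 3), 0.9)
  sys <- scs_screen(s)
  expect_equal(sys$molecular_tensor$matrix, diag(3) * s$alpha_ts43[1],
               tolerance = 1e-12)
  expect_lt(sys$solver_residual, 1e-12)
})

test_that("distant sites decouple to the TS43 tensor", {
  s <- aim_sites(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 800)), c(0.9, 1.05))
  sys <- scs_screen(s)
  expect_equal(sys$molecular_tensor$iso, ts43_alpha(s)$iso, tolerance = 1e-6)
  expect_lt(anisotropy(sys$molecular_tensor), 1e-4)
})

test_that("all three models are rotation-equivariant, translation- and permutation-invariant", {
  fx <- generate_fixture(6, seed = 11)
  s <- fx$sites
  Q <- rand_rotation(3)
  pos_rot <- fx$positions %*% t(Q)
  s_rot <- aim_sites(fx$elements, pos_rot, fx$v_ratio)
  for (m in c("ts", "ts43", "scs43")) {
    A <- molecular_alpha(s, m)$matrix
    Ar <- molecular_alpha(s_rot, m)$matrix
    expect_lt(max(abs(Ar - Q %*% A %*% t(Q))), 1e-9)
  }
  # translation
  s_tr <- aim_sites(fx$elements,
                    fx$positions + matrix(c(3, -2, 7), 6, 3, byrow = TRUE),
                    fx$v_ratio)
  expect_equal(molecular_alpha(s_tr, "scs43")$matrix,
               molecular_alpha(s, "scs43")$matrix, tolerance = 1e-10)
  # permutation
  pm <- c(4, 1, 6, 2, 5, 3)
  s_pm <- aim_sites(fx$elements[pm], fx$positions[pm, ], fx$v_ratio[pm])
  expect_equal(molecular_alpha(s_pm, "scs43")$matrix,
               molecular_alpha(s, "scs43")$matrix, tolerance = 1e-10)
})

test_that("anisotropy is the eigenvalue spread invariant", {
  expect_equal(anisotropy(diag(3) * 4), 0)
  expect_equal(anisotropy(diag(c(2, 1, 1))), 1)
  Q <- rand_rotation(5)
  A <- diag(c(3.2, 1.1, 0.7))
  expect_equal(anisotropy(Q %*% A %*% t(Q)), anisotropy(A),
               tolerance = 1e-10)
  expect_gte(anisotropy(Q %*% A %*% t(Q)), 0)
  expect_error(anisotropy(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3)),
               "symmetric")
})

test_that("pairwise dispersion energy follows the damped -C6/R^6 form", {
  s <- aim_sites(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, 6)), c(1, 1))
  ne <- effective_electrons()
  nHe <- ne$n_eff[ne$element == "He"]
  c6 <- slater_kirkwood_c6(1.38, 1.38, nHe, nHe)
  expect_equal(ts_dispersion_energy(s), -c6 / 6^6, tolerance = 1e-12)
  expect_equal(ts_dispersion_energy(s, damping = function(r) 0), 0)
  expect_equal(ts_dispersion_energy(s, damping = function(r) 0.5),
               -0.5 * c6 / 6^6, tolerance = 1e-12)
  one <- aim_sites("He", matrix(0, 1, 3), 1)
  expect_equal(ts_dispersion_energy(one), 0)
})
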