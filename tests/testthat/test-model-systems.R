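# one-electron model Hamiltonians: roots, counts, lengths, polarizabilities

test_that("finite-square-well ground-state root solves the boundary condition", {
  for (z0 in c(0.01, 0.3, 1, pi / 2, 5, 10)) {
    z <- solve_fsw_ground(z0)
    expect_lt(abs(z * tan(z) - sqrt(z0^2 - z^2)), 1e-12)
    expect_gt(z, 0)
    expect_lt(z, min(z0, pi / 2))
  }
  # shallow-well limit z -> z0
  expect_lt(abs(solve_fsw_ground(0.01) - 0.01), 1e-5)
  expect_error(solve_fsw_ground(-1), "positive")
  expect_error(solve_fsw_ground(0), "positive")
})

test_that("bound-state count matches the floor formula and a root-counting oracle", {
  expect_identical(bound_state_count(1), 1L)
  expect_identical(bound_state_count(5), 4L)
  expect_identical(bound_state_count(10), 7L)
  # independent oracle: count even roots of z tan z = sqrt(z0^2 - z^2) and
  # odd roots of -z cot z = sqrt(z0^2 - z^2) by sign changes on a fine grid
  count_roots <- function(z0) {
    zg <- seq(1e-6, z0 * (1 - 1e-12), length.out = 200000)
    rhs <- sqrt(z0^2 - zg^2)
    f_even <- zg * tan(zg) - rhs
    f_odd <- -zg / tan(zg) - rhs
    nz <- function(f) {
      ok <- is.finite(f)
      sum(diff(sign(f[ok])) != 0 & abs(diff(f[ok])) < z0 * 10)
    }
    nz(f_even) + nz(f_odd)
  }
  for (z0 in c(0.5, 2, 5, 10)) {
    expect_identical(bound_state_count(z0), as.integer(count_roots(z0)))
  }
  # half-open threshold convention: a marginal state at 2 z0/pi integer is
  # counted as bound
  expect_identical(bound_state_count(pi / 2), 2L)
  expect_identical(bound_state_count(pi / 2 - 1e-9), 1L)
})

test_that("characteristic length matches closed forms and is grid-stable", {
  st <- ground_state_1d(model1d("qdo"))
  expect_equal(characteristic_length(st), sqrt(0.5), tolerance = 1e-7)
  st_d <- ground_state_1d(model1d("delta"), n = 16001L)
  expect_equal(characteristic_length(st_d), sqrt(0.5), tolerance = 1e-4)
  # refinement invariance
  L1 <- characteristic_length(ground_state_1d(model1d("fsw", z0 = 5), n = 8001L))
  L2 <- characteristic_length(ground_state_1d(model1d("fsw", z0 = 5), n = 16001L))
  expect_lt(abs(L1 - L2), 1e-6)
  # unnormalized state rejected
  bad <- st; bad$psi <- 2 * bad$psi
  expect_error(characteristic_length(bad), "normalized")
})

test_that("exact polarizabilities reproduce the closed forms", {
  expect_equal(polarizability_exact(model1d("qdo")), 1)
  expect_equal(polarizability_exact(model1d("qdo", mu = 2, omega = 3, q = 2)),
               4 / (2 * 9))
  expect_equal(polarizability_exact(model1d("delta")), 1.25)
  expect_equal(polarizability_exact(model1d("hydrogen_like")), 4.5)
  # particle in a box: series against the independent box oracle
  a_series <- polarizability_exact(model1d("piab"))
  so <- sum_over_states_oracle(model1d("piab"), basis_size = 2000L)
  expect_equal(a_series, so$alpha, tolerance = 1e-5)
})

test_that("the C coefficient convention pins the three printed constants", {
  expect_equal(c_coefficient(1, sqrt(0.5)), 1)                   # QDO
  expect_equal(c_coefficient(4.5, 1), 1.125)                     # hydrogen
  expect_equal(c_coefficient(1.25, sqrt(0.5)), 1.25)             # delta well
  expect_error(c_coefficient(-1, 1), "positive")
})

test_that("hydrogen-like scaling invariance: alpha ~ Z^-4, L ~ 1/Z, C fixed", {
  for (Z in c(1, 2, 3)) {
    a <- polarizability_exact(model1d("hydrogen_like", Z = Z))
    expect_equal(a, 4.5 / Z^4)
    expect_equal(c_coefficient(a, 1 / Z), 1.125)
  }
  # numerical Dalgarno-Lewis agrees at Z = 2
  expect_equal(hydrogen_alpha_dalgarno_lewis(Z = 2), 4.5 / 16,
               tolerance = 1e-5)
})

test_that("Dalgarno-Lewis and the box oracle agree for the square well", {
  for (z0 in c(0.5, 5, 10)) {
    m <- model1d("fsw", z0 = z0)
    exact <- polarizability_exact(m)
    st <- ground_state_1d(m)
    adl <- polarizability_dalgarno_lewis(st, model_potential(m))
    expect_equal(adl, exact, tolerance = 2e-3)
    so <- sum_over_states_oracle(m, basis_size = 1500L)
    expect_equal(so$alpha, exact, tolerance = 5e-3)
  }
})

test_that("the quantum Drude oscillator has a single dipole-active transition", {
  so <- sum_over_states_oracle(model1d("qdo"), basis_size = 1200L)
  terms <- sort(so$alpha_terms, decreasing = TRUE)
  expect_equal(terms[1] / sum(terms), 1, tolerance = 1e-6)
  expect_true(so$box_ok)
})

test_that("C(z0) stays within the delta-well and box limits", {
  z0s <- exp(seq(log(0.01), log(10), length.out = 40))
  tab <- scan_c_vs_z0(z0s)
  expect_false(anyNA(tab$C))
  expect_true(all(tab$C <= 1.25 + 1e-6))
  expect_true(all(tab$C >= 1.0 - 1e-6))
  # shallow limit -> delta value, deep well -> box value
  expect_equal(tab$C[1], 1.25, tolerance = 0.01)
  C_piab <- c_coefficient(polarizability_exact(model1d("piab")),
                          model_L_exact(model1d("piab")))
  expect_equal(tab$C[length(z0s)], C_piab, tolerance = 0.01)
  # empty input -> empty table
  empty <- scan_c_vs_z0(numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("z0", "z", "n_bound", "L", "alpha", "C"))
})

test_that("hydrogen continuum carries about a fifth of the polarizability", {
  hc <- hydrogen_continuum_share()
  expect_gt(hc$continuum_share, 0.17)
  expect_lt(hc$continuum_share, 0.22)
  # the discrete series must converge (tail below 1e-8 by nmax = 2000)
  hc2 <- hydrogen_continuum_share(nmax = 1000L)
  expect_equal(hc$alpha_discrete, hc2$alpha_discrete, tolerance = 1e-5)
})
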