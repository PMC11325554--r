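# soft-wall confinement potential and the backend-driven scan

test_that("the soft wall is negligible inside and saturates outside", {
  sp <- confinement_spec(r0 = 4, S = 4, gamma_soft = 0.1)
  expect_lt(confinement_potential(0.5, sp), 1e-10)
  expect_lt(confinement_potential(2, sp), 1e-6)
  expect_equal(confinement_potential(4, sp), 2)       # half height at r0
  expect_equal(confinement_potential(40, sp), 4, tolerance = 1e-10)
  expect_error(confinement_potential(-1, sp), "non-negative")
  expect_error(confinement_spec(-1), "positive")
  # larger stiffness -> higher and steeper wall at and beyond r0
  hi <- confinement_spec(r0 = 4, S = 8, gamma_soft = 0.1)
  r <- seq(4, 8, by = 0.5)
  expect_true(all(confinement_potential(r, hi) >
                    confinement_potential(r, sp)))
})

test_that("the scan normalizes to the free atom and compresses the response", {
  sc <- confinement_scan("mock", c(Inf, 6, 4, 3),
                         confinement_spec(4), qdo_backend(alpha0 = 2))
  expect_true(all(is.na(sc$error)))
  free <- sc[is.infinite(sc$r0), ]
  expect_equal(free$dev_R4_pct, 0, tolerance = 1e-10)
  expect_equal(free$alpha, 2, tolerance = 1e-8)
  # tighter walls reduce the polarizability monotonically
  finite <- sc[is.finite(sc$r0), ]
  expect_true(all(diff(finite$alpha[order(finite$r0)]) >= 0))
  expect_true(all(is.finite(sc$R4_over_alpha)))
})

test_that("row-level failures are recorded without aborting the scan", {
  boom <- function(element, potential, field) {
    if (!is.null(potential)) stop("backend convergence failure")
    list(dipole = 0.5 * field * 2, rdms = hydrogen_rdm_fixture())
  }
  sc <- confinement_scan("mock", c(Inf, 3), confinement_spec(3), boom)
  expect_true(is.na(sc$alpha[2]))
  expect_match(sc$error[2], "convergence")
  expect_false(is.na(sc$alpha[1]))
})

test_that("the package's own correlated backend satisfies the scan contract", {
  # two-point helium scan: free atom plus one confined radius
  sc <- confinement_scan("He", c(Inf, 2.5), confinement_spec(2.5),
                         onecenter_backend)
  expect_true(all(is.na(sc$error)))
  # confinement raises energy levels and lowers the polarizability
  expect_lt(sc$alpha[2], sc$alpha[1])
  expect_gt(sc$alpha[2], 0)
  # the size metric shrinks with the response
  expect_lt(sc$R2[2], sc$R2[1])
  # free-atom normalization row
  expect_equal(sc$dev_R4_pct[1], 0, tolerance = 1e-8)
  # the correlated invariant moves less than the polarizability itself
  expect_lt(abs(sc$dev_R4_pct[2]),
            100 * abs(sc$alpha[2] / sc$alpha[1] - 1))
})
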