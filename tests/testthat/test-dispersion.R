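# Slater-Kirkwood combination, Drude dynamic response, volume rescaling

test_that("homoatomic Slater-Kirkwood reduces to (3/4) sqrt(N) alpha^(3/2)", {
  for (al in c(0.8, 1.38, 11.1)) {
    for (nn in c(0.9, 1.74, 7.4)) {
      expect_equal(slater_kirkwood_c6(al, al, nn, nn),
                   0.75 * sqrt(nn) * al^1.5, tolerance = 1e-12)
    }
  }
  expect_error(slater_kirkwood_c6(1, 1), "required")
  expect_error(slater_kirkwood_c6(-1, 1, 1, 1), "positive")
})

test_that("Slater-Kirkwood is the London formula with Unsoeld frequencies", {
  # omega_X = sqrt(N_X / alpha_X); heteroatomic SK equals the two-oscillator
  # London expression 3/2 * aA aB wA wB / (wA + wB)
  aA <- 1.38; nA <- 1.74; aB <- 11.1; nB <- 7.4
  wA <- sqrt(nA / aA); wB <- sqrt(nB / aB)
  london <- 1.5 * aA * aB * wA * wB / (wA + wB)
  expect_equal(slater_kirkwood_c6(aA, aB, nA, nB), london, tolerance = 1e-12)
})

test_that("Casimir-Polder quadrature reproduces the London closed form", {
  expect_equal(casimir_polder_c6(1, 1, 1, 1), 0.75, tolerance = 1e-10)
  set.seed(42)
  for (k in 1:10) {
    a <- stats::runif(2, 0.5, 20)
    w <- stats::runif(2, 0.1, 2)
    exact <- 1.5 * a[1] * a[2] * w[1] * w[2] / (w[1] + w[2])
    expect_equal(casimir_polder_c6(a[1], w[1], a[2], w[2]), exact,
                 tolerance = 1e-9)
  }
})

test_that("Drude dynamic polarizability obeys its closed-form checkpoints", {
  expect_equal(qdo_dynamic_alpha(2.5, 0.7, 0), 2.5)
  expect_equal(qdo_dynamic_alpha(2.5, 0.7, 0.7), 1.25)
  # (3/pi) int alpha(iw)^2 dw = (3/4) alpha0^2 omega_eff
  a0 <- 1.7; w0 <- 0.45
  gl <- pracma::gaussLegendre(200, -1, 1)
  w <- w0 * (1 + gl$x) / (1 - gl$x)
  dw <- 2 * w0 / (1 - gl$x)^2
  quad <- (3 / pi) * sum(gl$w * qdo_dynamic_alpha(a0, w0, w)^2 * dw)
  expect_equal(quad, 0.75 * a0^2 * w0, tolerance = 1e-8)
})

test_that("effective frequency inversion round-trips through Casimir-Polder", {
  expect_equal(omega_eff_from(1, 0.75), 1)
  set.seed(7)
  for (k in 1:8) {
    a0 <- stats::runif(1, 0.5, 25)
    c6 <- stats::runif(1, 0.5, 150)
    w <- omega_eff_from(a0, c6)
    expect_equal(casimir_polder_c6(a0, w, a0, w), c6, tolerance = 1e-8)
  }
  # scaling identity: C6 -> v^2 C6 and alpha -> v^(4/3) alpha
  # imply omega_eff -> v^(-2/3) omega_eff
  a0 <- 5; c6 <- 40; v <- 0.62
  expect_equal(omega_eff_from(a0 * v^(4 / 3), c6 * v^2),
               omega_eff_from(a0, c6) * v^(-2 / 3), tolerance = 1e-12)
})

test_that("C6 volume rescaling uses the square of the volume ratio", {
  expect_equal(c6_rescale(10, 1), 10)
  expect_equal(c6_rescale(10, 0.5), 2.5)
  # consistency with Slater-Kirkwood at alpha ~ v^(4/3), fixed n_eff:
  # C6(v) / C6(1) = (v^(4/3))^(3/2) = v^2
  al <- 7.4; nn <- 3.61; v <- 0.8
  ratio <- slater_kirkwood_c6(al * v^(4 / 3), al * v^(4 / 3), nn, nn) /
    slater_kirkwood_c6(al, al, nn, nn)
  expect_equal(ratio, v^2, tolerance = 1e-12)
  expect_error(c6_rescale(10, -0.1), "positive")
})

test_that("C6 increases with either polarizability", {
  base <- slater_kirkwood_c6(5, 7, 3, 4)
  expect_gt(slater_kirkwood_c6(6, 7, 3, 4), base)
  expect_gt(slater_kirkwood_c6(5, 8, 3, 4), base)
})

test_that("embedded effective electron numbers rise across each period", {
  ne <- effective_electrons()
  get <- function(els) ne$n_eff[match(els, ne$element)]
  expect_true(all(diff(get(c("Li", "Be", "B", "C", "N", "O", "F", "Ne"))) > 0))
  expect_true(all(diff(get(c("Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"))) > 0))
  expect_true(all(ne$n_eff > 0))
})
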