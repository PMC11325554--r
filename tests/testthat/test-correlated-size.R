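# correlated size functional, RDM container, effective electron numbers

test_that("one-electron reduction: hydrogen gives R2 = 3 and n_eff = 8/9", {
  rd <- hydrogen_rdm_fixture(Z = 1)
  cs <- correlated_size(rd)
  expect_equal(cs$R2, 3)
  expect_equal(cs$cross_term, 0)
  expect_equal(cs$R2, cs$R2_uncorrelated + cs$cross_term)
  expect_equal(neff_from_alpha_size(cs, 4.5), 8 / 9)
  # consistency with the one-electron law: n_eff = 1/C for hydrogen
  expect_equal(neff_from_alpha_size(cs, 4.5), 1 / c_coefficient(4.5, 1))
})

test_that("mean-field determinant cross term matches explicit 2-orbital algebra", {
  # closed-shell determinant, both electrons in orbital 1, general symmetric
  # position matrix: <sum_{i!=j} x_i x_j> = (tr g x)^2 - tr(g x g x)/2
  g <- diag(c(2, 0))
  G <- array(0, dim = rep(2, 4))
  for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
    G[p, q, r, s] <- g[p, q] * g[r, s] - 0.5 * g[p, s] * g[r, q]
  }
  xm <- matrix(c(0.4, 0.3, 0.3, -0.2), 2, 2)
  z0 <- matrix(0, 2, 2)
  rd <- rdm_set(g, G, xm, z0, z0, diag(c(1, 2.5)), diag(c(1, 2.5)),
                diag(c(1, 2.5)), n_electrons = 2L)
  cs <- correlated_size(rd)
  brute <- sum(diag(g %*% xm))^2 - 0.5 * sum(diag(g %*% xm %*% g %*% xm))
  expect_equal(cs$cross_term, brute, tolerance = 1e-12)
  expect_equal(cs$R2, cs$R2_uncorrelated + cs$cross_term)
})

test_that("rdm_set validates trace conditions and converts the half dialect", {
  rd <- determinant_rdm_fixture()
  # breaking the 1-RDM trace is caught and names the invariant
  expect_error(rdm_set(rd$gamma * 1.1, rd$Gamma, rd$x, rd$y, rd$z,
                       rd$xx, rd$yy, rd$zz, n_electrons = 2L),
               "trace condition")
  expect_error(rdm_set(rd$gamma, rd$Gamma * 2, rd$x, rd$y, rd$z,
                       rd$xx, rd$yy, rd$zz, n_electrons = 2L),
               "trace condition")
  # half-normalized container is accepted and rescaled to the full dialect
  half <- rdm_set(rd$gamma, rd$Gamma / 2, rd$x, rd$y, rd$z,
                  rd$xx, rd$yy, rd$zz, n_electrons = 2L,
                  pair_normalization = "half")
  expect_equal(correlated_size(half)$R2, correlated_size(rd)$R2)
})

test_that("n_eff is inversely proportional to the reference polarizability", {
  cs <- correlated_size(hydrogen_rdm_fixture())
  expect_equal(neff_from_alpha_size(cs, 2 * 4.5),
               neff_from_alpha_size(cs, 4.5) / 2)
  expect_error(neff_from_alpha_size(-1, 1), "positive")
})

test_that("RDM text container round-trips and rejects malformed input", {
  rd <- determinant_rdm_fixture()
  p <- tempfile(fileext = ".rdm")
  write_rdm(rd, p)
  rd2 <- read_rdm(p)
  expect_equal(rd2$gamma, rd$gamma, tolerance = 1e-10)
  expect_equal(rd2$Gamma, rd$Gamma, tolerance = 1e-10)
  expect_equal(correlated_size(rd2)$R2, correlated_size(rd)$R2,
               tolerance = 1e-9)
  # corrupt the declared electron count -> trace validation must fire
  txt <- readLines(p)
  writeLines(sub("^n_electrons 2", "n_electrons 3", txt), p)
  expect_error(read_rdm(p), "trace condition")
  # missing section
  writeLines(txt[!grepl("^\\[zz\\]", txt)][seq_len(length(txt) - 2)], p)
  expect_error(read_rdm(p), "missing|expected|non-numeric")
})

test_that("the helium backend reproduces its frozen reference state", {
  st <- atomic_state("He")
  expect_equal(st$e_hf, -2.8611834, tolerance = 1e-6)
  expect_equal(st$e_total, -2.9005979, tolerance = 1e-6)
  cs <- correlated_size(st$rdms)
  # electron correlation shrinks the dipole fluctuation (cross term < 0)
  expect_lt(cs$cross_term, 0)
  expect_equal(cs$R2, 2.26680, tolerance = 1e-4)
  # symmetry and trace sanity of the assembled RDMs
  g <- st$rdms$gamma
  expect_lt(max(abs(g - t(g))), 1e-10)
  expect_equal(sum(diag(g)), 2, tolerance = 1e-8)
  Gm <- st$rdms$Gamma
  n <- dim(Gm)[1]
  # chemist-convention symmetries: electron exchange and hermiticity
  expect_lt(max(abs(Gm - aperm(Gm, c(3, 4, 1, 2)))), 1e-10)
  expect_lt(max(abs(Gm - aperm(Gm, c(2, 1, 4, 3)))), 1e-10)
})
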