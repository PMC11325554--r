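# One-center Gaussian-basis integral engine.
#
# Every basis function shares the nucleus at the origin,
#   phi_{k,lm}(r) = R_k(r) S_lm(theta, phi),
#   R_k = sum_j c_j N_j r^l exp(-a_j r^2),
# so all integrals factor into (radial quadrature) x (exact angular factor).
# Two-electron repulsion uses the Laplace (multipole) expansion
#   1/r12 = sum_L 4 pi/(2L+1) (r_<^L / r_>^{L+1}) sum_M S_LM(1) S_LM(2),
# giving (ab|cd) = sum_LM [4pi/(2L+1)] G_ab^LM G_cd^LM RSL_L(ab;cd) with
# real Gaunt factors G (numeric-exact product quadrature) and Slater-type
# radial integrals RSL on a log grid (cumulative Simpson).

# ---- angular product grid (Gauss-Legendre in cos(theta), uniform phi) ----
ang_grid_env <- new.env(parent = emptyenv())

ang_grid <- function(nth = 64L, nph = 129L) {
  key <- paste(nth, nph)
  if (!is.null(ang_grid_env[[key]])) return(ang_grid_env[[key]])
  gl <- pracma::gaussLegendre(nth, -1, 1)
  ct <- gl$x                       # cos(theta)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- 2 * pi * (seq_len(nph) - 1) / nph
  CT <- matrix(ct, nth, nph)
  ST <- matrix(st, nth, nph)
  PH <- matrix(ph, nth, nph, byrow = TRUE)
  W <- matrix(gl$w, nth, nph) * (2 * pi / nph)
  g <- list(CT = CT, ST = ST, PH = PH, W = W,
            nx = ST * cos(PH), ny = ST * sin(PH), nz = CT)
  ang_grid_env[[key]] <- g
  g
}

# associated Legendre P_l^m(x) (no Condon-Shortley phase), stable recursion
assoc_legendre <- function(l, m, x) {
  if (m > l) return(0 * x)
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(1 - x^2, 0))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmm
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# real orthonormal spherical harmonic on the angular grid
real_sph <- function(l, m, g = ang_grid()) {
  am <- abs(m)
  nlm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  P <- assoc_legendre(l, am, g$CT)
  if (m == 0) return(nlm * P)
  if (m > 0) return(sqrt(2) * nlm * P * cos(m * g$PH))
  sqrt(2) * nlm * P * sin(am * g$PH)
}

ang_int <- function(vals, g = ang_grid()) sum(vals * g$W)

# ---- radial log grid ----
radial_grid <- function(nr = 4000L, rmin = 1e-7, rmax = 80) {
  t <- seq(log(rmin), log(rmax), length.out = nr)
  list(t = t, r = exp(t), dt = t[2] - t[1])
}

# integral of y dt on the uniform t grid (trapezoid; y already carries
# the r dr Jacobian where needed)
int_t <- function(y, dt) dt * (sum(y) - 0.5 * (y[1] + y[length(y)]))

# cumulative Simpson along the uniform t grid (vector in, vector out)
cumsimpson <- function(y, dt) {
  n <- length(y)
  incr <- numeric(n)
  incr[3:n] <- (y[1:(n - 2)] + 4 * y[2:(n - 1)] + y[3:n]) * (dt / 3)
  cs <- numeric(n)
  cs[seq(3, n, by = 2)] <- cumsum(incr[seq(3, n, by = 2)])
  cs[2] <- 0.5 * (y[1] + y[2]) * dt
  odd <- seq(4, n, by = 2)
  cs[odd] <- cs[2] + cumsum(incr[odd])
  # note: with 1-based indexing, even t-indices continue the Simpson chain
  # seeded by a trapezoid on the first interval
  cs
}

# ---- shells and basis ----

#' Gaussian shell and one-center basis constructors
#'
#' `gauss_shell()` defines one (possibly contracted) radial shell
#' `R(r) = sum_j c_j N_j r^l exp(-a_j r^2)`; `onecenter_basis()` expands a
#' list of shells into the full set of `(shell, l, m)` orbitals used by the
#' atomic electronic-structure backend.
#'
#' @param l Angular momentum (0..3 supported).
#' @param exps Primitive exponents (bohr^-2).
#' @param coefs Contraction coefficients (default: uncontracted).
#' @return `gauss_shell()`: a shell object; `onecenter_basis()`: a basis
#'   object with `n` orbitals.
#' @export
gauss_shell <- function(l, exps, coefs = NULL) {
  stopifnot(l %in% 0:3, all(exps > 0))
  if (is.null(coefs)) coefs <- rep(1, length(exps))
  stopifnot(length(coefs) == length(exps))
  prim_norm <- sqrt(2 * (2 * exps)^(l + 1.5) / gamma(l + 1.5))
  structure(list(l = l, exps = exps, coefs = coefs, prim_norm = prim_norm),
            class = "gauss_shell")
}

shell_radial <- function(sh, r, deriv = FALSE) {
  out <- numeric(length(r))
  for (j in seq_along(sh$exps)) {
    a <- sh$exps[j]; cN <- sh$coefs[j] * sh$prim_norm[j]
    if (!deriv) {
      out <- out + cN * r^sh$l * exp(-a * r^2)
    } else if (sh$l == 0) {
      out <- out + cN * (-2 * a * r) * exp(-a * r^2)
    } else {
      out <- out + cN * (sh$l * r^(sh$l - 1) - 2 * a * r^(sh$l + 1)) *
        exp(-a * r^2)
    }
  }
  out
}

#' @rdname gauss_shell
#' @param shells List of `gauss_shell` objects.
#' @export
onecenter_basis <- function(shells) {
  orb <- do.call(rbind, lapply(seq_along(shells), function(i) {
    l <- shells[[i]]$l
    data.frame(shell = i, l = l, m = seq(-l, l))
  }))
  rg <- radial_grid()
  # overall shell normalization on the quadrature grid
  norms <- vapply(shells, function(sh) {
    R <- shell_radial(sh, rg$r)
    1 / sqrt(int_t(R^2 * rg$r^3, rg$dt))
  }, numeric(1))
  structure(list(shells = shells, orb = orb, n = nrow(orb),
                 lmax = max(orb$l), norms = norms, rg = rg),
            class = "onecenter_basis")
}

# normalized radial values (matrix nr x nshell), optionally derivative
basis_radials <- function(basis, deriv = FALSE) {
  vapply(seq_along(basis$shells), function(i) {
    basis$norms[i] * shell_radial(basis$shells[[i]], basis$rg$r, deriv)
  }, numeric(length(basis$rg$r)))
}

#' One-electron integrals of a one-center basis
#'
#' Overlap, kinetic, nuclear attraction (`-Z/r`), Cartesian dipole,
#' squared-position matrices, and optionally the matrix of an additional
#' spherically symmetric one-body potential (e.g. a confining wall).
#'
#' @param basis A [onecenter_basis()].
#' @param Z Nuclear charge.
#' @param extra_potential Optional function of `r` (bohr) added to the
#'   external potential; must be smooth on the radial grid.
#' @return List with matrices `S`, `T`, `V`, `x`, `y`, `z`, `xx`, `yy`,
#'   `zz` (and `Vextra` when a potential is supplied).
#' @export
onecenter_one_electron <- function(basis, Z, extra_potential = NULL) {
  n <- basis$n
  g <- ang_grid()
  rg <- basis$rg
  Rv <- basis_radials(basis)
  dRv <- basis_radials(basis, deriv = TRUE)
  orb <- basis$orb
  # angular tables
  Y <- lapply(seq_len(n), function(p) real_sph(orb$l[p], orb$m[p], g))
  dirs <- list(x = g$nx, y = g$ny, z = g$nz)
  r3 <- rg$r^3
  S <- matrix(0, n, n); Tk <- matrix(0, n, n); V <- matrix(0, n, n)
  D <- list(x = matrix(0, n, n), y = matrix(0, n, n), z = matrix(0, n, n))
  Q <- list(xx = matrix(0, n, n), yy = matrix(0, n, n), zz = matrix(0, n, n))
  Vx <- if (!is.null(extra_potential)) matrix(0, n, n) else NULL
  vex <- if (!is.null(extra_potential)) extra_potential(rg$r) else NULL
  for (p in seq_len(n)) {
    for (q in p:n) {
      ip <- orb$shell[p]; iq <- orb$shell[q]
      lp <- orb$l[p]; lq <- orb$l[q]
      ang_same <- ang_int(Y[[p]] * Y[[q]], g)
      rad0 <- int_t(Rv[, ip] * Rv[, iq] * r3, rg$dt)
      rad1 <- int_t(Rv[, ip] * Rv[, iq] * rg$r * r3, rg$dt)
      rad2 <- int_t(Rv[, ip] * Rv[, iq] * rg$r^2 * r3, rg$dt)
      radm1 <- int_t(Rv[, ip] * Rv[, iq] / rg$r * r3, rg$dt)
      S[p, q] <- S[q, p] <- ang_same * rad0
      V[p, q] <- V[q, p] <- -Z * ang_same * radm1
      if (!is.null(Vx)) {
        radx <- int_t(Rv[, ip] * Rv[, iq] * vex * r3, rg$dt)
        Vx[p, q] <- Vx[q, p] <- ang_same * radx
      }
      kin <- if (lp == lq) {
        0.5 * ang_same * int_t((dRv[, ip] * dRv[, iq] +
          lp * (lp + 1) * Rv[, ip] * Rv[, iq] / rg$r^2) * r3, rg$dt)
      } else 0
      Tk[p, q] <- Tk[q, p] <- kin
      for (cc in c("x", "y", "z")) {
        aa <- ang_int(Y[[p]] * dirs[[cc]] * Y[[q]], g)
        D[[cc]][p, q] <- D[[cc]][q, p] <- aa * rad1
      }
      for (cc in c("xx", "yy", "zz")) {
        d1 <- substr(cc, 1, 1)
        aa <- ang_int(Y[[p]] * dirs[[d1]]^2 * Y[[q]], g)
        Q[[cc]][p, q] <- Q[[cc]][q, p] <- aa * rad2
      }
    }
  }
  out <- list(S = S, T = Tk, V = V,
              x = D$x, y = D$y, z = D$z,
              xx = Q$xx, yy = Q$yy, zz = Q$zz)
  if (!is.null(Vx)) out$Vextra <- Vx
  out
}

#' Two-electron repulsion integrals of a one-center basis
#'
#' Full chemist-notation tensor `(pq|rs)` via the multipole expansion; see
#' the file header for the factorization.  Cost grows as
#' `O(n^2_pairs * n_L)` for the radial part plus a sparse angular assembly.
#'
#' @param basis A [onecenter_basis()].
#' @return Numeric array `n x n x n x n` (chemist order).
#' @export
onecenter_eri <- function(basis) {
  n <- basis$n
  g <- ang_grid()
  rg <- basis$rg
  orb <- basis$orb
  Lmax <- 2 * basis$lmax
  Y <- lapply(seq_len(n), function(p) real_sph(orb$l[p], orb$m[p], g))
  # radial pair table (shell pairs)
  ns <- length(basis$shells)
  Rv <- basis_radials(basis)
  pair_idx <- matrix(0L, ns, ns)
  pairs <- list()
  k <- 0L
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      k <- k + 1L
      pairs[[k]] <- Rv[, i] * Rv[, j]
      pair_idx[i, j] <- pair_idx[j, i] <- k
    }
  }
  npair <- k
  rho <- do.call(cbind, pairs)          # nr x npair
  r <- rg$r; dt <- rg$dt
  # Slater radial integrals per L
  RSL <- vector("list", Lmax + 1)
  w_end <- function(M) {                # trapezoid end-correction weights
    M[1, ] <- M[1, ] / 2; M[nrow(M), ] <- M[nrow(M), ] / 2; M
  }
  for (L in 0:Lmax) {
    inner <- apply(rho * r^(L + 3), 2, cumsimpson, dt = dt)
    outer_full <- apply(rho * r^(2 - L), 2, cumsimpson, dt = dt)
    outer <- matrix(outer_full[nrow(outer_full), ], nrow(outer_full),
                    ncol(outer_full), byrow = TRUE) - outer_full
    Ypot <- inner * r^(-(L + 1)) + outer * r^L
    A <- w_end(rho * r^3) * dt
    RSL[[L + 1]] <- crossprod(A, Ypot)  # npair x npair
    RSL[[L + 1]] <- 0.5 * (RSL[[L + 1]] + t(RSL[[L + 1]]))
  }
  # angular (real Gaunt) assembly
  eri <- numeric(n^4)
  orb_pair_shell <- function(p, q) pair_idx[orb$shell[p], orb$shell[q]]
  for (L in 0:Lmax) {
    for (M in seq(-L, L)) {
      YL <- real_sph(L, M, g)
      ps <- integer(0); qs <- integer(0); vals <- numeric(0)
      for (p in seq_len(n)) {
        lp <- orb$l[p]
        for (q in seq_len(n)) {
          lq <- orb$l[q]
          if ((lp + lq + L) %% 2 == 1 || L < abs(lp - lq) || L > lp + lq) next
          if (q < p) next
          v <- ang_int(Y[[p]] * Y[[q]] * YL, g)
          if (abs(v) > 1e-14) {
            ps <- c(ps, p, if (p != q) q)
            qs <- c(qs, q, if (p != q) p)
            vals <- c(vals, v, if (p != q) v)
          }
        }
      }
      if (!length(vals)) next
      fac <- 4 * pi / (2 * L + 1)
      pq_lin <- ps + n * (qs - 1L)                 # 1-based linear pair idx
      sp <- mapply(orb_pair_shell, ps, qs)
      Rsub <- RSL[[L + 1]][sp, sp, drop = FALSE]
      contrib <- fac * (vals %o% vals) * Rsub
      pos <- outer(pq_lin, (pq_lin - 1L) * n^2, `+`)
      eri[pos] <- eri[pos] + contrib
    }
  }
  array(eri, dim = rep(n, 4))
}
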