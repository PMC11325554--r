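# Configuration-interaction (singles + doubles) correlation for closed-shell
# atoms, with expectation-value ("direct projection") reduced density
# matrices.  The eigenproblem is solved in spin-orbital amplitude form
# (c0, c1[i,a], t[i,j,a,b] antisymmetric) by subspace Davidson; the
# spin-traced RDMs are then assembled blockwise in the *spatial* orbital
# basis from the alpha-beta pair amplitudes, so no spin-orbital four-index
# object beyond the amplitude/integral blocks is ever formed.
#
# Spin-orbital layout: (spatial P, spin s), interleaved index 2P - 2 + s.

# ---- reshape helper: move `rows` dims in front and flatten to a matrix ----
m2 <- function(a, rows) {
  d <- dim(a)
  cols <- setdiff(seq_along(d), rows)
  m <- aperm(a, c(rows, cols))
  dim(m) <- c(prod(d[rows]), prod(d[cols]))
  m
}

# antisymmetrized spin-orbital block <pq||rs> from spatial chemist ERIs
so_block <- function(Vmo, sl1, sl2, sl3, sl4) {
  P <- aperm(Vmo[sl1, sl3, sl2, sl4, drop = FALSE], c(1, 3, 2, 4))  # <pq|rs>
  X <- aperm(Vmo[sl1, sl4, sl2, sl3, drop = FALSE], c(1, 3, 4, 2))  # <pq|sr>
  d <- dim(P)
  out <- array(0, dim = 2 * d)
  ix <- function(s, m) seq(s, 2 * m, by = 2)
  for (s1 in 1:2) for (s2 in 1:2) for (s3 in 1:2) for (s4 in 1:2) {
    term <- NULL
    if (s1 == s3 && s2 == s4) term <- P
    if (s1 == s4 && s2 == s3) term <- if (is.null(term)) -X else term - X
    if (!is.null(term)) {
      out[ix(s1, d[1]), ix(s2, d[2]), ix(s3, d[3]), ix(s4, d[4])] <- term
    }
  }
  out
}

cisd_blocks <- function(Vmo, nocc) {
  n <- dim(Vmo)[1]
  o <- seq_len(nocc); v <- seq(nocc + 1, n)
  # the particle-particle ladder uses the *spatial* <AB|CD> matrix directly
  # (sector-wise contraction), avoiding the 16x larger spin-orbital block
  vvmat <- m2(aperm(Vmo[v, v, v, v, drop = FALSE], c(1, 3, 2, 4)), c(1, 2))
  list(oovv = so_block(Vmo, o, o, v, v),
       vvmat = vvmat, nv_sp = n - nocc,
       oooo = so_block(Vmo, o, o, o, o),
       ovvo = so_block(Vmo, o, v, v, o),
       voov = so_block(Vmo, v, o, o, v),
       vovv = so_block(Vmo, v, o, v, v),
       ooov = so_block(Vmo, o, o, o, v),
       vvvo = so_block(Vmo, v, v, v, o),
       ovoo = so_block(Vmo, o, v, o, o))
}

# (H - E_HF) action on a CISD vector (canonical orbitals, f_ov = 0)
cisd_sigma <- function(c0, c1, t, eps_o, eps_v, B) {
  no <- length(eps_o); nv <- length(eps_v)
  dt <- dim(t)
  s0 <- 0.25 * sum(B$oovv * t)
  # --- singles ---
  s1 <- outer(-eps_o, eps_v, `+`) * c1
  # sum_jb <aj||ib> c1[j,b]: voov[a,j,i,b] -> [i,a] x (j,b)
  s1 <- s1 + matrix(m2(aperm(B$voov, c(3, 1, 2, 4)), c(1, 2)) %*%
                      as.vector(c1), no, nv)
  # + 1/2 sum_jbc <aj||bc> t[i,j,b,c]
  s1 <- s1 + 0.5 * m2(t, 1) %*% t(m2(B$vovv, 1))
  # - 1/2 sum_jkb <jk||ib> t[j,k,a,b]
  s1 <- s1 - 0.5 * m2(aperm(B$ooov, c(3, 1, 2, 4)), 1) %*%
    t(m2(aperm(t, c(3, 1, 2, 4)), 1))
  # --- doubles ---
  st <- c0 * B$oovv +
    t * outer(outer(-eps_o, -eps_o, `+`), outer(eps_v, eps_v, `+`), `+`)
  # particle ladder 1/2 <ab||cd> t[i,j,c,d] = sum_cd <ab|cd> t[i,j,c,d],
  # done per spin sector of (a,b) with the spatial <AB|CD> matrix
  nvs <- B$nv_sp
  for (sa in 1:2) for (sb in 1:2) {
    tsl <- t[, , seq(sa, 2 * nvs, 2), seq(sb, 2 * nvs, 2), drop = FALSE]
    mt <- m2(aperm(tsl, c(3, 4, 1, 2)), c(1, 2))         # (C,D) x (i,j)
    osl <- B$vvmat %*% mt                                # (A,B) x (i,j)
    st[, , seq(sa, 2 * nvs, 2), seq(sb, 2 * nvs, 2)] <-
      st[, , seq(sa, 2 * nvs, 2), seq(sb, 2 * nvs, 2)] +
      aperm(array(osl, c(nvs, nvs, dt[1], dt[2])), c(3, 4, 1, 2))
  }
  # hole ladder 1/2 <kl||ij> t[k,l,a,b]
  hhl <- m2(aperm(B$oooo, c(3, 4, 1, 2)), c(1, 2)) %*% m2(t, c(1, 2))
  st <- st + 0.5 * array(hhl, dt)
  # ring P(ij)P(ab) sum_kc <kb||cj> t[i,k,a,c]
  rg <- m2(aperm(t, c(1, 3, 2, 4)), c(1, 2)) %*%
    t(m2(aperm(B$ovvo, c(4, 2, 1, 3)), c(1, 2)))          # (i,a) x (j,b)
  rg <- aperm(array(rg, dt[c(1, 3, 2, 4)]), c(1, 3, 2, 4))
  rg <- rg - aperm(rg, c(2, 1, 3, 4))
  rg <- rg - aperm(rg, c(1, 2, 4, 3))
  st <- st + rg
  # singles coupling: + P(ij) sum_c <ab||cj> c1[i,c]
  sc <- c1 %*% m2(aperm(B$vvvo, c(3, 1, 2, 4)), 1)        # i x (a,b,j)
  sc <- aperm(array(sc, dt[c(1, 3, 4, 2)]), c(1, 4, 2, 3))
  st <- st + sc - aperm(sc, c(2, 1, 3, 4))
  # - P(ab) sum_k <kb||ij> c1[k,a]
  sk <- t(m2(aperm(B$ovoo, c(1, 3, 4, 2)), 1)) %*% c1     # (i,j,b) x a
  sk <- aperm(array(sk, dt[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  st <- st - (sk - aperm(sk, c(1, 2, 4, 3)))
  list(s0 = s0, s1 = s1, st = st)
}

cisd_dot <- function(a, b) {
  a$s0 * b$s0 + sum(a$s1 * b$s1) + 0.25 * sum(a$st * b$st)
}

cisd_vec <- function(c0, c1, t) list(s0 = c0, s1 = c1, st = t)

#' Closed-shell CISD ground state
#'
#' Lowest root of the singles-and-doubles CI eigenproblem by subspace
#' Davidson iteration (starting from the first-order doubles guess).
#'
#' @param hmo One-electron Hamiltonian in the MO basis.
#' @param Vmo ERI tensor in the MO basis (chemist order).
#' @param eps Canonical orbital energies.
#' @param nocc Doubly occupied spatial orbitals.
#' @param maxit,tol,nsub Davidson controls.
#' @return List `e_corr`, `c0`, `c1`, `t` (normalized spin-orbital
#'   amplitudes), `converged`, `n_iter`.
#' @export
cisd_solve <- function(hmo, Vmo, eps, nocc, maxit = 60L, tol = 1e-9,
                       nsub = 14L) {
  n <- dim(Vmo)[1]
  B <- cisd_blocks(Vmo, nocc)
  eps_o <- rep(eps[seq_len(nocc)], each = 2)
  eps_v <- rep(eps[seq(nocc + 1, n)], each = 2)
  no <- length(eps_o); nv <- length(eps_v)
  den2 <- outer(outer(eps_o, eps_o, `+`), outer(-eps_v, -eps_v, `+`), `+`)
  den1 <- outer(eps_o, -eps_v, `+`)
  v0 <- cisd_vec(1, matrix(0, no, nv), B$oovv / den2)
  nrm <- sqrt(cisd_dot(v0, v0))
  v0 <- lapply(v0, function(x) x / nrm)
  Vs <- list(v0)
  Ss <- list(cisd_sigma(v0$s0, v0$s1, v0$st, eps_o, eps_v, B))
  E <- cisd_dot(v0, Ss[[1]])
  x <- v0; conv <- FALSE; it <- 0L
  axpy <- function(al, u, w) Map(function(a, b) b + al * a, u, w)
  for (it in seq_len(maxit)) {
    m <- length(Vs)
    Hm <- matrix(0, m, m); Sm <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      Hm[i, j] <- cisd_dot(Vs[[i]], Ss[[j]])
      Sm[i, j] <- cisd_dot(Vs[[i]], Vs[[j]])
    }
    Xh <- sym_orth(Sm)
    es <- eigen(t(Xh) %*% (0.5 * (Hm + t(Hm))) %*% Xh, symmetric = TRUE)
    kmin <- which.min(es$values)
    u <- Xh %*% es$vectors[, kmin]
    E <- es$values[kmin]
    x <- lapply(Vs[[1]], function(z) z * u[1])
    s <- lapply(Ss[[1]], function(z) z * u[1])
    if (m > 1) for (i in 2:m) {
      x <- axpy(u[i], Vs[[i]], x)
      s <- axpy(u[i], Ss[[i]], s)
    }
    r <- axpy(-E, x, s)
    rn <- sqrt(cisd_dot(r, r))
    if (rn < tol) { conv <- TRUE; break }
    d <- list(s0 = r$s0 / (E - 1e-2), s1 = r$s1 / (E + den1),
              st = r$st / (E + den2))
    for (v in Vs) d <- axpy(-cisd_dot(v, d), v, d)
    nd <- sqrt(cisd_dot(d, d))
    if (nd < 1e-12) { conv <- TRUE; break }
    d <- lapply(d, function(z) z / nd)
    if (length(Vs) >= nsub) {
      Vs <- list(x)
      Ss <- list(cisd_sigma(x$s0, x$s1, x$st, eps_o, eps_v, B))
    }
    Vs[[length(Vs) + 1]] <- d
    Ss[[length(Ss) + 1]] <- cisd_sigma(d$s0, d$s1, d$st, eps_o, eps_v, B)
  }
  nrm <- sqrt(cisd_dot(x, x))
  list(e_corr = E, c0 = x$s0 / nrm, c1 = x$s1 / nrm, t = x$st / nrm,
       converged = conv, n_iter = it)
}

# ---- spin-traced RDM assembly in the spatial orbital basis ----

# spatial array for t_so[(I,si),(J,sj),(A,sa),(B,sb)]; NULL if zero by spin
tsel <- function(Tab, si, sj, sa, sb) {
  Ts <- aperm(Tab, c(1, 2, 4, 3))
  if (si == sj) {
    if (sa == si && sb == si) return(Tab - Ts)
    return(NULL)
  }
  if (sa == si && sb == sj) return(Tab)
  if (sa == sj && sb == si) return(-Ts)
  NULL
}

cisd_intermediates <- function(c0, c1, Tab) {
  Ts <- aperm(Tab, c(1, 2, 4, 3))
  Tm <- Tab - Ts
  W <- sum(Tab * (2 * Tab - Ts))
  S2 <- 2 * sum(c1^2)
  rh1 <- 0.5 * (m2(Tm, 1) %*% t(m2(Tm, 1)) +
                  2 * m2(Tab, 1) %*% t(m2(Tab, 1)))
  A3 <- function(x) m2(aperm(x, c(3, 1, 2, 4)), 1)       # rows a, cols (i,j,c)
  A4 <- function(x) m2(aperm(x, c(4, 1, 2, 3)), 1)
  rp1 <- 0.5 * (A3(Tm) %*% t(A3(Tm)) + 2 * A4(Tab) %*% t(A4(Tab)))
  u1 <- matrix(m2(aperm(Tm + Tab, c(1, 3, 2, 4)), c(1, 2)) %*%
                 as.vector(c1), nrow(c1), ncol(c1))
  list(Tm = Tm, Ts = Ts, W = W, S2 = S2, NN = c0^2 + S2 + W,
       rh1 = rh1, rp1 = rp1,
       sh1 = tcrossprod(c1), sp1 = crossprod(c1),
       u1 = u1, w1 = c0 * c1 + u1)
}

# spin-traced 1-RDM (occupied block first)
cisd_gamma <- function(c0, c1, Tab) {
  I <- cisd_intermediates(c0, c1, Tab)
  no <- nrow(c1); nv <- ncol(c1)
  g <- matrix(0, no + nv, no + nv)
  o <- seq_len(no); v <- seq(no + 1, no + nv)
  g[o, o] <- 2 * diag(no) * I$NN - 2 * (I$rh1 + I$sh1)
  g[v, v] <- 2 * (I$rp1 + I$sp1)
  g[o, v] <- 2 * I$w1
  g[v, o] <- t(g[o, v])
  g
}

# full spatial chemist-convention 2-RDM:
#   Gamma[P,Q,R,S] = sum_{s,s'} <a+_{Ps} a+_{Rs'} a_{Ss'} a_{Qs}>
cisd_gamma2 <- function(c0, c1, Tab) {
  I <- cisd_intermediates(c0, c1, Tab)
  no <- nrow(c1); nv <- ncol(c1)
  n <- no + nv
  Io <- diag(no)
  M1 <- I$rh1 + I$sh1
  P1 <- I$rp1 + I$sp1
  G <- array(0, dim = rep(n, 4))
  o <- seq_len(no); v <- seq(no + 1, n)
  spins <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  e4 <- function(A, B, perm = NULL) {          # outer + permutation
    x <- outer(A, B)
    if (!is.null(perm)) x <- aperm(x, perm)
    x
  }
  # (oo|oo)
  blk <- 4 * I$NN * e4(Io, Io) - 2 * I$NN * e4(Io, Io, c(1, 4, 3, 2)) -
    4 * e4(M1, Io) - 4 * e4(Io, M1) +
    2 * e4(M1, Io, c(1, 4, 3, 2)) + 2 * e4(Io, M1, c(1, 4, 3, 2))
  tt <- array(0, dim = rep(no, 4))
  for (sp in spins) for (sa in 1:2) for (sb in 1:2) {
    t1 <- tsel(Tab, sp[1], sp[2], sa, sb)
    if (is.null(t1)) next
    m <- m2(t1, c(1, 2))
    tt <- tt + 0.5 * aperm(array(m %*% t(m), rep(no, 4)), c(1, 3, 2, 4))
  }
  G[o, o, o, o] <- blk + tt
  # (oo|ov):  d_PQ w[R,S] (x4) - d_RQ w[P,S] (x2, same-spin)
  #           + sum_b c1[Q,b] t_so[(P,s),(R,s'),(S,s'),(B,s)]
  blk <- 4 * e4(Io, I$w1) - 2 * aperm(e4(Io, I$w1), c(3, 2, 1, 4))
  acc <- array(0, dim = c(no, no, no, nv))
  for (sp in spins) {
    t1 <- tsel(Tab, sp[1], sp[2], sp[2], sp[1])
    if (is.null(t1)) next
    tmp <- c1 %*% m2(aperm(t1, c(4, 1, 2, 3)), 1)        # q x (p,r,s)
    acc <- acc + aperm(array(tmp, c(no, no, no, nv)), c(2, 1, 3, 4))
  }
  Gooov <- blk + acc
  Goovo <- aperm(Gooov, c(2, 1, 4, 3))
  G[o, o, o, v] <- Gooov
  G[o, v, o, o] <- aperm(Gooov, c(3, 4, 1, 2))
  G[o, o, v, o] <- Goovo
  G[v, o, o, o] <- aperm(Goovo, c(3, 4, 1, 2))
  # (oo|vv): 4 d_PQ P1[R,S] - rm - sterm
  acc <- array(0, dim = c(no, no, nv, nv))
  for (sp in spins) for (sk in 1:2) for (sc in 1:2) {
    t1 <- tsel(Tab, sp[1], sk, sp[2], sc)                # [Q,K,R,C]
    if (is.null(t1)) next
    m1 <- m2(aperm(t1, c(1, 3, 2, 4)), c(1, 2))          # (q,r) x (k,c)
    # t2 = t_so[(P,s),(K,sk),(S,s'),(C,sc)] shares the spin signature
    pr <- m1 %*% t(m1)                                   # (q,r) x (p,s)
    acc <- acc + aperm(array(pr, c(no, nv, no, nv)), c(3, 1, 2, 4))
  }
  sterm <- 2 * aperm(outer(c1, c1), c(3, 1, 2, 4))       # c1[q,r] c1[p,s]
  Goovv <- 4 * e4(Io, P1) - acc - sterm
  G[o, o, v, v] <- Goovv
  G[v, v, o, o] <- aperm(Goovv, c(3, 4, 1, 2))
  # (ov|ov): c0 * (2 Tm + 2 Tab)[P,R,Q,S]
  acc <- array(0, dim = c(no, no, nv, nv))
  for (sp in spins) {
    t1 <- tsel(Tab, sp[1], sp[2], sp[1], sp[2])
    if (!is.null(t1)) acc <- acc + t1
  }
  Govov <- c0 * aperm(acc, c(1, 3, 2, 4))
  G[o, v, o, v] <- Govov
  G[v, o, v, o] <- aperm(Govov, c(2, 1, 4, 3))
  # (ov|vo): -2 d_PS P1[R,Q] + rm + 4 c1[P,Q] c1[S,R]
  blk <- -2 * aperm(outer(Io, P1), c(1, 4, 3, 2))
  rm <- array(0, dim = c(no, nv, nv, no))
  for (sp in spins) for (sk in 1:2) for (sc in 1:2) {
    t1 <- tsel(Tab, sp[2], sk, sp[2], sc)                # [S,K,R,C]
    t2 <- tsel(Tab, sp[1], sk, sp[1], sc)                # [P,K,Q,C]
    if (is.null(t1) || is.null(t2)) next
    m1 <- m2(aperm(t1, c(1, 3, 2, 4)), c(1, 2))          # (s,r) x (k,c)
    m2m <- m2(aperm(t2, c(1, 3, 2, 4)), c(1, 2))         # (p,q) x (k,c)
    pq <- m2m %*% t(m1)                                  # (p,q) x (s,r)
    rm <- rm + aperm(array(pq, c(no, nv, no, nv)), c(1, 2, 4, 3))
  }
  sterm <- 4 * aperm(outer(c1, c1), c(1, 2, 4, 3))       # c1[p,q] c1[s,r]
  Govvo <- blk + rm + sterm
  G[o, v, v, o] <- Govvo
  G[v, o, o, v] <- aperm(Govvo, c(3, 4, 1, 2))
  # (ov|vv): sum_j c1[j,R] t_so[(P,s),(J,s'),(Q,s),(S,s')]
  acc <- array(0, dim = c(no, no, nv, nv))
  for (sp in spins) {
    t1 <- tsel(Tab, sp[1], sp[2], sp[1], sp[2])
    if (!is.null(t1)) acc <- acc + t1
  }
  tmp <- crossprod(c1, m2(aperm(acc, c(2, 1, 3, 4)), 1)) # r x (p,q,s)
  Govvv <- aperm(array(tmp, c(nv, no, nv, nv)), c(2, 3, 1, 4))
  Gvovv <- aperm(Govvv, c(2, 1, 4, 3))
  G[o, v, v, v] <- Govvv
  G[v, v, o, v] <- aperm(Govvv, c(3, 4, 1, 2))
  G[v, o, v, v] <- Gvovv
  G[v, v, v, o] <- aperm(Gvovv, c(3, 4, 1, 2))
  # (vv|vv)
  acc <- array(0, dim = rep(nv, 4))
  for (sp in spins) for (si in 1:2) for (sj in 1:2) {
    t1 <- tsel(Tab, si, sj, sp[1], sp[2])
    if (is.null(t1)) next
    m <- m2(aperm(t1, c(3, 4, 1, 2)), c(1, 2))           # (p,r) x (i,j)
    acc <- acc + 0.5 * aperm(array(m %*% t(m), rep(nv, 4)), c(1, 3, 2, 4))
  }
  G[v, v, v, v] <- acc
  G
}
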