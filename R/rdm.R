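#' Spin-traced reduced density matrix set
#'
#' Container for the spin-traced one- and two-electron reduced density
#' matrices of an atomic (or molecular) state in an orthonormal orbital
#' basis, together with the position and squared-position one-electron
#' integral matrices needed by the correlated size functional.
#'
#' Conventions (all validated by the constructor):
#' \itemize{
#'   \item `gamma` is symmetric with `trace(gamma) = n_electrons`.
#'   \item `Gamma` is stored in chemist index order: `Gamma[p,q,r,s]`
#'     multiplies `x[p,q] * x[r,s]` in two-electron expectation values, and
#'     `sum_{p,r} Gamma[p,p,r,r] = N (N - 1)` (`pair_normalization`
#'     `"full"`: both orderings of each electron pair are counted).  A
#'     container declaring `pair_normalization = "half"` (trace
#'     `N (N - 1) / 2`) is accepted and converted on construction.
#' }
#'
#' @param gamma `n x n` spin-traced 1-RDM.
#' @param Gamma `n x n x n x n` spin-traced 2-RDM (chemist order).
#' @param x,y,z `n x n` position-operator integrals (bohr).
#' @param xx,yy,zz `n x n` squared-position integrals (bohr^2).
#' @param n_electrons Integer electron count.
#' @param pair_normalization `"full"` (default) or `"half"`.
#' @param basis_label Free-text provenance tag.
#' @param tol Validation tolerance for the trace conditions (default 1e-6).
#' @return An object of class `rdm_set`.
#' @export
rdm_set <- function(gamma, Gamma, x, y, z, xx, yy, zz, n_electrons,
                    pair_normalization = c("full", "half"),
                    basis_label = "", tol = 1e-6) {
  pair_normalization <- match.arg(pair_normalization)
  n <- nrow(gamma)
  mats <- list(gamma = gamma, x = x, y = y, z = z, xx = xx, yy = yy, zz = zz)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || any(dim(m) != n)) {
      stop("matrix '", nm, "' must be ", n, " x ", n)
    }
    if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
      stop("matrix '", nm, "' is not symmetric")
    }
  }
  if (length(dim(Gamma)) != 4L || any(dim(Gamma) != n)) {
    stop("Gamma must be an n x n x n x n array")
  }
  if (abs(sum(diag(gamma)) - n_electrons) > tol) {
    stop("trace condition violated: trace(gamma) = ",
         format(sum(diag(gamma))), " but n_electrons = ", n_electrons)
  }
  ptr <- gamma2_pair_trace(Gamma)
  expected <- n_electrons * (n_electrons - 1)
  if (pair_normalization == "half") {
    if (abs(ptr - expected / 2) > tol) {
      stop("declared half pair normalization but Gamma pair trace = ",
           format(ptr), " (expected ", format(expected / 2), ")")
    }
    Gamma <- 2 * Gamma
    ptr <- 2 * ptr
  }
  if (abs(ptr - expected) > tol) {
    stop("trace condition violated: Gamma pair trace = ", format(ptr),
         " but N(N-1) = ", expected)
  }
  structure(list(gamma = gamma, Gamma = Gamma,
                 x = x, y = y, z = z, xx = xx, yy = yy, zz = zz,
                 n_electrons = as.integer(n_electrons),
                 n_orb = n, basis_label = basis_label),
            class = "rdm_set")
}

gamma2_pair_trace <- function(Gamma) {
  n <- dim(Gamma)[1]
  pr <- expand.grid(p = seq_len(n), r = seq_len(n))
  sum(Gamma[cbind(pr$p, pr$p, pr$r, pr$r)])
}

#' @export
print.rdm_set <- function(x, ...) {
  cat("<rdm_set> ", x$n_orb, " orbitals, ", x$n_electrons, " electrons",
      if (nzchar(x$basis_label)) paste0(" [", x$basis_label, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Correlated atomic size from reduced density matrices
#'
#' Evaluates the many-electron size
#' `R^2 = < (sum_i r_i)^2 > = sum_i <r_i^2> + sum_{i != j} <r_i . r_j>`,
#' i.e. the ground-state variance of the total dipole operator.  The
#' one-electron part comes from the 1-RDM contracted with the
#' squared-position integrals; the cross term contracts the 2-RDM with the
#' product of position integrals (both orderings of each electron pair).
#' The decomposition identity `R2 = R2_uncorrelated + cross_term` holds by
#' construction.
#'
#' @param rdms An [rdm_set()].
#' @return List of class `correlated_size` with `R2`, `R2_uncorrelated`,
#'   `cross_term` (all bohr^2) and `R` (bohr).
#' @export
correlated_size <- function(rdms) {
  stopifnot(inherits(rdms, "rdm_set"))
  n <- rdms$n_orb
  r2u <- sum(rdms$gamma * rdms$xx) + sum(rdms$gamma * rdms$yy) +
    sum(rdms$gamma * rdms$zz)
  Gm <- matrix(rdms$Gamma, n * n, n * n)   # [pq, rs] column-major pairing
  cross <- 0
  for (m in list(rdms$x, rdms$y, rdms$z)) {
    v <- as.vector(m)
    cross <- cross + drop(crossprod(v, Gm %*% v))
  }
  if (!is.finite(r2u) || !is.finite(cross)) {
    stop("non-finite size expectation; check the RDM inputs")
  }
  structure(list(R2 = r2u + cross, R2_uncorrelated = r2u,
                 cross_term = cross, R = sqrt(r2u + cross)),
            class = "correlated_size")
}

#' @export
print.correlated_size <- function(x, ...) {
  cat(sprintf("R^2 = %.6f bohr^2 (one-electron %.6f, cross %.6f)\n",
              x$R2, x$R2_uncorrelated, x$cross_term))
  invisible(x)
}

#' Effective number of electrons from size and polarizability
#'
#' Inverts the atomic four-dimensional scaling relation
#' `alpha = 4 R^4 / (9 N_eff)` (atomic units, spherical symmetry) to give
#' the number of electrons effectively participating in the dipolar
#' response: `N_eff = 4 R^4 / (9 alpha)`.  For a one-electron atom this
#' reduces to the single-particle law with `R^2 = 3 L^2`, e.g. hydrogen
#' (`R^2 = 3`, `alpha = 4.5`) gives `N_eff = 8/9`.
#'
#' @param R2 Correlated squared size (bohr^2), or a `correlated_size`.
#' @param alpha Reference static polarizability (bohr^3).
#' @return `N_eff` (dimensionless).
#' @examples
#' neff_from_alpha_size(3, 4.5)  # 8/9
#' @export
neff_from_alpha_size <- function(R2, alpha) {
  if (inherits(R2, "correlated_size")) R2 <- R2$R2
  if (any(R2 <= 0) || any(alpha <= 0)) stop("R2 and alpha must be positive")
  (4 / 9) * R2^2 / alpha
}

#' Read / write the plain-text RDM container
#'
#' A self-describing text format for [rdm_set()] objects: a header with
#' `n_orb`, `n_electrons`, `pair_normalization` and `basis_label`, followed
#' by one `[section]` per array (`gamma`, `Gamma`, `x`, `y`, `z`, `xx`,
#' `yy`, `zz`) holding whitespace-separated numbers in column-major order.
#'
#' @param path File path.
#' @return `read_rdm()` returns an [rdm_set()]; `write_rdm()` returns
#'   `path` invisibly.
#' @export
read_rdm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  hdr <- list()
  body_start <- which(grepl("^\\[", lines))[1]
  if (is.na(body_start)) stop("malformed RDM container: no [section] found")
  for (l in lines[seq_len(body_start - 1)]) {
    if (!nzchar(trimws(l))) next
    kv <- strsplit(trimws(l), "\\s+")[[1]]
    hdr[[kv[1]]] <- paste(kv[-1], collapse = " ")
  }
  for (k in c("n_orb", "n_electrons", "pair_normalization")) {
    if (is.null(hdr[[k]])) stop("RDM container header missing '", k, "'")
  }
  n <- as.integer(hdr$n_orb)
  sec_at <- which(grepl("^\\[", lines))
  sections <- list()
  for (i in seq_along(sec_at)) {
    nm <- gsub("^\\[|\\]$", "", trimws(lines[sec_at[i]]))
    to <- if (i < length(sec_at)) sec_at[i + 1] - 1 else length(lines)
    toks <- unlist(strsplit(paste(lines[(sec_at[i] + 1):to],
                                  collapse = " "), "\\s+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop("non-numeric data in RDM container section '", nm, "'")
    }
    sections[[nm]] <- vals
  }
  need <- c("gamma", "Gamma", "x", "y", "z", "xx", "yy", "zz")
  miss <- setdiff(need, names(sections))
  if (length(miss)) stop("RDM container missing section(s): ",
                         paste(miss, collapse = ", "))
  getm <- function(nm) {
    v <- sections[[nm]]
    if (length(v) != n * n) stop("section '", nm, "' has ", length(v),
                                 " values; expected ", n * n)
    matrix(v, n, n)
  }
  gv <- sections$Gamma
  if (length(gv) != n^4) stop("section 'Gamma' has ", length(gv),
                              " values; expected ", n^4)
  rdm_set(getm("gamma"), array(gv, dim = rep(n, 4)),
          getm("x"), getm("y"), getm("z"),
          getm("xx"), getm("yy"), getm("zz"),
          n_electrons = as.integer(hdr$n_electrons),
          pair_normalization = hdr$pair_normalization,
          basis_label = if (is.null(hdr$basis_label)) "" else hdr$basis_label)
}

#' @rdname read_rdm
#' @param rdms An [rdm_set()] to write.
#' @param digits Significant digits retained (default 12).
#' @export
write_rdm <- function(rdms, path, digits = 12) {
  stopifnot(inherits(rdms, "rdm_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rdm container v1",
               paste("n_orb", rdms$n_orb),
               paste("n_electrons", rdms$n_electrons),
               "pair_normalization full",
               paste("basis_label", rdms$basis_label)), con)
  wr <- function(nm, v) {
    writeLines(paste0("[", nm, "]"), con)
    writeLines(paste(formatC(v, digits = digits, format = "g"),
                     collapse = " "), con)
  }
  for (nm in c("gamma", "x", "y", "z", "xx", "yy", "zz")) {
    wr(nm, as.vector(rdms[[nm]]))
  }
  wr("Gamma", as.vector(rdms$Gamma))
  invisible(path)
}
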