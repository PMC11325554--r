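#' Angstrom to bohr conversion factor
#' @export
ANGSTROM_TO_BOHR <- 1.8897261254578281

#' Read a molecular geometry in XYZ format
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' `element x y z` record per atom with coordinates in Angstrom
#' (converted to bohr on read).
#'
#' @param path Path to the `.xyz` file.
#' @return List `elements` (character), `positions` (n x 3 matrix, bohr),
#'   `comment`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("malformed XYZ file (line 1): atom count is not a positive integer")
  }
  if (length(lines) < 2L + n) {
    stop("malformed XYZ file: header declares ", n, " atoms but only ",
         max(length(lines) - 2L, 0), " coordinate lines follow")
  }
  elements <- character(n)
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- trimws(lines[2L + i])
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("malformed XYZ coordinate (line ", 2L + i, "): '", ln, "'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop("non-numeric coordinate in XYZ (line ", 2L + i, "): '", ln, "'")
    }
    elements[i] <- tok[1]
    pos[i, ] <- xyz
  }
  list(elements = elements, positions = pos * ANGSTROM_TO_BOHR,
       comment = lines[2])
}

#' @rdname read_xyz
#' @param elements Character vector of element symbols.
#' @param positions n x 3 matrix of positions in bohr (written in
#'   Angstrom).
#' @param comment Comment line.
#' @param digits Coordinate precision (default 12 significant digits).
#' @export
write_xyz <- function(path, elements, positions, comment = "", digits = 12) {
  positions <- as.matrix(positions) / ANGSTROM_TO_BOHR
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(elements)), comment), con)
  for (i in seq_along(elements)) {
    writeLines(paste(elements[i],
                     paste(formatC(positions[i, ], digits = digits,
                                   format = "g"), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a per-atom volume-ratio table
#'
#' CSV with header `index,element,v_ratio`; `index` is 0-based and must
#' match the XYZ atom order.
#'
#' @param path CSV path.
#' @param elements Optional element vector from the geometry, checked
#'   against the table.
#' @return Numeric vector of volume ratios in atom order.
#' @export
read_ratios <- function(path, elements = NULL) {
  if (!file.exists(path)) stop("ratio table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "element", "v_ratio")
  if (!all(need %in% names(df))) {
    stop("ratio table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$index), ]
  if (!identical(df$index, seq_len(nrow(df)) - 1L) &&
      !identical(as.integer(df$index), seq_len(nrow(df)) - 1L)) {
    stop("ratio table 'index' must be 0-based consecutive integers")
  }
  if (!is.null(elements)) {
    if (nrow(df) != length(elements)) {
      stop("ratio table has ", nrow(df), " rows but geometry has ",
           length(elements), " atoms")
    }
    bad <- which(df$element != elements)
    if (length(bad)) {
      stop("element mismatch between geometry and ratio table at 0-based ",
           "index ", bad[1] - 1, ": '", elements[bad[1]], "' vs '",
           df$element[bad[1]], "'")
    }
  }
  if (any(!is.finite(df$v_ratio)) || any(df$v_ratio <= 0)) {
    stop("volume ratios must be positive numbers")
  }
  df$v_ratio
}

#' Load atoms-in-molecules sites from files
#'
#' Combines [read_xyz()] and [read_ratios()] into an [aim_sites()] table.
#'
#' @param xyz_path XYZ geometry path (Angstrom).
#' @param ratios_path CSV volume-ratio path.
#' @return An [aim_sites()] table.
#' @export
read_aim_sites <- function(xyz_path, ratios_path) {
  geo <- read_xyz(xyz_path)
  v <- read_ratios(ratios_path, geo$elements)
  aim_sites(geo$elements, geo$positions, v)
}

#' Seeded synthetic molecule generator
#'
#' Draws a random molecular fixture: element symbols from an allowed set,
#' positions packed into a cube with a minimum pairwise distance, and
#' volume ratios uniform in a range.  Deterministic for a fixed seed (a
#' private RNG stream; the global RNG state is left untouched).
#'
#' @param n_atoms Number of atoms, `>= 1`.
#' @param elements Allowed element symbols (must have reference data).
#' @param min_distance Minimum pairwise distance in bohr.
#' @param v_ratio_range Length-2 range for the volume ratios.
#' @param seed Integer seed.
#' @param box Cube half-width in bohr (default scaled to the atom count).
#' @param max_tries Packing retries before giving up.
#' @return List `sites` ([aim_sites()]), `elements`, `positions` (bohr),
#'   `v_ratio`, `seed`.
#' @export
generate_fixture <- function(n_atoms, elements = c("H", "C", "N", "O"),
                             min_distance = 2.0,
                             v_ratio_range = c(0.7, 1.1),
                             seed = 1L, box = NULL, max_tries = 200L) {
  stopifnot(n_atoms >= 1, min_distance > 0,
            length(v_ratio_range) == 2, v_ratio_range[1] > 0,
            v_ratio_range[1] <= v_ratio_range[2])
  if (is.null(box)) box <- max(4, min_distance * n_atoms^(1 / 3) * 1.6)
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    list(el = sample(elements, n_atoms, replace = TRUE),
         vr = stats::runif(n_atoms, v_ratio_range[1], v_ratio_range[2]),
         unif = stats::runif(3 * n_atoms * max_tries, -1, 1))
  })
  pos <- matrix(NA_real_, n_atoms, 3)
  draw <- 0L
  for (i in seq_len(n_atoms)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- box * rng$unif[draw + 1:3]
      draw <- draw + 3L
      ok <- i == 1L ||
        all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand, i - 1, 3, byrow = TRUE))^2)) >=
              min_distance)
      if (ok) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("packing failed after ", max_tries, " tries for atom ", i,
           "; increase 'box' or reduce 'min_distance'")
    }
  }
  list(sites = aim_sites(rng$el, pos, rng$vr),
       elements = rng$el, positions = pos, v_ratio = rng$vr, seed = seed)
}

#' JSON result document for a molecular prediction
#'
#' @param tensor A [polarizability_tensor()].
#' @param method Model name.
#' @param units `"bohr3"` or `"angstrom3"`.
#' @return A list ready for [jsonlite::write_json()] (row-major tensor).
#' @export
tensor_result <- function(tensor, method, units = c("bohr3", "angstrom3")) {
  units <- match.arg(units)
  f <- if (units == "angstrom3") (1 / ANGSTROM_TO_BOHR)^3 else 1
  list(method = method,
       alpha_tensor = as.vector(t(tensor$matrix * f)),
       alpha_iso = tensor$iso * f,
       delta_aniso = tensor$delta_aniso * f,
       units = units)
}
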