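# Embedded reference tables (free-atom polarizabilities / C6, effective
# electron numbers) live in inst/extdata as versioned JSON.

ref_env <- new.env(parent = emptyenv())

ref_path <- function(name, override = NULL) {
  if (!is.null(override)) return(override)
  system.file("extdata", name, package = "polar4d", mustWork = TRUE)
}

#' Free-atom reference polarizabilities and dispersion coefficients
#'
#' Returns the embedded table of free-atom static dipole polarizabilities
#' (bohr^3) and homoatomic C6 coefficients (hartree bohr^6) used by the
#' atoms-in-molecules models, as compiled from the standard reference set
#' recorded in the table's `source` field.
#'
#' @param path Optional path to an alternative JSON table with the same
#'   schema (element records with `alpha` and `c6`).
#' @return Data frame with columns `element`, `alpha`, `c6`.
#' @export
free_atom_reference <- function(path = NULL) {
  key <- if (is.null(path)) "free" else path
  if (is.null(ref_env[[key]])) {
    j <- jsonlite::fromJSON(ref_path("free_atom_reference.json", path))
    ref_env[[key]] <- as.data.frame(j$elements)
  }
  ref_env[[key]]
}

#' Effective electron numbers of free atoms
#'
#' The embedded per-element table of effective electron numbers
#' (`n_eff`, inferred from atomic size and polarizability through the
#' four-dimensional scaling law) together with the formal valence electron
#' counts.
#'
#' @param path Optional alternative JSON table.
#' @return Data frame with columns `element`, `n_eff`, `n_valence`.
#' @export
effective_electrons <- function(path = NULL) {
  key <- if (is.null(path)) "neff" else paste0("neff:", path)
  if (is.null(ref_env[[key]])) {
    j <- jsonlite::fromJSON(ref_path("effective_electrons.json", path))
    ref_env[[key]] <- as.data.frame(j$elements)
  }
  ref_env[[key]]
}

ref_lookup <- function(element, what = c("alpha", "c6")) {
  what <- match.arg(what)
  tab <- free_atom_reference()
  i <- match(element, tab$element)
  if (any(is.na(i))) {
    stop("no reference data for element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  }
  tab[[what]][i]
}
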