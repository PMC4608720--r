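#' Build a topology table
#'
#' A topology is a tibble with one row per atom and columns `atom_name`,
#' `residue_name`, `residue_id` (author numbering, preserved verbatim),
#' `element`, `mass` (Da) and `vdw_radius` (Angstrom). Atom indices used by
#' selections are the 0-based row positions of this table.
#'
#' @param atoms data frame with at least `atom_name`, `residue_name`,
#'   `residue_id` and `element`. `mass`/`vdw_radius` are filled from the
#'   bundled element table when absent.
#' @return a `kd_topology` tibble.
#' @export
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("atom_name", "residue_name", "residue_id", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("topology is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(c("mass", "vdw_radius") %in% names(atoms))) {
    props <- element_properties(atoms$element)
    if (!"mass" %in% names(atoms)) atoms$mass <- props$mass
    if (!"vdw_radius" %in% names(atoms)) atoms$vdw_radius <- props$vdw_radius
  }
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms <- atoms[, c("atom_name", "residue_name", "residue_id", "element",
                     "mass", "vdw_radius")]
  validate_topology(atoms)
  class(atoms) <- c("kd_topology", class(atoms))
  atoms
}

validate_topology <- function(atoms) {
  if (nrow(atoms) == 0) abort("topology has no atoms")
  if (any(atoms$mass <= 0)) abort("all atom masses must be > 0")
  if (any(atoms$vdw_radius <= 0)) abort("all van-der-Waals radii must be > 0")
  key <- paste(atoms$residue_id, atoms$atom_name)
  if (anyDuplicated(key) > 0) {
    abort(paste0("duplicated (residue_id, atom_name) pair: ",
                 key[anyDuplicated(key)][1]))
  }
  if (is.unsorted(atoms$residue_id)) {
    abort("residue_id must be non-decreasing in atom order")
  }
  invisible(atoms)
}

#' @export
print.kd_topology <- function(x, ...) {
  cat(sprintf("<kd_topology> %d atoms, %d residues (%d-%d)\n",
              nrow(x), length(unique(x$residue_id)),
              min(x$residue_id), max(x$residue_id)))
  NextMethod()
}

n_atoms <- function(topology) nrow(topology)

#' Subset a topology to a selection
#'
#' @param topology a `kd_topology`.
#' @param selection a `kd_selection` (see [select_atoms()]).
#' @return a `kd_topology` containing only the selected atoms, in index order.
#' @export
subset_topology <- function(topology, selection) {
  topology(topology[selection$indices + 1L, , drop = FALSE])
}
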