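#' Residue-role map
#'
#' Functional residues of the kinase domain are addressed by role names so
#' that descriptor code never hard-codes residue numbers. Each role maps to
#' residue id(s) (author numbering) and optionally atom name(s).
#'
#' Required roles (defaults follow the ZAP-70 kinase-domain convention):
#' `DFG_D` (D479 side-chain carboxylate carbon), `DFG_F` (F480 CZ),
#' `DFG_G` (G481 backbone amide), `SB_K` (K369 NZ), `SB_E` (E386 carboxylate
#' oxygens), `HELIX_C` (alphaC helix D379-Q392), `CLOBE` (C-lobe residue
#' range), `STA_SB_D` (D379), `STA_SB_R` (R496), `HB_N` (N348), `HB_S`
#' (S497), `LOOP_R` (R514), `PY1` (Y492), `PY2` (Y493), `GATE_W` (W505),
#' `FLAP` (537-569) and `POCKET` (the ten pocket-lining residues R460, D461,
#' L462, A463, K500, W501, P502, W505, Y506, S524).
#'
#' @param ... named role overrides, each a list with `resid` and optional
#'   `atom`.
#' @return a named list of roles, class `kd_roles`.
#' @export
residue_roles <- function(...) {
  roles <- default_role_list()
  dots <- list(...)
  for (nm in names(dots)) roles[[nm]] <- normalize_role(dots[[nm]], nm)
  structure(roles, class = "kd_roles")
}

default_role_list <- function() {
  list(
    DFG_D    = list(resid = 479L, atom = "CG"),
    DFG_F    = list(resid = 480L, atom = "CZ"),
    DFG_G    = list(resid = 481L, atom = c("N", "H")),
    SB_K     = list(resid = 369L, atom = "NZ"),
    SB_E     = list(resid = 386L, atom = c("OE1", "OE2")),
    HELIX_C  = list(resid = 379:392, atom = NULL),
    CLOBE    = list(resid = 440:536, atom = NULL),
    ACTLOOP  = list(resid = 479:500, atom = NULL),
    STA_SB_D = list(resid = 379L, atom = "CG"),
    STA_SB_R = list(resid = 496L, atom = "NH1"),
    HB_N     = list(resid = 348L, atom = "ND2"),
    HB_S     = list(resid = 497L, atom = "OG"),
    LOOP_R   = list(resid = 514L, atom = "NH1"),
    PY1      = list(resid = 492L, atom = "OH"),
    PY2      = list(resid = 493L, atom = "OH"),
    GATE_W   = list(resid = 505L, atom = NULL),
    FLAP     = list(resid = 537:569, atom = NULL),
    POCKET   = list(resid = c(460L, 461L, 462L, 463L, 500L, 501L, 502L,
                              505L, 506L, 524L), atom = NULL)
  )
}

required_roles <- function() {
  c("DFG_D", "DFG_F", "DFG_G", "SB_K", "SB_E", "HELIX_C", "CLOBE",
    "STA_SB_D", "STA_SB_R", "HB_N", "HB_S", "LOOP_R", "PY1", "PY2",
    "GATE_W", "FLAP", "POCKET")
}

normalize_role <- function(role, name) {
  if (is.numeric(role)) role <- list(resid = role, atom = NULL)
  if (is.null(role$resid)) abort(paste0("role '", name, "' has no resid"))
  role$resid <- as.integer(role$resid)
  if (!is.null(role$atom)) role$atom <- as.character(role$atom)
  role[c("resid", "atom")]
}

#' Read or write a role map as YAML
#'
#' The file holds one key per role; each value is either a residue id, a
#' list of ids, or a mapping with `resid` and optional `atom` entries.
#' Roles absent from the file keep their defaults.
#'
#' @param path YAML file.
#' @return for `read_roles`, a `kd_roles` list.
#' @export
read_roles <- function(path) {
  raw <- yaml::read_yaml(path)
  roles <- default_role_list()
  for (nm in names(raw)) roles[[nm]] <- normalize_role(raw[[nm]], nm)
  structure(roles, class = "kd_roles")
}

#' @rdname read_roles
#' @param roles a `kd_roles` list.
#' @export
write_roles <- function(roles, path) {
  yaml::write_yaml(lapply(unclass(roles), function(r) {
    r[!vapply(r, is.null, logical(1))]
  }), path)
  invisible(path)
}

#' Resolve every role against a topology
#'
#' @param roles a `kd_roles` list.
#' @param topology a [topology()].
#' @param required role names that must resolve to at least one atom
#'   (default: the full required set).
#' @return named list of `kd_selection` objects.
#' @export
resolve_roles <- function(roles, topology, required = required_roles()) {
  miss <- setdiff(required, names(roles))
  if (length(miss) > 0) {
    abort(paste0("role map is missing required role(s): ",
                 paste(miss, collapse = ", ")))
  }
  sels <- lapply(names(roles), function(nm) {
    suppressWarnings(select_atoms(topology, paste("role", nm), roles = roles))
  })
  names(sels) <- names(roles)
  empty <- names(sels)[vapply(sels, function(s) length(s$indices) == 0, logical(1))]
  bad <- intersect(empty, required)
  if (length(bad) > 0) {
    abort(paste0("role(s) not resolvable against this topology: ",
                 paste(bad, collapse = ", ")))
  }
  sels
}

#' Resolve a single role to a selection
#'
#' @inheritParams resolve_roles
#' @param name role name.
#' @param atom optional atom-name filter overriding the role's own.
#' @return a `kd_selection`.
#' @export
role_selection <- function(roles, topology, name, atom = NULL) {
  if (!name %in% names(roles)) {
    abort(paste0("unknown role name '", name, "'; known roles: ",
                 paste(names(roles), collapse = ", ")))
  }
  role <- roles[[name]]
  mask <- topology$residue_id %in% role$resid
  atoms <- atom %||% role$atom
  if (!is.null(atoms)) mask <- mask & topology$atom_name %in% atoms
  selection_from_mask(mask, paste("role", name))
}
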