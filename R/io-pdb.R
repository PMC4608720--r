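# PDB reading/writing is delegated to bio3d; this file adds record
# validation, the first-altloc policy, and conversion to kindyn containers.

scan_pdb_records <- function(path) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort(paste0("no ATOM/HETATM records found in ", path))
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed PDB record at line %d (too short): %s", i, ln))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      abort(sprintf("malformed PDB record at line %d (bad coordinates): %s", i, ln))
    }
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (is.na(resno)) {
      abort(sprintf("malformed PDB record at line %d (bad residue number): %s", i, ln))
    }
  }
  invisible(lines)
}

pdb_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  fallback <- is.na(el) | el == ""
  if (any(fallback)) {
    # derive from the atom name: first alphabetic character, two-letter
    # symbols only when the name starts in column 13 style (e.g. "MG")
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", elety)))
    one <- substr(guess, 1, 1)
    two <- substr(guess, 1, 2)
    known2 <- two %in% element_table()$element & nchar(guess) > 1 &
      !(one %in% c("C", "N", "O", "H", "S", "P"))
    el[fallback] <- ifelse(known2[fallback], two[fallback], one[fallback])
  }
  el
}

# keep the first altloc seen for each (residue, atom name) pair
first_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$elety)
  keep <- !duplicated(key)
  if (!all(keep)) {
    warn(sprintf("dropping %d alternate-location atom record(s); keeping the first altloc",
                 sum(!keep)))
  }
  keep
}

#' Read a PDB structure
#'
#' Parses coordinate records of a PDB v3 file into a topology plus a
#' single-frame trajectory. One atom is kept per ATOM/HETATM record, first
#' altloc only; van-der-Waals radii and masses are assigned from the bundled
#' element table; author residue numbering is preserved verbatim.
#'
#' @param path PDB file.
#' @param format only `"pdb"` is supported.
#' @return list with elements `topology` (a [topology()]) and `trajectory`
#'   (a single-frame [trajectory()]).
#' @export
read_structure <- function(path, format = "pdb") {
  if (!identical(format, "pdb")) abort("read_structure supports format = \"pdb\" only")
  scan_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  atom <- pdb$atom
  keep <- first_altloc(atom)
  atom <- atom[keep, , drop = FALSE]
  el <- pdb_element(atom$elesy, atom$elety)
  topo <- topology(tibble(
    atom_name = trimws(atom$elety),
    residue_name = trimws(atom$resid),
    residue_id = atom$resno,
    element = el
  ))
  coords <- as.matrix(atom[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  list(topology = topo, trajectory = trajectory(coords))
}

read_pdb_frames <- function(path) {
  scan_pdb_records(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  keep <- first_altloc(pdb$atom)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(nf, na, 3))
  coords[, , 1] <- xyz[, seq(1, ncol(xyz), by = 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, ncol(xyz), by = 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, ncol(xyz), by = 3), drop = FALSE]
  coords <- coords[, keep, , drop = FALSE]
  list(coords = coords, times = NULL)
}

write_pdb_frames <- function(traj, topology, path) {
  nf <- n_frames(traj)
  na <- nrow(topology)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * na)
  xyz[, seq(1, 3 * na, by = 3)] <- traj$coords[, , 1]
  xyz[, seq(2, 3 * na, by = 3)] <- traj$coords[, , 2]
  xyz[, seq(3, 3 * na, by = 3)] <- traj$coords[, , 3]
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topology$residue_id,
                   resid = topology$residue_name,
                   eleno = seq_len(na),
                   elety = topology$atom_name,
                   elesy = topology$element,
                   chain = rep("A", na))
  invisible(path)
}
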