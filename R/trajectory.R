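#' Build a trajectory object
#'
#' A trajectory stores coordinates as a `frames x atoms x 3` numeric array in
#' Angstrom, per-frame times in nanoseconds, and a state label. All readers
#' convert on-disk units to Angstrom/nanosecond.
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom). A single
#'   `atoms x 3` matrix is promoted to one frame.
#' @param times numeric vector of frame times (ns), strictly increasing.
#'   Defaults to `0, dt, 2 dt, ...`.
#' @param state state label, one of `"STA"`, `"Y0Y0"`, `"YP_Y0"`, `"Y0_YP"`,
#'   `"YP_YP"` or any custom string.
#' @param dt frame spacing in ns used when `times` is not given.
#' @return a `kd_trajectory`.
#' @export
trajectory <- function(coords, times = NULL, state = "custom", dt = 0.1) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be a frames x atoms x 3 array")
  }
  if (!all(is.finite(coords))) abort("all coordinates must be finite")
  n_frames <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  if (length(times) != n_frames) {
    abort(sprintf("times has length %d but trajectory has %d frames",
                  length(times), n_frames))
  }
  if (n_frames > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  structure(list(coords = coords, times = as.numeric(times),
                 state = as.character(state)),
            class = "kd_trajectory")
}

#' @export
print.kd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<kd_trajectory> state=%s, %d frames x %d atoms, t = %.3f..%.3f ns\n",
              x$state, d[1], d[2], x$times[1], x$times[d[1]]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an atoms x 3 matrix
#'
#' @param traj a `kd_trajectory`.
#' @param i frame index (1-based).
#' @return numeric matrix `atoms x 3`.
#' @export
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) abort("frame index out of range")
  matrix(traj$coords[i, , ], ncol = 3L)
}

check_traj_topology <- function(traj, topology) {
  if (dim(traj$coords)[2] != nrow(topology)) {
    abort(sprintf("trajectory has %d atoms but topology has %d",
                  dim(traj$coords)[2], nrow(topology)))
  }
  invisible(TRUE)
}

#' Read a trajectory file
#'
#' Supported formats: `"dcd"` (CHARMM/NAMD 32-bit) and `"pdb"` (multi-model
#' PDB). Coordinates are returned in Angstrom. For DCD the frame times come
#' from the stored start/stride/delta header fields; for PDB they are
#' `t0 + (0:(n-1)) * dt`.
#'
#' @param path input file.
#' @param topology the matching `kd_topology`; the per-frame atom count must
#'   agree.
#' @param format `"dcd"` or `"pdb"` (default: from the file extension).
#' @param dt,t0 frame spacing and first-frame time in ns, used for formats
#'   without time metadata.
#' @param state state label to attach.
#' @return a `kd_trajectory`.
#' @export
read_trajectory <- function(path, topology, format = NULL,
                            dt = 0.1, t0 = 0, state = "custom") {
  format <- format %||% guess_format(path)
  coords_times <- switch(format,
    dcd = read_dcd_file(path),
    pdb = read_pdb_frames(path),
    xtc = abort("XTC is not a supported format; convert to DCD or multi-model PDB"),
    abort(paste0("unsupported trajectory format: ", format))
  )
  coords <- coords_times$coords
  if (dim(coords)[2] != nrow(topology)) {
    abort(sprintf("atom-count mismatch: file has %d atoms per frame, topology has %d",
                  dim(coords)[2], nrow(topology)))
  }
  times <- coords_times$times
  if (is.null(times)) times <- t0 + (seq_len(dim(coords)[1]) - 1) * dt
  trajectory(coords, times = times, state = state)
}

#' Write a trajectory file
#'
#' PDB output is multi-model fixed-precision text (0.001 Angstrom); DCD is
#' 32-bit binary.
#'
#' @param traj a `kd_trajectory`.
#' @param topology the matching `kd_topology`.
#' @param path output file.
#' @param format `"dcd"` or `"pdb"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, topology, path, format = NULL) {
  check_traj_topology(traj, topology)
  if (n_frames(traj) == 0) abort("refusing to write an empty (0-frame) trajectory")
  format <- format %||% guess_format(path)
  switch(format,
    dcd = write_dcd_file(traj, path),
    pdb = write_pdb_frames(traj, topology, path),
    xtc = abort("XTC is not a supported format; write DCD or multi-model PDB"),
    abort(paste0("unsupported trajectory format: ", format))
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("dcd", "pdb", "xtc")) ext else abort(
    paste0("cannot guess trajectory format from extension '.", ext,
           "'; pass format = \"dcd\" or \"pdb\""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
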