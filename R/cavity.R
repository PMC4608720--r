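#' Voxelize one frame onto a cubic grid
#'
#' A voxel is marked `protein` when its centre lies within
#' `vdw_radius + probe` of any atom centre (water-probe convention, probe
#' 1.4 Angstrom). The grid margin exceeds the largest atom reach plus two
#' voxels, so no interior cavity can touch the boundary.
#'
#' @param frame `atoms x 3` coordinate matrix (one trajectory frame).
#' @param topology the matching [topology()] (supplies vdw radii).
#' @param spacing voxel edge in Angstrom, in (0.25, 3.0); default 1.0.
#' @param probe probe radius in Angstrom; default 1.4.
#' @return a `kd_voxelgrid`: list with `origin`, `spacing`, `dims` and the
#'   logical `occupancy` vector (x fastest).
#' @export
voxelize <- function(frame, topology, spacing = 1.0, probe = 1.4) {
  if (!is.matrix(frame)) frame <- matrix(frame, ncol = 3)
  if (nrow(frame) == 0) abort("cannot voxelize an empty frame")
  if (nrow(frame) != nrow(topology)) {
    abort(sprintf("frame has %d atoms but topology has %d",
                  nrow(frame), nrow(topology)))
  }
  if (spacing <= 0.25 || spacing >= 3.0) abort("spacing must lie in (0.25, 3.0)")
  g <- cpp_voxelize(frame, topology$vdw_radius, spacing, probe)
  structure(list(origin = g$origin, spacing = spacing, probe = probe,
                 dims = g$dims, occupancy = g$occupancy),
            class = "kd_voxelgrid")
}

#' @export
print.kd_voxelgrid <- function(x, ...) {
  cat(sprintf("<kd_voxelgrid> %d x %d x %d voxels @ %.2f A (%d protein)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$occupancy)))
  invisible(x)
}

#' Detect buried cavities in a voxel grid
#'
#' An empty voxel is a cavity candidate when a ray along at least
#' `min_blocked` of the 6 axis directions hits a protein voxel within the
#' grid. Candidates are grouped by 26-connectivity flood fill and components
#' below `min_volume` are discarded. Volume is voxel count times
#' `spacing^3`.
#'
#' @param grid a [voxelize()] result.
#' @param min_blocked required blocked axis directions, 4, 5 or 6
#'   (default 6: fully enclosed).
#' @param min_volume minimum component volume in Angstrom^3 (default 27, a
#'   one-voxel cube floor at 3 Angstrom equivalent spacing).
#' @return tibble with one row per cavity component: `component`,
#'   `volume_A3`, `n_voxels`, centroid `x`/`y`/`z` (Angstrom); the voxel
#'   index lists are kept in `attr(, "members")`, the grid in
#'   `attr(, "grid")`.
#' @export
detect_cavities <- function(grid, min_blocked = 6, min_volume = 27) {
  if (!min_blocked %in% 4:6) abort("min_blocked must be one of 4, 5, 6")
  res <- cpp_detect_cavities(grid$occupancy, grid$dims, grid$spacing,
                             as.integer(min_blocked), min_volume)
  nv <- length(res$volumes)
  cent <- res$centroids_vox
  out <- tibble(
    component = seq_len(nv),
    volume_A3 = as.numeric(res$volumes),
    n_voxels = vapply(res$members, length, integer(1)),
    x = if (nv) grid$origin[1] + (cent[, 1] + 0.5) * grid$spacing else numeric(0),
    y = if (nv) grid$origin[2] + (cent[, 2] + 0.5) * grid$spacing else numeric(0),
    z = if (nv) grid$origin[3] + (cent[, 3] + 0.5) * grid$spacing else numeric(0)
  )
  out <- out[order(-out$volume_A3), , drop = FALSE]
  out$component <- seq_len(nv)
  attr(out, "members") <- res$members[order(-as.numeric(res$volumes))]
  attr(out, "grid") <- grid[c("origin", "dims", "spacing")]
  class(out) <- c("kd_cavities", class(out))
  out
}

#' Track a seeded pocket's volume along a trajectory
#'
#' Every `stride`-th frame is voxelized and screened for buried cavities;
#' the tracked volume is that of the single largest component having at
#' least one voxel within `seed_radius` of any seed atom (0 when none
#' qualifies). The open/close series applies `open_threshold` to the
#' volume.
#'
#' @param traj a [trajectory()].
#' @param topology the matching [topology()].
#' @param roles a [residue_roles()] map; the default seed is the `POCKET`
#'   role (the ten pocket-lining residues).
#' @param seed optional `kd_selection` overriding the POCKET role.
#' @param seed_radius seed capture radius in Angstrom (default 5).
#' @param open_threshold volume (Angstrom^3) above which the pocket counts
#'   as open (default 200; a reporting convention).
#' @param spacing,probe,min_blocked,min_volume grid parameters, see
#'   [voxelize()] and [detect_cavities()].
#' @param stride analyse every stride-th frame (default 1).
#' @return a `kd_pockettrack` tibble: `frame`, `time_ns`, `volume_A3`,
#'   `open`; attributes `max_volume`, `argmax_frame`, `open_fraction`.
#' @export
track_pocket <- function(traj, topology, roles, seed = NULL,
                         seed_radius = 5.0, open_threshold = 200,
                         spacing = 1.0, probe = 1.4,
                         min_blocked = 6, min_volume = 27, stride = 1L) {
  check_traj_topology(traj, topology)
  if (is.null(seed)) seed <- role_selection(roles, topology, "POCKET")
  if (length(seed$indices) == 0) abort("pocket seed selection is empty")
  seed_rows <- sel_rows(seed)
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  vols <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    fr <- matrix(traj$coords[frames[fi], , ], ncol = 3)
    grid <- voxelize(fr, topology, spacing, probe)
    res <- cpp_detect_cavities(grid$occupancy, grid$dims, grid$spacing,
                               as.integer(min_blocked), min_volume)
    if (length(res$volumes) > 0) {
      near <- cpp_components_near(res$members, grid$origin, grid$dims,
                                  grid$spacing, fr[seed_rows, , drop = FALSE],
                                  seed_radius)
      if (any(near)) vols[fi] <- max(res$volumes[near])
    }
  }
  out <- tibble(frame = frames, time_ns = traj$times[frames],
                volume_A3 = vols, open = vols >= open_threshold)
  attr(out, "max_volume") <- max(vols)
  attr(out, "argmax_frame") <- frames[which.max(vols)]
  attr(out, "open_fraction") <- mean(out$open)
  attr(out, "kd_metadata") <- list(state = traj$state, seed = seed$expression,
                                   seed_radius = seed_radius,
                                   open_threshold = open_threshold,
                                   spacing = spacing, probe = probe,
                                   min_blocked = min_blocked,
                                   min_volume = min_volume, stride = stride)
  class(out) <- c("kd_pockettrack", class(out))
  out
}

#' @export
print.kd_pockettrack <- function(x, ...) {
  cat(sprintf("<kd_pockettrack> %d frames: max %.0f A^3 at frame %d, open fraction %.2f\n",
              nrow(x), attr(x, "max_volume"), attr(x, "argmax_frame"),
              attr(x, "open_fraction")))
  NextMethod()
}

#' @export
glance.kd_pockettrack <- function(x, ...) {
  meta <- attr(x, "kd_metadata")
  tibble(state = meta$state %||% NA_character_,
         n_frames = nrow(x),
         max_volume_A3 = attr(x, "max_volume"),
         argmax_frame = attr(x, "argmax_frame"),
         open_fraction = attr(x, "open_fraction"),
         open_threshold = meta$open_threshold)
}

#' Export cavity voxels of one detection as a pseudo-atom PDB
#'
#' @param cavities a [detect_cavities()] result.
#' @param path output PDB path.
#' @export
write_cavity_pdb <- function(cavities, path) {
  g <- attr(cavities, "grid")
  members <- attr(cavities, "members")
  rows <- list()
  for (c in seq_along(members)) {
    v <- members[[c]]
    i <- v %% g$dims[1]
    j <- (v %/% g$dims[1]) %% g$dims[2]
    k <- v %/% (g$dims[1] * g$dims[2])
    rows[[c]] <- tibble(
      x = g$origin[1] + (i + 0.5) * g$spacing,
      y = g$origin[2] + (j + 0.5) * g$spacing,
      z = g$origin[3] + (k + 0.5) * g$spacing,
      comp = c
    )
  }
  pts <- dplyr::bind_rows(rows)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (r in seq_len(nrow(pts))) {
    writeLines(sprintf("HETATM%5d  DUM CAV A%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
                       r %% 100000, pts$comp[r] %% 10000,
                       pts$x[r], pts$y[r], pts$z[r]), con)
  }
  writeLines("END", con)
  invisible(path)
}
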