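#' Per-frame distance series
#'
#' Three modes: `"atom"` (both selections must be singletons), `"com"`
#' (mass-weighted centre of mass of each selection), `"min"` (minimum
#' pairwise heavy-atom distance).
#'
#' @param traj a [trajectory()].
#' @param topology the matching [topology()] (supplies masses and elements).
#' @param a,b `kd_selection` objects.
#' @param mode `"atom"`, `"com"` or `"min"`.
#' @param name series name.
#' @return a `kd_series`.
#' @export
distance_series <- function(traj, topology, a, b, mode = c("atom", "com", "min"),
                            name = "distance") {
  mode <- match.arg(mode)
  check_traj_topology(traj, topology)
  if (length(a$indices) == 0 || length(b$indices) == 0) {
    abort("distance_series: empty selection")
  }
  vals <- switch(mode,
    atom = {
      if (length(a$indices) != 1 || length(b$indices) != 1) {
        abort("mode = \"atom\" requires singleton selections")
      }
      d <- traj$coords[, sel_rows(a), , drop = FALSE] -
           traj$coords[, sel_rows(b), , drop = FALSE]
      sqrt(rowSums(matrix(d, ncol = 3)^2))
    },
    com = {
      ca <- com_series(traj, topology, a)
      cb <- com_series(traj, topology, b)
      sqrt(rowSums((ca - cb)^2))
    },
    min = min_distance_series(traj, topology, a, b)
  )
  new_series(name, traj$times, vals,
             metadata = list(a = a$expression, b = b$expression, mode = mode,
                             state = traj$state))
}

com_series <- function(traj, topology, sel) {
  rows <- sel_rows(sel)
  w <- topology$mass[rows]
  w <- w / sum(w)
  sub <- traj$coords[, rows, , drop = FALSE]
  nf <- dim(sub)[1]
  out <- matrix(0, nrow = nf, ncol = 3)
  for (ax in 1:3) out[, ax] <- matrix(sub[, , ax], nrow = nf) %*% w
  out
}

heavy_rows <- function(topology, sel) {
  rows <- sel_rows(sel)
  rows[topology$element[rows] != "H"]
}

min_distance_series <- function(traj, topology, a, b) {
  ra <- heavy_rows(topology, a)
  rb <- heavy_rows(topology, b)
  if (length(ra) == 0 || length(rb) == 0) {
    abort("min-distance selection contains no heavy atoms")
  }
  nf <- n_frames(traj)
  best <- rep(Inf, nf)
  for (i in ra) {
    for (j in rb) {
      d2 <- rowSums(matrix(traj$coords[, i, ] - traj$coords[, j, ], ncol = 3)^2)
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Contact occupancy from a distance criterion
#'
#' Occupancy is the fraction of frames in which the minimum heavy-atom
#' distance between the two selections is strictly below `cutoff`.
#'
#' @inheritParams distance_series
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return a `kd_occupancy`: list with `occupancy` and a per-frame tibble
#'   `series` (`time_ns`, `distance`, `in_contact`).
#' @export
contact_occupancy <- function(traj, topology, a, b, cutoff = 4.0, mode = "min") {
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (!identical(mode, "min")) abort("contact_occupancy supports mode = \"min\" only")
  if (length(a$indices) == 0 || length(b$indices) == 0) {
    abort("contact_occupancy: empty selection")
  }
  d <- min_distance_series(traj, topology, a, b)
  contact <- d < cutoff
  structure(list(
    occupancy = mean(contact),
    series = tibble(time_ns = traj$times, distance = d, in_contact = contact),
    cutoff = cutoff,
    a = a$expression, b = b$expression, state = traj$state
  ), class = "kd_occupancy")
}

#' @export
print.kd_occupancy <- function(x, ...) {
  cat(sprintf("<kd_occupancy> %s / %s, cutoff %.2f A: occupancy %.3f over %d frames\n",
              x$a, x$b, x$cutoff, x$occupancy, nrow(x$series)))
  invisible(x)
}

#' @export
glance.kd_occupancy <- function(x, ...) {
  tibble(occupancy = x$occupancy, cutoff = x$cutoff,
         n_frames = nrow(x$series), state = x$state)
}

#' The canonical kinase-domain descriptor panel
#'
#' Computes, with canonical names:
#' * `dfg_cyclization` — DFG aspartate carboxylate carbon to the glycine
#'   backbone amide hydrogen (atom mode). When the structure has no amide
#'   hydrogen the amide nitrogen is used with a nominal -1.0 Angstrom
#'   N-to-H correction, and the fallback is flagged in the metadata.
#' * `alphaC_clobe` — alphaC helix to C-lobe, mass-weighted COM distance.
#' * `sb_K369_E386` — catalytic salt bridge, minimum NZ to carboxylate-O
#'   distance.
#' * `f480_m390` — DFG phenylalanine CZ to the alphaC M390 backbone N.
#' * `sb_D379_R496`, `hb_N348_S497`, `hb_R514_Y493` — inhibitor-state
#'   contacts (minimum heavy-atom distance).
#' * `gate_W505` — tryptophan gate to the ATP site: minimum distance to
#'   ligand atoms (residue names ATP/ANP/STU) when present, otherwise to the
#'   configured `ATP_ANCHOR` role, flagged in the metadata.
#'
#' @param traj a [trajectory()].
#' @param topology the matching [topology()].
#' @param roles a [residue_roles()] map resolvable against the topology.
#' @return a `kd_panel` tibble.
#' @export
descriptor_panel <- function(traj, topology, roles) {
  resolve_roles(roles, topology)
  get <- function(nm, atom = NULL) role_selection(roles, topology, nm, atom)

  # DFG cyclization, with amide-N fallback when no hydrogen is present
  dfg_d <- get("DFG_D")
  dfg_h <- role_selection(roles, topology, "DFG_G", atom = "H")
  h_fallback <- length(dfg_h$indices) == 0
  if (h_fallback) dfg_h <- role_selection(roles, topology, "DFG_G", atom = "N")
  if (length(dfg_h$indices) == 0) abort("role DFG_G resolves to neither H nor N")
  dfg <- distance_series(traj, topology, dfg_d, dfg_h, mode = "atom",
                         name = "dfg_cyclization")
  if (h_fallback) {
    dfg$value <- pmax(dfg$value - 1.0, 0)
    attr(dfg, "kd_metadata")$dfg_cyclization$h_fallback <- TRUE
    attr(dfg, "kd_metadata")$dfg_cyclization$correction_A <- -1.0
  }

  alphac <- distance_series(traj, topology, get("HELIX_C"), get("CLOBE"),
                            mode = "com", name = "alphaC_clobe")
  sb <- distance_series(traj, topology, get("SB_K"), get("SB_E"),
                        mode = "min", name = "sb_K369_E386")

  m390_n <- select_atoms(topology, "resid 390 and name N")
  f480 <- if (length(m390_n$indices) == 1) {
    distance_series(traj, topology, get("DFG_F"), m390_n, mode = "atom",
                    name = "f480_m390")
  } else {
    distance_series(traj, topology, get("DFG_F"),
                    role_selection(roles, topology, "HELIX_C"),
                    mode = "min", name = "f480_m390")
  }

  sta_sb <- distance_series(traj, topology, get("STA_SB_D"), get("STA_SB_R"),
                            mode = "min", name = "sb_D379_R496")
  hb_ns <- distance_series(traj, topology, get("HB_N"), get("HB_S"),
                           mode = "min", name = "hb_N348_S497")
  hb_ry <- distance_series(traj, topology, get("LOOP_R"), get("PY2"),
                           mode = "min", name = "hb_R514_Y493")

  lig <- suppressWarnings(select_atoms(topology, "resname ATP ANP STU"))
  anchor_used <- length(lig$indices) == 0
  if (anchor_used) {
    if (!"ATP_ANCHOR" %in% names(roles)) {
      abort("no ligand present and no ATP_ANCHOR role configured for gate_W505")
    }
    lig <- role_selection(roles, topology, "ATP_ANCHOR")
  }
  gate <- distance_series(traj, topology, get("GATE_W"), lig,
                          mode = "min", name = "gate_W505")
  attr(gate, "kd_metadata")$gate_W505$anchor_used <- anchor_used

  bind_series(list(dfg, alphac, sb, f480, sta_sb, hb_ns, hb_ry, gate),
              state = traj$state)
}
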