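#' Generator configuration
#'
#' Conditions for the synthetic kinase-domain ensemble generator. The
#' defaults mirror a production run saving one frame per 100 ps: 15,000
#' frames at dt = 0.1 ns. `noise_sd` is the baseline per-coordinate thermal
#' jitter; `ou_tau` the relaxation time of the mean-reverting descriptor
#' processes.
#'
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing in ns (> 0).
#' @param seed integer RNG seed; generator output is a pure function of
#'   (profile, config).
#' @param n_residues residue count of the pseudo-domain; must be large
#'   enough to host every functional role (>= 233 with the default first
#'   residue).
#' @param noise_sd baseline thermal noise, Angstrom (>= 0).
#' @param ou_tau descriptor relaxation time, ns.
#' @param first_resid author number of the first residue (default 337,
#'   ZAP-70 numbering).
#' @return a `kd_generator_config` list.
#' @export
generator_config <- function(n_frames = 15000, dt = 0.1, seed = 1,
                             n_residues = 240, noise_sd = 0.15,
                             ou_tau = 1.0, first_resid = 337) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (dt <= 0) abort("dt must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 seed = as.integer(seed), n_residues = as.integer(n_residues),
                 noise_sd = noise_sd, ou_tau = ou_tau,
                 first_resid = as.integer(first_resid)),
            class = "kd_generator_config")
}

#' State profile for the synthetic generator
#'
#' Parameterizes one kinase activation state: target means/sds for the DFG
#' cyclization and alphaC-COM distances (optionally a two-level schedule
#' with a transition fraction), the salt-bridge telegraph process
#' (stationary occupancy and switching rate), the activation-loop
#' flexibility multiplier, planted collective-mode amplitudes, and the
#' cryptic-pocket gating.
#'
#' @param name state label.
#' @param dfg_mean target DFG distance (Angstrom); length 2 with
#'   `dfg_transition` for a scheduled change.
#' @param dfg_sd stationary sd of the DFG distance.
#' @param dfg_transition schedule transition as a fraction of the run in
#'   `[0, 1]`.
#' @param alphaC_mean,alphaC_sd,alphaC_transition same for the alphaC-COM
#'   distance.
#' @param saltbridge_occupancy stationary K369-E386 occupancy in `[0, 1]`.
#' @param switching_rate telegraph relaxation rate, events/ns.
#' @param loop_flex_scale multiplier on activation-loop thermal noise.
#' @param mode_amplitudes named list: planted collective mode id ->
#'   amplitude (Angstrom, >= 0).
#' @param pocket_gating list with `mode` ("off"/"gated") and `open_dwell`,
#'   `close_dwell` in ns.
#' @return a `kd_state_profile` list.
#' @export
state_profile <- function(name,
                          dfg_mean = 5.0, dfg_sd = 0.3, dfg_transition = NULL,
                          alphaC_mean = 14.5, alphaC_sd = 0.3,
                          alphaC_transition = NULL,
                          saltbridge_occupancy = 0.5, switching_rate = 20,
                          loop_flex_scale = 1.0, mode_amplitudes = list(),
                          pocket_gating = list(mode = "off")) {
  if (saltbridge_occupancy < 0 || saltbridge_occupancy > 1) {
    abort("saltbridge_occupancy must lie in [0, 1]")
  }
  if (dfg_sd < 0 || alphaC_sd < 0) abort("profile sds must be >= 0")
  for (tr in list(dfg_transition, alphaC_transition)) {
    if (!is.null(tr) && (tr < 0 || tr > 1)) {
      abort("schedule transition time must lie in [0, 1]")
    }
  }
  if (length(mode_amplitudes) > 0) {
    if (any(unlist(mode_amplitudes) < 0)) abort("mode amplitudes must be >= 0")
  }
  gating <- modifyList(list(mode = "off", open_dwell = 6, close_dwell = 14),
                       pocket_gating)
  if (!gating$mode %in% c("off", "gated")) {
    abort("pocket_gating mode must be 'off' or 'gated'")
  }
  structure(list(name = name, dfg_mean = dfg_mean, dfg_sd = dfg_sd,
                 dfg_transition = dfg_transition,
                 alphaC_mean = alphaC_mean, alphaC_sd = alphaC_sd,
                 alphaC_transition = alphaC_transition,
                 saltbridge_occupancy = saltbridge_occupancy,
                 switching_rate = switching_rate,
                 loop_flex_scale = loop_flex_scale,
                 mode_amplitudes = mode_amplitudes,
                 pocket_gating = gating),
            class = "kd_state_profile")
}

#' The five default kinase activation-state profiles
#'
#' Descriptor targets transcribed from the reference state levels:
#' staurosporine-inhibited STA (DFG closed at 3.0 A, alphaC 15.0 A, salt
#' bridge permanent), apo-like Y0Y0 (DFG semi-closed at 5.0 A, alphaC
#' 14.5 A, bridge intermittent at 0.5, gated cryptic pocket), Y492-
#' phosphorylated YP_Y0 (DFG 5.0 -> 8.0 A at 0.4 of the run, alphaC
#' 13.5 -> 14.5 A at 1/3, bridge 0.1), Y493-phosphorylated Y0_YP
#' (semi-closed, alphaC displaced at 15.5 A, bridge off) and
#' di-phosphorylated YP_YP (open at 8.0 A, displaced, bridge off).
#' Loop-flexibility scales increase with phosphorylation.
#'
#' @return named list of [state_profile()]s in canonical order
#'   STA, Y0Y0, YP_Y0, Y0_YP, YP_YP.
#' @export
default_state_profiles <- function() {
  list(
    STA = state_profile("STA", dfg_mean = 3.0, alphaC_mean = 15.0,
                        saltbridge_occupancy = 1.0, loop_flex_scale = 1.0),
    Y0Y0 = state_profile("Y0Y0", dfg_mean = 5.0, alphaC_mean = 14.5,
                         saltbridge_occupancy = 0.5, loop_flex_scale = 1.2,
                         mode_amplitudes = list(`4` = 2.0),
                         pocket_gating = list(mode = "gated")),
    YP_Y0 = state_profile("YP_Y0", dfg_mean = c(5.0, 8.0), dfg_transition = 0.4,
                          alphaC_mean = c(13.5, 14.5), alphaC_transition = 1 / 3,
                          saltbridge_occupancy = 0.1, loop_flex_scale = 2.0,
                          mode_amplitudes = list(`1` = 2.5, `3` = 2.0)),
    Y0_YP = state_profile("Y0_YP", dfg_mean = 5.0, alphaC_mean = 15.5,
                          saltbridge_occupancy = 0.0, loop_flex_scale = 2.5,
                          mode_amplitudes = list(`1` = 2.5, `2` = 2.0)),
    YP_YP = state_profile("YP_YP", dfg_mean = 8.0, alphaC_mean = 15.5,
                          saltbridge_occupancy = 0.0, loop_flex_scale = 3.0,
                          mode_amplitudes = list(`1` = 1.8, `2` = 1.5, `3` = 1.5))
  )
}

pocket_resids <- function() c(460L, 461L, 462L, 463L, 500L, 501L, 502L,
                              505L, 506L, 524L)

# deterministic compact lattice of n points with pitch a, centred at centre
lattice_points <- function(n, a, centre) {
  side <- ceiling(n^(1 / 3))
  g <- expand.grid(i = seq_len(side), j = seq_len(side), k = seq_len(side))
  g <- g[order(g$k, g$j, g$i), ][seq_len(n), ]
  pts <- cbind(g$i, g$j, g$k) * a
  sweep(pts, 2, colMeans(pts)) + matrix(centre, n, 3, byrow = TRUE)
}

normalize <- function(v) v / sqrt(sum(v^2))

#' Build the synthetic kinase-domain topology
#'
#' Constructs a coarse C-alpha + pseudo-side-chain pseudo-domain: two
#' compact lobes joined at a hinge, an activation-loop arc, a 14-residue
#' alphaC helix, a flap segment, pseudo-atoms for every functional role,
#' and a wall-enclosed cubic cavity of analytically known volume (default
#' 5 x 5 x 5 Angstrom = 125 Angstrom^3) on the C-lobe surface whose gate
#' residue (W505) either fills it ("in") or vacates it ("out").
#'
#' @param config a [generator_config()].
#' @param gate gate position of the returned reference frame, `"in"` or
#'   `"out"`.
#' @param void_edge edge length of the planted cavity, Angstrom.
#' @return a `kd_synthetic_build`: list with `topology`, `roles`, `frame`
#'   (reference coordinates), and an `aux` list used by [simulate_state()]
#'   (pocket centre, gate positions, planted directions, atom bookkeeping).
#' @export
build_topology <- function(config = generator_config(),
                           gate = c("in", "out"), void_edge = 5.0) {
  gate <- match.arg(gate)
  first <- config$first_resid
  min_n <- 569L - first + 1L
  if (config$n_residues < min_n) {
    abort(sprintf("n_residues = %d cannot host all functional roles; minimum is %d (first residue %d, last role residue 569)",
                  config$n_residues, min_n, first))
  }
  rid <- first:(first + config$n_residues - 1L)
  helix_res <- 379:392
  loop_res <- 479:499
  flap_res <- 537:569
  pocket_res <- pocket_resids()
  clobe_res <- setdiff(intersect(440:536, rid),
                       c(loop_res, pocket_res, helix_res))
  nlobe_res <- setdiff(rid[rid < 440], helix_res)
  tail_res <- rid[rid > 569]

  # the cavity box sits on the outer C-lobe face, clear of the inter-lobe
  # cleft, so the seeded pocket region captures only the planted void and
  # never transient cleft voids
  pocket_centre <- c(0, 0, 26)
  half_wall <- void_edge / 2 + 3.1    # wall-atom reach = 1.7 vdw + 1.4 probe

  ca <- list()
  add_ca <- function(res, pts) {
    for (ii in seq_along(res)) ca[[as.character(res[ii])]] <<- pts[ii, ]
  }
  add_ca(nlobe_res, lattice_points(length(nlobe_res), 3.6, c(0, 0, -12)))
  add_ca(clobe_res, lattice_points(length(clobe_res), 3.6, c(0, 0, 12)))
  add_ca(flap_res, lattice_points(length(flap_res), 3.6, c(-10, 9, -7)))
  if (length(tail_res) > 0) {
    add_ca(tail_res, cbind(-12, -10 + 1.5 * seq_along(tail_res), 10))
  }
  # activation loop: arc spanning the inter-lobe cleft
  th <- seq(-1.2, 1.2, length.out = length(loop_res))
  add_ca(loop_res, cbind(9 + 1.5 * sin(3 * th), 7 * sin(th), 7 * cos(th)))
  # pocket-lining residues: ring around the cavity box flanks, away from
  # the lobe surface
  phi <- 2 * pi * (seq_along(pocket_res) - 1) / length(pocket_res)
  add_ca(pocket_res, cbind(9 * cos(phi), 9 * sin(phi), pocket_centre[3]))
  # alphaC helix: ideal helix along x, centred near the cleft (translated
  # to its reference COM after the side-chain atoms exist)
  i <- seq_along(helix_res)
  add_ca(helix_res, cbind((i - mean(i)) * 1.5, 2.3 * cos(1.745 * i),
                          -3 + 2.3 * sin(1.745 * i)))

  atoms <- list()
  add_atom <- function(res, name, resname, element, xyz, vdw = NULL, mass = NULL) {
    atoms[[length(atoms) + 1L]] <<- list(res = res, name = name,
                                         resname = resname, element = element,
                                         xyz = xyz, vdw = vdw, mass = mass)
  }
  resname_of <- function(r) {
    known <- c(`369` = "LYS", `379` = "ASP", `386` = "GLU", `390` = "MET",
               `348` = "ASN", `479` = "ASP", `480` = "PHE", `481` = "GLY",
               `492` = "TYR", `493` = "TYR", `496` = "ARG", `497` = "SER",
               `505` = "TRP", `514` = "ARG", `524` = "SER")
    out <- known[as.character(r)]
    ifelse(is.na(out), "ALA", out)
  }
  for (r in sort(as.integer(names(ca)))) {
    add_atom(r, "CA", resname_of(r), "C", ca[[as.character(r)]])
  }

  u_dfg <- normalize(c(0.3, 0.8, 0.52))
  cg479 <- ca[["479"]] + c(1.5, 0.8, 0)
  add_atom(479L, "CG", "ASP", "C", cg479)
  add_atom(481L, "N", "GLY", "N", cg479 + 4.0 * u_dfg)
  add_atom(481L, "H", "GLY", "H", cg479 + 3.0 * u_dfg)
  add_atom(480L, "CZ", "PHE", "C", ca[["480"]] + c(-1.8, 0.5, -0.5))
  add_atom(386L, "OE1", "GLU", "O", ca[["386"]] + c(1.8, 0, 0))
  add_atom(386L, "OE2", "GLU", "O", ca[["386"]] + c(1.8, 2.2, 0))
  add_atom(390L, "N", "MET", "N", ca[["390"]] + c(-1.2, 0.4, 0))
  add_atom(379L, "CG", "ASP", "C", ca[["379"]] + c(1.8, 0, 0.5))
  add_atom(348L, "ND2", "ASN", "N", ca[["348"]] + c(1.6, 0, 0))
  add_atom(492L, "OH", "TYR", "O", ca[["492"]] + c(1.9, 0, 0))
  add_atom(493L, "OH", "TYR", "O", ca[["493"]] + c(1.9, 0, 0))
  add_atom(514L, "NH1", "ARG", "N", ca[["514"]] + c(2.0, 0, 0))
  add_atom(497L, "OG", "SER", "O", ca[["497"]] + c(1.5, 0, 0))
  # K369 NZ: reference formed-bridge geometry, set after helix translation
  add_atom(369L, "NZ", "LYS", "N", c(0, 0, 0))
  # R496 NH1: reference broken STA bridge, set below
  add_atom(496L, "NH1", "ARG", "N", c(0, 0, 0))
  # gate pseudo side chain: one fat sphere that fills the cavity when "in"
  gate_in <- pocket_centre
  gate_out <- pocket_centre + c(0, 0, half_wall + 5.5)
  add_atom(505L, "GATE", "TRP", "C",
           if (gate == "in") gate_in else gate_out, vdw = 3.0)
  # cavity walls: lattice over the 6 faces of a cube, assigned as pseudo
  # side-chain atoms of the pocket-lining residues
  s <- seq(-half_wall, half_wall, length.out = 6)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  on_face <- apply(abs(abs(g) - half_wall) < 1e-9, 1, any)
  wall <- sweep(g[on_face, , drop = FALSE], 2, -pocket_centre)
  widx <- seq_len(nrow(wall))
  wres <- pocket_res[(widx - 1L) %% length(pocket_res) + 1L]
  wnum <- stats::ave(widx, wres, FUN = seq_along)
  for (t in widx) {
    add_atom(wres[t], sprintf("W%02d", wnum[t]), resname_of(wres[t]), "C",
             wall[t, ])
  }
  # ATP-site anchor pseudo-ligand
  add_atom(601L, "PG", "ATP", "P", c(8, 0, 4))

  df <- tibble(
    residue_id = vapply(atoms, function(a) as.integer(a$res), integer(1)),
    atom_name = vapply(atoms, function(a) a$name, character(1)),
    residue_name = vapply(atoms, function(a) a$resname, character(1)),
    element = vapply(atoms, function(a) a$element, character(1))
  )
  xyz <- do.call(rbind, lapply(atoms, function(a) a$xyz))
  props <- element_properties(df$element)
  df$mass <- props$mass
  df$vdw_radius <- props$vdw_radius
  ovr <- which(!vapply(atoms, function(a) is.null(a$vdw), logical(1)))
  for (t in ovr) df$vdw_radius[t] <- atoms[[t]]$vdw
  # CA first within each residue, residues in order
  ord <- order(df$residue_id, df$atom_name != "CA", df$atom_name)
  df <- df[ord, ]
  xyz <- xyz[ord, , drop = FALSE]
  topo <- topology(df)

  roles <- residue_roles(GATE_W = list(resid = 505L, atom = "GATE"),
                         ATP_ANCHOR = list(resid = 601L, atom = "PG"))

  row_of <- function(res, name) which(topo$residue_id == res & topo$atom_name == name)
  helix_rows <- which(topo$residue_id %in% helix_res)
  clobe_rows <- which(topo$residue_id %in% 440:536)
  ca_rows <- which(topo$atom_name == "CA")
  loop_ca_rows <- which(topo$atom_name == "CA" & topo$residue_id %in% 479:500)

  # place the helix reference so its mass-weighted COM sits 15 A from the
  # C-lobe COM (the inhibited-state reference level)
  w_cl <- topo$mass[clobe_rows] / sum(topo$mass[clobe_rows])
  clobe_com <- as.numeric(crossprod(xyz[clobe_rows, , drop = FALSE], w_cl))
  w_hx <- topo$mass[helix_rows] / sum(topo$mass[helix_rows])
  helix_com <- as.numeric(crossprod(xyz[helix_rows, , drop = FALSE], w_hx))
  u_helix <- normalize(helix_com - clobe_com)
  shift <- (clobe_com + 15.0 * u_helix) - helix_com
  xyz[helix_rows, ] <- sweep(xyz[helix_rows, , drop = FALSE], 2, -shift)
  helix_local <- sweep(xyz[helix_rows, , drop = FALSE], 2,
                       clobe_com + 15.0 * u_helix)

  # salt-bridge direction: from E386 OE1 toward K369 CA, orthogonal to the
  # OE1->OE2 axis so the minimum NZ-carboxylate distance is the planted one
  oe1 <- xyz[row_of(386L, "OE1"), ]
  oe2 <- xyz[row_of(386L, "OE2"), ]
  v <- normalize(oe2 - oe1)
  u_sb <- normalize(xyz[row_of(369L, "CA"), ] - oe1)
  u_sb <- normalize(u_sb - sum(u_sb * v) * v)
  xyz[row_of(369L, "NZ"), ] <- oe1 + 3.0 * u_sb
  cg379 <- xyz[row_of(379L, "CG"), ]
  u_sta <- normalize(xyz[row_of(496L, "CA"), ] - cg379)
  xyz[row_of(496L, "NH1"), ] <- cg379 + 8.0 * u_sta

  aux <- list(
    pocket_centre = pocket_centre, void_edge = void_edge,
    gate_in = gate_in, gate_out = gate_out,
    u_dfg = u_dfg, u_sb = u_sb, u_sta = u_sta, u_helix = u_helix,
    helix_rows = helix_rows, helix_local = helix_local,
    clobe_rows = clobe_rows, clobe_w = w_cl,
    ca_rows = ca_rows, loop_ca_rows = loop_ca_rows,
    row = list(
      cg479 = row_of(479L, "CG"), h481 = row_of(481L, "H"),
      n481 = row_of(481L, "N"), nz369 = row_of(369L, "NZ"),
      oe1 = row_of(386L, "OE1"), cg379 = row_of(379L, "CG"),
      nh496 = row_of(496L, "NH1"), nd348 = row_of(348L, "ND2"),
      og497 = row_of(497L, "OG"), gate = row_of(505L, "GATE")
    ),
    controlled_rows = sort(unique(c(
      helix_rows, row_of(479L, "CG"), row_of(481L, "H"), row_of(481L, "N"),
      row_of(369L, "NZ"), row_of(496L, "NH1"), row_of(348L, "ND2"),
      row_of(497L, "OG"), row_of(505L, "GATE")
    )))
  )
  aux$mode_rows <- setdiff(aux$ca_rows, aux$helix_rows)
  structure(list(topology = topo, roles = roles, frame = xyz, aux = aux),
            class = "kd_synthetic_build")
}

#' Planted collective-mode direction fields
#'
#' Deterministic orthonormal displacement fields over the C-alpha atoms
#' (helix C-alphas excluded, where the rigid helix placement overrides
#' them), expressed in the coordinate space of the `"name CA"` selection.
#' Mode fields depend only on the topology size and the mode id, never on
#' the simulation seed.
#'
#' @param build a [build_topology()] result.
#' @param ids mode ids (default 1:4).
#' @return matrix `(3 * n_CA) x length(ids)`, columns of unit norm,
#'   pairwise orthogonal, with zeros on helix C-alphas. Coordinates are
#'   interleaved (x1, y1, z1, x2, ...) in CA-selection order.
#' @export
planted_mode_vectors <- function(build, ids = 1:4) {
  ca_rows <- build$aux$ca_rows
  elig <- match(build$aux$mode_rows, ca_rows)  # positions within CA set
  n_ca <- length(ca_rows)
  k_max <- max(ids)
  # rigid-body fields of the eligible atoms (3 translations + 3 rotations
  # about their centroid): planted modes are internal motions, orthogonal
  # to anything the trajectory alignment can remove
  pos <- build$frame[build$aux$mode_rows, , drop = FALSE]
  pos <- sweep(pos, 2, colMeans(pos))
  ne <- nrow(pos)
  rigid <- cbind(
    rep(c(1, 0, 0), ne), rep(c(0, 1, 0), ne), rep(c(0, 0, 1), ne),
    as.vector(t(cbind(0, -pos[, 3], pos[, 2]))),
    as.vector(t(cbind(pos[, 3], 0, -pos[, 1]))),
    as.vector(t(cbind(-pos[, 2], pos[, 1], 0))))
  rigid <- qr.Q(qr(rigid))
  basis <- matrix(0, nrow = 3 * ne, ncol = k_max)
  for (m in seq_len(k_max)) {
    raw <- withr::with_seed(770000L + m, rnorm(3 * ne))
    raw <- raw - rigid %*% crossprod(rigid, raw)
    if (m > 1) {
      for (j in seq_len(m - 1)) raw <- raw - sum(raw * basis[, j]) * basis[, j]
    }
    basis[, m] <- raw / sqrt(sum(raw^2))
  }
  out <- matrix(0, nrow = 3 * n_ca, ncol = length(ids))
  dof <- as.vector(rbind(3 * (elig - 1) + 1, 3 * (elig - 1) + 2, 3 * elig))
  for (c in seq_along(ids)) out[dof, c] <- basis[, ids[c]]
  out
}

# exact AR(1) discretization of an OU deviation process
ou_deviation <- function(n, dt, tau, sd) {
  if (sd == 0) return(rep(0, n))
  phi <- exp(-dt / tau)
  eps <- rnorm(n, sd = sd * sqrt(1 - phi^2))
  z0 <- rnorm(1, sd = sd)
  as.numeric(stats::filter(eps, phi, method = "recursive", init = z0))
}

scheduled_mean <- function(n, mean, transition) {
  if (length(mean) == 1) return(rep(mean, n))
  if (is.null(transition)) abort("two-level mean schedule needs a transition fraction")
  cut <- floor(transition * n)
  c(rep(mean[1], cut), rep(mean[2], n - cut))
}

# two-state telegraph chain with stationary occupancy p and relaxation
# rate lambda (events/ns); returns a logical vector (TRUE = formed/open)
telegraph_chain <- function(n, dt, p, lambda) {
  if (p <= 0) return(rep(FALSE, n))
  if (p >= 1) return(rep(TRUE, n))
  ef <- exp(-lambda * dt)
  s <- logical(n)
  s[1] <- runif(1) < p
  u <- runif(n - 1)
  for (i in 2:n) {
    pf <- p + (as.numeric(s[i - 1]) - p) * ef
    s[i] <- u[i - 1] < pf
  }
  s
}

#' Simulate one synthetic state trajectory
#'
#' Role-atom distances follow exact AR(1) discretizations of
#' Ornstein-Uhlenbeck processes around the profile targets (stationary sd =
#' profile sd, relaxation time `ou_tau`); the salt bridge follows a
#' two-state telegraph process over formed (3.0 A) / broken (8.0 A)
#' geometries; activation-loop C-alphas get `noise_sd * loop_flex_scale`
#' thermal noise; planted collective modes displace C-alpha atoms along
#' fixed orthonormal direction fields with sinusoid-plus-noise amplitudes;
#' pocket gating toggles the gate atom between its in/out positions with
#' exponential dwell times. Identical (profile, config) gives bit-identical
#' output.
#'
#' @param profile a [state_profile()].
#' @param config a [generator_config()].
#' @param build optional pre-built [build_topology()] (rebuilt from
#'   `config` when NULL).
#' @return a [trajectory()] labelled with the profile name.
#' @export
simulate_state <- function(profile, config = generator_config(), build = NULL) {
  if (is.null(build)) build <- build_topology(config)
  topo <- build$topology
  aux <- build$aux
  ref <- build$frame
  n <- config$n_frames
  dt <- config$dt
  na <- nrow(topo)
  times <- (seq_len(n) - 1) * dt

  withr::with_seed(config$seed, {
    coords <- array(0, dim = c(n, na, 3))
    # baseline thermal noise everywhere; controlled atoms are overwritten
    sd_atom <- rep(config$noise_sd, na)
    sd_atom[aux$loop_ca_rows] <- config$noise_sd * profile$loop_flex_scale
    for (ax in 1:3) {
      coords[, , ax] <- matrix(ref[, ax], n, na, byrow = TRUE) +
        matrix(rnorm(n * na, sd = rep(sd_atom, each = n)), n, na)
    }
    # planted collective modes over eligible C-alphas
    if (length(profile$mode_amplitudes) > 0) {
      ids <- as.integer(names(profile$mode_amplitudes))
      fields <- planted_mode_vectors(build, ids = ids)
      ca_rows <- aux$ca_rows
      for (c in seq_along(ids)) {
        A <- profile$mode_amplitudes[[c]]
        if (A <= 0) next
        period <- 6 + 3 * ids[c]
        phase <- runif(1, 0, 2 * pi)
        a <- A * sin(2 * pi * times / period + phase) + rnorm(n, sd = 0.1 * A)
        fld <- matrix(fields[, c], ncol = 3, byrow = TRUE)  # n_ca x 3
        nz <- which(rowSums(fld^2) > 0)
        for (ax in 1:3) {
          coords[, ca_rows[nz], ax] <- coords[, ca_rows[nz], ax] +
            outer(a, fld[nz, ax])
        }
      }
    }
    # DFG cyclization distance: anchor CG static, amide H/N on the planted axis
    d_dfg <- scheduled_mean(n, profile$dfg_mean, profile$dfg_transition) +
      ou_deviation(n, dt, config$ou_tau, profile$dfg_sd)
    d_dfg <- pmax(d_dfg, 0.5)
    r <- aux$row
    for (ax in 1:3) {
      coords[, r$cg479, ax] <- ref[r$cg479, ax]
      coords[, r$h481, ax] <- ref[r$cg479, ax] + d_dfg * aux$u_dfg[ax]
      coords[, r$n481, ax] <- ref[r$cg479, ax] + (d_dfg + 1.0) * aux$u_dfg[ax]
    }
    # gate placement first (the gate belongs to the C-lobe residue range)
    gating <- profile$pocket_gating
    if (gating$mode == "gated") {
      p_open <- gating$open_dwell / (gating$open_dwell + gating$close_dwell)
      lambda <- 1 / gating$open_dwell + 1 / gating$close_dwell
      open <- telegraph_chain(n, dt, p_open, lambda)
    } else {
      open <- rep(FALSE, n)
    }
    for (ax in 1:3) {
      coords[, r$gate, ax] <- ifelse(open, aux$gate_out[ax], aux$gate_in[ax])
    }
    # inhibited-state-specific contacts across the catalytic cleft; placed
    # relative to reference geometry so every C-lobe atom is final before
    # the per-frame C-lobe COM is taken
    d_sta <- if (profile$name == "STA") 3.0 else 8.0
    u_hb <- normalize(ref[r$og497, ] - ref[r$nd348, ])
    d_hb <- if (profile$name == "STA") {
      ifelse(telegraph_chain(n, dt, 0.5, profile$switching_rate), 2.8, 7.0) +
        rnorm(n, sd = 0.2)
    } else {
      rep(7.0, n)
    }
    for (ax in 1:3) {
      coords[, r$nh496, ax] <- ref[r$cg379, ax] + d_sta * aux$u_sta[ax]
      coords[, r$nd348, ax] <- ref[r$nd348, ax]
      coords[, r$og497, ax] <- ref[r$nd348, ax] + d_hb * u_hb[ax]
    }
    # alphaC helix: rigid placement at the planted COM distance from the
    # per-frame C-lobe COM
    d_ac <- scheduled_mean(n, profile$alphaC_mean, profile$alphaC_transition) +
      ou_deviation(n, dt, config$ou_tau, profile$alphaC_sd)
    com <- matrix(0, n, 3)
    for (ax in 1:3) com[, ax] <- coords[, aux$clobe_rows, ax] %*% aux$clobe_w
    nh <- length(aux$helix_rows)
    for (ax in 1:3) {
      target <- com[, ax] + d_ac * aux$u_helix[ax]
      coords[, aux$helix_rows, ax] <-
        matrix(aux$helix_local[, ax], n, nh, byrow = TRUE) + target
    }
    # salt bridge: telegraph over formed/broken geometries, NZ anchored to
    # the (helix-placed) E386 carboxylate
    formed <- telegraph_chain(n, dt, profile$saltbridge_occupancy,
                              profile$switching_rate)
    d_sb <- ifelse(formed, 3.0, 8.0) + rnorm(n, sd = 0.25)
    d_sb <- pmax(d_sb, 0.5)
    for (ax in 1:3) {
      coords[, r$nz369, ax] <- coords[, r$oe1, ax] + d_sb * aux$u_sb[ax]
    }
    trajectory(coords, times = times, state = profile$name)
  })
}

#' Simulate the five-state panel
#'
#' Runs [simulate_state()] for the five [default_state_profiles()] with
#' seeds `seed + 0..4` and attaches state labels.
#'
#' @param config a [generator_config()].
#' @param profiles optional named list of profiles overriding the defaults.
#' @return list with `trajectories` (named by state), `topology`, `roles`
#'   and the `build`.
#' @export
simulate_panel <- function(config = generator_config(), profiles = NULL) {
  profiles <- profiles %||% default_state_profiles()
  build <- build_topology(config)
  trajs <- list()
  for (k in seq_along(profiles)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    trajs[[names(profiles)[k]]] <- simulate_state(profiles[[k]], cfg_k, build)
  }
  list(trajectories = trajs, topology = build$topology, roles = build$roles,
       build = build)
}

#' Two-state benchmark panel with three planted modes
#'
#' A mode-recovery fixture: state A carries planted modes 1/2/3 at
#' amplitudes 3/2/1 Angstrom, state B carries modes 2/3 only, so mode 1 is
#' the state-differential motion. Descriptor processes are kept quiet
#' (small sds) so the planted modes dominate the covariance spectrum.
#'
#' @param config a [generator_config()].
#' @return as [simulate_panel()], plus `planted` (the three planted mode
#'   fields from [planted_mode_vectors()]).
#' @export
simulate_mode_benchmark <- function(config = generator_config(n_frames = 5000)) {
  quiet <- function(name, modes) {
    state_profile(name, dfg_mean = 5.0, dfg_sd = 0.1,
                  alphaC_mean = 14.5, alphaC_sd = 0.05,
                  saltbridge_occupancy = 0.5, loop_flex_scale = 1.0,
                  mode_amplitudes = modes)
  }
  profiles <- list(
    A = quiet("A", list(`1` = 3.0, `2` = 2.0, `3` = 1.0)),
    B = quiet("B", list(`2` = 2.0, `3` = 1.0))
  )
  out <- simulate_panel(config, profiles = profiles)
  out$planted <- planted_mode_vectors(out$build, ids = 1:3)
  out
}
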