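# Shared fixtures and independent oracles. Everything is generated in code;
# heavier objects are cached per test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, make(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

tiny_config <- function(n_frames = 200, seed = 11, ...) {
  generator_config(n_frames = n_frames, seed = seed, ...)
}

tiny_build <- function() fixture("tiny_build", function() build_topology(tiny_config()))

# a small CA-only topology with author numbering `resids`
toy_topology <- function(resids, atom_name = "CA", element = "C") {
  topology(tibble::tibble(
    atom_name = atom_name, residue_name = "ALA",
    residue_id = resids, element = element
  ))
}

# random coordinates for n atoms
rand_frame <- function(n, scale = 10) matrix(stats::runif(3 * n, -scale, scale), ncol = 3)

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# independent superposition oracle: minimise RMSD over rotations
# parameterised by quaternions, with random restarts
rmsd_quaternion_oracle <- function(X, Y, n_starts = 25) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(q) {
    R <- quat_to_rot(q / sqrt(sum(q^2)))
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    q0 <- stats::rnorm(4)
    fit <- stats::optim(q0, obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

# apply one rigid motion (rotation R then translation t) to a whole trajectory
transform_trajectory <- function(traj, R, t) {
  out <- traj
  for (i in seq_len(dim(traj$coords)[1])) {
    fr <- matrix(traj$coords[i, , ], ncol = 3)
    out$coords[i, , ] <- sweep(fr %*% t(R), 2, t, `+`)
  }
  out
}

# standard error of the mean of an AR(1) process with autocorrelation phi
se_mean_ar1 <- function(sd, n, phi) sd * sqrt((1 + phi) / (1 - phi)) / sqrt(n)

# largest principal angle (degrees) between the column spans of U and V
max_principal_angle <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  sv <- svd(crossprod(qu, qv))$d
  acos(min(pmin(pmax(sv, -1), 1))) * 180 / pi
}

# fixed-width PDB ATOM record
pdb_line <- function(serial, name, resname, resid, x, y, z, altloc = " ",
                     element = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, substr(paste0(" ", name), 1, 4), altloc, resname, resid,
          x, y, z, element)
}

# a hollow box of wall pseudo-atoms with an empty cubic interior of edge
# `edge` centred at `centre`; wall reach is vdw 1.7 + probe 1.4 = 3.1 and a
# dense wall lattice (pitch <= 0.8) keeps the realized void close to edge^3
hollow_box <- function(edge = 5, centre = c(0, 0, 0), pitch = 0.75) {
  half <- edge / 2 + 3.1
  s <- seq(-half, half, length.out = ceiling(2 * half / pitch) + 1)
  g <- as.matrix(expand.grid(s, s, s))
  on_face <- apply(abs(abs(g) - half) < 1e-9, 1, any)
  pts <- sweep(g[on_face, , drop = FALSE], 2, -centre)
  topo <- toy_topology(seq_len(nrow(pts)), atom_name = "DUM")
  list(topology = topo, frame = pts)
}

required_roles_for_test <- function() {
  c("DFG_D", "DFG_F", "DFG_G", "SB_K", "SB_E", "HELIX_C", "CLOBE",
    "STA_SB_D", "STA_SB_R", "HB_N", "HB_S", "LOOP_R", "PY1", "PY2",
    "GATE_W", "FLAP", "POCKET")
}

# project the 3 translation + 3 rotation rigid-body fields of `base` out of
# each column of U, then re-orthonormalise
remove_rigid_fields <- function(U, base) {
  pos <- sweep(base, 2, colMeans(base))
  n <- nrow(pos)
  rigid <- cbind(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.vector(t(cbind(0, -pos[, 3], pos[, 2]))),
    as.vector(t(cbind(pos[, 3], 0, -pos[, 1]))),
    as.vector(t(cbind(-pos[, 2], pos[, 1], 0))))
  rigid <- qr.Q(qr(rigid))
  qr.Q(qr(U - rigid %*% crossprod(rigid, U)))
}
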