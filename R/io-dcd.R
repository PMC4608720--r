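# Minimal CHARMM/NAMD-dialect DCD (32-bit, fixed atom count, no unit cell).
# Frame times are encoded through the header: time = (istart + i*nsavc)*delta,
# with delta stored in ns. bio3d::read.dcd reads files written here.

write_dcd_file <- function(traj, path) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else 0.1
  istart <- as.integer(round(traj$times[1] / dt))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_int <- function(x) writeBin(as.integer(x), con, size = 4L)
  # header record (84 bytes): "CORD" + 20 control ints, delta as float at slot 10
  w_int(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  w_int(c(nf, istart, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(dt, con, size = 4L)              # delta (ns)
  w_int(c(0L, rep(0L, 8L), 24L))            # no unit cell; CHARMM version tag
  w_int(84L)
  # title record
  title <- formatC("kindyn trajectory", width = 80L, flag = "-")
  w_int(84L); w_int(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  w_int(84L)
  # atom-count record
  w_int(4L); w_int(na); w_int(4L)
  for (i in seq_len(nf)) {
    for (ax in 1:3) {
      w_int(4L * na)
      writeBin(as.numeric(traj$coords[i, , ax]), con, size = 4L)
      w_int(4L * na)
    }
  }
  invisible(path)
}

read_dcd_file <- function(path) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  endian <- "little"
  r_int <- function(n = 1L) readBin(con, "integer", n = n, size = 4L, endian = endian)
  r_float <- function(n = 1L) readBin(con, "numeric", n = n, size = 4L, endian = endian)
  marker <- r_int()
  if (length(marker) == 0) abort("empty DCD file")
  if (marker != 84L) {
    endian <- "big"
    seek(con, 0)
    marker <- r_int()
    if (length(marker) == 0 || marker != 84L) abort("not a DCD file (bad header record)")
  }
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (magic != "CORD") abort("not a DCD file (missing CORD magic)")
  icntrl1 <- r_int(9L)
  delta <- r_float(1L)
  icntrl2 <- r_int(10L)
  if (r_int() != 84L) abort("corrupt DCD header record")
  nf_declared <- icntrl1[1]
  istart <- icntrl1[2]
  nsavc <- max(icntrl1[3], 1L)
  tlen <- r_int()
  ntitle <- r_int()
  readChar(con, tlen - 4L, useBytes = TRUE)
  r_int()
  if (r_int() != 4L) abort("corrupt DCD atom-count record")
  na <- r_int()
  r_int()
  frames <- list()
  repeat {
    m <- r_int()
    if (length(m) == 0) break
    frame <- matrix(NA_real_, nrow = na, ncol = 3)
    ok <- TRUE
    for (ax in 1:3) {
      if (ax > 1) {
        m <- r_int()
        if (length(m) == 0) { ok <- FALSE; break }
      }
      vals <- r_float(na)
      if (length(vals) < na) { ok <- FALSE; break }
      frame[, ax] <- vals
      tail_m <- r_int()
      if (length(tail_m) == 0) { ok <- FALSE; break }
    }
    if (!ok) {
      abort(sprintf("truncated DCD file: last complete frame is %d", length(frames)))
    }
    frames[[length(frames) + 1L]] <- frame
  }
  if (length(frames) == 0) abort("DCD file contains no frames")
  nf <- length(frames)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (i in seq_len(nf)) coords[i, , ] <- frames[[i]]
  if (delta <= 0) delta <- 0.1
  times <- (istart + (seq_len(nf) - 1) * nsavc) * delta
  list(coords = coords, times = times)
}
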