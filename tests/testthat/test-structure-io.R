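test_that("PDB parsing echoes residue fields and keeps the first altloc", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ASP", 479, 1.0, 2.0, 3.0),
    pdb_line(2, "CA", "PHE", 480, 4.0, 5.0, 6.0),
    pdb_line(3, "CA", "GLY", 481, 7.0, 8.0, 9.0),
    "END"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$topology), 3)
  expect_equal(st$topology$residue_id, c(479L, 480L, 481L))
  expect_equal(st$topology$atom_name, rep("CA", 3))
  expect_equal(frame_coords(st$trajectory)[2, ], c(4, 5, 6))
  expect_gt(min(st$topology$vdw_radius), 0)

  # two altlocs for one atom: one atom retained, with a warning
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ASP", 479, 1.0, 2.0, 3.0, altloc = "A"),
    pdb_line(2, "CA", "ASP", 479, 1.1, 2.1, 3.1, altloc = "B"),
    pdb_line(3, "CA", "PHE", 480, 4.0, 5.0, 6.0),
    "END"), f2)
  expect_warning(st2 <- read_structure(f2), "altloc")
  expect_equal(nrow(st2$topology), 2)
  expect_equal(frame_coords(st2$trajectory)[1, ], c(1, 2, 3))
})

test_that("malformed PDB records raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ASP", 479, 1.0, 2.0, 3.0),
    "ATOM      2  CA  PHE A 480      bad coordinates here",
    "END"), f)
  expect_error(read_structure(f), "line 2")
  expect_error(read_structure(tempfile()), "does not exist")
})

test_that("unknown elements are reported with the offending atom", {
  expect_error(
    topology(tibble::tibble(atom_name = "XX", residue_name = "UNK",
                            residue_id = 1L, element = "Qq")),
    "unknown element")
})

test_that("topology invariants are enforced", {
  base <- tibble::tibble(atom_name = c("CA", "CA"), residue_name = "ALA",
                         residue_id = c(2L, 1L), element = "C")
  expect_error(topology(base), "non-decreasing")
  dup <- tibble::tibble(atom_name = c("CA", "CA"), residue_name = "ALA",
                        residue_id = c(1L, 1L), element = "C")
  expect_error(topology(dup), "duplicated")
})

test_that("trajectory round-trips preserve coordinates within format precision", {
  cfg <- tiny_config(n_frames = 20)
  b <- tiny_build()
  tr <- simulate_state(default_state_profiles()$Y0Y0, cfg, b)

  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(tr, b$topology, dcd)
  tr_d <- read_trajectory(dcd, b$topology)
  expect_lt(max(abs(tr_d$coords - tr$coords)), 1e-4)   # float32 storage
  expect_equal(tr_d$times, tr$times, tolerance = 1e-6)

  # independent reader oracle for the DCD writer
  oracle <- bio3d::read.dcd(dcd, verbose = FALSE)
  for (i in c(1, 7, 20)) {
    expect_lt(max(abs(oracle[i, ] - as.vector(t(frame_coords(tr, i))))), 1e-4)
  }

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, b$topology, pdb)
  tr_p <- read_trajectory(pdb, b$topology, dt = cfg$dt)
  expect_lt(max(abs(tr_p$coords - tr$coords)), 1e-3)   # 3-decimal text

  # write-then-read of a structure preserves the atom table
  st <- read_structure(pdb)
  expect_equal(st$topology$atom_name, b$topology$atom_name)
  expect_equal(st$topology$residue_id, b$topology$residue_id)
  expect_equal(st$topology$element, b$topology$element)
})

test_that("single-frame and empty writes behave per contract", {
  b <- tiny_build()
  one <- trajectory(b$frame)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(one, b$topology, f)
  back <- read_trajectory(f, b$topology)
  expect_equal(dim(back$coords)[1], 1)
  expect_lt(max(abs(back$coords[1, , ] - b$frame)), 1e-4)

  empty <- one
  empty$coords <- one$coords[0, , , drop = FALSE]
  empty$times <- numeric(0)
  expect_error(write_trajectory(empty, b$topology, f), "empty")
})

test_that("DCD times encode the supplied stride and truncation is detected", {
  b <- tiny_build()
  tr <- simulate_state(default_state_profiles()$STA, tiny_config(n_frames = 10), b)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(tr, b$topology, f)
  back <- read_trajectory(f, b$topology)
  expect_equal(diff(back$times), rep(0.1, 9), tolerance = 1e-6)

  # chop the file mid-frame: error must report the last complete frame
  sz <- file.size(f)
  raw <- readBin(f, "raw", sz)
  trunc <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw[1:(sz - 700)], trunc)
  expect_error(read_trajectory(trunc, b$topology), "last complete frame is 9")
})

test_that("multi-model PDB reading yields the declared shape; XTC is rejected", {
  lines <- character(0)
  for (m in 1:5) {
    lines <- c(lines, sprintf("MODEL     %4d", m),
               pdb_line(1, "CA", "ALA", 1, m, 0, 0),
               pdb_line(2, "CA", "ALA", 2, 0, m, 0),
               pdb_line(3, "CA", "ALA", 3, 0, 0, m),
               "ENDMDL")
  }
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  topo <- toy_topology(1:3)
  tr <- read_trajectory(f, topo)
  expect_equal(dim(tr$coords), c(5, 3, 3))
  expect_equal(tr$coords[4, 1, 1], 4)

  expect_error(read_trajectory("x.xtc", topo), "XTC")
  expect_error(write_trajectory(trajectory(rand_frame(3)), topo, "x.xtc"), "XTC")
})

test_that("atom-count mismatches report both counts", {
  b <- tiny_build()
  tr <- trajectory(b$frame)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(tr, b$topology, f)
  small <- toy_topology(1:5)
  expect_error(read_trajectory(f, small), "409.*5|5.*409")
})

test_that("selection grammar agrees with a brute-force predicate scan", {
  topo <- tiny_build()$topology
  sel <- select_atoms(topo, "resid 379-392 and name CA")
  expect_equal(length(sel$indices), 14)
  brute <- which(topo$residue_id %in% 379:392 & topo$atom_name == "CA") - 1L
  expect_identical(sel$indices, sort(brute))

  cases <- c("name CA", "resid 440-536", "element N and resid 340-500",
             "resname ATP", "noh and resid 479-481", "all")
  preds <- list(
    function(t) t$atom_name == "CA",
    function(t) t$residue_id %in% 440:536,
    function(t) t$element == "N" & t$residue_id %in% 340:500,
    function(t) t$residue_name == "ATP",
    function(t) t$element != "H" & t$residue_id %in% 479:481,
    function(t) rep(TRUE, nrow(t))
  )
  for (i in seq_along(cases)) {
    sel_i <- suppressWarnings(select_atoms(topo, cases[i]))
    expect_identical(sel_i$indices, sort(which(preds[[i]](topo)) - 1L),
                     info = cases[i])
    # determinism: resolving again gives the identical index vector
    expect_identical(sel_i$indices,
                     suppressWarnings(select_atoms(topo, cases[i]))$indices)
  }
})

test_that("selection errors and empty matches behave per contract", {
  topo <- toy_topology(1:10)
  expect_error(select_atoms(topo, "bogus CA"), "unknown keyword")
  expect_error(select_atoms(topo, "resid x-y"), "bad resid token")
  expect_error(select_atoms(topo, "name"), "needs arguments")
  expect_warning(select_atoms(topo, "name CB"), "no atoms")
  expect_error(select_atoms(topo, "role NOPE", roles = residue_roles()),
               "known roles")
})

test_that("role maps resolve, round-trip through YAML, and miss loudly", {
  b <- tiny_build()
  sels <- resolve_roles(b$roles, b$topology)
  expect_true(all(required_roles_for_test() %in% names(sels)))
  expect_equal(length(sels$POCKET$indices),
               sum(b$topology$residue_id %in% c(460:463, 500:502, 505, 506, 524)))

  f <- withr::local_tempfile(fileext = ".yaml")
  write_roles(b$roles, f)
  back <- read_roles(f)
  expect_equal(back$DFG_D$resid, 479L)
  expect_equal(back$GATE_W$atom, "GATE")

  broken <- b$roles
  broken$DFG_D$resid <- 9999L
  expect_error(resolve_roles(broken, b$topology), "DFG_D")
})
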