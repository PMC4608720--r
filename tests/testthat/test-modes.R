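# a minimal planted-oscillation ensemble built directly (independent of the
# kinase generator): base structure + sum of sinusoidal collective motions
planted_ensemble <- function(n_frames, n_atoms, amps, periods, noise = 0.05,
                             seed = 1) {
  withr::with_seed(seed, {
    base <- rand_frame(n_atoms)
    k <- length(amps)
    U <- remove_rigid_fields(matrix(rnorm(3 * n_atoms * k), ncol = k), base)
    coords <- array(rep(base, each = n_frames), dim = c(n_frames, n_atoms, 3)) +
      array(rnorm(n_frames * n_atoms * 3, sd = noise), dim = c(n_frames, n_atoms, 3))
    t <- seq_len(n_frames)
    for (m in seq_len(k)) {
      a <- amps[m] * sin(2 * pi * t / periods[m] + runif(1, 0, 2 * pi))
      fld <- matrix(U[, m], ncol = 3, byrow = TRUE)
      for (ax in 1:3) coords[, , ax] <- coords[, , ax] + outer(a, fld[, ax])
    }
    list(coords = coords, base = base, U = U)
  })
}

test_that("concatenation preserves counts, labels and insertion order", {
  topo <- toy_topology(1:10)
  withr::local_seed(2)
  t1 <- trajectory(array(rnorm(100 * 10 * 3), dim = c(100, 10, 3)), state = "A")
  t2 <- trajectory(array(rnorm(100 * 10 * 3), dim = c(100, 10, 3)), state = "B")
  al <- concat_align(list(A = t1, B = t2), topo)
  expect_equal(nrow(al$xyz), 200)
  expect_equal(al$labels, rep(c("A", "B"), each = 100))
  expect_equal(ncol(al$xyz), 30)

  # pre-applying a rigid motion to one input changes nothing after alignment
  t2r <- transform_trajectory(t2, random_rotation(), c(12, -4, 3))
  al2 <- concat_align(list(A = t1, B = t2r), topo)
  expect_lt(max(abs(al2$xyz - al$xyz)), 1e-6)

  t3 <- trajectory(array(rnorm(5 * 4 * 3), dim = c(5, 4, 3)))
  expect_error(concat_align(list(t1, t3), topo), "topology mismatch")
})

test_that("a planted oscillation direction is recovered by the leading mode", {
  pe <- planted_ensemble(2000, 25, amps = 2.5, periods = 17, seed = 31)
  topo <- toy_topology(1:25)
  tr <- trajectory(pe$coords)
  al <- concat_align(list(all = tr), topo)
  m <- compute_modes(al, n_modes = 5)
  expect_gt(abs(sum(m$vectors[, 1] * pe$U[, 1])), 0.99)
})

test_that("mode sets satisfy orthonormality, ordering and trace conservation", {
  pe <- planted_ensemble(800, 20, amps = c(2, 1), periods = c(13, 29), seed = 8)
  m <- compute_modes(matrix(pe$coords, nrow = 800), n_modes = 10)
  expect_equal(crossprod(m$vectors), diag(10), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
  expect_true(all(m$eigenvalues >= 0))
  expect_equal(sum(m$eigenvalues), m$total_variance, tolerance = 1e-6 * m$total_variance)

  # projection reconstruction: residual variance = discarded eigenvalue sum
  X <- matrix(pe$coords, nrow = 800)
  Xc <- sweep(X, 2, colMeans(X))
  resid <- Xc - m$projections %*% t(m$vectors)
  discarded <- sum(m$eigenvalues[-(1:10)])
  expect_equal(sum(resid^2) / (800 - 1), discarded,
               tolerance = 1e-6 * max(discarded, 1e-12))
})

test_that("isotropic data shows no spurious dominant mode", {
  withr::local_seed(14)
  X <- matrix(rnorm(10000 * 90), nrow = 10000)
  m <- compute_modes(X)
  expect_lt(m$eigenvalues[1] / mean(m$eigenvalues), 1.5)
})

test_that("RMS projection of a pure sinusoid is amplitude / sqrt(2)", {
  A <- 3
  pe <- planted_ensemble(4000, 15, amps = A, periods = 23, noise = 0.01,
                         seed = 77)
  m <- compute_modes(matrix(pe$coords, nrow = 4000), n_modes = 1)
  stats <- state_amplitude_stats(m)
  se <- (A / sqrt(2)) / sqrt(2 * 4000 / 23)   # ~2 independent draws per period
  expect_lt(abs(stats$by_state$rms[1] - A / sqrt(2)), 3 * se)
})

test_that("compute_modes rejects degenerate inputs", {
  expect_error(compute_modes(matrix(1:3, nrow = 1)), "at least 2")
  expect_error(compute_modes(matrix(rnorm(30), nrow = 10), n_modes = 10),
               "exceeds")
})

test_that("state-differential amplitude puts the planted mode on top", {
  # two states sharing a quiet background; mode 1 active (3 A) in state A only
  withr::local_seed(21)
  n <- 1500; na <- 20
  base <- rand_frame(na)
  U <- remove_rigid_fields(matrix(rnorm(3 * na * 2), ncol = 2), base)
  make_state <- function(amp1) {
    coords <- array(rep(base, each = n), dim = c(n, na, 3)) +
      array(rnorm(n * na * 3, sd = 0.05), dim = c(n, na, 3))
    t <- seq_len(n)
    a1 <- amp1 * sin(2 * pi * t / 19 + runif(1, 0, 2 * pi))
    a2 <- 1.5 * sin(2 * pi * t / 31 + runif(1, 0, 2 * pi))
    for (ax in 1:3) {
      fld1 <- matrix(U[, 1], ncol = 3, byrow = TRUE)
      fld2 <- matrix(U[, 2], ncol = 3, byrow = TRUE)
      coords[, , ax] <- coords[, , ax] + outer(a1, fld1[, ax]) +
        outer(a2, fld2[, ax])
    }
    trajectory(coords)
  }
  topo <- toy_topology(1:na)
  al <- concat_align(list(A = make_state(3), B = make_state(0)), topo)
  m <- compute_modes(al, n_modes = 6)
  stats <- state_amplitude_stats(m)
  top <- stats$by_mode$mode[stats$by_mode$rank == 1]
  # the top-ranked mode is the one carrying the planted differential motion
  overlaps <- abs(crossprod(m$vectors, U[, 1]))
  expect_equal(top, which.max(overlaps))
  perm <- mode_permutation_test(m, n_perm = 200, seed = 9)
  expect_lte(perm$p_value[perm$mode == top], 0.005)
})

test_that("statistically identical states stay below the permutation null", {
  withr::local_seed(33)
  n <- 400; na <- 12
  base <- rand_frame(na)
  mk <- function() trajectory(array(rep(base, each = n), dim = c(n, na, 3)) +
                                array(rnorm(n * na * 3, sd = 0.3),
                                      dim = c(n, na, 3)))
  al <- concat_align(list(A = mk(), B = mk(), C = mk()), toy_topology(1:na))
  m <- compute_modes(al, n_modes = 8)
  stats <- state_amplitude_stats(m)
  perm <- mode_permutation_test(m, n_perm = 200, seed = 4)
  expect_true(all(stats$by_mode$score <= perm$null_q99[1]))
})

test_that("state_amplitude_stats needs two frames per state", {
  m <- compute_modes(matrix(rnorm(40 * 6), nrow = 40), n_modes = 2)
  m$labels <- c("solo", rep("rest", 39))
  expect_error(state_amplitude_stats(m), "fewer than 2")
})

test_that("mode animation honours its endpoint and linearity contracts", {
  cfg <- tiny_config(n_frames = 120, seed = 61)
  b <- build_topology(cfg)
  tr <- simulate_state(default_state_profiles()$Y0_YP, cfg, b)
  al <- concat_align(list(x = tr), b$topology)
  m <- compute_modes(al, n_modes = 3)
  anim <- mode_animation(m, mode = 1, scale = 2)
  expect_equal(dim(anim$trajectory$coords)[1], 20)
  mean_mat <- matrix(m$mean, ncol = 3, byrow = TRUE)
  v_mat <- matrix(m$vectors[, 1], ncol = 3, byrow = TRUE)
  expect_equal(frame_coords(anim$trajectory, 1), mean_mat - 2 * v_mat,
               tolerance = 1e-12)
  expect_equal(frame_coords(anim$trajectory, 20), mean_mat + 2 * v_mat,
               tolerance = 1e-12)

  tiny <- mode_animation(m, mode = 1, scale = 0.001)
  disp <- apply(abs(tiny$trajectory$coords[20, , ] - mean_mat), 1, max)
  expect_equal(max(disp), 0.001 * max(abs(v_mat)), tolerance = 1e-8)

  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(anim$trajectory, anim$topology, f)
  expect_equal(dim(read_trajectory(f, anim$topology)$coords)[1], 20)

  expect_error(mode_animation(m, mode = 1, scale = 0), "> 0")
  expect_error(mode_animation(m, mode = 99, scale = 1), "mode id")
})

test_that("mode sets persist as a text CSV family", {
  pe <- planted_ensemble(100, 8, amps = 1, periods = 11, seed = 3)
  al <- concat_align(list(s = trajectory(pe$coords)), toy_topology(1:8))
  m <- compute_modes(al, n_modes = 2)
  dir <- withr::local_tempdir()
  write_modeset(m, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "modes_mean.pdb", "modes_vectors.csv", "modes_eigenvalues.csv",
    "modes_projections.csv")))))
  vec <- readr::read_csv(file.path(dir, "modes_vectors.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(vec), 24)
})
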