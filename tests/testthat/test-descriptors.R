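test_that("superposition is exact for identity and rigid motions", {
  withr::local_seed(1)
  X <- rand_frame(12)
  expect_lt(superpose(X, X)$rmsd, 1e-10)

  # 90 degree rotation about z plus a translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- sweep(X %*% t(Rz), 2, c(5, 5, 5), `+`)
  fit <- superpose(Y, X)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$fitted - X)), 1e-8)
})

test_that("superposition matches a brute-force quaternion search", {
  withr::local_seed(42)
  for (case in 1:6) {
    X <- rand_frame(4, scale = 5)
    Y <- rand_frame(4, scale = 5)
    expect_equal(superpose(X, Y)$rmsd, rmsd_quaternion_oracle(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("proper rotations are enforced on mirror-image inputs", {
  withr::local_seed(7)
  X <- rand_frame(8)
  Y <- X %*% diag(c(-1, 1, 1))   # reflection
  fit <- superpose(Y, X)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0.1)       # a reflection must NOT be recovered exactly
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("RMSD series handles static, planted and rotated trajectories", {
  withr::local_seed(3)
  base <- rand_frame(20)
  n <- 8
  coords <- array(rep(base, each = n), dim = c(n, 20, 3))
  topo <- toy_topology(1:20)
  all_sel <- select_atoms(topo, "all")
  tr <- trajectory(coords)
  expect_equal(rmsd_series(tr, all_sel)$value, rep(0, n), tolerance = 1e-10)

  # one atom displaced by 3 A in alternate frames; fit on the others
  coords2 <- coords
  for (i in seq(2, n, by = 2)) coords2[i, 20, 1] <- coords2[i, 20, 1] + 3
  tr2 <- trajectory(coords2)
  fit_sel <- selection_from_indices(0:18, 20)
  calc_sel <- selection_from_indices(19, 20)
  vals <- rmsd_series(tr2, fit_sel, calc_sel = calc_sel)$value
  expect_equal(vals, rep(c(0, 3), n / 2), tolerance = 1e-7)

  # per-frame global rigid motions leave the series untouched
  tr3 <- tr2
  for (i in seq_len(n)) {
    R <- random_rotation()
    tr3$coords[i, , ] <- sweep(matrix(tr2$coords[i, , ], ncol = 3) %*% t(R),
                               2, runif(3, -20, 20), `+`)
  }
  expect_equal(rmsd_series(tr3, fit_sel, calc_sel = calc_sel)$value, vals,
               tolerance = 1e-7)
})

test_that("B-factors vanish for static input and match a brute-force oracle", {
  withr::local_seed(5)
  topo <- toy_topology(1:15)
  base <- rand_frame(15)
  static <- trajectory(array(rep(base, each = 10), dim = c(10, 15, 3)))
  ca <- select_atoms(topo, "name CA")
  bf0 <- bfactor_profile(static, topo, ca, n_segments = 2)
  expect_equal(bf0$bfactor, rep(0, 15), tolerance = 1e-12)
  expect_equal(bf0$segment_variance, rep(0, 15), tolerance = 1e-12)

  # 50 random frames: compare against direct per-atom variance computation
  # on independently re-aligned coordinates
  coords <- array(rnorm(50 * 15 * 3, sd = 1), dim = c(50, 15, 3)) +
    array(rep(base, each = 50), dim = c(50, 15, 3))
  tr <- trajectory(coords)
  bf <- bfactor_profile(tr, topo, ca)
  expect_equal(bf$bfactor, (8 * pi^2 / 3) * bf$rmsf^2, tolerance = 1e-12)

  aligned <- coords
  m <- apply(coords, c(2, 3), mean)
  for (pass in 1:2) {
    for (i in 1:50) {
      aligned[i, , ] <- superpose(matrix(aligned[i, , ], ncol = 3), m)$fitted
    }
    m <- apply(aligned, c(2, 3), mean)
  }
  msf <- sapply(1:15, function(a) {
    dev <- sweep(aligned[, a, ], 2, colMeans(aligned[, a, ]))
    mean(rowSums(dev^2))
  })
  expect_equal(bf$bfactor, (8 * pi^2 / 3) * msf, tolerance = 1e-8)
})

test_that("B-factor segmentation follows the remainder-to-last-segment rule", {
  withr::local_seed(6)
  topo <- toy_topology(1:5)
  tr <- trajectory(array(rnorm(23 * 5 * 3), dim = c(23, 5, 3)))
  ca <- select_atoms(topo, "name CA")
  bf <- bfactor_profile(tr, topo, ca, n_segments = 10)
  seg <- attr(bf, "segments")
  expect_equal(sort(unique(seg$segment)), 1:10)
  expect_error(bfactor_profile(tr, topo, ca, n_segments = 1), ">= 2")
  expect_error(bfactor_profile(tr, topo, ca, n_segments = 30), "fewer than")
})

test_that("distance series are exact on constructed geometries", {
  topo <- toy_topology(1:3)
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  coords[1, 3, ] <- c(2, 0, 0)
  tr <- trajectory(coords)
  s1 <- selection_from_indices(0, 3)
  s2 <- selection_from_indices(1, 3)
  expect_equal(distance_series(tr, topo, s1, s2, mode = "atom")$value, 5)

  # COM of two unit-mass-style atoms at (0,0,0),(2,0,0) vs atom at (1,4,0)
  coords2 <- array(0, dim = c(1, 3, 3))
  coords2[1, 2, ] <- c(2, 0, 0)
  coords2[1, 3, ] <- c(1, 4, 0)
  tr2 <- trajectory(coords2)
  pair <- selection_from_indices(0:1, 3)
  one <- selection_from_indices(2, 3)
  expect_equal(distance_series(tr2, topo, pair, one, mode = "com")$value, 4)

  expect_error(distance_series(tr, topo, pair, one, mode = "atom"), "singleton")
})

test_that("minimum-distance mode matches a brute-force all-pairs scan", {
  withr::local_seed(8)
  topo <- toy_topology(1:20)
  coords <- array(runif(5 * 20 * 3, -8, 8), dim = c(5, 20, 3))
  tr <- trajectory(coords)
  a <- selection_from_indices(0:9, 20)
  b <- selection_from_indices(10:19, 20)
  got <- distance_series(tr, topo, a, b, mode = "min")$value
  brute <- sapply(1:5, function(f) {
    min(as.matrix(dist(matrix(coords[f, , ], ncol = 3)))[1:10, 11:20])
  })
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("contact occupancy applies a strict cutoff", {
  topo <- toy_topology(1:2)
  n <- 10
  coords <- array(0, dim = c(n, 2, 3))
  coords[, 2, 1] <- rep(c(3, 9), n / 2)
  tr <- trajectory(coords)
  a <- selection_from_indices(0, 2)
  b <- selection_from_indices(1, 2)
  expect_equal(contact_occupancy(tr, topo, a, b, cutoff = 4)$occupancy, 0.5)
  # strictly-below rule: distance exactly at the cutoff does not count
  coords[, 2, 1] <- 4
  expect_equal(contact_occupancy(trajectory(coords), topo, a, b, cutoff = 4)$occupancy, 0)
  coords[, 2, 1] <- 2.5
  expect_equal(contact_occupancy(trajectory(coords), topo, a, b, cutoff = 4)$occupancy, 1)
  expect_error(contact_occupancy(tr, topo, a, b, cutoff = -1), "> 0")
})

test_that("the canonical panel is complete and consistent", {
  cfg <- tiny_config(n_frames = 300, seed = 21)
  b <- build_topology(cfg)
  tr <- simulate_state(default_state_profiles()$STA, cfg, b)
  panel <- descriptor_panel(tr, b$topology, b$roles)
  nms <- c("dfg_cyclization", "alphaC_clobe", "sb_K369_E386", "f480_m390",
           "sb_D379_R496", "hb_N348_S497", "hb_R514_Y493", "gate_W505")
  expect_setequal(unique(panel$name), nms)
  counts <- table(panel$name)
  expect_true(all(counts == 300))
  phi <- exp(-cfg$dt / cfg$ou_tau)
  dfg_mean <- mean(panel$value[panel$name == "dfg_cyclization"])
  expect_lt(abs(dfg_mean - 3.0), 3 * se_mean_ar1(0.3, 300, phi))

  broken <- b$roles
  broken$HB_S <- NULL
  expect_error(descriptor_panel(tr, b$topology, broken), "HB_S")
})

test_that("gate descriptor falls back to the configured anchor without ligand", {
  cfg <- tiny_config(n_frames = 30, seed = 2)
  b <- build_topology(cfg)
  keep <- which(b$topology$residue_name != "ATP")
  topo2 <- topology(b$topology[keep, ])
  tr <- simulate_state(default_state_profiles()$STA, cfg, b)
  tr2 <- trajectory(tr$coords[, keep, , drop = FALSE], times = tr$times,
                    state = tr$state)
  roles2 <- b$roles
  roles2$ATP_ANCHOR <- list(resid = 440L, atom = "CA")
  panel <- descriptor_panel(tr2, topo2, roles2)
  expect_true(series_metadata(panel)$gate_W505$anchor_used)
  roles2$ATP_ANCHOR <- NULL
  expect_error(descriptor_panel(tr2, topo2, roles2), "ATP_ANCHOR")
})

test_that("descriptors are invariant under a global rigid motion", {
  cfg <- tiny_config(n_frames = 100, seed = 13)
  b <- build_topology(cfg)
  tr <- simulate_state(default_state_profiles()$Y0Y0, cfg, b)
  withr::local_seed(99)
  moved <- transform_trajectory(tr, random_rotation(), runif(3, -30, 30))
  p1 <- descriptor_panel(tr, b$topology, b$roles)
  p2 <- descriptor_panel(moved, b$topology, b$roles)
  expect_equal(p2$value, p1$value, tolerance = 1e-9)

  ca <- select_atoms(b$topology, "name CA")
  b1 <- bfactor_profile(tr, b$topology, ca, n_segments = 5)
  b2 <- bfactor_profile(moved, b$topology, ca, n_segments = 5)
  expect_equal(b2$bfactor, b1$bfactor, tolerance = 1e-6)
})

test_that("segment B-factor variance shrinks for longer stationary segments", {
  # stationary jitter: across-segment variance decreases in expectation as
  # segments lengthen; compare 4 vs 20 segments over three generator seeds
  worse <- 0
  for (seed in 1:3) {
    cfg <- generator_config(n_frames = 2000, seed = 400 + seed)
    b <- build_topology(cfg)
    tr <- simulate_state(state_profile("flat", saltbridge_occupancy = 0.5),
                         cfg, b)
    ca <- select_atoms(b$topology, "name CA")
    v_long <- mean(bfactor_profile(tr, b$topology, ca, n_segments = 4)$segment_variance)
    v_short <- mean(bfactor_profile(tr, b$topology, ca, n_segments = 20)$segment_variance)
    if (v_long > v_short) worse <- worse + 1
  }
  expect_lte(worse, 1)
})
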