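#' Concatenate and align multi-state trajectories
#'
#' All frames from all trajectories are superposed (Kabsch fit over
#' `fit_sel`) onto the global mean structure, iterated twice; per-frame
#' state labels are preserved in the input (insertion) order. The returned
#' coordinates are those of the fit selection, the set over which collective
#' modes are computed (C-alpha atoms by convention).
#'
#' @param trajs named list of [trajectory()] objects sharing one topology;
#'   names are used as state labels (falling back to each trajectory's own
#'   label).
#' @param topology the shared [topology()].
#' @param fit_sel selection used for fitting and retained for analysis
#'   (default `"name CA"`).
#' @return a `kd_aligned`: list with `xyz` (frames x 3N matrix), `labels`,
#'   `times`, `mean` (mean structure, N x 3), `selection`, and the
#'   sub-`topology` of the selection.
#' @export
concat_align <- function(trajs, topology, fit_sel = NULL) {
  if (length(trajs) == 0) abort("no trajectories supplied")
  na <- nrow(topology)
  for (tr in trajs) {
    if (dim(tr$coords)[2] != na) {
      abort(sprintf("topology mismatch: trajectory has %d atoms, topology has %d",
                    dim(tr$coords)[2], na))
    }
  }
  if (is.null(fit_sel)) fit_sel <- select_atoms(topology, "name CA")
  rows <- sel_rows(fit_sel)
  labels <- character(0)
  times <- numeric(0)
  nm <- names(trajs) %||% vapply(trajs, function(t) t$state, character(1))
  total <- sum(vapply(trajs, n_frames, integer(1)))
  coords <- array(NA_real_, dim = c(total, length(rows), 3))
  at <- 0L
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    nf <- n_frames(tr)
    coords[at + seq_len(nf), , ] <- tr$coords[, rows, , drop = FALSE]
    lab <- if (!is.null(names(trajs)) && nzchar(nm[k])) nm[k] else tr$state
    labels <- c(labels, rep(lab, nf))
    times <- c(times, tr$times)
    at <- at + nf
  }
  al <- align_to_mean(coords, seq_len(length(rows)), n_pass = 2, init = "first")
  nfr <- dim(al$coords)[1]
  xyz <- matrix(NA_real_, nrow = nfr, ncol = 3 * length(rows))
  xyz[, seq(1, ncol(xyz), 3)] <- al$coords[, , 1]
  xyz[, seq(2, ncol(xyz), 3)] <- al$coords[, , 2]
  xyz[, seq(3, ncol(xyz), 3)] <- al$coords[, , 3]
  structure(list(xyz = xyz, labels = labels, times = times, mean = al$mean,
                 selection = fit_sel,
                 topology = subset_topology(topology, fit_sel)),
            class = "kd_aligned")
}

#' Quasi-harmonic collective modes of aligned coordinates
#'
#' Eigendecomposition of the covariance matrix of the centred, aligned
#' coordinates ("essential dynamics"): eigenvectors are orthonormal 3N-dim
#' collective mode vectors sorted by decreasing eigenvalue (variance,
#' Angstrom^2); projections are the centred coordinates on each retained
#' mode. Rigid-body motion is removed by the prior alignment, not by
#' discarding eigenmodes, so near-zero modes are reported rather than
#' dropped. No mass weighting by default.
#'
#' @param aligned a [concat_align()] result (or any frames x 3N matrix;
#'   labels then default to one state).
#' @param n_modes number of modes to retain (default: all).
#' @return a `kd_modeset`: mean structure, `vectors` (3N x k), `eigenvalues`
#'   (all eigenvalues, length 3N), `projections` (frames x k), `labels`,
#'   `total_variance` (trace of the covariance) and the selection topology.
#' @export
compute_modes <- function(aligned, n_modes = NULL) {
  if (is.matrix(aligned)) {
    aligned <- list(xyz = aligned, labels = rep("all", nrow(aligned)),
                    times = seq_len(nrow(aligned)), mean = NULL,
                    selection = NULL, topology = NULL)
  }
  X <- aligned$xyz
  nf <- nrow(X)
  if (nf < 2) abort("compute_modes needs at least 2 frames")
  p <- ncol(X)
  max_modes <- min(nf - 1L, p)
  if (is.null(n_modes)) n_modes <- max_modes
  if (n_modes > max_modes) {
    abort(sprintf("n_modes = %d exceeds min(frames - 1, 3N) = %d",
                  n_modes, max_modes))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nf - 1)
  eig <- eigen(C, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  vectors <- eig$vectors[, seq_len(n_modes), drop = FALSE]
  projections <- Xc %*% vectors
  structure(list(
    mean = mu, mean_structure = aligned$mean,
    vectors = vectors, eigenvalues = evals, n_modes = n_modes,
    projections = projections, labels = aligned$labels,
    times = aligned$times, total_variance = sum(diag(C)),
    topology = aligned$topology, selection = aligned$selection
  ), class = "kd_modeset")
}

#' @export
print.kd_modeset <- function(x, ...) {
  cat(sprintf("<kd_modeset> %d modes over %d frames (%d dof); top eigenvalues: %s A^2\n",
              x$n_modes, nrow(x$projections), length(x$mean),
              paste(sprintf("%.2f", head(x$eigenvalues, 4)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.kd_modeset <- function(x, ...) {
  k <- x$n_modes
  tibble(
    frame = rep(seq_len(nrow(x$projections)), k),
    state = rep(x$labels, k),
    mode = rep(seq_len(k), each = nrow(x$projections)),
    projection = as.vector(x$projections)
  )
}

#' @export
glance.kd_modeset <- function(x, ...) {
  tibble(n_modes = x$n_modes, n_frames = nrow(x$projections),
         total_variance = x$total_variance,
         var_explained = sum(x$eigenvalues[seq_len(x$n_modes)]) / x$total_variance,
         leading_eigenvalue = x$eigenvalues[1])
}

# one-way ANOVA-style F statistic on a response grouped by state
anova_f <- function(y, groups) {
  gm <- tapply(y, groups, mean)
  gn <- tapply(y, groups, length)
  mu <- mean(y)
  k <- length(gm)
  between <- sum(gn * (gm - mu)^2) / (k - 1)
  within <- sum((y - gm[groups])^2) / (length(y) - k)
  if (within <= 0) return(Inf)
  between / within
}

#' Per-state projection statistics and discriminative-mode ranking
#'
#' For every (mode, state) pair reports the mean, variance and RMS
#' amplitude of the projections. Each mode also gets a discrimination
#' score: a one-way ANOVA F statistic over states computed on the squared
#' projections, which responds to state differences in either the mean
#' position along the mode or the oscillation amplitude; modes are ranked
#' by decreasing score.
#'
#' @param modes a [compute_modes()] result with state labels.
#' @return a `kd_modestats`: list with `by_state` (tibble mode, state, mean,
#'   variance, rms, n) and `by_mode` (tibble mode, score, rank).
#' @export
state_amplitude_stats <- function(modes) {
  labs <- factor(modes$labels, levels = unique(modes$labels))
  cnt <- table(labs)
  if (any(cnt < 2)) {
    abort(paste0("state(s) with fewer than 2 frames: ",
                 paste(names(cnt)[cnt < 2], collapse = ", ")))
  }
  k <- modes$n_modes
  by_state <- dplyr::bind_rows(lapply(seq_len(k), function(m) {
    p <- modes$projections[, m]
    tibble(mode = m, state = levels(labs),
           mean = as.numeric(tapply(p, labs, mean)),
           variance = as.numeric(tapply(p, labs, function(v) mean((v - mean(v))^2))),
           rms = as.numeric(tapply(p, labs, function(v) sqrt(mean(v^2)))),
           n = as.integer(cnt))
  }))
  scores <- vapply(seq_len(k), function(m) {
    anova_f(modes$projections[, m]^2, labs)
  }, numeric(1))
  by_mode <- tibble(mode = seq_len(k), score = scores,
                    rank = rank(-scores, ties.method = "first"))
  structure(list(by_state = by_state, by_mode = by_mode,
                 states = levels(labs)), class = "kd_modestats")
}

#' @export
print.kd_modestats <- function(x, ...) {
  top <- x$by_mode[order(x$by_mode$rank), ][1, ]
  cat(sprintf("<kd_modestats> %d modes x %d states; top discriminative mode %d (F = %.1f)\n",
              nrow(x$by_mode), length(x$states), top$mode, top$score))
  invisible(x)
}

#' @export
tidy.kd_modestats <- function(x, ...) x$by_state

#' @export
glance.kd_modestats <- function(x, ...) {
  top <- x$by_mode[order(x$by_mode$rank), ][1, ]
  tibble(n_modes = nrow(x$by_mode), n_states = length(x$states),
         top_mode = top$mode, top_score = top$score)
}

#' Label-permutation null for the mode discrimination score
#'
#' State labels are permuted across frames `n_perm` times; each mode's
#' p-value is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param modes a [compute_modes()] result.
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return tibble with mode, score, p_value, and the 99th percentile of the
#'   per-permutation maximum score (`null_q99` column, same for all rows).
#' @export
mode_permutation_test <- function(modes, n_perm = 200, seed = 1) {
  labs <- factor(modes$labels, levels = unique(modes$labels))
  k <- modes$n_modes
  p2 <- modes$projections^2
  obs <- vapply(seq_len(k), function(m) anova_f(p2[, m], labs), numeric(1))
  null <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      pl <- sample(labs)
      vapply(seq_len(k), function(m) anova_f(p2[, m], pl), numeric(1))
    }, numeric(k)))
  })
  pvals <- vapply(seq_len(k), function(m) {
    (1 + sum(null[, m] >= obs[m])) / (1 + n_perm)
  }, numeric(1))
  tibble(mode = seq_len(k), score = obs, p_value = pvals,
         null_q99 = as.numeric(stats::quantile(null, 0.99)))
}

#' Animate a collective mode as a multi-frame trajectory
#'
#' Interpolates the mean structure from `-scale` to `+scale` along one mode
#' vector over `n_frames` frames; the result can be written as a multi-model
#' PDB for visualization.
#'
#' @param modes a [compute_modes()] result carrying a mean structure.
#' @param mode mode index.
#' @param scale displacement amplitude in Angstrom (> 0).
#' @param n_frames number of interpolation frames (default 20).
#' @return list with `trajectory` (a [trajectory()] over the mode's atom
#'   selection) and `topology` (the matching sub-topology).
#' @export
mode_animation <- function(modes, mode, scale, n_frames = 20) {
  if (scale <= 0) abort("scale must be > 0")
  if (mode < 1 || mode > modes$n_modes) abort("mode id outside the mode set")
  v <- modes$vectors[, mode]
  mu <- modes$mean
  s <- seq(-scale, scale, length.out = n_frames)
  na <- length(mu) / 3
  coords <- array(NA_real_, dim = c(n_frames, na, 3))
  for (i in seq_len(n_frames)) {
    fr <- mu + s[i] * v
    coords[i, , ] <- matrix(fr, ncol = 3, byrow = TRUE)
  }
  list(trajectory = trajectory(coords, times = seq_len(n_frames) * 0.1,
                               state = sprintf("mode%d", mode)),
       topology = modes$topology)
}

#' Persist a mode set as text files
#'
#' Writes the mean structure as PDB, mode vectors and eigenvalues as a CSV
#' pair, and projections as a long CSV (frame, state, mode, value).
#'
#' @param modes a [compute_modes()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_modeset <- function(modes, dir, prefix = "modes") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(modes$topology) && !is.null(modes$mean)) {
    mu <- matrix(modes$mean, ncol = 3, byrow = TRUE)
    write_trajectory(trajectory(mu), modes$topology,
                     file.path(dir, paste0(prefix, "_mean.pdb")), format = "pdb")
  }
  vec <- as_tibble(modes$vectors, .name_repair = ~paste0("mode", seq_len(modes$n_modes)))
  vec <- dplyr::bind_cols(tibble(dof = seq_len(nrow(modes$vectors))), vec)
  readr::write_csv(vec, file.path(dir, paste0(prefix, "_vectors.csv")))
  readr::write_csv(tibble(mode = seq_along(modes$eigenvalues),
                          eigenvalue_A2 = modes$eigenvalues),
                   file.path(dir, paste0(prefix, "_eigenvalues.csv")))
  readr::write_csv(tidy(modes), file.path(dir, paste0(prefix, "_projections.csv")))
  invisible(dir)
}
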