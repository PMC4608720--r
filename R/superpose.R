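#' Least-squares rigid-body superposition (Kabsch)
#'
#' Fits `mobile` onto `reference` by the rotation and translation minimizing
#' the RMSD over the selected atoms. A proper rotation (determinant +1) is
#' enforced, so mirror images are never produced.
#'
#' @param mobile,reference `atoms x 3` coordinate matrices sharing an atom
#'   order.
#' @param selection `kd_selection` of atoms used for the fit (default: all).
#' @return list with `rotation` (3x3), `mobile_centroid`, `reference_centroid`,
#'   `rmsd` (Angstrom, over the fit selection), and `fitted` (the whole mobile
#'   frame after transformation).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (!is.matrix(mobile)) mobile <- matrix(mobile, ncol = 3)
  if (!is.matrix(reference)) reference <- matrix(reference, ncol = 3)
  rows <- if (is.null(selection)) seq_len(nrow(mobile)) else sel_rows(selection)
  if (length(rows) < 3) abort("superposition needs at least 3 selected atoms")
  X <- mobile[rows, , drop = FALSE]
  Y <- reference[rows, , drop = FALSE]
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Yc)^2)))
  fitted <- sweep(sweep(mobile, 2, cx) %*% R, 2, cy, `+`)
  list(rotation = R, mobile_centroid = cx, reference_centroid = cy,
       rmsd = rmsd, fitted = fitted)
}

rmsd_between <- function(a, b, rows) {
  sqrt(mean(rowSums((a[rows, , drop = FALSE] - b[rows, , drop = FALSE])^2)))
}

#' Per-frame RMSD series
#'
#' Each frame is superposed on the reference using `fit_sel`, then the RMSD
#' is evaluated over `calc_sel` (default: the fit selection).
#'
#' @param traj a [trajectory()].
#' @param reference reference frame (`atoms x 3`); default is frame 1.
#' @param fit_sel selection used for the superposition.
#' @param calc_sel selection over which the RMSD is reported.
#' @return a `kd_series` named `"rmsd"`.
#' @export
rmsd_series <- function(traj, fit_sel, reference = NULL, calc_sel = fit_sel) {
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  calc_rows <- sel_rows(calc_sel)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fit <- superpose(frame_coords(traj, i), reference, fit_sel)
    rmsd_between(fit$fitted, reference, calc_rows)
  }, numeric(1))
  new_series("rmsd", traj$times, vals,
             metadata = list(fit = fit_sel$expression, calc = calc_sel$expression,
                             reference = "supplied-or-first-frame",
                             state = traj$state))
}

# Align every frame of a coordinate array (frames x atoms x 3) onto the mean
# structure, iterated n_pass times; fit computed on `rows`. `init` chooses
# the bootstrap reference: the raw mean, or the first frame (which makes the
# result exactly invariant to rigid motions pre-applied to any subset of
# frames). Returns the aligned array and the final mean frame.
align_to_mean <- function(coords, rows, n_pass = 2, init = c("mean", "first")) {
  init <- match.arg(init)
  nf <- dim(coords)[1]
  sel <- selection_from_indices(rows - 1L, dim(coords)[2])
  aligned <- coords
  m <- if (init == "first") matrix(coords[1, , ], ncol = 3) else
    apply(coords, c(2, 3), mean)
  if (init == "first") {
    for (i in seq_len(nf)) {
      aligned[i, , ] <- superpose(matrix(aligned[i, , ], ncol = 3), m, sel)$fitted
    }
    m <- apply(aligned, c(2, 3), mean)
  }
  for (pass in seq_len(n_pass)) {
    for (i in seq_len(nf)) {
      aligned[i, , ] <- superpose(matrix(aligned[i, , ], ncol = 3), m, sel)$fitted
    }
    m <- apply(aligned, c(2, 3), mean)
  }
  list(coords = aligned, mean = m)
}
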