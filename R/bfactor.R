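#' Per-residue B-factor profile with segment convergence diagnostics
#'
#' All frames are aligned to the average structure (iterated mean-structure
#' alignment, two passes, fit over `fit_sel`), then for each residue's
#' C-alpha atom B = (8 pi^2 / 3) * <|r - <r>|^2>. The trajectory is also
#' split into `n_segments` sequential parts of equal length (remainder
#' frames go to the last segment); per-segment B-factors use the segment's
#' own mean position, and their across-segment variance is a convergence
#' diagnostic: it shrinks when local flexibility and the average structure
#' are stationary.
#'
#' @param traj a [trajectory()].
#' @param topology the matching [topology()].
#' @param fit_sel selection used for the alignment (typically C-alpha atoms).
#' @param n_segments number of sequential segments (>= 2; default 10).
#' @param calc_sel selection of atoms reported per residue (default
#'   `"name CA"`).
#' @param reference `"mean"` (iterated mean structure, default) or
#'   `"first"` (frame 1).
#' @return a `kd_bfactor` tibble with columns `residue_id`, `rmsf`,
#'   `bfactor` and `segment_variance`; the long per-segment table is in
#'   `attr(x, "segments")`.
#' @export
bfactor_profile <- function(traj, topology, fit_sel,
                            n_segments = 10, calc_sel = NULL,
                            reference = c("mean", "first")) {
  reference <- match.arg(reference)
  if (n_segments < 2) abort("n_segments must be >= 2")
  nf <- n_frames(traj)
  if (nf < n_segments) {
    abort(sprintf("trajectory has %d frames, fewer than n_segments = %d",
                  nf, n_segments))
  }
  check_traj_topology(traj, topology)
  if (is.null(calc_sel)) calc_sel <- select_atoms(topology, "name CA")
  rows_fit <- sel_rows(fit_sel)
  if (reference == "mean") {
    al <- align_to_mean(traj$coords, rows_fit, n_pass = 2)
    coords <- al$coords
  } else {
    ref <- frame_coords(traj, 1L)
    coords <- traj$coords
    for (i in seq_len(nf)) {
      coords[i, , ] <- superpose(matrix(traj$coords[i, , ], ncol = 3), ref,
                                 fit_sel)$fitted
    }
  }
  rows_calc <- sel_rows(calc_sel)
  msf_of <- function(frame_idx) {
    sub <- coords[frame_idx, rows_calc, , drop = FALSE]
    m <- apply(sub, c(2, 3), mean)
    dev <- sweep(sub, c(2, 3), m)
    apply(dev^2, 2, sum) / length(frame_idx)
  }
  msf <- msf_of(seq_len(nf))
  seg_id <- pmin(floor((seq_len(nf) - 1) / floor(nf / n_segments)) + 1, n_segments)
  seg_b <- sapply(seq_len(n_segments), function(s) {
    (8 * pi^2 / 3) * msf_of(which(seg_id == s))
  })
  res_ids <- topology$residue_id[rows_calc]
  segments <- tidyr::pivot_longer(
    tibble(residue_id = res_ids, as_tibble(seg_b, .name_repair = ~paste0("seg", seq_len(n_segments)))),
    -"residue_id", names_to = "segment", values_to = "bfactor")
  segments$segment <- as.integer(sub("seg", "", segments$segment))
  out <- tibble(
    residue_id = res_ids,
    rmsf = sqrt(msf),
    bfactor = (8 * pi^2 / 3) * msf,
    segment_variance = apply(seg_b, 1, function(v) mean((v - mean(v))^2))
  )
  attr(out, "segments") <- segments
  attr(out, "kd_metadata") <- list(fit = fit_sel$expression,
                                   calc = calc_sel$expression,
                                   n_segments = n_segments,
                                   reference = reference,
                                   state = traj$state)
  class(out) <- c("kd_bfactor", class(out))
  out
}

#' @export
print.kd_bfactor <- function(x, ...) {
  meta <- attr(x, "kd_metadata")
  cat(sprintf("<kd_bfactor> %d residues, %d segments, mean B = %.2f A^2\n",
              nrow(x), meta$n_segments, mean(x$bfactor)))
  NextMethod()
}
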