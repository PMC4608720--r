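# ggplot2 views of the result objects

#' @export
autoplot.kd_panel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue4") +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = "distance (Å)",
                  title = attr(object, "state")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kd_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue4") +
    ggplot2::labs(x = "time (ns)", y = object$name[1]) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kd_bfactor <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("residue_id", "bfactor", "segment_variance")],
    -"residue_id", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue_id, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick4") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "residue", y = "B (Å²) / var(B) (Å⁴)") +
    ggplot2::theme_minimal()
}

#' Overlay per-state B-factor profiles
#'
#' @param bfactors named list of [bfactor_profile()] results (names =
#'   states).
#' @return a ggplot.
#' @export
plot_bfactors <- function(bfactors) {
  long <- dplyr::bind_rows(lapply(names(bfactors), function(s) {
    tibble(state = s, residue_id = bfactors[[s]]$residue_id,
           bfactor = bfactors[[s]]$bfactor)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue_id, y = .data$bfactor,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "B-factor (Å²)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kd_modestats <- function(object, ...) {
  ggplot2::ggplot(object$by_state,
                  ggplot2::aes(x = factor(.data$mode), y = .data$rms,
                               fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mode", y = "RMS projection amplitude (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kd_modeset <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$projection,
                                   colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = "concatenated frame", y = "projection (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kd_pockettrack <- function(object, ...) {
  meta <- attr(object, "kd_metadata")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$volume_A3)) +
    ggplot2::geom_line(colour = "darkorange3") +
    ggplot2::geom_hline(yintercept = meta$open_threshold, linetype = 2) +
    ggplot2::labs(x = "time (ns)", y = "pocket volume (Å³)") +
    ggplot2::theme_minimal()
}

#' Overlay per-state pocket volume tracks
#'
#' @param pockets named list of [track_pocket()] results.
#' @return a ggplot.
#' @export
plot_pockets <- function(pockets) {
  long <- dplyr::bind_rows(lapply(names(pockets), function(s) {
    tibble(state = s, time_ns = pockets[[s]]$time_ns,
           volume_A3 = pockets[[s]]$volume_A3)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ns, y = .data$volume_A3,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "pocket volume (Å³)") +
    ggplot2::theme_minimal()
}
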