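#' Classification thresholds for the conformational fingerprint
#'
#' The DFG cyclization distance partitions into closed / semi-closed / open
#' states; the defaults 4.5 and 7.0 Angstrom are the midpoints between the
#' reference state centres of ~3, ~6 and ~8 Angstrom. The alphaC COM
#' distance partitions into buried / intermediate / displaced at 14.25 and
#' 15.25 Angstrom, midpoints between the reported 13.5, 14.5-15 and 15.5
#' Angstrom levels. The salt bridge is "formed" when the minimum heavy-atom
#' distance is below `sb_cutoff` (default 4.0 Angstrom between charged-group
#' heavy atoms).
#'
#' @param dfg_closed,dfg_open DFG boundaries (Angstrom).
#' @param alphaC_buried,alphaC_displaced alphaC boundaries (Angstrom).
#' @param sb_cutoff salt-bridge cutoff (Angstrom).
#' @return a list of thresholds.
#' @export
fingerprint_thresholds <- function(dfg_closed = 4.5, dfg_open = 7.0,
                                   alphaC_buried = 14.25, alphaC_displaced = 15.25,
                                   sb_cutoff = 4.0) {
  if (dfg_closed >= dfg_open) abort("dfg_closed boundary must be < dfg_open")
  if (alphaC_buried >= alphaC_displaced) {
    abort("alphaC_buried boundary must be < alphaC_displaced")
  }
  list(dfg_closed = dfg_closed, dfg_open = dfg_open,
       alphaC_buried = alphaC_buried, alphaC_displaced = alphaC_displaced,
       sb_cutoff = sb_cutoff)
}

dfg_levels <- c("closed", "semi_closed", "open")
alphac_levels <- c("buried", "intermediate", "displaced")

#' Classify DFG-motif conformations from the cyclization distance
#'
#' The partition of `[0, Inf)` is total and left-closed on the upper side:
#' closed for d < `dfg_closed`, semi-closed for `dfg_closed` <= d <
#' `dfg_open`, open for d >= `dfg_open`.
#'
#' @param distance numeric vector of distances (Angstrom, >= 0).
#' @param thresholds a [fingerprint_thresholds()] list.
#' @return factor with levels closed, semi_closed, open.
#' @export
classify_dfg <- function(distance, thresholds = fingerprint_thresholds()) {
  if (any(distance < 0)) abort("distances must be non-negative")
  factor(ifelse(distance < thresholds$dfg_closed, "closed",
         ifelse(distance < thresholds$dfg_open, "semi_closed", "open")),
         levels = dfg_levels)
}

#' Classify alphaC-helix position from the COM distance
#'
#' buried for d < `alphaC_buried`, intermediate for `alphaC_buried` <= d <
#' `alphaC_displaced`, displaced for d >= `alphaC_displaced` (boundaries
#' inclusive upward).
#'
#' @inheritParams classify_dfg
#' @return factor with levels buried, intermediate, displaced.
#' @export
classify_alphaC <- function(distance, thresholds = fingerprint_thresholds()) {
  if (any(distance < 0)) abort("distances must be non-negative")
  factor(ifelse(distance < thresholds$alphaC_buried, "buried",
         ifelse(distance < thresholds$alphaC_displaced, "intermediate",
                "displaced")),
         levels = alphac_levels)
}

#' Conformational fingerprint of a trajectory
#'
#' Combines the per-frame DFG state, alphaC state and salt-bridge status
#' from a descriptor panel into per-frame classifications and trajectory
#' level summaries. Occupancy fractions over the three DFG (and alphaC)
#' states always sum to one; the dominant state is the occupancy argmax,
#' with ties broken toward the more closed / more buried state.
#'
#' @param panel a [descriptor_panel()] containing the series
#'   `dfg_cyclization`, `alphaC_clobe` and `sb_K369_E386`.
#' @param thresholds a [fingerprint_thresholds()] list.
#' @return a `kd_fingerprint`: list with `frames` (per-frame tibble) and
#'   `summary` (named list, JSON-serializable).
#' @export
fingerprint_trajectory <- function(panel, thresholds = fingerprint_thresholds()) {
  dfg <- panel_series(panel, "dfg_cyclization")
  ac <- panel_series(panel, "alphaC_clobe")
  sb <- panel_series(panel, "sb_K369_E386")
  frames <- tibble(
    time_ns = dfg$time_ns,
    dfg_distance = dfg$value,
    dfg_state = classify_dfg(dfg$value, thresholds),
    alphaC_distance = ac$value,
    alphaC_state = classify_alphaC(ac$value, thresholds),
    saltbridge = sb$value < thresholds$sb_cutoff
  )
  occ <- function(f, levels) {
    p <- table(factor(f, levels = levels)) / length(f)
    setNames(as.numeric(p), levels)
  }
  dfg_occ <- occ(frames$dfg_state, dfg_levels)
  ac_occ <- occ(frames$alphaC_state, alphac_levels)
  # ties break toward the more closed / buried state: which.max takes the
  # first maximum and the levels are ordered closed -> open
  summary <- list(
    state = attr(panel, "state") %||% "custom",
    n_frames = nrow(frames),
    dfg_occupancy = as.list(dfg_occ),
    dominant_dfg = dfg_levels[which.max(dfg_occ)],
    alphaC_occupancy = as.list(ac_occ),
    dominant_alphaC = alphac_levels[which.max(ac_occ)],
    saltbridge_occupancy = mean(frames$saltbridge),
    mean_alphaC_distance = mean(frames$alphaC_distance),
    mean_dfg_distance = mean(frames$dfg_distance),
    thresholds = thresholds
  )
  structure(list(frames = frames, summary = summary), class = "kd_fingerprint")
}

#' @export
print.kd_fingerprint <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<kd_fingerprint> %s: DFG %s (occ %.2f), alphaC %s, salt bridge %.2f, %d frames\n",
    s$state, s$dominant_dfg, max(unlist(s$dfg_occupancy)), s$dominant_alphaC,
    s$saltbridge_occupancy, s$n_frames))
  invisible(x)
}

#' @export
tidy.kd_fingerprint <- function(x, ...) x$frames

#' @export
glance.kd_fingerprint <- function(x, ...) {
  s <- x$summary
  tibble(state = s$state, n_frames = s$n_frames,
         dominant_dfg = s$dominant_dfg,
         dfg_closed = s$dfg_occupancy$closed,
         dfg_semi_closed = s$dfg_occupancy$semi_closed,
         dfg_open = s$dfg_occupancy$open,
         dominant_alphaC = s$dominant_alphaC,
         saltbridge_occupancy = s$saltbridge_occupancy,
         mean_alphaC_distance = s$mean_alphaC_distance)
}

#' Write a fingerprint to JSON (summary) and CSV (per-frame states)
#'
#' @param fp a `kd_fingerprint`.
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @export
write_fingerprint <- function(fp, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(x = fp$summary, path = json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    out <- fp$frames
    out$dfg_state <- as.character(out$dfg_state)
    out$alphaC_state <- as.character(out$alphaC_state)
    readr::write_csv(out, csv_path)
  }
  invisible(fp)
}
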