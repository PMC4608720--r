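# Descriptor series are tidy tibbles: one row per frame with columns
# name / time_ns / value, plus a metadata attribute recording selections
# and conventions. Several series bound together form a panel.

new_series <- function(name, times, values, metadata = list()) {
  out <- tibble(name = name, time_ns = as.numeric(times),
                value = as.numeric(values))
  if (!all(is.finite(out$value))) abort(paste0("non-finite values in series ", name))
  attr(out, "kd_metadata") <- setNames(list(metadata), name)
  class(out) <- c("kd_series", class(out))
  out
}

#' Combine descriptor series into a panel
#'
#' @param ... `kd_series` tibbles (or a single list of them).
#' @param state optional state label attached to the panel.
#' @return a `kd_panel` tibble (long format) whose `kd_metadata` attribute
#'   holds each member's metadata.
#' @export
bind_series <- function(..., state = NULL) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "data.frame")) parts <- parts[[1]]
  meta <- list()
  for (p in parts) meta <- c(meta, attr(p, "kd_metadata"))
  out <- dplyr::bind_rows(lapply(parts, function(p) {
    class(p) <- setdiff(class(p), c("kd_series", "kd_panel"))
    p
  }))
  attr(out, "kd_metadata") <- meta
  attr(out, "state") <- state
  class(out) <- c("kd_panel", class(out))
  out
}

#' Metadata attached to a series or panel
#'
#' @param x a `kd_series` or `kd_panel`.
#' @return named list of per-series metadata.
#' @export
series_metadata <- function(x) attr(x, "kd_metadata")

panel_series <- function(panel, name) {
  if (!name %in% panel$name) {
    abort(paste0("panel is missing required series '", name, "'"))
  }
  panel[panel$name == name, , drop = FALSE]
}

#' Write a panel (or any series tibble) to CSV
#'
#' Columns `time_ns`, `value`, `name`; per-series metadata goes to a JSON
#' sidecar `<path>.meta.json`.
#'
#' @param panel a `kd_panel` or `kd_series`.
#' @param path output CSV path.
#' @export
write_series_csv <- function(panel, path) {
  readr::write_csv(tibble(time_ns = panel$time_ns, value = panel$value,
                          name = panel$name), path)
  meta <- series_metadata(panel)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
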