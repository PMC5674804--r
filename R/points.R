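#' Construct a tibble of MS points
#'
#' An MS point is one centroided observation in an LC-MS map: a mass-to-charge
#' value (m/z, Thomson), a retention time (seconds) and an intensity
#' (arbitrary units). Points are the currency of the whole stack: the mzML
#' reader produces them, the level-of-detail index stores them, and viewport
#' queries return them.
#'
#' @param mz Numeric vector of m/z values (Thomson), all > 0.
#' @param rt Numeric vector of retention times (seconds), all >= 0.
#' @param intensity Numeric vector of intensities, all >= 0.
#' @param id Optional integer ids, unique and >= 0. Defaults to `0:(n-1)` in
#'   input order, matching the encounter-order ids assigned when flattening
#'   spectra.
#' @return A tibble with columns `id`, `mz`, `rt`, `intensity`.
#' @examples
#' ms_points(mz = c(400.1, 500.2), rt = c(10, 10), intensity = c(150, 3))
#' @export
ms_points <- function(mz, rt, intensity, id = NULL) {
  n <- length(mz)
  if (length(rt) != n || length(intensity) != n) {
    rlang::abort("mz, rt and intensity must have equal length")
  }
  if (is.null(id)) {
    id <- if (n > 0) 0:(n - 1) else integer()
  }
  pts <- tibble::tibble(
    id = as.integer(id),
    mz = as.numeric(mz),
    rt = as.numeric(rt),
    intensity = as.numeric(intensity)
  )
  validate_ms_points(pts)
  pts
}

#' Validate an MS point table
#'
#' Checks the invariants every point table must satisfy: unique non-negative
#' ids, positive m/z, non-negative retention time and intensity.
#'
#' @param points A data frame with columns `id`, `mz`, `rt`, `intensity`.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_ms_points <- function(points) {
  needed <- c("id", "mz", "rt", "intensity")
  missing <- setdiff(needed, names(points))
  if (length(missing) > 0) {
    rlang::abort(paste0("point table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(points) > 0) {
    if (anyDuplicated(points$id)) rlang::abort("point ids must be unique")
    if (any(points$id < 0)) rlang::abort("point ids must be >= 0")
    if (any(!is.finite(points$mz)) || any(points$mz <= 0)) {
      rlang::abort("mz values must be finite and > 0")
    }
    if (any(points$rt < 0)) rlang::abort("rt values must be >= 0")
    if (any(points$intensity < 0)) rlang::abort("intensities must be >= 0")
  }
  invisible(points)
}

#' Flatten spectra into a point cloud
#'
#' Every (m/z, intensity) pair of every spectrum becomes one MS point carrying
#' that spectrum's retention time. Ids are assigned sequentially from 0 in
#' encounter order (file order, then within-spectrum array order). No
#' filtering happens at this stage.
#'
#' @param spectra A spectrum table as returned by [stream_spectra()] or
#'   [reference_parse()]: columns `index`, `scan_start_time`, `ms_level` and
#'   list-columns `mz` and `intensity`.
#' @return A tibble of MS points (`id`, `mz`, `rt`, `intensity`).
#' @seealso [stream_spectra()], [cull_points()]
#' @export
spectra_to_points <- function(spectra) {
  lens <- lengths(spectra$mz)
  ms_points(
    mz = unlist(spectra$mz, use.names = FALSE) %||% numeric(),
    rt = rep(spectra$scan_start_time, lens),
    intensity = unlist(spectra$intensity, use.names = FALSE) %||% numeric()
  )
}

#' Remove sub-threshold noise points
#'
#' Static summarization begins by culling the point cloud to the points at or
#' above an intensity floor; points below the floor are treated as noise and
#' dropped. The conventional floor for centroided MS1 data is 1 intensity
#' unit. The boundary is inclusive: a point with intensity exactly equal to
#' the floor is retained (strictly-below is noise).
#'
#' @param points An MS point table.
#' @param floor Intensity threshold (default 1). Points with
#'   `intensity >= floor` survive, order preserved.
#' @return The retained points, original order and ids preserved.
#' @export
cull_points <- function(points, floor = 1) {
  dplyr::filter(points, .data$intensity >= floor)
}

#' Define a viewport over the LC-MS map
#'
#' A view window is the (m/z, RT) rectangle a client currently displays.
#' Both intervals are closed on both ends: boundary points are inside.
#'
#' @param mz_min,mz_max m/z bounds (Thomson), `mz_min <= mz_max`.
#' @param rt_min,rt_max RT bounds (seconds), `rt_min <= rt_max`.
#' @return An object of class `view_window`.
#' @export
view_window <- function(mz_min, mz_max, rt_min, rt_max) {
  for (v in list(mz_min, mz_max, rt_min, rt_max)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      rlang::abort("window bounds must be single finite numbers")
    }
  }
  if (mz_min > mz_max) rlang::abort("mz_min must be <= mz_max")
  if (rt_min > rt_max) rlang::abort("rt_min must be <= rt_max")
  structure(
    list(mz_min = mz_min, mz_max = mz_max, rt_min = rt_min, rt_max = rt_max),
    class = "view_window"
  )
}

#' @export
print.view_window <- function(x, ...) {
  cat(sprintf("<view_window> m/z [%g, %g] Th x RT [%g, %g] s\n",
              x$mz_min, x$mz_max, x$rt_min, x$rt_max))
  invisible(x)
}

#' Linear-scan viewport filter (oracle)
#'
#' Returns every point whose m/z lies in `[mz_min, mz_max]` and RT in
#' `[rt_min, rt_max]` (closed intervals), by a direct scan of the point
#' table. This is the reference against which the level-of-detail index is
#' validated; it ignores any index structure.
#'
#' @param points An MS point table.
#' @param window A [view_window()].
#' @return The in-window points, input order preserved.
#' @export
brute_force_query <- function(points, window) {
  dplyr::filter(
    points,
    .data$mz >= window$mz_min, .data$mz <= window$mz_max,
    .data$rt >= window$rt_min, .data$rt <= window$rt_max
  )
}

#' Jump the viewport to an m/z position
#'
#' Re-centers the window at a target m/z while preserving the m/z width and
#' the RT bounds exactly — the "jump to m/z" navigation of an MS map viewer,
#' which keeps the current RT position and zoom level.
#'
#' @param window A [view_window()].
#' @param target_mz Positive m/z to center on.
#' @return A new `view_window` of identical m/z width and RT bounds, centered
#'   at `target_mz`.
#' @examples
#' w <- view_window(400, 500, 10, 20)
#' jump_window(w, 1000) # [950, 1050] x [10, 20]
#' @export
jump_window <- function(window, target_mz) {
  if (!is.numeric(target_mz) || length(target_mz) != 1 ||
      !is.finite(target_mz) || target_mz <= 0) {
    rlang::abort("target_mz must be a single positive number")
  }
  width <- window$mz_max - window$mz_min
  new_min <- target_mz - width / 2
  # max is derived from min + width so the m/z width is preserved bit-exactly
  view_window(new_min, new_min + width, window$rt_min, window$rt_max)
}

#' Plot an MS point cloud
#'
#' A bird's-eye (2-D) view of a point table: m/z against RT, intensity on a
#' log10 color scale. Useful for eyeballing generated fixtures and query
#' results.
#'
#' @param points An MS point table.
#' @param window Optional [view_window()] drawn as a rectangle.
#' @return A ggplot object.
#' @export
plot_points <- function(points, window = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(.data$mz, .data$rt)) +
    ggplot2::geom_point(ggplot2::aes(colour = log10(.data$intensity + 1)),
                        size = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "log10 intensity") +
    ggplot2::labs(x = "m/z (Th)", y = "RT (s)")
  if (!is.null(window)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = window$mz_min, xmax = window$mz_max,
      ymin = window$rt_min, ymax = window$rt_max,
      fill = NA, colour = "red"
    )
  }
  p
}

`%||%` <- function(x, y) if (is.null(x)) y else x
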