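# HTTP JSON service over a loaded level-of-detail index.
#
# Routes (GET only):
#   /api/v1/points?mzmin=&mzmax=&rtmin=&rtmax=&n=  -> PointsResponse
#   /api/v1/bounds                                 -> BoundsResponse
# Errors are {"error": "<message>"} with 400 (bad parameters), 404 (unknown
# path), 405 (non-GET) or 503 (no index loaded). The route shapes are this
# package's own design; the service is stateless and the index immutable
# after load, so identical requests yield byte-identical responses and
# concurrent reads are safe.

parse_query_string <- function(qs) {
  if (is.null(qs) || qs == "" || qs == "?") return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) utils::URLdecode(if (length(p) > 1) p[2] else ""))
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

service_error <- function(status, message) {
  list(status = status,
       body = list(error = jsonlite::unbox(message)))
}

num_param <- function(params, name) {
  if (is.null(params[[name]])) return(NA_real_)
  suppressWarnings(as.numeric(params[[name]]))
}

#' Answer a viewport point request
#'
#' Validates the five request parameters (`mzmin`, `mzmax`, `rtmin`,
#' `rtmax`, `n`), runs [query_points()] on the index and shapes the result
#' as a points payload: the point list, its length, and a `truncated` flag
#' that is true when the window held more retained points than the budget.
#'
#' @param tree An `mz_lod_tree`, or `NULL` when no index is loaded.
#' @param params Named list of parameter strings (or numbers), as decoded
#'   from an HTTP query string.
#' @return A list with elements `status` (HTTP status code) and `body`
#'   (JSON-ready list: either `points`/`returned_count`/`truncated` or
#'   `error`).
#' @export
handle_points <- function(tree, params) {
  if (is.null(tree)) return(service_error(503L, "no index loaded"))
  wanted <- c("mzmin", "mzmax", "rtmin", "rtmax", "n")
  vals <- vapply(wanted, function(nm) num_param(params, nm), numeric(1))
  if (any(is.na(vals))) {
    missing <- wanted[is.na(vals)]
    return(service_error(400L, paste0(
      "missing or non-numeric parameter(s): ", paste(missing, collapse = ", ")
    )))
  }
  if (vals[["mzmin"]] > vals[["mzmax"]]) {
    return(service_error(400L, "mzmin must be <= mzmax"))
  }
  if (vals[["rtmin"]] > vals[["rtmax"]]) {
    return(service_error(400L, "rtmin must be <= rtmax"))
  }
  if (vals[["n"]] < 0 || vals[["n"]] != floor(vals[["n"]])) {
    return(service_error(400L, "n must be a non-negative integer"))
  }
  w <- view_window(vals[["mzmin"]], vals[["mzmax"]],
                   vals[["rtmin"]], vals[["rtmax"]])
  pts <- query_points(tree, w, vals[["n"]])
  supply <- nrow(brute_force_query(tree$points, w))
  list(
    status = 200L,
    body = list(
      points = pts[, c("id", "mz", "rt", "intensity")],
      returned_count = jsonlite::unbox(nrow(pts)),
      truncated = jsonlite::unbox(supply > nrow(pts))
    )
  )
}

#' Report dataset bounds over the service
#'
#' @param tree An `mz_lod_tree`, or `NULL` when no index is loaded.
#' @return A list with `status` and JSON-ready `body` mirroring
#'   [tree_bounds()].
#' @export
handle_bounds <- function(tree) {
  if (is.null(tree)) return(service_error(503L, "no index loaded"))
  b <- tree_bounds(tree)
  list(status = 200L, body = lapply(as.list(b), jsonlite::unbox))
}

response_json <- function(res) {
  list(
    status = res$status,
    headers = list("Content-Type" = "application/json"),
    body = as.character(jsonlite::toJSON(
      res$body, dataframe = "rows", auto_unbox = FALSE, digits = NA,
      na = "null"
    ))
  )
}

#' Build the httpuv application for an index
#'
#' @param tree An `mz_lod_tree` or `NULL`.
#' @return A list with a `call` function, suitable for [httpuv::startServer()].
#' @keywords internal
#' @export
ms_service_app <- function(tree) {
  list(call = function(req) {
    if (!identical(req$REQUEST_METHOD, "GET")) {
      return(response_json(service_error(405L, "only GET is supported")))
    }
    path <- req$PATH_INFO
    if (identical(path, "/api/v1/bounds")) {
      return(response_json(handle_bounds(tree)))
    }
    if (identical(path, "/api/v1/points")) {
      params <- parse_query_string(req$QUERY_STRING)
      return(response_json(handle_points(tree, params)))
    }
    response_json(service_error(404L, paste0("no such route: ", path)))
  })
}

#' Serve a level-of-detail index over HTTP
#'
#' Starts a JSON point service for the given index, exposing
#' `GET /api/v1/points` (viewport + point budget) and `GET /api/v1/bounds`.
#' The service is designed to run either next to the client or as a
#' stand-alone server; it holds the index immutable in memory and keeps no
#' per-request state.
#'
#' @param tree An `mz_lod_tree`, or a path to an index saved with
#'   [save_lod_index()].
#' @param host Interface to bind (default 127.0.0.1).
#' @param port TCP port (default 4567).
#' @param blocking If `TRUE`, run the event loop in the calling process
#'   until interrupted (the CLI's serve mode); if `FALSE` (default) return
#'   a handle whose `$stop()` shuts the server down.
#' @return Invisibly, an object of class `mz_lod_server` with fields
#'   `host`, `port` and methods `$stop()`.
#' @export
ms_serve <- function(tree, host = "127.0.0.1", port = 4567L,
                     blocking = FALSE) {
  if (is.character(tree)) tree <- load_lod_index(tree)
  if (!is.null(tree) && !inherits(tree, "mz_lod_tree")) {
    rlang::abort("tree must be an mz_lod_tree, an index path, or NULL")
  }
  server <- tryCatch(
    httpuv::startServer(host, as.integer(port), ms_service_app(tree)),
    error = function(e) {
      rlang::abort(sprintf("cannot bind %s:%d: %s", host, port,
                           conditionMessage(e)),
                   class = "mzlod_io_error", parent = e)
    }
  )
  handle <- structure(
    list(host = host, port = as.integer(port),
         stop = function() httpuv::stopServer(server)),
    class = "mz_lod_server"
  )
  if (blocking) {
    on.exit(httpuv::stopServer(server))
    message(sprintf("serving on http://%s:%d (interrupt to stop)", host, port))
    while (TRUE) httpuv::service(250)
  }
  invisible(handle)
}

#' @export
print.mz_lod_server <- function(x, ...) {
  cat(sprintf("<mz_lod_server> http://%s:%d/api/v1/{points,bounds}\n",
              x$host, x$port))
  invisible(x)
}
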