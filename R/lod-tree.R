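#' Configuration for building a level-of-detail index
#'
#' @param intensity_floor Static-summarization cull threshold (default 1):
#'   points with intensity strictly below it are treated as noise and never
#'   enter the index.
#' @param leaf_capacity Maximum points stored in one leaf (default 512).
#' @param branching Children per internal node (default 4).
#' @param sample_size Preset per-node sample count S (default 256): every
#'   internal node keeps references to the S most intense points of its
#'   subtree, giving each tree level a progressively coarser summary of the
#'   data below it.
#' @param seed Integer recorded in the index header so a rebuild from the
#'   same inputs is reproducible. The default build is fully deterministic
#'   (intensity-ranked sampling), so the seed currently influences nothing,
#'   but it travels with the index by contract.
#' @return An object of class `lod_config`.
#' @export
lod_config <- function(intensity_floor = 1, leaf_capacity = 512L,
                       branching = 4L, sample_size = 256L, seed = 1L) {
  if (intensity_floor < 0) rlang::abort("intensity_floor must be >= 0")
  if (leaf_capacity < 1) rlang::abort("leaf_capacity must be >= 1")
  if (branching < 2) rlang::abort("branching must be >= 2")
  if (sample_size < 1) rlang::abort("sample_size must be >= 1")
  structure(
    list(
      intensity_floor = as.numeric(intensity_floor),
      leaf_capacity = as.integer(leaf_capacity),
      branching = as.integer(branching),
      sample_size = as.integer(sample_size),
      seed = as.integer(seed)
    ),
    class = "lod_config"
  )
}

# selection order shared by static sampling and dynamic whittling:
# intensity descending, ties broken on ascending (mz, rt, id)
top_order <- function(df) order(-df$intensity, df$mz, df$rt, df$id)

#' Sample the most intense points of a node's children
#'
#' Static summarization at one node: given the point sets of all children,
#' keep references to all of them when there are at most `S`, otherwise to
#' exactly the `S` most intense, ties broken on the smaller (mz, rt, id)
#' triple. The output order is the selection order (intensity descending),
#' so the choice is fully deterministic.
#'
#' @param points A point table, or a list of point tables (one per child).
#' @param S Preset sample count, >= 1.
#' @return A point table of at most `S` rows.
#' @export
sample_node <- function(points, S) {
  if (S < 1) rlang::abort("S must be >= 1")
  if (is.list(points) && !is.data.frame(points)) {
    points <- dplyr::bind_rows(points)
  }
  ord <- top_order(points)
  points[ord[seq_len(min(S, nrow(points)))], ]
}

#' Reduce a candidate set to an exact point budget
#'
#' Dynamic summarization: keeps exactly `n` of the candidates — the `n` most
#' intense, with the same deterministic tie-break as [sample_node()]. The
#' caller must supply at least `n` candidates; shortfall handling (a window
#' that simply does not hold `n` points) is the query's job, not whittling's.
#'
#' @param candidates A point table with at least `n` rows.
#' @param n Number of points to keep, >= 0.
#' @return A point table of exactly `n` rows, intensity-descending.
#' @export
whittle <- function(candidates, n) {
  if (n > nrow(candidates)) {
    rlang::abort(sprintf("cannot whittle %d candidates down to %d",
                         nrow(candidates), n))
  }
  candidates[top_order(candidates)[seq_len(n)], ]
}

node_bounds <- function(pts) {
  c(mz_min = min(pts$mz), mz_max = max(pts$mz),
    rt_min = min(pts$rt), rt_max = max(pts$rt))
}

build_node <- function(points, rows, depth, config) {
  pts <- points[rows, ]
  bounds <- node_bounds(pts)
  S <- config$sample_size
  if (length(rows) <= config$leaf_capacity) {
    return(list(
      bounds = bounds,
      sample = rows[top_order(pts)[seq_len(min(S, length(rows)))]],
      children = list(),
      leaf = TRUE,
      leaf_rows = rows,
      n_desc = length(rows),
      depth = depth
    ))
  }
  # median-style split: alternate axes by depth, cut the sorted run into
  # near-equal contiguous chunks
  if (depth %% 2L == 0L) {
    ord <- order(pts$mz, pts$rt, pts$id)
  } else {
    ord <- order(pts$rt, pts$mz, pts$id)
  }
  sorted_rows <- rows[ord]
  k <- min(config$branching, length(rows))
  cuts <- floor(seq(0, length(rows), length.out = k + 1))
  children <- vector("list", k)
  for (i in seq_len(k)) {
    child_rows <- sorted_rows[(cuts[i] + 1):cuts[i + 1]]
    children[[i]] <- build_node(points, child_rows, depth + 1L, config)
  }
  # each child's sample holds its subtree's top-S, so the top-S of the pooled
  # child samples equals the top-S of all descendant points
  pooled <- unlist(lapply(children, `[[`, "sample"), use.names = FALSE)
  pooled_pts <- points[pooled, ]
  list(
    bounds = bounds,
    sample = pooled[top_order(pooled_pts)[seq_len(min(S, length(pooled)))]],
    children = children,
    leaf = FALSE,
    leaf_rows = NULL,
    n_desc = length(rows),
    depth = depth
  )
}

#' Build a level-of-detail index over an MS point cloud
#'
#' Static summarization: the point cloud is first culled at the intensity
#' floor, then partitioned recursively into hierarchical bounding boxes
#' (median splits alternating between the m/z and RT axes), and every
#' internal node stores a sample of the most intense points of its subtree —
#' references into one shared point table, never copies. The result supports
#' viewport queries returning an exact requested number of real data points
#' at any zoom level.
#'
#' @param points An MS point table (see [ms_points()]).
#' @param config An [lod_config()].
#' @return An object of class `mz_lod_tree`.
#' @examples
#' pts <- ms_points(mz = runif(1000, 400, 900), rt = runif(1000, 0, 600),
#'                  intensity = rexp(1000, 1 / 50))
#' tree <- build_lod_tree(pts)
#' query_points(tree, view_window(500, 600, 100, 300), n = 50)
#' @export
build_lod_tree <- function(points, config = lod_config()) {
  validate_ms_points(points)
  retained <- cull_points(points, config$intensity_floor)
  root <- if (nrow(retained) > 0) {
    build_node(retained, seq_len(nrow(retained)), 0L, config)
  } else {
    NULL
  }
  structure(
    list(points = retained, root = root, config = config,
         n_input = nrow(points)),
    class = "mz_lod_tree"
  )
}

window_overlaps <- function(bounds, w) {
  bounds[["mz_min"]] <= w$mz_max && bounds[["mz_max"]] >= w$mz_min &&
    bounds[["rt_min"]] <= w$rt_max && bounds[["rt_max"]] >= w$rt_min
}

window_contains <- function(bounds, w) {
  bounds[["mz_min"]] >= w$mz_min && bounds[["mz_max"]] <= w$mz_max &&
    bounds[["rt_min"]] >= w$rt_min && bounds[["rt_max"]] <= w$rt_max
}

collect_leaf_rows <- function(node) {
  if (node$leaf) return(node$leaf_rows)
  unlist(lapply(node$children, collect_leaf_rows), use.names = FALSE)
}

gather_in_window <- function(node, points, w) {
  if (!window_overlaps(node$bounds, w)) return(integer())
  if (window_contains(node$bounds, w)) return(collect_leaf_rows(node))
  if (node$leaf) {
    rows <- node$leaf_rows
    pts <- points[rows, ]
    return(rows[pts$mz >= w$mz_min & pts$mz <= w$mz_max &
                  pts$rt >= w$rt_min & pts$rt <= w$rt_max])
  }
  unlist(lapply(node$children, gather_in_window, points = points, w = w),
         use.names = FALSE)
}

query_level_mode <- function(tree, w, n) {
  frontier <- Filter(function(nd) window_overlaps(nd$bounds, w),
                     list(tree$root))
  points <- tree$points
  repeat {
    rows <- unlist(lapply(frontier, function(nd) {
      cand <- if (nd$leaf) nd$leaf_rows else nd$sample
      pts <- points[cand, ]
      cand[pts$mz >= w$mz_min & pts$mz <= w$mz_max &
             pts$rt >= w$rt_min & pts$rt <= w$rt_max]
    }), use.names = FALSE)
    if (length(rows) >= n) return(whittle(points[rows, ], n))
    if (all(vapply(frontier, `[[`, logical(1), "leaf"))) {
      # leaf level: fewer points than requested must be returned
      return(points[rows, ][top_order(points[rows, ]), ])
    }
    frontier <- unlist(lapply(frontier, function(nd) {
      if (nd$leaf) list(nd)
      else Filter(function(ch) window_overlaps(ch$bounds, w), nd$children)
    }), recursive = FALSE)
  }
}

#' Query a viewport for an exact number of real points
#'
#' Dynamic summarization: the index is traversed from the root, nodes whose
#' bounding boxes miss the viewing area are pruned, the surviving in-view
#' points form the prospective set, and that set is whittled down to exactly
#' `n` points — the `n` most intense, deterministically. Every returned
#' point is a real stored observation, never an aggregate; when the window
#' holds fewer than `n` retained points all of them are returned (the
#' leaf-level shortfall rule).
#'
#' The default `"exact"` mode evaluates the prospective set at the leaves,
#' so the result equals the top-`n` of a brute-force window scan. Mode
#' `"level"` instead walks the tree breadth-first and stops at the first
#' level whose in-view node samples already reach `n` — cheaper on huge
#' trees and faithful to per-level summaries, but the selection may then
#' miss in-window points hidden behind mostly out-of-window samples, so it
#' is offered as an approximate preview path only.
#'
#' @param tree An `mz_lod_tree`.
#' @param window A [view_window()].
#' @param n Requested number of points (>= 0).
#' @param mode `"exact"` (default) or `"level"`.
#' @return A point table of `min(n, supply)` rows, intensity-descending.
#' @export
query_points <- function(tree, window, n, mode = c("exact", "level")) {
  mode <- match.arg(mode)
  if (!inherits(tree, "mz_lod_tree")) rlang::abort("tree must be an mz_lod_tree")
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    rlang::abort("n must be a single non-negative number")
  }
  n <- as.integer(n)
  if (is.null(tree$root)) return(tree$points[0, ])
  if (mode == "level") return(query_level_mode(tree, window, n))
  rows <- gather_in_window(tree$root, tree$points, window)
  supply <- length(rows)
  keep <- min(supply, n)
  whittle(tree$points[rows, ], keep)
}

#' Dataset bounds and size of a level-of-detail index
#'
#' The tight bounding box, maximum intensity and retained point count of the
#' indexed data — what a viewer needs to draw its legend and initial view.
#'
#' @param tree An `mz_lod_tree`.
#' @return A one-row tibble: `mz_min`, `mz_max`, `rt_min`, `rt_max`,
#'   `intensity_max`, `point_count`.
#' @export
tree_bounds <- function(tree) {
  if (is.null(tree$root)) {
    return(tibble::tibble(mz_min = NA_real_, mz_max = NA_real_,
                          rt_min = NA_real_, rt_max = NA_real_,
                          intensity_max = NA_real_, point_count = 0L))
  }
  b <- tree$root$bounds
  tibble::tibble(
    mz_min = b[["mz_min"]], mz_max = b[["mz_max"]],
    rt_min = b[["rt_min"]], rt_max = b[["rt_max"]],
    intensity_max = max(tree$points$intensity),
    point_count = nrow(tree$points)
  )
}

#' Save a level-of-detail index to disk
#'
#' The index (config header, node table and point table) is serialized
#' uncompressed, so identical trees produce byte-identical files and a
#' saved index answers queries identically after reload.
#'
#' @param tree An `mz_lod_tree`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_lod_index <- function(tree, path) {
  if (!inherits(tree, "mz_lod_tree")) rlang::abort("tree must be an mz_lod_tree")
  saveRDS(tree, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_lod_index
#' @export
load_lod_index <- function(path) {
  tree <- readRDS(path)
  if (!inherits(tree, "mz_lod_tree")) {
    rlang::abort(paste0(path, " does not contain a level-of-detail index"))
  }
  tree
}

#' @export
print.mz_lod_tree <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mz_lod_tree> %d points retained of %d (floor %g), depth %d, %d nodes\n",
    g$n_retained, g$n_input, x$config$intensity_floor, g$depth, g$n_nodes
  ))
  if (g$n_retained > 0) {
    cat(sprintf("  m/z [%g, %g] Th x RT [%g, %g] s\n",
                g$mz_min, g$mz_max, g$rt_min, g$rt_max))
  }
  invisible(x)
}

walk_nodes <- function(node, id_env, parent_id) {
  id_env$n <- id_env$n + 1L
  my_id <- id_env$n
  id_env$rows[[my_id]] <- tibble::tibble(
    node_id = my_id,
    parent_id = parent_id,
    depth = node$depth,
    is_leaf = node$leaf,
    n_points = node$n_desc,
    n_sample = length(node$sample),
    mz_min = node$bounds[["mz_min"]], mz_max = node$bounds[["mz_max"]],
    rt_min = node$bounds[["rt_min"]], rt_max = node$bounds[["rt_max"]]
  )
  for (ch in node$children) walk_nodes(ch, id_env, my_id)
}

#' Tidy a level-of-detail index into a per-node table
#'
#' One row per tree node with its depth, descendant point count, sample size
#' and bounding box — handy for inspecting how the space was partitioned.
#'
#' @param x An `mz_lod_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node.
#' @export
tidy.mz_lod_tree <- function(x, ...) {
  if (is.null(x$root)) {
    return(tibble::tibble(
      node_id = integer(), parent_id = integer(), depth = integer(),
      is_leaf = logical(), n_points = integer(), n_sample = integer(),
      mz_min = numeric(), mz_max = numeric(),
      rt_min = numeric(), rt_max = numeric()
    ))
  }
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$rows <- list()
  walk_nodes(x$root, env, NA_integer_)
  dplyr::bind_rows(env$rows)
}

#' One-row summary of a level-of-detail index
#'
#' @param x An `mz_lod_tree`.
#' @param ... Unused.
#' @return A one-row tibble: input/retained counts, bounds, tree depth and
#'   node/leaf counts, and the build configuration.
#' @export
glance.mz_lod_tree <- function(x, ...) {
  nodes <- tidy(x)
  b <- tree_bounds(x)
  tibble::tibble(
    n_input = x$n_input,
    n_retained = nrow(x$points),
    mz_min = b$mz_min, mz_max = b$mz_max,
    rt_min = b$rt_min, rt_max = b$rt_max,
    intensity_max = b$intensity_max,
    depth = if (nrow(nodes)) max(nodes$depth) else NA_integer_,
    n_nodes = nrow(nodes),
    n_leaves = sum(nodes$is_leaf),
    intensity_floor = x$config$intensity_floor,
    leaf_capacity = x$config$leaf_capacity,
    branching = x$config$branching,
    sample_size = x$config$sample_size,
    seed = x$config$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
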