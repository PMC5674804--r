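# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files these helpers just wrote.

# deterministic spectrum table with reproducible pseudo-random peaks
make_spectra <- function(n_spectra, peaks = 20, seed = 1, rt_step = 1.5) {
  set.seed(seed)
  spectrum_records(
    scan_start_time = seq(0, by = rt_step, length.out = n_spectra),
    mz = replicate(n_spectra, sort(runif(peaks, 300, 1500)), simplify = FALSE),
    intensity = replicate(n_spectra, rexp(peaks, 1 / 100), simplify = FALSE)
  )
}

all_dialects <- function() {
  grid <- expand.grid(
    precision = c("float64", "float32"),
    compression = c("none", "zlib"),
    indexed = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    mzml_dialect(grid$precision[i], grid$compression[i],
                 indexed = grid$indexed[i])
  })
}

# a mid-sized seeded point cloud with both signal and sub-threshold noise
make_cloud <- function(n = 10000, seed = 99) {
  set.seed(seed)
  ms_points(
    mz = runif(n, 300, 1500),
    rt = runif(n, 0, 600),
    intensity = c(rexp(n %/% 2, 1 / 200) + 1, runif(n - n %/% 2, 0.01, 5))
  )
}

random_window <- function(mz_range = c(300, 1500), rt_range = c(0, 600)) {
  mzs <- sort(runif(2, mz_range[1], mz_range[2]))
  rts <- sort(runif(2, rt_range[1], rt_range[2]))
  view_window(mzs[1], mzs[2], rts[1], rts[2])
}

# the documented selection rule, written independently of the tree code:
# full sort by intensity desc, ties on ascending (mz, rt, id)
oracle_top_n <- function(points, n) {
  ord <- order(-points$intensity, points$mz, points$rt, points$id)
  points[ord[seq_len(min(n, nrow(points)))], ]
}

# run an httpuv server and fetch URLs from within the same process:
# alternate the httpuv event loop with a non-blocking curl multi pool
local_fetch <- function(url, max_wait = 10) {
  result <- new.env(parent = emptyenv())
  h <- curl::new_handle(url = url)
  curl::multi_add(h,
    done = function(res) result$res <- res,
    fail = function(msg) result$err <- msg
  )
  deadline <- Sys.time() + max_wait
  while (is.null(result$res) && is.null(result$err)) {
    if (Sys.time() > deadline) stop("timed out fetching ", url)
    httpuv::service(20)
    curl::multi_run(timeout = 0.02)
  }
  if (!is.null(result$err)) stop("fetch failed: ", result$err)
  list(
    status = result$res$status_code,
    body = rawToChar(result$res$content)
  )
}

with_ms_server <- function(tree, fn) {
  srv <- ms_serve(tree, host = "127.0.0.1", port = httpuv::randomPort())
  on.exit(srv$stop())
  fn(sprintf("http://127.0.0.1:%d", srv$port))
}
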