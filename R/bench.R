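#' Measure parser scaling over prefix subsets of an mzML file
#'
#' Creates `num_subsets` prefix-subset files of increasing spectrum count
#' (via [subset_spectra()]) and times, for each file and each parser, the
#' construction of the parser object (`build_seconds`) and the full
#' extraction of all spectra (`parse_seconds`) separately. Because the
#' subsets come from one file, everything but length is held constant, so
#' parse time against spectrum count traces the parser's scaling — expected
#' to be linear for a single-pass reader. Wall times are reported for
#' inspection, never asserted: they depend on the machine.
#'
#' @param source Path to an mzML file with at least `num_subsets` spectra.
#' @param num_subsets Number of subset files (sizes spread evenly up to the
#'   full spectrum count).
#' @param dir Directory for the subset files (default a fresh temp dir).
#' @param parsers Which parsers to time: `"stream"` ([stream_spectra()])
#'   and/or `"reference"` ([reference_parse()]).
#' @param repeats Timings per file; the minimum is reported (the standard
#'   way to suppress garbage-collection pauses in wall-clock benchmarks).
#' @return A tibble with one row per (file, parser): `file`, `parser`,
#'   `spectrum_count`, `file_bytes`, `build_seconds`, `parse_seconds`.
#' @export
bench_parse <- function(source, num_subsets = 10L,
                        dir = tempfile("mzlod_bench_"),
                        parsers = c("stream", "reference"),
                        repeats = 1L) {
  parsers <- match.arg(parsers, several.ok = TRUE)
  total <- nrow(stream_spectra(source))
  if (total < num_subsets) {
    rlang::abort(sprintf("source has %d spectra; need at least %d",
                         total, num_subsets),
                 class = "mzlod_argument_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ks <- unique(round(seq(total / num_subsets, total,
                         length.out = num_subsets)))
  files <- character(length(ks))
  for (i in seq_along(ks)) {
    files[i] <- file.path(dir, sprintf("subset_%05d.mzML", ks[i]))
    subset_spectra(source, ks[i], files[i])
  }

  time_one <- function(dest, p) {
    gc(FALSE) # keep collector pauses out of the timed region
    if (p == "stream") {
      t0 <- proc.time()[["elapsed"]]
      s <- mzml_stream(dest)
      t1 <- proc.time()[["elapsed"]]
      while (!is.null(s$read_next())) {}
      t2 <- proc.time()[["elapsed"]]
      s$close()
    } else {
      t0 <- proc.time()[["elapsed"]]
      doc <- xml2::read_xml(dest)
      t1 <- proc.time()[["elapsed"]]
      xml2::xml_ns_strip(doc)
      nodes <- xml2::xml_find_all(doc, "//spectrum")
      for (i in seq_along(nodes)) parse_spectrum_node(nodes[[i]], i - 1L)
      t2 <- proc.time()[["elapsed"]]
    }
    c(build = t1 - t0, parse = t2 - t1)
  }

  # repeats are interleaved round-robin over the files so a transient slow
  # period of the machine cannot masquerade as a size effect
  best <- array(Inf, dim = c(length(files), length(parsers), 2))
  for (r in seq_len(max(1L, repeats))) {
    for (i in seq_along(files)) {
      for (j in seq_along(parsers)) {
        t <- time_one(files[i], parsers[j])
        best[i, j, ] <- pmin(best[i, j, ], t)
      }
    }
  }
  rows <- list()
  for (i in seq_along(files)) {
    for (j in seq_along(parsers)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        file = files[i], parser = parsers[j],
        spectrum_count = as.integer(ks[i]),
        file_bytes = as.numeric(file.size(files[i])),
        build_seconds = best[i, j, 1], parse_seconds = best[i, j, 2]
      )
    }
  }
  dplyr::bind_rows(rows)
}
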