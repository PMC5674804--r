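# Accessions consumed by the readers (PSI-MS / Unit Ontology):
#   MS:1000514 m/z array            MS:1000515 intensity array
#   MS:1000523 64-bit float         MS:1000521 32-bit float
#   MS:1000574 zlib compression     MS:1000576 no compression
#   MS:1000016 scan start time      UO:0000010 second / UO:0000031 minute
#   MS:1000511 ms level

ACC_PRECISION <- c("MS:1000523" = "float64", "MS:1000521" = "float32")
ACC_BAD_PRECISION <- c("MS:1000522", "MS:1000519") # integer arrays: unsupported
ACC_COMPRESSION <- c("MS:1000574" = "zlib", "MS:1000576" = "none")
ACC_BAD_COMPRESSION <- c("MS:1002312", "MS:1002313", "MS:1002314",
                         "MS:1002746", "MS:1002747", "MS:1002748") # numpress

parse_binary_array <- function(ba) {
  cv <- xml2::xml_find_all(ba, "./cvParam")
  accs <- xml2::xml_attr(cv, "accession")

  role <- if ("MS:1000514" %in% accs) "mz"
          else if ("MS:1000515" %in% accs) "intensity"
          else return(NULL) # extra arrays are skipped

  prec_acc <- intersect(names(ACC_PRECISION), accs)
  if (length(prec_acc) == 0) {
    bad <- intersect(ACC_BAD_PRECISION, accs)
    rlang::abort(paste0(
      "unsupported or missing precision CV term in binaryDataArray",
      if (length(bad)) paste0(" (", bad[1], ")")
    ), class = "mzlod_dialect_error")
  }
  precision <- unname(ACC_PRECISION[prec_acc[1]])

  comp_acc <- intersect(names(ACC_COMPRESSION), accs)
  if (length(comp_acc) == 0) {
    bad <- intersect(ACC_BAD_COMPRESSION, accs)
    if (length(bad)) {
      rlang::abort(paste0("unsupported compression CV term ", bad[1]),
                   class = "mzlod_dialect_error")
    }
    compression <- "none" # absent term: uncompressed per common practice
  } else {
    compression <- unname(ACC_COMPRESSION[comp_acc[1]])
  }

  btext <- trimws(xml2::xml_text(
    xml2::xml_find_first(ba, "./binary")
  ))
  declared <- xml2::xml_attr(ba, "encodedLength")
  if (!is.na(declared) && as.integer(declared) != nchar(btext)) {
    rlang::abort(sprintf(
      "encodedLength %s does not match actual base64 length %d",
      declared, nchar(btext)
    ), class = "mzlod_integrity_error")
  }
  list(
    role = role,
    values = decode_binary_array(btext, precision, compression),
    precision = precision,
    compression = compression
  )
}

parse_spectrum_node <- function(node, file_index) {
  lvl_node <- xml2::xml_find_first(node, "./cvParam[@accession='MS:1000511']")
  ms_level <- if (inherits(lvl_node, "xml_missing")) 1L
              else as.integer(xml2::xml_attr(lvl_node, "value"))

  rt_node <- xml2::xml_find_first(node, ".//cvParam[@accession='MS:1000016']")
  rt_unit <- "second"
  rt <- 0
  if (!inherits(rt_node, "xml_missing")) {
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitAccession")
    if (!is.na(unit) && unit == "UO:0000031") {
      rt <- rt * 60 # minutes in the file; seconds in memory
      rt_unit <- "minute"
    }
  }

  dal <- suppressWarnings(as.integer(xml2::xml_attr(node, "defaultArrayLength")))
  arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
  mz <- numeric()
  intensity <- numeric()
  precision <- NA_character_
  compression <- NA_character_
  for (ba in arrays) {
    parsed <- parse_binary_array(ba)
    if (is.null(parsed)) next
    if (!is.na(dal) && length(parsed$values) != dal) {
      rlang::abort(sprintf(
        "spectrum %d: %s array has %d values but defaultArrayLength is %d",
        file_index, parsed$role, length(parsed$values), dal
      ), class = "mzlod_integrity_error")
    }
    if (parsed$role == "mz") mz <- parsed$values else intensity <- parsed$values
    precision <- parsed$precision
    compression <- parsed$compression
  }
  if (length(mz) != length(intensity)) {
    rlang::abort(sprintf(
      "spectrum %d: m/z array (%d) and intensity array (%d) differ in length",
      file_index, length(mz), length(intensity)
    ), class = "mzlod_integrity_error")
  }
  list(
    index = file_index, scan_start_time = rt, ms_level = ms_level,
    mz = mz, intensity = intensity,
    precision = precision, compression = compression, rt_unit = rt_unit
  )
}

#' Open an mzML file as an incremental spectrum stream
#'
#' The single-pass reader: the file is consumed front-to-back in fixed-size
#' chunks, each `<spectrum>` element is decoded as soon as its closing tag
#' has been seen, and nothing before or after the current element is kept.
#' The first spectrum is therefore available long before the file has been
#' fully read, and memory use is bounded by the size of one spectrum plus
#' one read chunk regardless of file size. The trailing byte-offset index of
#' an `indexedmzML` wrapper is ignored; reading stays strictly sequential.
#'
#' @param path Path to an mzML 1.1 file (plain or `indexedmzML`).
#' @param ms_level Optional integer; when set, only spectra of that MS level
#'   are returned (file ordinals still count all spectra).
#' @param chunk_size Bytes per read (default 65536).
#' @return An object of class `mzml_stream` with methods
#'   `$read_next()` (one spectrum record as a list, or `NULL` at end of
#'   file), `$bytes_read()` (bytes consumed from the file so far),
#'   `$dialect()` (the [mzml_dialect()] observed once a spectrum has been
#'   read) and `$close()`.
#' @seealso [stream_spectra()] to collect the whole stream into a tibble.
#' @export
mzml_stream <- function(path, ms_level = NULL, chunk_size = 65536L) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "mzlod_io_error")
  }
  e <- new.env(parent = emptyenv())
  e$con <- file(path, open = "rb")
  e$buffer <- ""
  e$buf_start <- 0    # byte offset (0-based) of buffer[1] in the file
  e$bytes <- 0
  e$eof <- FALSE
  e$open <- TRUE
  e$idx <- 0L
  e$indexed <- NA
  e$precision <- NA_character_
  e$compression <- NA_character_
  e$rt_unit <- "second"

  read_more <- function() {
    if (e$eof) return(FALSE)
    chunk <- readBin(e$con, raw(), n = chunk_size)
    if (length(chunk) == 0) {
      e$eof <- TRUE
      return(FALSE)
    }
    e$bytes <- e$bytes + length(chunk)
    e$buffer <- paste0(e$buffer, rawToChar(chunk))
    if (is.na(e$indexed)) e$indexed <- grepl("<indexedmzML", e$buffer, fixed = TRUE)
    TRUE
  }

  read_next <- function() {
    if (!e$open) rlang::abort("stream is closed", class = "mzlod_io_error")
    repeat {
      open_at <- regexpr("<spectrum[ >]", e$buffer)
      if (open_at < 0) {
        # nothing pending: keep only a short tail (a tag may straddle chunks)
        if (nchar(e$buffer) > 256) {
          drop <- nchar(e$buffer) - 256L
          e$buffer <- substr(e$buffer, drop + 1L, nchar(e$buffer))
          e$buf_start <- e$buf_start + drop
        }
        if (!read_more()) return(NULL)
        next
      }
      close_pat <- "</spectrum>"
      close_at <- regexpr(close_pat, e$buffer, fixed = TRUE)
      while (close_at < 0 || close_at < open_at) {
        if (!read_more()) {
          rlang::abort(sprintf(
            "malformed mzML: unterminated <spectrum> starting at byte offset %d",
            e$buf_start + open_at - 1
          ), class = "mzlod_parse_error")
        }
        close_at <- regexpr(close_pat, e$buffer, fixed = TRUE)
      }
      end <- close_at + nchar(close_pat) - 1L
      block <- substr(e$buffer, open_at, end)
      block_offset <- e$buf_start + open_at - 1
      e$buf_start <- e$buf_start + end
      e$buffer <- substr(e$buffer, end + 1L, nchar(e$buffer))

      node <- tryCatch(
        xml2::read_xml(block),
        error = function(err) {
          rlang::abort(sprintf(
            "malformed XML in spectrum at byte offset %d: %s",
            block_offset, conditionMessage(err)
          ), class = "mzlod_parse_error", parent = err)
        }
      )
      rec <- parse_spectrum_node(node, e$idx)
      e$idx <- e$idx + 1L
      if (!is.na(rec$precision)) {
        e$precision <- rec$precision
        e$compression <- rec$compression
      }
      e$rt_unit <- rec$rt_unit
      if (!is.null(ms_level) && rec$ms_level != ms_level) next
      return(rec)
    }
  }

  structure(
    list(
      read_next = read_next,
      bytes_read = function() e$bytes,
      dialect = function() mzml_dialect(
        precision = if (is.na(e$precision)) "float64" else e$precision,
        compression = if (is.na(e$compression)) "none" else e$compression,
        indexed = isTRUE(e$indexed),
        rt_unit = e$rt_unit
      ),
      close = function() {
        if (e$open) close(e$con)
        e$open <- FALSE
        invisible(NULL)
      }
    ),
    class = "mzml_stream"
  )
}

records_to_tibble <- function(recs) {
  tibble::tibble(
    index = vapply(recs, `[[`, integer(1), "index"),
    scan_start_time = vapply(recs, `[[`, numeric(1), "scan_start_time"),
    ms_level = vapply(recs, `[[`, integer(1), "ms_level"),
    mz = lapply(recs, `[[`, "mz"),
    intensity = lapply(recs, `[[`, "intensity")
  )
}

#' Read all spectra of an mzML file via the streaming parser
#'
#' Drives [mzml_stream()] to the end of the file and collects the records
#' into a spectrum table. Retention times are normalized to seconds whatever
#' unit the file declares. The dialect observed while parsing (precision,
#' compression, index wrapper, RT unit) is attached as attribute
#' `"dialect"`, which lets [subset_spectra()] rewrite a file in its own
#' dialect.
#'
#' @inheritParams mzml_stream
#' @return A spectrum table (see [spectrum_records()]) with a `"dialect"`
#'   attribute.
#' @export
stream_spectra <- function(path, ms_level = NULL, chunk_size = 65536L) {
  s <- mzml_stream(path, ms_level = ms_level, chunk_size = chunk_size)
  on.exit(s$close())
  recs <- list()
  i <- 0L
  repeat {
    rec <- s$read_next()
    if (is.null(rec)) break
    i <- i + 1L
    recs[[i]] <- rec
  }
  out <- records_to_tibble(recs)
  attr(out, "dialect") <- s$dialect()
  out
}

#' Whole-document mzML reader (reference oracle)
#'
#' Loads the entire document into memory with a DOM parser and then extracts
#' the spectrum records. Functionally equivalent to [stream_spectra()] —
#' the test suite holds the two to record-for-record agreement — but without
#' the streaming memory profile; it exists as an independent correctness
#' reference for the single-pass parser, not as the production path.
#'
#' @inheritParams mzml_stream
#' @return A spectrum table, as [stream_spectra()].
#' @export
reference_parse <- function(path, ms_level = NULL) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(err) {
      rlang::abort(paste0("malformed mzML document: ", conditionMessage(err)),
                   class = "mzlod_parse_error", parent = err)
    }
  )
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//spectrum")
  recs <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    recs[[i]] <- parse_spectrum_node(nodes[[i]], i - 1L)
  }
  if (!is.null(ms_level)) {
    recs <- Filter(function(r) r$ms_level == ms_level, recs)
  }
  out <- records_to_tibble(recs)
  first <- if (length(recs)) recs[[1]] else NULL
  attr(out, "dialect") <- mzml_dialect(
    precision = if (!is.null(first) && !is.na(first$precision)) first$precision else "float64",
    compression = if (!is.null(first) && !is.na(first$compression)) first$compression else "none",
    indexed = identical(xml2::xml_name(doc), "indexedmzML"),
    rt_unit = if (!is.null(first)) first$rt_unit else "second"
  )
  out
}
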