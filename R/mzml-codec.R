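#' Describe an mzML encoding dialect
#'
#' mzML binary arrays come in four on-disk flavours (32- or 64-bit IEEE
#' floats, zlib-compressed or plain), the document may or may not be wrapped
#' in an `indexedmzML` element carrying a trailing byte-offset index, and
#' scan start times may be declared in seconds or minutes. A dialect bundles
#' those choices for the writer; the reader discovers them from the file's
#' controlled-vocabulary terms.
#'
#' @param precision `"float64"` or `"float32"`.
#' @param compression `"none"` or `"zlib"`.
#' @param indexed Logical; wrap the document in `indexedmzML`?
#' @param rt_unit `"second"` or `"minute"`: the unit declared for scan start
#'   times in the file. In memory RT is always seconds.
#' @return An object of class `mzml_dialect`.
#' @export
mzml_dialect <- function(precision = c("float64", "float32"),
                         compression = c("none", "zlib"),
                         indexed = FALSE,
                         rt_unit = c("second", "minute")) {
  structure(
    list(
      precision = match.arg(precision),
      compression = match.arg(compression),
      indexed = isTRUE(indexed),
      rt_unit = match.arg(rt_unit)
    ),
    class = "mzml_dialect"
  )
}

#' @export
print.mzml_dialect <- function(x, ...) {
  cat(sprintf("<mzml_dialect> %s, %s compression, %s, RT in %ss\n",
              x$precision, x$compression,
              if (x$indexed) "indexedmzML" else "plain mzML", x$rt_unit))
  invisible(x)
}

element_size <- function(precision) {
  switch(precision, float64 = 8L, float32 = 4L,
         rlang::abort(paste0("unknown precision: ", precision),
                      class = "mzlod_dialect_error"))
}

#' Encode a numeric vector as an mzML binary array
#'
#' Serializes to little-endian IEEE floats at the requested precision,
#' optionally deflates with zlib (RFC 1950), and base64-encodes. This is the
#' exact payload stored in an mzML `<binary>` element.
#'
#' @param x Numeric vector.
#' @param precision `"float64"` or `"float32"`.
#' @param compression `"none"` or `"zlib"`.
#' @return A single base64 string (no line breaks; empty string for empty
#'   input with no compression overhead omitted).
#' @export
encode_binary_array <- function(x, precision = "float64",
                                compression = "none") {
  size <- element_size(precision)
  payload <- writeBin(as.numeric(x), raw(), size = size, endian = "little")
  if (compression == "zlib") {
    payload <- memCompress(payload, type = "gzip") # R emits RFC-1950 zlib
  } else if (compression != "none") {
    rlang::abort(paste0("unknown compression: ", compression),
                 class = "mzlod_dialect_error")
  }
  gsub("\n", "", jsonlite::base64_enc(payload), fixed = TRUE)
}

#' Decode an mzML binary array
#'
#' Inverse of [encode_binary_array()]: base64-decodes, inflates if
#' zlib-compressed, and reads little-endian floats. Float64 payloads
#' round-trip bit-exactly; float32 within single-precision epsilon.
#'
#' @param encoded Base64 text (whitespace tolerated).
#' @param precision `"float64"` or `"float32"`.
#' @param compression `"none"` or `"zlib"`.
#' @return A numeric vector.
#' @export
decode_binary_array <- function(encoded, precision = "float64",
                                compression = "none") {
  size <- element_size(precision)
  payload <- tryCatch(
    jsonlite::base64_dec(gsub("[[:space:]]", "", encoded)),
    error = function(e) {
      rlang::abort("invalid base64 in binary array",
                   class = "mzlod_decode_error", parent = e)
    }
  )
  if (compression == "zlib") {
    payload <- tryCatch(
      memDecompress(payload, type = "gzip"),
      error = function(e) {
        rlang::abort("zlib inflate failed for binary array",
                     class = "mzlod_decode_error", parent = e)
      }
    )
  } else if (compression != "none") {
    rlang::abort(paste0("unknown compression: ", compression),
                 class = "mzlod_dialect_error")
  }
  if (length(payload) %% size != 0) {
    rlang::abort(sprintf(
      "binary payload of %d bytes is not a multiple of the %d-byte element size",
      length(payload), size
    ), class = "mzlod_integrity_error")
  }
  readBin(payload, what = "double", n = length(payload) %/% size,
          size = size, endian = "little")
}
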