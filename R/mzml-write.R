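#' Build a spectrum table
#'
#' The in-memory representation of a sequence of scans: one row per spectrum
#' with its 0-based file ordinal, retention time (always seconds), MS level
#' and parallel m/z / intensity arrays as list-columns. This is what the
#' readers return and what [write_mzml()] consumes.
#'
#' @param scan_start_time Numeric vector of retention times in seconds.
#' @param mz,intensity Lists of numeric vectors, one per spectrum, of equal
#'   per-spectrum length.
#' @param ms_level Integer vector (or scalar, recycled) of MS levels, >= 1.
#' @return A tibble with columns `index`, `scan_start_time`, `ms_level`,
#'   `mz`, `intensity`.
#' @export
spectrum_records <- function(scan_start_time, mz, intensity, ms_level = 1L) {
  n <- length(scan_start_time)
  if (length(mz) != n || length(intensity) != n) {
    rlang::abort("mz and intensity lists must have one element per spectrum")
  }
  if (any(lengths(mz) != lengths(intensity))) {
    rlang::abort("mz and intensity arrays must have equal length per spectrum")
  }
  if (any(scan_start_time < 0)) rlang::abort("scan_start_time must be >= 0")
  ms_level <- as.integer(rep_len(ms_level, n))
  if (n > 0 && any(ms_level < 1)) rlang::abort("ms_level must be >= 1")
  tibble::tibble(
    index = if (n > 0) 0:(n - 1) else integer(),
    scan_start_time = as.numeric(scan_start_time),
    ms_level = ms_level,
    mz = lapply(mz, as.numeric),
    intensity = lapply(intensity, as.numeric)
  )
}

fmt_num <- function(x) sprintf("%.17g", x)

spectrum_xml <- function(index, rt_seconds, ms_level, mz, intensity, dialect) {
  prec_cv <- switch(dialect$precision,
    float64 = '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    float32 = '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>'
  )
  comp_cv <- switch(dialect$compression,
    none = '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    zlib = '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression" value=""/>'
  )
  if (dialect$rt_unit == "second") {
    rt_val <- fmt_num(rt_seconds)
    rt_unit <- 'unitCvRef="UO" unitAccession="UO:0000010" unitName="second"'
  } else {
    rt_val <- fmt_num(rt_seconds / 60)
    rt_unit <- 'unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"'
  }
  enc_mz <- encode_binary_array(mz, dialect$precision, dialect$compression)
  enc_in <- encode_binary_array(intensity, dialect$precision, dialect$compression)
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
            index, index + 1L, length(mz)),
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>\n',
            ms_level),
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '<scanList count="1">\n<scan>\n',
    sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%s" %s/>\n',
            rt_val, rt_unit),
    '</scan>\n</scanList>\n',
    '<binaryDataArrayList count="2">\n',
    sprintf('<binaryDataArray encodedLength="%d">\n', nchar(enc_mz)),
    prec_cv, "\n", comp_cv, "\n",
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    "<binary>", enc_mz, "</binary>\n",
    "</binaryDataArray>\n",
    sprintf('<binaryDataArray encodedLength="%d">\n', nchar(enc_in)),
    prec_cv, "\n", comp_cv, "\n",
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    "<binary>", enc_in, "</binary>\n",
    "</binaryDataArray>\n",
    "</binaryDataArrayList>\n",
    "</spectrum>\n"
  )
}

mzml_header <- function(n_spectra, standalone) {
  paste0(
    if (standalone) '<?xml version="1.0" encoding="utf-8"?>\n' else "",
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" xsi:schemaLocation="http://psi.hupo.org/ms/mzml http://psidev.info/files/ms/mzML/xsd/mzML1.1.0.xsd" id="mzlod_export" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" version="2014-04-09" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription>\n<fileContent>\n',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '</fileContent>\n</fileDescription>\n',
    '<softwareList count="1">\n<software id="mzlod" version="0.1.0">\n',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="mzlod"/>\n',
    '</software>\n</softwareList>\n',
    '<instrumentConfigurationList count="1">\n<instrumentConfiguration id="IC1">\n',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>\n',
    '</instrumentConfiguration>\n</instrumentConfigurationList>\n',
    '<dataProcessingList count="1">\n<dataProcessing id="DP1">\n',
    '<processingMethod order="1" softwareRef="mzlod">\n',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '</processingMethod>\n</dataProcessing>\n</dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="DP1">\n',
            n_spectra)
  )
}

mzml_footer <- function() "</spectrumList>\n</run>\n</mzML>\n"

#' Write a spectrum table to an mzML 1.1 file
#'
#' Emits schema-conformant mzML declaring the controlled-vocabulary terms for
#' the dialect's precision, compression and retention-time unit. With an
#' indexed dialect the document is wrapped in `indexedmzML` with correct
#' spectrum byte offsets, `indexListOffset` and SHA-1 `fileChecksum`. Output
#' is byte-identical for identical inputs, which makes fixture generation and
#' round-trip tests reproducible.
#'
#' @param spectra A spectrum table (see [spectrum_records()]); `scan_start_time`
#'   is interpreted as seconds regardless of the unit written to disk.
#' @param path Destination file path.
#' @param dialect An [mzml_dialect()].
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path, dialect = mzml_dialect()) {
  n <- nrow(spectra)
  sp <- character(n)
  for (i in seq_len(n)) {
    sp[i] <- spectrum_xml(
      index = i - 1L,
      rt_seconds = spectra$scan_start_time[i],
      ms_level = spectra$ms_level[i],
      mz = spectra$mz[[i]],
      intensity = spectra$intensity[[i]],
      dialect = dialect
    )
  }
  hdr <- mzml_header(n, standalone = !dialect$indexed)
  body <- paste0(hdr, paste(sp, collapse = ""), mzml_footer())

  if (!dialect$indexed) {
    doc <- body
  } else {
    outer_hdr <- paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml" xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" xsi:schemaLocation="http://psi.hupo.org/ms/mzml http://psidev.info/files/ms/mzML/xsd/mzML1.1.2_idx.xsd">\n'
    )
    # byte offsets of each <spectrum within the final document (ASCII: 1 char = 1 byte)
    base <- nchar(outer_hdr) + nchar(hdr)
    lens <- nchar(sp)
    offsets <- base + c(0, cumsum(lens))[seq_len(n)]
    idx_entries <- paste0(
      sprintf('<offset idRef="scan=%d">%d</offset>\n', seq_len(n), offsets),
      collapse = ""
    )
    pre_index <- paste0(outer_hdr, body)
    index_list_offset <- nchar(pre_index)
    with_index <- paste0(
      pre_index,
      '<indexList count="1">\n<index name="spectrum">\n',
      idx_entries,
      '</index>\n</indexList>\n',
      sprintf('<indexListOffset>%d</indexListOffset>\n', index_list_offset),
      '<fileChecksum>'
    )
    checksum <- digest::digest(charToRaw(with_index), algo = "sha1",
                               serialize = FALSE)
    doc <- paste0(with_index, checksum, "</fileChecksum>\n</indexedmzML>\n")
  }

  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) {
                    rlang::abort(paste0("cannot open destination: ", path),
                                 class = "mzlod_io_error", parent = e)
                  })
  on.exit(close(con))
  writeBin(charToRaw(doc), con)
  invisible(path)
}

#' Extract the first k spectra of an mzML file
#'
#' Writes a new, valid mzML file holding exactly the first `k` spectra of the
#' source, in the source's own dialect (precision, compression, index
#' wrapper, RT unit). Prefix-subset files of increasing size are the standard
#' way to measure parser scaling with file size while holding everything else
#' about the file constant.
#'
#' @param source Path to an mzML file.
#' @param k Number of leading spectra to keep, `1 <= k <=` spectrum count.
#' @param destination Output path.
#' @return `destination`, invisibly.
#' @export
subset_spectra <- function(source, k, destination) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    rlang::abort("k must be a positive integer", class = "mzlod_argument_error")
  }
  spectra <- stream_spectra(source)
  if (k > nrow(spectra)) {
    rlang::abort(sprintf("k = %d exceeds the %d spectra in %s",
                         k, nrow(spectra), source),
                 class = "mzlod_argument_error")
  }
  dialect <- attr(spectra, "dialect")
  write_mzml(spectra[seq_len(k), ], destination, dialect = dialect)
}
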