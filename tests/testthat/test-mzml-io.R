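test_that("write then stream round-trips records exactly at float64", {
  sp <- make_spectra(3, peaks = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f)
  back <- stream_spectra(f)
  expect_equal(nrow(back), 3)
  expect_identical(back$scan_start_time, sp$scan_start_time)
  expect_identical(back$ms_level, sp$ms_level)
  expect_identical(back$mz, sp$mz)
  expect_identical(back$intensity, sp$intensity)
})

test_that("streaming and reference parses agree on every dialect combination", {
  sp <- make_spectra(5, peaks = 12, seed = 7)
  for (d in all_dialects()) {
    f <- withr::local_tempfile(fileext = ".mzML")
    write_mzml(sp, f, d)
    got_s <- stream_spectra(f)
    got_r <- reference_parse(f)
    expect_identical(got_s$scan_start_time, got_r$scan_start_time)
    expect_identical(got_s$mz, got_r$mz)
    expect_identical(got_s$intensity, got_r$intensity)
    expect_identical(got_s$ms_level, got_r$ms_level)
    # observed dialect matches what was written
    obs <- attr(got_s, "dialect")
    expect_identical(obs$precision, d$precision)
    expect_identical(obs$compression, d$compression)
    expect_identical(obs$indexed, d$indexed)
    if (d$precision == "float64") {
      expect_identical(got_s$mz, sp$mz)
    } else {
      expect_equal(got_s$mz, sp$mz, tolerance = 1e-6)
    }
  }
})

test_that("indexed wrapper changes bytes but not the record sequence", {
  sp <- make_spectra(4, peaks = 8, seed = 5)
  f_plain <- withr::local_tempfile(fileext = ".mzML")
  f_idx <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f_plain, mzml_dialect(indexed = FALSE))
  write_mzml(sp, f_idx, mzml_dialect(indexed = TRUE))
  a <- stream_spectra(f_plain)
  b <- stream_spectra(f_idx)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$scan_start_time, b$scan_start_time)
  # the index block must carry the true byte offsets of each spectrum
  txt <- rawToChar(readBin(f_idx, raw(), file.size(f_idx)))
  offs <- as.integer(regmatches(txt, gregexpr("(?<=>)[0-9]+(?=</offset>)",
                                              txt, perl = TRUE))[[1]])
  for (o in offs) {
    expect_identical(substr(txt, o + 1, o + 9), "<spectrum")
  }
})

test_that("identical input and dialect produce byte-identical files", {
  sp <- make_spectra(3, peaks = 6, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".mzML")
  f2 <- withr::local_tempfile(fileext = ".mzML")
  d <- mzml_dialect("float64", "zlib", indexed = TRUE)
  write_mzml(sp, f1, d)
  write_mzml(sp, f2, d)
  expect_identical(readBin(f1, raw(), file.size(f1)),
                   readBin(f2, raw(), file.size(f2)))
})

test_that("an empty spectrumList reads back as zero records without error", {
  sp <- make_spectra(0)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f)
  expect_identical(nrow(stream_spectra(f)), 0L)
  expect_identical(nrow(reference_parse(f)), 0L)
})

test_that("minute-declared retention times are normalized to seconds", {
  sp <- make_spectra(3, peaks = 4, seed = 9, rt_step = 30)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f, mzml_dialect(rt_unit = "minute"))
  # the file itself declares minutes
  txt <- rawToChar(readBin(f, raw(), file.size(f)))
  expect_true(grepl("UO:0000031", txt, fixed = TRUE))
  back <- stream_spectra(f)
  expect_equal(back$scan_start_time, sp$scan_start_time)
  expect_identical(attr(back, "dialect")$rt_unit, "minute")
})

test_that("the first record is produced before the file is fully consumed", {
  sp <- make_spectra(120, peaks = 60, seed = 13)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f)
  s <- mzml_stream(f)
  on.exit(s$close())
  rec <- s$read_next()
  expect_identical(rec$index, 0L)
  expect_identical(rec$mz, sp$mz[[1]])
  expect_lt(s$bytes_read() / file.size(f), 0.5)
})

test_that("ms_level filtering yields only matching spectra", {
  sp <- make_spectra(6, peaks = 3, seed = 21)
  sp$ms_level <- rep(c(1L, 2L), 3)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f)
  ms1 <- stream_spectra(f, ms_level = 1)
  expect_identical(nrow(ms1), 3L)
  expect_true(all(ms1$ms_level == 1L))
  expect_identical(ms1$mz, sp$mz[c(1, 3, 5)])
  # unfiltered parse keeps every level
  expect_identical(nrow(stream_spectra(f)), 6L)
})

test_that("malformed and inconsistent files raise typed errors", {
  sp <- make_spectra(3, peaks = 4, seed = 4)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f)
  txt <- rawToChar(readBin(f, raw(), file.size(f)))

  # truncated spectrum element: parse error naming a byte offset
  cut <- regexpr("</spectrum>", txt)
  broken <- withr::local_tempfile(fileext = ".mzML")
  writeBin(charToRaw(substr(txt, 1, cut - 1)), broken)
  err <- expect_error(stream_spectra(broken), class = "mzlod_parse_error")
  expect_match(conditionMessage(err), "byte offset [0-9]+")

  # invalid XML inside a spectrum: parse error naming a byte offset
  bad <- withr::local_tempfile(fileext = ".mzML")
  writeBin(charToRaw(sub("</binaryDataArrayList>", "</wrongTag>", txt)), bad)
  expect_error(stream_spectra(bad), class = "mzlod_parse_error")

  # declared encodedLength inconsistent with the base64 payload
  mis <- withr::local_tempfile(fileext = ".mzML")
  writeBin(charToRaw(sub('encodedLength="([0-9]+)"', 'encodedLength="1"', txt)),
           mis)
  expect_error(stream_spectra(mis), class = "mzlod_integrity_error")

  # declared defaultArrayLength inconsistent with the decoded array
  dal <- withr::local_tempfile(fileext = ".mzML")
  writeBin(charToRaw(sub('defaultArrayLength="4"', 'defaultArrayLength="7"',
                         txt)), dal)
  expect_error(stream_spectra(dal), class = "mzlod_integrity_error")

  # unknown precision term
  unk <- withr::local_tempfile(fileext = ".mzML")
  writeBin(charToRaw(gsub("MS:1000523", "MS:1000522", txt, fixed = TRUE)), unk)
  expect_error(stream_spectra(unk), class = "mzlod_dialect_error")
})

test_that("an independent external reader agrees with the streaming parser", {
  # mzR (proteowizard) as a third, fully independent mzML implementation
  sp <- make_spectra(8, peaks = 15, seed = 31)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f, mzml_dialect("float64", "zlib", indexed = TRUE))
  ours <- stream_spectra(f)
  h <- mzR::openMSfile(f)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  expect_equal(nrow(hd), nrow(ours))
  expect_equal(hd$retentionTime, ours$scan_start_time)
  for (i in c(1, 4, 8)) {
    pk <- mzR::peaks(h, i)
    expect_equal(unname(pk[, 1]), ours$mz[[i]])
    expect_equal(unname(pk[, 2]), ours$intensity[[i]])
  }
})

test_that("subsetting keeps exactly the first k spectra in the same dialect", {
  sp <- make_spectra(30, peaks = 6, seed = 17)
  for (d in list(mzml_dialect(), mzml_dialect("float32", "zlib", indexed = TRUE))) {
    f <- withr::local_tempfile(fileext = ".mzML")
    g <- withr::local_tempfile(fileext = ".mzML")
    write_mzml(sp, f, d)
    src <- stream_spectra(f)
    subset_spectra(f, 20, g)
    sub <- stream_spectra(g)
    expect_identical(nrow(sub), 20L)
    expect_identical(sub$mz, src$mz[1:20])
    expect_identical(sub$intensity, src$intensity[1:20])
    d2 <- attr(sub, "dialect")
    expect_identical(d2$precision, d$precision)
    expect_identical(d2$compression, d$compression)
    expect_identical(d2$indexed, d$indexed)
  }
})

test_that("subsetting with k equal to the spectrum count reproduces the file", {
  sp <- make_spectra(10, peaks = 5, seed = 23)
  f <- withr::local_tempfile(fileext = ".mzML")
  g <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sp, f)
  subset_spectra(f, 10, g)
  expect_identical(readBin(g, raw(), file.size(g)),
                   readBin(f, raw(), file.size(f)))
  expect_error(subset_spectra(f, 11, g), class = "mzlod_argument_error")
  expect_error(subset_spectra(f, 0, g), class = "mzlod_argument_error")
})
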