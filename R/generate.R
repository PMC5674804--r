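# C13 neutron mass spacing (Da) used for isotope positions: a generator
# convention for realistic spacing, as in peptide/metabolite MS1 data.
NEUTRON_DA <- 1.003355

#' Describe one synthetic isotopic envelope
#'
#' One molecule at one charge state produces an isotopic envelope: a group of
#' co-eluting isotope traces spaced `1.003355 / charge` Th apart, each trace
#' a Gaussian elution profile over retention time. Isotope `k` sits at
#' `monoisotopic_mz + k * 1.003355 / charge` and reaches
#' `base_intensity * isotope_decay^k` at the elution apex.
#'
#' @param monoisotopic_mz m/z of isotope 0 (Th), > 0.
#' @param charge Positive integer charge state z.
#' @param num_isotopes Number of isotope traces K, >= 1.
#' @param base_intensity Apex intensity of isotope 0, > 0.
#' @param isotope_decay Per-isotope abundance ratio in (0, 1].
#' @param rt_center Elution apex (seconds).
#' @param rt_sigma Gaussian elution width (seconds), > 0.
#' @return An object of class `envelope_spec`.
#' @export
envelope_spec <- function(monoisotopic_mz, charge, num_isotopes,
                          base_intensity, isotope_decay,
                          rt_center, rt_sigma) {
  if (monoisotopic_mz <= 0) rlang::abort("monoisotopic_mz must be > 0")
  if (charge < 1 || charge != floor(charge)) {
    rlang::abort("charge must be a positive integer")
  }
  if (num_isotopes < 1) rlang::abort("num_isotopes must be >= 1")
  if (base_intensity <= 0) rlang::abort("base_intensity must be > 0")
  if (isotope_decay <= 0 || isotope_decay > 1) {
    rlang::abort("isotope_decay must be in (0, 1]")
  }
  if (rt_center < 0) rlang::abort("rt_center must be >= 0")
  if (rt_sigma <= 0) rlang::abort("rt_sigma must be > 0")
  structure(
    list(monoisotopic_mz = monoisotopic_mz, charge = as.integer(charge),
         num_isotopes = as.integer(num_isotopes),
         base_intensity = base_intensity, isotope_decay = isotope_decay,
         rt_center = rt_center, rt_sigma = rt_sigma),
    class = "envelope_spec"
  )
}

#' Draw random envelope specifications
#'
#' Samples `n` envelopes with field-realistic ranges for tryptic-peptide-like
#' MS1 data: charges 1-3, 3-6 isotopes, apex intensities log-uniform over
#' 10-10000, decay 0.5-0.9 and elution widths of 3-15 s. Deterministic under
#' `seed`.
#'
#' @param n Number of envelopes.
#' @param seed Integer seed.
#' @param mz_range,rt_range Bounds within which apexes are placed.
#' @return A list of [envelope_spec()] objects.
#' @export
random_envelopes <- function(n, seed = 1L, mz_range = c(300, 1500),
                             rt_range = c(0, 600)) {
  with_preserved_seed(seed, {
    lapply(seq_len(n), function(i) {
      envelope_spec(
        monoisotopic_mz = stats::runif(1, mz_range[1], mz_range[2] - 10),
        charge = sample(1:3, 1),
        num_isotopes = sample(3:6, 1),
        base_intensity = 10^stats::runif(1, 1, 4),
        isotope_decay = stats::runif(1, 0.5, 0.9),
        rt_center = stats::runif(1, rt_range[1], rt_range[2]),
        rt_sigma = stats::runif(1, 3, 15)
      )
    })
  })
}

#' Configure the synthetic MS1 generator
#'
#' @param seed Integer seed; identical configs generate identical output.
#' @param envelopes A list of [envelope_spec()] objects (possibly empty).
#' @param noise_count Number of noise points.
#' @param noise_intensity_range Interval for uniform noise intensities; may
#'   lie partly or wholly below the conventional cull floor of 1.
#' @param mz_range m/z bounds for noise placement (Th), min < max.
#' @param rt_range RT bounds of the run (seconds); scan times cover it.
#' @param scan_interval Seconds between consecutive spectra, > 0.
#' @param trace_floor Envelope points below this intensity are dropped
#'   (default 0.01): a Gaussian tail is not observed forever.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(seed = 1L, envelopes = list(), noise_count = 0L,
                       noise_intensity_range = c(0.01, 2),
                       mz_range = c(300, 1500), rt_range = c(0, 600),
                       scan_interval = 1, trace_floor = 0.01) {
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2]) {
    rlang::abort("mz_range must be a non-empty interval",
                 class = "mzlod_argument_error")
  }
  if (length(rt_range) != 2 || rt_range[1] > rt_range[2]) {
    rlang::abort("rt_range must be a valid interval",
                 class = "mzlod_argument_error")
  }
  if (length(noise_intensity_range) != 2 ||
      noise_intensity_range[1] > noise_intensity_range[2] ||
      noise_intensity_range[1] <= 0) {
    rlang::abort("noise_intensity_range must be a positive interval",
                 class = "mzlod_argument_error")
  }
  if (scan_interval <= 0) {
    rlang::abort("scan_interval must be > 0", class = "mzlod_argument_error")
  }
  if (noise_count < 0) {
    rlang::abort("noise_count must be >= 0", class = "mzlod_argument_error")
  }
  structure(
    list(seed = as.integer(seed), envelopes = envelopes,
         noise_count = as.integer(noise_count),
         noise_intensity_range = as.numeric(noise_intensity_range),
         mz_range = as.numeric(mz_range), rt_range = as.numeric(rt_range),
         scan_interval = as.numeric(scan_interval),
         trace_floor = as.numeric(trace_floor)),
    class = "gen_config"
  )
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

scan_times <- function(config) {
  seq(config$rt_range[1], config$rt_range[2], by = config$scan_interval)
}

#' Generate a synthetic MS1 point cloud with known truth
#'
#' Rasterizes the configured isotopic envelopes onto the scan grid — one
#' centroid per isotope trace per scan, with Gaussian elution intensity —
#' and adds uniform noise points at scan times. Envelope points whose
#' intensity falls below the trace floor are dropped. Output is fully
#' deterministic under the config seed, and every point carries a truth
#' label (`envelope` = 1-based envelope index, `NA` for noise) for test
#' bookkeeping.
#'
#' @param config A [gen_config()].
#' @return An MS point tibble with columns `id`, `mz`, `rt`, `intensity`
#'   and the truth column `envelope`.
#' @examples
#' cfg <- gen_config(seed = 7, envelopes = random_envelopes(3, seed = 7),
#'                   noise_count = 200)
#' pts <- gen_points(cfg)
#' table(is.na(pts$envelope))
#' @export
gen_points <- function(config) {
  if (!inherits(config, "gen_config")) rlang::abort("config must be a gen_config")
  times <- scan_times(config)

  env_parts <- lapply(seq_along(config$envelopes), function(j) {
    e <- config$envelopes[[j]]
    parts <- lapply(0:(e$num_isotopes - 1L), function(k) {
      mz_k <- e$monoisotopic_mz + k * NEUTRON_DA / e$charge
      int_k <- e$base_intensity * e$isotope_decay^k *
        exp(-(times - e$rt_center)^2 / (2 * e$rt_sigma^2))
      keep <- int_k >= config$trace_floor
      tibble::tibble(mz = rep(mz_k, sum(keep)), rt = times[keep],
                     intensity = int_k[keep], envelope = j)
    })
    dplyr::bind_rows(parts)
  })

  noise <- with_preserved_seed(config$seed, {
    if (config$noise_count > 0) {
      tibble::tibble(
        mz = stats::runif(config$noise_count,
                          config$mz_range[1], config$mz_range[2]),
        rt = sample(times, config$noise_count, replace = TRUE),
        intensity = stats::runif(config$noise_count,
                                 config$noise_intensity_range[1],
                                 config$noise_intensity_range[2]),
        envelope = NA_integer_
      )
    } else {
      tibble::tibble(mz = numeric(), rt = numeric(), intensity = numeric(),
                     envelope = integer())
    }
  })

  all_pts <- dplyr::bind_rows(c(env_parts, list(noise)))
  out <- tibble::tibble(
    id = if (nrow(all_pts) > 0) 0:(nrow(all_pts) - 1L) else integer(),
    mz = all_pts$mz, rt = all_pts$rt, intensity = all_pts$intensity,
    envelope = all_pts$envelope
  )
  validate_ms_points(out)
  out
}

#' Generate a synthetic mzML fixture
#'
#' Runs [gen_points()], groups the points by scan time into spectra (m/z
#' ascending within each spectrum) and writes them with [write_mzml()] in
#' the requested dialect. Parsing the file back recovers the generated
#' points — exactly at float64, within single-precision epsilon at float32.
#'
#' @param config A [gen_config()].
#' @param path Destination mzML path.
#' @param dialect An [mzml_dialect()].
#' @param truth_path Optional path for a TSV truth table (`id`, `envelope`).
#' @return The generated point tibble, invisibly.
#' @export
gen_mzml <- function(config, path, dialect = mzml_dialect(),
                     truth_path = NULL) {
  pts <- gen_points(config)
  times <- scan_times(config)
  by_scan <- lapply(times, function(t) {
    rows <- pts[pts$rt == t, ]
    rows[order(rows$mz, rows$intensity), ]
  })
  spectra <- spectrum_records(
    scan_start_time = times,
    mz = lapply(by_scan, `[[`, "mz"),
    intensity = lapply(by_scan, `[[`, "intensity"),
    ms_level = 1L
  )
  write_mzml(spectra, path, dialect)
  if (!is.null(truth_path)) {
    utils::write.table(pts[, c("id", "envelope")], truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(pts)
}
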