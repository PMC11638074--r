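# MALDI-TOF readout for linkage-cleavage quantification: smoothing,
# top-hat baseline subtraction, S/N-thresholded peak detection with
# envelope-width validation, single-point internal calibration against the
# heavy-ubiquitin standard, peak-to-moiety assignment, and the
# percent-linkage-cleaved computation.

#' Read / write a spectrum
#'
#' Two-column text (m/z, intensity; whitespace- or tab-separated, `#`
#' comments allowed) is the native format. Files ending in `.mzML` are read
#' through the mzR package when it is installed (first spectrum of the run
#' unless `scan` is given).
#'
#' @param path File path.
#' @param scan Scan index for mzML input.
#' @return A `maldi_spectrum`.
#' @export
read_spectrum <- function(path, scan = 1L) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package", call. = FALSE)
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, scan)
    mzs <- pk[, 1]; int <- pk[, 2]
  } else {
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("mz", "intensity"))
    mzs <- tab$mz; int <- tab$intensity
  }
  o <- order(mzs)
  new_spectrum(mzs[o], int[o])
}

#' @rdname read_spectrum
#' @param x A `maldi_spectrum` to write (two-column text).
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "maldi_spectrum"))
  utils::write.table(data.frame(mz = x$mz, intensity = x$intensity),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

new_spectrum <- function(mz, intensity,
                         window = if (length(mz)) range(mz) else
                           c(NA_real_, NA_real_),
                         calibrated = FALSE) {
  stopifnot(length(mz) == length(intensity), !is.unsorted(mz, strictly = TRUE),
            all(is.finite(intensity)))
  structure(list(mz = mz, intensity = intensity, window = window,
                 calibrated = calibrated),
            class = "maldi_spectrum")
}

#' Peak-processing parameters
#'
#' @param sn_threshold Minimum peak signal-to-noise ratio (default 5).
#' @param smooth_order Savitzky-Golay polynomial order (default 3).
#' @param smooth_window Filter length in points (odd, > order). Default
#'   `NULL`: twice the expected envelope FWHM in points plus one.
#' @param baseline_width Width of the top-hat structuring element in Da
#'   (default 30; must exceed the envelope width so peaks survive opening).
#' @param resolution Resolving power used to predict envelope FWHM
#'   (FWHM = m/z / R) for smoothing defaults and width validation.
#' @param width_band Acceptable peak FWHM as multiples of the predicted
#'   envelope FWHM at that mass (default 0.5-2x); candidates outside the
#'   band are rejected as artifacts (width-validation surrogate for
#'   model-based envelope fitting).
#' @param tolerance Peak-to-moiety assignment tolerance in Da after
#'   calibration (default 2).
#' @param standard_search Search half-window in Da around the standard
#'   reference during calibration (default 5).
#' @return Object of class `peak_params`.
#' @export
peak_params <- function(sn_threshold = 5, smooth_order = 3,
                        smooth_window = NULL, baseline_width = 30,
                        resolution = 1000, width_band = c(0.5, 2),
                        tolerance = 2, standard_search = 5) {
  stopifnot(sn_threshold > 0, baseline_width > 0, resolution > 0,
            tolerance > 0, standard_search > 0,
            length(width_band) == 2L, width_band[1] < width_band[2])
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window %% 2L == 1L, smooth_window > smooth_order)
  }
  structure(list(sn_threshold = sn_threshold, smooth_order = smooth_order,
                 smooth_window = smooth_window,
                 baseline_width = baseline_width, resolution = resolution,
                 width_band = width_band, tolerance = tolerance,
                 standard_search = standard_search),
            class = "peak_params")
}

default_smooth_window <- function(spectrum, params) {
  step <- stats::median(diff(spectrum$mz))
  fwhm <- stats::median(spectrum$mz) / params$resolution
  n <- 2L * floor(fwhm / step) + 1L
  max(n, params$smooth_order + 2L - (params$smooth_order %% 2L == 0L))
}

#' Savitzky-Golay smoothing
#'
#' Polynomial moving-window least-squares smoothing; preserves trace length
#' and reproduces any polynomial of degree <= the filter order exactly.
#'
#' @param spectrum A `maldi_spectrum`.
#' @param params A [peak_params()].
#' @return Smoothed `maldi_spectrum`.
#' @export
smooth_spectrum <- function(spectrum, params = peak_params()) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  n <- params$smooth_window %||% default_smooth_window(spectrum, params)
  if (n > length(spectrum$mz)) {
    stop("smoothing window longer than the spectrum", call. = FALSE)
  }
  sm <- signal::sgolayfilt(spectrum$intensity, p = params$smooth_order, n = n)
  out <- spectrum
  out$intensity <- as.numeric(sm)
  out
}

#' Top-hat baseline subtraction
#'
#' Subtracts the morphological opening (erosion followed by dilation with a
#' flat structuring element) of the trace. Flat or slowly varying baseline
#' maps to ~0 while peaks narrower than the element survive with their area
#' essentially intact.
#'
#' @inheritParams smooth_spectrum
#' @return Baseline-subtracted `maldi_spectrum`.
#' @export
subtract_baseline <- function(spectrum, params = peak_params()) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  step <- stats::median(diff(spectrum$mz))
  k <- 2L * floor(params$baseline_width / step / 2) + 1L
  opening <- morph_open(spectrum$intensity, k)
  out <- spectrum
  out$intensity <- spectrum$intensity - opening
  out
}

#' Detect peaks with S/N thresholding and width validation
#'
#' The raw trace is smoothed and baseline-subtracted (unless those steps
#' were applied already and the processed trace is passed in alongside the
#' raw one via `raw`); local maxima are taken as candidates, noise is
#' estimated robustly as 1.4826 x MAD of the raw-minus-smoothed residual,
#' and candidates are retained when (i) smoothed height / noise >= the S/N
#' threshold and (ii) the envelope FWHM lies in the acceptance band around
#' the FWHM predicted from the mass and the resolving power. Centroid is
#' the intensity-weighted mean over the envelope support; area the
#' trapezoidal integral over the support.
#'
#' @param spectrum A `maldi_spectrum`: the processed (smoothed,
#'   baseline-subtracted) trace.
#' @param params A [peak_params()].
#' @param raw Optional raw `maldi_spectrum` used for noise estimation; when
#'   `NULL` the noise is estimated from `spectrum` itself via the residual
#'   against a Savitzky-Golay re-smoothing.
#' @return Object of class `peak_set`: data frame with columns `mz`
#'   (centroid), `height`, `area`, `sn`, `fwhm`, plus attributes `noise`,
#'   `calibration_shift` (0 until calibrated) and `params`.
#' @export
detect_peaks <- function(spectrum, params = peak_params(), raw = NULL) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  if (!length(spectrum$mz)) stop("empty spectrum", call. = FALSE)
  y <- spectrum$intensity
  mz <- spectrum$mz
  # noise: robust scale of the high-frequency residual of the raw trace
  # (raw minus its own Savitzky-Golay fit); peak regions contribute little
  # and the MAD ignores what they do contribute
  trace <- if (!is.null(raw)) raw$intensity else spectrum$intensity
  ref <- signal::sgolayfilt(trace, p = params$smooth_order,
                            n = params$smooth_window %||%
                              default_smooth_window(spectrum, params))
  resid <- trace - ref
  noise <- 1.4826 * stats::mad(resid, center = 0, constant = 1)
  if (noise <= 0) noise <- .Machine$double.eps

  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y / noise >= params$sn_threshold)

  rows <- list()
  for (apex in cand) {
    # envelope support: walk out until the trace falls to the floor level
    # (1% of apex or the noise level) or starts climbing into a
    # neighbouring peak; small noise upticks are tolerated
    floor_lvl <- max(0.01 * y[apex], noise)
    climb_tol <- max(noise, 0.02 * y[apex])
    expand <- function(dir) {
      i <- apex; runmin <- y[apex]
      repeat {
        nxt <- i + dir
        if (nxt < 1L || nxt > n) break
        if (y[nxt] <= floor_lvl) { i <- nxt; break }
        if (y[nxt] > runmin + climb_tol) break
        i <- nxt
        if (y[i] < runmin) runmin <- y[i]
      }
      i
    }
    lo <- expand(-1L)
    hi <- expand(+1L)
    if (hi - lo < 3L) next
    seg_mz <- mz[lo:hi]
    seg_y <- pmax(y[lo:hi], 0)
    centroid <- sum(seg_mz * seg_y) / sum(seg_y)
    fwhm <- envelope_fwhm(mz, y, apex, lo, hi)
    expected <- centroid / params$resolution
    # integrate the area over a fixed +/- 3 sigma window of the expected
    # envelope: every peak loses the same tail fraction, so area ratios
    # stay unbiased regardless of peak height relative to the noise floor
    sig <- expected / (2 * sqrt(2 * log(2)))
    ia <- range(which(mz >= centroid - 3 * sig & mz <= centroid + 3 * sig))
    int_y <- pmax(y[ia[1]:ia[2]], 0)
    int_mz <- mz[ia[1]:ia[2]]
    area <- sum(diff(int_mz) * (int_y[-1] + int_y[-length(int_y)]) / 2)
    if (is.na(fwhm) ||
        fwhm < params$width_band[1] * expected ||
        fwhm > params$width_band[2] * expected) next
    rows[[length(rows) + 1L]] <- data.frame(
      mz = centroid, height = y[apex], area = area,
      sn = y[apex] / noise, fwhm = fwhm)
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mz = numeric(), height = numeric(), area = numeric(),
               sn = numeric(), fwhm = numeric())
  # a rippled apex can yield several candidates inside one envelope: merge
  # centroids closer than half the local envelope width, keeping the taller
  if (nrow(peaks) > 1L) {
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    for (i in 2:nrow(peaks)) {
      prev <- max(which(keep[1:(i - 1L)]))
      if (peaks$mz[i] - peaks$mz[prev] <
            0.5 * peaks$mz[i] / params$resolution) {
        if (peaks$height[i] > peaks$height[prev]) keep[prev] <- FALSE
        else keep[i] <- FALSE
      }
    }
    peaks <- peaks[keep, , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(peaks, class = c("peak_set", "data.frame"),
            noise = noise, calibration_shift = 0, params = params)
}

# full width at half maximum by linear interpolation around the apex
envelope_fwhm <- function(mz, y, apex, lo, hi) {
  half <- y[apex] / 2
  left <- NA_real_; right <- NA_real_
  i <- apex
  while (i > lo) {
    if (y[i - 1L] <= half) {
      left <- mz[i - 1L] + (mz[i] - mz[i - 1L]) *
        (half - y[i - 1L]) / (y[i] - y[i - 1L])
      break
    }
    i <- i - 1L
  }
  i <- apex
  while (i < hi) {
    if (y[i + 1L] <= half) {
      right <- mz[i] + (mz[i + 1L] - mz[i]) *
        (half - y[i]) / (y[i + 1L] - y[i])
      break
    }
    i <- i + 1L
  }
  right - left
}

#' Internally calibrate a peak set against the heavy-ubiquitin standard
#'
#' Locates the internal-standard peak within the search window around the
#' reference m/z (largest area wins when several fall inside) and applies
#' the constant offset that places its centroid exactly on the reference to
#' all centroids. Calibrating an already calibrated peak set applies a zero
#' shift. A spectrum in which the standard cannot be found is rejected: the
#' assay has no valid normalization anchor without it.
#'
#' @param peaks A `peak_set`.
#' @param reference_mz Reference position of the standard (default
#'   [UB15N_CALIBRANT_MZ], 8,669.470).
#' @param search_tol Search half-window in Da (default 5).
#' @return The calibrated `peak_set`; attribute `calibration_shift` records
#'   the applied offset and `standard_area` the standard's peak area.
#' @export
calibrate_internal <- function(peaks, reference_mz = UB15N_CALIBRANT_MZ,
                               search_tol = 5) {
  stopifnot(inherits(peaks, "peak_set"))
  hit <- which(abs(peaks$mz - reference_mz) <= search_tol)
  if (!length(hit)) {
    stop(sprintf(
      "internal standard not found: no peak within %.1f Da of %.3f; spectrum rejected",
      search_tol, reference_mz), call. = FALSE)
  }
  hit <- hit[which.max(peaks$area[hit])]
  shift <- reference_mz - peaks$mz[hit]
  out <- peaks
  out$mz <- out$mz + shift
  attr(out, "calibration_shift") <- attr(peaks, "calibration_shift") + shift
  attr(out, "standard_area") <- peaks$area[hit]
  attr(out, "standard_row") <- hit
  out
}

#' Assign calibrated peaks to theoretical moiety positions
#'
#' Each peak is assigned to the nearest theoretical m/z within the
#' tolerance; when several peaks land on one moiety the largest area wins
#' and the conflict is recorded. Requires the theory table to be
#' distinguishable at more than twice the tolerance, otherwise nearest-m/z
#' assignment is ambiguous.
#'
#' @param peaks A calibrated `peak_set`.
#' @param table Data frame from [released_moieties()] (columns `unit`,
#'   `mz`).
#' @param tolerance Assignment tolerance in Da (default from the peak-set
#'   params).
#' @return List with `assignments` (data frame: `unit`, `theory_mz`,
#'   `obs_mz`, `area`, `height`, `sn`), `unassigned` (peaks matching no
#'   moiety, e.g. metastable satellites and the standard) and `conflicts`.
#' @export
assign_peaks <- function(peaks, table, tolerance = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  tolerance <- tolerance %||% attr(peaks, "params")$tolerance
  table <- as.data.frame(table)
  stopifnot(all(c("unit", "mz") %in% names(table)))
  if (nrow(table) > 1L && min(diff(sort(table$mz))) <= 2 * tolerance) {
    stop("moiety table not distinguishable at 2 x assignment tolerance; ",
         "assignment would be ambiguous", call. = FALSE)
  }
  std_row <- attr(peaks, "standard_row") %||% integer()
  idx_all <- setdiff(seq_len(nrow(peaks)), std_row)
  nearest <- vapply(idx_all, function(i) {
    d <- abs(table$mz - peaks$mz[i])
    j <- which.min(d)
    if (d[j] <= tolerance) j else NA_integer_
  }, integer(1))
  assigned <- list(); conflicts <- list()
  for (j in seq_len(nrow(table))) {
    hits <- idx_all[which(nearest == j)]
    if (!length(hits)) next
    win <- hits[which.max(peaks$area[hits])]
    assigned[[length(assigned) + 1L]] <- data.frame(
      unit = table$unit[j], theory_mz = table$mz[j],
      obs_mz = peaks$mz[win], area = peaks$area[win],
      height = peaks$height[win], sn = peaks$sn[win],
      stringsAsFactors = FALSE)
    losers <- setdiff(hits, win)
    if (length(losers)) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        unit = table$unit[j], obs_mz = peaks$mz[losers],
        area = peaks$area[losers], stringsAsFactors = FALSE)
    }
  }
  unassigned <- idx_all[is.na(nearest)]
  list(
    assignments = if (length(assigned)) do.call(rbind, assigned) else
      data.frame(unit = character(), theory_mz = numeric(),
                 obs_mz = numeric(), area = numeric(), height = numeric(),
                 sn = numeric(), stringsAsFactors = FALSE),
    unassigned = as.data.frame(peaks)[unassigned, , drop = FALSE],
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else NULL
  )
}

#' Percent of a linkage cleaved
#'
#' The released-monoUb quantification:
#' percent = (moiety peak area / standard peak area) x
#' (\[standard\] / \[substrate\]) x 100. Values above 100 are retained and
#' flagged rather than clipped: they indicate response-factor mismatch and
#' should be visible.
#'
#' @param area Numeric vector of moiety peak areas (optionally named).
#' @param standard_area Peak area of the internal standard (> 0).
#' @param standard_conc,substrate_conc Concentrations in uM.
#' @return Data frame with columns `moiety`, `percent`, `over_100`.
#' @export
quantify_cleavage <- function(area, standard_area, standard_conc = 0.8,
                              substrate_conc = 0.96) {
  stopifnot(is.numeric(area), all(area >= 0),
            length(standard_area) == 1L,
            standard_conc > 0, substrate_conc > 0)
  if (!is.finite(standard_area) || standard_area <= 0) {
    stop("standard peak area must be positive: cannot normalize",
         call. = FALSE)
  }
  pct <- area / standard_area * (standard_conc / substrate_conc) * 100
  data.frame(
    moiety = if (!is.null(names(area))) names(area) else
      paste0("m", seq_along(area)),
    percent = as.numeric(pct),
    over_100 = as.numeric(pct) > 100,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Full spectrum-to-percent pipeline
#'
#' Smooths, baseline-subtracts, detects peaks (noise taken from the raw
#' trace residual), calibrates internally, assigns peaks to the moiety
#' table and quantifies percent cleaved per moiety. Moieties with no
#' detected peak are reported at 0%.
#'
#' @param spectrum Raw `maldi_spectrum`.
#' @param table Moiety theory table from [released_moieties()].
#' @param params A [peak_params()].
#' @param standard_mz Internal standard reference m/z.
#' @param standard_conc,substrate_conc Concentrations in uM.
#' @return Data frame as from [quantify_cleavage()] (one row per moiety in
#'   `table`), with attributes `calibration_shift`, `noise`,
#'   `standard_area` and `assignment` (the full [assign_peaks()] result).
#' @export
process_spectrum <- function(spectrum, table, params = peak_params(),
                             standard_mz = UB15N_CALIBRANT_MZ,
                             standard_conc = 0.8, substrate_conc = 0.96) {
  sm <- smooth_spectrum(spectrum, params)
  bs <- subtract_baseline(sm, params)
  pk <- detect_peaks(bs, params, raw = spectrum)
  pk <- calibrate_internal(pk, reference_mz = standard_mz,
                           search_tol = params$standard_search)
  asn <- assign_peaks(pk, table, tolerance = params$tolerance)
  area <- stats::setNames(rep(0, nrow(table)), table$unit)
  area[asn$assignments$unit] <- asn$assignments$area
  out <- quantify_cleavage(area, attr(pk, "standard_area"),
                           standard_conc, substrate_conc)
  attr(out, "calibration_shift") <- attr(pk, "calibration_shift")
  attr(out, "noise") <- attr(pk, "noise")
  attr(out, "standard_area") <- attr(pk, "standard_area")
  attr(out, "assignment") <- asn
  out
}
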