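# Seeded synthetic data: deubiquitinase reaction outcomes and
# reflectron-mode MALDI-TOF spectra of released monoUb species.
#
# The spectrum generator emulates the acquisition characteristics the
# quantification pipeline has to cope with: Gaussian envelope peaks of
# width m/R, a decaying chemical baseline, additive detector noise, a
# constant calibration offset, and metastable-ion satellite peaks.

#' Spectrum simulation parameters
#'
#' @param window Acquisition window in m/z (default 7,820-9,200, the
#'   released-monoUb detection window).
#' @param step Sampling step in m/z (default 0.2).
#' @param resolution Instrument resolving power R; envelope FWHM = m/z / R
#'   (default 1,000, i.e. ~8.5 Da FWHM at 8.5 kDa, an unresolved isotope
#'   envelope).
#' @param baseline_offset Constant baseline level (intensity units).
#' @param baseline_amp,baseline_scale Amplitude and decay scale (Da) of an
#'   exponentially decaying chemical baseline anchored at the window start.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param calibration_offset Constant m/z miscalibration delta added to all
#'   peak positions (what internal calibration must undo).
#' @param metastable Data frame with columns `shift_frac` and `rel_amp`:
#'   each row adds one satellite per parent peak at parent m/z x shift_frac
#'   with area rel_amp x parent area (synthetic defaults: one satellite at
#'   0.985 of the parent position, 5% relative amplitude). `NULL` disables.
#' @param response Named numeric vector of per-species response factors
#'   (area per unit concentration multiplier); unnamed species default to 1.
#' @param area_scale Peak area corresponding to 1 uM at response factor 1.
#' @return Object of class `spectrum_params`.
#' @export
spectrum_params <- function(window = c(7820, 9200), step = 0.2,
                            resolution = 1000,
                            baseline_offset = 20, baseline_amp = 80,
                            baseline_scale = 300, noise_sd = 1,
                            calibration_offset = 0,
                            metastable = data.frame(shift_frac = 0.985,
                                                    rel_amp = 0.05),
                            response = NULL, area_scale = 1000) {
  stopifnot(length(window) == 2L, window[1] < window[2], step > 0,
            resolution > 0, noise_sd >= 0, area_scale > 0)
  if (!is.null(response)) stopifnot(all(response > 0))
  if (!is.null(metastable)) {
    metastable <- as.data.frame(metastable)
    stopifnot(all(c("shift_frac", "rel_amp") %in% names(metastable)))
  }
  structure(list(window = window, step = step, resolution = resolution,
                 baseline_offset = baseline_offset,
                 baseline_amp = baseline_amp,
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 calibration_offset = calibration_offset,
                 metastable = metastable, response = response,
                 area_scale = area_scale),
            class = "spectrum_params")
}

#' Simulate a MALDI-TOF spectrum
#'
#' Sums Gaussian envelopes (FWHM = m/z / R) for the given species, with
#' areas proportional to concentration x response factor, all positions
#' shifted by the calibration offset; adds metastable satellites, baseline
#' and seeded additive noise. Pure function of (species, params, seed).
#'
#' @param species Data frame with columns `mz` and `conc` (uM); optionally
#'   `name` (used to look up response factors).
#' @param params A [spectrum_params()].
#' @param seed Integer seed for the noise draw (`NULL` for the ambient RNG).
#' @return Object of class `maldi_spectrum`: list with `mz`, `intensity`,
#'   `window`, and `calibrated = FALSE`.
#' @export
simulate_spectrum <- function(species, params = spectrum_params(),
                              seed = NULL) {
  stopifnot(inherits(params, "spectrum_params"))
  species <- as.data.frame(species)
  if (nrow(species)) stopifnot(all(c("mz", "conc") %in% names(species)))
  grid <- seq(params$window[1], params$window[2], by = params$step)
  signal <- numeric(length(grid))

  peaks <- data.frame(mz = numeric(), area = numeric())
  if (nrow(species)) {
    resp <- rep(1, nrow(species))
    if (!is.null(params$response) && "name" %in% names(species)) {
      hit <- match(species$name, names(params$response))
      resp[!is.na(hit)] <- params$response[hit[!is.na(hit)]]
    }
    area <- species$conc * resp * params$area_scale
    peaks <- data.frame(mz = species$mz, area = area)
    if (!is.null(params$metastable)) {
      for (r in seq_len(nrow(params$metastable))) {
        peaks <- rbind(peaks, data.frame(
          mz = species$mz * params$metastable$shift_frac[r],
          area = area * params$metastable$rel_amp[r]))
      }
    }
  }
  if (nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      center <- peaks$mz[i] + params$calibration_offset
      fwhm <- center / params$resolution
      sigma <- fwhm / (2 * sqrt(2 * log(2)))
      # skip species far outside the window
      if (center < params$window[1] - 6 * sigma ||
          center > params$window[2] + 6 * sigma) next
      signal <- signal + peaks$area[i] *
        stats::dnorm(grid, mean = center, sd = sigma)
    }
  }
  baseline <- params$baseline_offset +
    params$baseline_amp * exp(-(grid - params$window[1]) /
                                params$baseline_scale)
  noise <- with_seed(seed, stats::rnorm(length(grid), 0, params$noise_sd))
  structure(list(mz = grid, intensity = signal + baseline + noise,
                 window = params$window, calibrated = FALSE),
            class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum> %d points, %.1f-%.1f m/z%s\n",
              length(x$mz), min(x$mz), max(x$mz),
              if (isTRUE(x$calibrated)) ", calibrated" else ""))
  invisible(x)
}

#' Deubiquitinase reaction specification
#'
#' Defines an in-silico reaction: the substrate architecture, the per-edge
#' cleavage fraction (the probability that a given linkage is hydrolysed by
#' the end of the incubation, independently across linkages), and the final
#' concentrations after stop-solution dilution. The defaults follow the
#' assay format: 1.2 uM substrate in 10 ul stopped with 2.5 ul acid carrying
#' 4 uM heavy standard, giving final 0.96 uM substrate and 0.8 uM standard.
#'
#' @param arch Substrate `ub_chain` or notation string.
#' @param fractions Per-edge cleavage fractions in \[0, 1\]: a single value
#'   recycled to all edges, or a vector of length `nrow(arch$edges)` in edge
#'   row order.
#' @param substrate_conc,standard_conc Final concentrations in uM.
#' @param replicates Technical replicate count (default 2).
#' @return Object of class `reaction_spec`.
#' @export
reaction_spec <- function(arch, fractions, substrate_conc = 0.96,
                          standard_conc = 0.8, replicates = 2L) {
  if (is.character(arch)) arch <- parse_chain(arch)
  stopifnot(inherits(arch, "ub_chain"))
  n_edges <- nrow(arch$edges)
  if (length(fractions) == 1L) fractions <- rep(fractions, n_edges)
  stopifnot(length(fractions) == n_edges,
            all(fractions >= 0 & fractions <= 1),
            substrate_conc > 0, standard_conc > 0, replicates >= 1L)
  structure(list(arch = arch, fractions = as.numeric(fractions),
                 substrate_conc = substrate_conc,
                 standard_conc = standard_conc,
                 replicates = as.integer(replicates)),
            class = "reaction_spec")
}

#' Expected species composition of a reaction
#'
#' Enumerates every subset of cut linkages (linkages are cleaved
#' independently with their per-edge fractions), splits the substrate into
#' components and aggregates the expected concentration of each resulting
#' species. Released monoUb species are reported per moiety; residual
#' multi-moiety species are reported under their canonical notation. Total
#' moiety concentration is conserved.
#'
#' @param spec A [reaction_spec()].
#' @param window m/z window used to flag species as detectable.
#' @param mode Mass mode for the species m/z.
#' @return Data frame with columns `species`, `unit` (moiety id for released
#'   monoUb, `NA` for chain species), `n_units`, `mz`, `conc`,
#'   `detectable`.
#' @export
simulate_reaction <- function(spec, window = c(7820, 9200),
                              mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "reaction_spec"))
  arch <- spec$arch
  n_edges <- nrow(arch$edges)
  acc <- new.env(parent = emptyenv())
  acc$tab <- list()
  add <- function(key, row, p) {
    if (is.null(acc$tab[[key]])) {
      row$conc <- spec$substrate_conc * p
      acc$tab[[key]] <- row
    } else {
      acc$tab[[key]]$conc <- acc$tab[[key]]$conc + spec$substrate_conc * p
    }
  }
  subsets <- if (n_edges) expand.grid(rep(list(c(FALSE, TRUE)), n_edges))
             else data.frame(row.names = 1)
  for (r in seq_len(nrow(subsets))) {
    cut <- if (n_edges) which(unlist(subsets[r, ])) else integer()
    p <- prod(ifelse(seq_len(n_edges) %in% cut,
                     spec$fractions, 1 - spec$fractions))
    if (p == 0) next
    comps <- cleave_chain(arch, cut)
    for (comp in comps) {
      if (length(comp$units) == 1L) {
        u <- comp$units[[1L]]
        add(paste0("unit:", u$id),
            data.frame(species = paste0("monoUb:", u$id), unit = u$id,
                       n_units = 1L, mz = moiety_mass(u, mode)$mz,
                       conc = 0, stringsAsFactors = FALSE), p)
      } else {
        key <- format_chain(comp)[[1]]
        add(paste0("chain:", key),
            data.frame(species = key, unit = NA_character_,
                       n_units = length(comp$units),
                       mz = chain_mass(comp, mode) + MASS_PROTON,
                       conc = 0, stringsAsFactors = FALSE), p)
      }
    }
  }
  out <- do.call(rbind, unname(acc$tab))
  out$detectable <- out$mz >= window[1] & out$mz <= window[2]
  rownames(out) <- NULL
  out[order(out$mz), , drop = FALSE]
}

#' Species list for a simulated assay spectrum
#'
#' Restricts a [simulate_reaction()] table to detectable species and appends
#' the heavy-ubiquitin internal standard at its calibrant position.
#'
#' @param reaction Output of [simulate_reaction()].
#' @param standard_conc Standard concentration in uM.
#' @param standard_mz Position of the standard (default the empirical
#'   calibrant m/z, [UB15N_CALIBRANT_MZ]).
#' @return Data frame with columns `name`, `mz`, `conc` suitable for
#'   [simulate_spectrum()].
#' @export
assay_species <- function(reaction, standard_conc = 0.8,
                          standard_mz = UB15N_CALIBRANT_MZ) {
  det <- reaction[reaction$detectable, , drop = FALSE]
  data.frame(
    name = c(det$species, "Ub15N_standard"),
    mz = c(det$mz, standard_mz),
    conc = c(det$conc, standard_conc),
    stringsAsFactors = FALSE
  )
}
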