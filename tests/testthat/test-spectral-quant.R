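# Spectral pipeline: smoothing, baseline, peak detection, calibration,
# assignment, quantification, panel normalization and aggregation.

make_spectrum <- function(intensity, mz = seq(8000, 8000 + (length(intensity) - 1) * 0.2, by = 0.2)) {
  branchedub:::new_spectrum(mz, intensity)
}

test_that("Savitzky-Golay smoothing preserves polynomials and cuts noise", {
  n <- 2001
  mz <- seq(8000, 8400, length.out = n)
  # a cubic trace is reproduced exactly by an order-3 filter
  y <- 5 + 0.01 * (mz - 8200) + 1e-5 * (mz - 8200)^2 + 1e-8 * (mz - 8200)^3
  s <- make_spectrum(y, mz)
  pp <- peak_params(smooth_window = 41L, smooth_order = 3)
  sm <- smooth_spectrum(s, pp)
  core <- 50:(n - 50)  # edges are handled by padding, compare the interior
  expect_equal(sm$intensity[core], y[core], tolerance = 1e-6)
  expect_length(sm$intensity, n)

  # white noise variance is strictly reduced
  set.seed(4)
  noise <- make_spectrum(rnorm(n), mz)
  smn <- smooth_spectrum(noise, pp)
  expect_lt(var(smn$intensity[core]), var(noise$intensity[core]))

  # a delta spike spreads but keeps its summed weight
  spike <- numeric(n); spike[1000] <- 1
  sms <- smooth_spectrum(make_spectrum(spike, mz), pp)
  expect_equal(sum(sms$intensity), 1, tolerance = 1e-6)

  expect_error(smooth_spectrum(make_spectrum(rnorm(10)),
                               peak_params(smooth_window = 101L)),
               "longer than")
})

test_that("top-hat baseline subtraction removes offsets, keeps peak area", {
  n <- 6901
  mz <- seq(7820, 9200, by = 0.2)
  pp <- peak_params(baseline_width = 30)
  # constant offset maps to ~0
  flat <- make_spectrum(rep(7.5, n), mz)
  expect_lt(max(abs(subtract_baseline(flat, pp)$intensity)), 1e-9)

  # Gaussian on a linear ramp: recovered area within 5%
  sigma <- 8.6 / 2.3548
  peak <- 400 * dnorm(mz, 8500, sigma)
  ramp <- 10 + (mz - 7820) * 0.01
  bs <- subtract_baseline(make_spectrum(peak + ramp, mz), pp)
  i <- which(mz > 8500 - 5 * sigma & mz < 8500 + 5 * sigma)
  area <- sum(bs$intensity[i]) * 0.2
  expect_lt(abs(area - 400) / 400, 0.05)

  # baseline-free trace is unchanged within tolerance
  bs2 <- subtract_baseline(make_spectrum(peak, mz), pp)
  expect_lt(max(abs(bs2$intensity[i] - peak[i])) / max(peak), 0.05)
})

test_that("peak detection finds injected peaks and rejects weak ones", {
  table <- released_moieties(ultimat_substrate("branched_48"))
  species <- data.frame(mz = c(table$mz, UB15N_CALIBRANT_MZ),
                        conc = c(rep(0.5, 4), 0.8))
  pars <- spectrum_params(noise_sd = 1)  # S/N ~ 50 at these areas
  s <- simulate_spectrum(species, pars, seed = 31)
  pp <- peak_params()
  sm <- smooth_spectrum(s, pp)
  bs <- subtract_baseline(sm, pp)
  pk <- detect_peaks(bs, pp, raw = s)
  # 5 analyte peaks plus their metastable satellites in the window
  main <- pk[pk$mz > 8100, ]
  expect_identical(nrow(main[sapply(main$mz, function(m)
    min(abs(m - species$mz)) < 2), ]), 5L)
  for (mzi in species$mz) {
    expect_lt(min(abs(pk$mz - mzi)), 0.5)
  }
  expect_true(all(pk$sn >= 5))

  # an injected peak at S/N ~2 stays undetected
  weak_pars <- spectrum_params(noise_sd = 1, baseline_amp = 0,
                               baseline_offset = 0, metastable = NULL,
                               area_scale = 1000)
  h <- 2 * 1 * (8500 / 1000 / 2.3548) * sqrt(2 * pi)  # area for height 2
  weak <- simulate_spectrum(data.frame(mz = 8500, conc = h / 1000),
                            weak_pars, seed = 8)
  smw <- smooth_spectrum(weak, pp)
  bsw <- subtract_baseline(smw, pp)
  pkw <- detect_peaks(bsw, pp, raw = weak)
  expect_false(any(abs(pkw$mz - 8500) < 5))

  expect_error(detect_peaks(branchedub:::new_spectrum(numeric(),
                                                      numeric())),
               "empty")
})

test_that("internal calibration is exact, idempotent and mandatory", {
  pk <- structure(
    data.frame(mz = c(8565.2, 8671.0), height = c(10, 20),
               area = c(100, 200), sn = c(20, 40), fwhm = c(8.5, 8.6)),
    class = c("peak_set", "data.frame"),
    noise = 1, calibration_shift = 0, params = peak_params())
  cal <- calibrate_internal(pk, reference_mz = 8669.470)
  expect_equal(attr(cal, "calibration_shift"), -1.530, tolerance = 1e-9)
  expect_equal(cal$mz[2], 8669.470, tolerance = 1e-12)
  expect_equal(cal$mz[1], 8565.2 - 1.530, tolerance = 1e-9)
  # idempotence: recalibrating applies zero shift
  cal2 <- calibrate_internal(cal, reference_mz = 8669.470)
  expect_equal(attr(cal2, "calibration_shift"),
               attr(cal, "calibration_shift"), tolerance = 1e-12)
  expect_identical(cal2$mz, cal$mz)
  # already at reference: zero shift
  pk$mz[2] <- 8669.470
  expect_equal(attr(calibrate_internal(pk), "calibration_shift"), 0,
               tolerance = 1e-12)
  # no standard: explicit rejection
  pk$mz[2] <- 8700
  expect_error(calibrate_internal(pk), "standard not found")
})

test_that("peak assignment picks nearest within tolerance, flags the rest", {
  table <- data.frame(unit = c("a", "b"), mz = c(8500, 8600))
  mk <- function(mz, area) structure(
    data.frame(mz = mz, height = area / 10, area = area,
               sn = rep(50, length(mz)), fwhm = rep(8.5, length(mz))),
    class = c("peak_set", "data.frame"),
    noise = 1, calibration_shift = 0, params = peak_params())
  asn <- assign_peaks(mk(c(8500.4, 8601.1), c(100, 50)), table)
  expect_identical(asn$assignments$unit, c("a", "b"))
  # a peak 10 Da from every theory entry stays unassigned
  asn2 <- assign_peaks(mk(8510, 100), table)
  expect_identical(nrow(asn2$assignments), 0L)
  expect_identical(nrow(asn2$unassigned), 1L)
  # conflict: larger area wins, loser flagged
  asn3 <- assign_peaks(mk(c(8499.5, 8500.5), c(40, 90)), table)
  expect_identical(nrow(asn3$assignments), 1L)
  expect_equal(asn3$assignments$area, 90)
  expect_identical(nrow(asn3$conflicts), 1L)
  # ambiguous theory table rejected
  close_table <- data.frame(unit = c("a", "b"), mz = c(8500, 8503))
  expect_error(assign_peaks(mk(8500, 10), close_table), "ambiguous")
})

test_that("percent-cleaved formula and flags are exact", {
  # equal areas, equal concentrations: 100%
  expect_equal(quantify_cleavage(1, 1, 1, 1)$percent, 100)
  # area ratio 0.5 with the default concentration ratio 0.8/0.96
  q <- quantify_cleavage(50, 100, 0.8, 0.96)
  expect_equal(q$percent, 0.5 * (0.8 / 0.96) * 100, tolerance = 1e-12)
  expect_equal(round(q$percent, 1), 41.7)
  expect_equal(quantify_cleavage(0, 100)$percent, 0)
  # >100% retained and flagged, not clipped
  over <- quantify_cleavage(200, 100, 1, 1)
  expect_gt(over$percent, 100)
  expect_true(over$over_100)
  expect_error(quantify_cleavage(1, 0), "positive")
  # linear in moiety area; invariant to joint rescaling
  a <- quantify_cleavage(c(10, 20), 100)$percent
  expect_equal(a[2], 2 * a[1], tolerance = 1e-12)
  b <- quantify_cleavage(c(10, 20) * 7, 700)$percent
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("full pipeline recovers moiety percentages and is deterministic", {
  sub <- ultimat_substrate("branched_48")
  spec <- reaction_spec(sub, fractions = c(0.5, 0.75, 0.25))
  pars <- spectrum_params(noise_sd = 1, calibration_offset = -1.2)
  q1 <- ultimat_measurement(spec, pars, seed = 3)
  q2 <- ultimat_measurement(spec, pars, seed = 3)
  expect_identical(q1$percent, q2$percent)
  truth <- c(proximal = 50, branch = 9.375, k48_arm = 75, k63_arm = 25)
  agg <- tapply(q1$percent, q1$moiety, mean)
  expect_true(all(abs(agg[names(truth)] - truth) < 5))
})

test_that("panel normalization modes behave as specified", {
  panel <- data.frame(
    dub = rep(c("DUB1", "DUB2"), each = 4),
    substrate = rep(c("ctrl", "48Ub3"), 4),
    moiety = rep(c("mono", "distal"), 4),
    replicate = rep(1:2, each = 2, times = 2),
    percent = c(40, 10, 60, 14, 20, 30, 20, 30),
    is_control = rep(c(TRUE, FALSE), 4))
  none <- normalize_panel(panel, "none")
  expect_identical(none$value, none$percent)

  ctl <- normalize_panel(panel, "control_substrate")
  # DUB1 control mean = 50; its control rows normalize to 40/50 and 60/50
  expect_equal(ctl$value[ctl$dub == "DUB1" & ctl$is_control], c(0.8, 1.2))
  expect_equal(mean(ctl$value[ctl$dub == "DUB1" & ctl$is_control]), 1.0)

  dst <- normalize_panel(panel, "distal_48Ub3")
  # DUB1 reference (48Ub3 distal) mean = 12; branched-type cells scale by it
  expect_equal(dst$value[dst$dub == "DUB1" & dst$substrate == "ctrl"],
               c(40, 60) / 12)
  # reference rows normalize to their own mean
  expect_equal(mean(dst$value[dst$dub == "DUB1" &
                                dst$substrate == "48Ub3"]), 1.0)

  # all-zero reference row is flagged, not dropped
  panel0 <- panel
  panel0$percent[panel0$dub == "DUB2" & panel0$substrate == "48Ub3"] <- 0
  d0 <- normalize_panel(panel0, "distal_48Ub3")
  expect_true(all(d0$flagged[d0$dub == "DUB2"]))
  expect_true(all(is.na(d0$value[d0$dub == "DUB2"])))
  expect_identical(nrow(d0), nrow(panel0))
})

test_that("replicate aggregation keeps points and hand-computed means", {
  panel <- data.frame(
    dub = c("D", "D", "D"),
    substrate = c("s", "s", "t"),
    moiety = c("m", "m", "m"),
    replicate = c(1, 2, 1),
    percent = c(40, 60, 55))
  agg <- aggregate_replicates(panel)
  cells <- agg$cells
  expect_equal(cells$mean[cells$cell == "s:m"], 50)
  expect_identical(cells$n[cells$cell == "s:m"], 2L)
  expect_true(cells$single_replicate[cells$cell == "t:m"])
  expect_identical(nrow(agg$points), 3L)
  # wide table matches a brute-force recomputation
  expect_equal(agg$table["D", "s:m"], mean(c(40, 60)))
})

test_that("spectrum text round trip preserves the trace", {
  s <- simulate_spectrum(data.frame(mz = 8500, conc = 1),
                         spectrum_params(noise_sd = 0.5), seed = 1)
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  write_spectrum(s, tmp)
  r <- read_spectrum(tmp)
  expect_equal(r$mz, s$mz, tolerance = 1e-9)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-9)
})
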