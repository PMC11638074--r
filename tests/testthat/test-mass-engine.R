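# Mass engine: moiety and chain masses, 15N labelling, distinguishability,
# substrate design. Reference masses were frozen from an independent
# elemental-composition computation (pyteomics) on the canonical sequence.

test_that("wild-type and labelled ubiquitin masses match references", {
  wt <- moiety_mass(ub_unit())
  expect_equal(wt$mass, 8564.751, tolerance = 1e-6)   # frozen oracle value
  expect_equal(wt$mz, 8565.759, tolerance = 1e-6)
  expect_lt(abs(wt$mz - 8565.7), 0.3)                 # published value
  expect_lt(abs(wt$mass - 8564.9), 0.2)
  expect_identical(wt$n_nitrogen, 105L)               # 76 backbone + 29 side

  heavy <- moiety_mass(ub_unit(isotope = "15N"))
  expect_equal(round(heavy$mz), 8670)                 # published value
  shift <- heavy$mz - wt$mz
  expect_gt(shift, 104.2)
  expect_lt(shift, 104.8)
  expect_equal(shift, 105 * (15.0001089 - 14.0067), tolerance = 1e-9)
})

test_that("substitutions, truncations and tags shift masses correctly", {
  wt <- moiety_mass(ub_unit())$mz
  dbl <- moiety_mass(ub_unit(substitutions = c("K48R", "K63R")))$mz
  expect_equal(dbl - wt, 2 * 28.0134, tolerance = 1e-3)  # 2 x (Arg - Lys)
  # substitution order does not matter; unit id does not matter
  a <- moiety_mass(ub_unit("x", substitutions = c("K63R", "K48R")))$mz
  expect_identical(a, dbl)
  # 1-72 truncation removes L73 R74 G75 G76
  tr <- moiety_mass(ub_unit(c_term = 72L))$mz
  expect_equal(wt - tr, 113.15787 + 156.18592 + 2 * 57.05140,
               tolerance = 1e-4)
  # AviTag adds its 15 residues
  tag <- moiety_mass(ub_unit(tags = "AVI"))$mz
  expect_equal(tag - wt, 1810.962, tolerance = 1e-3)
  expect_error(ub_unit(c_term = 80L), "1-76")
  expect_error(ub_unit(tags = "FLAG"), "unknown tag")
})

test_that("monoisotopic mode is consistent and lighter than average", {
  wt_m <- moiety_mass(ub_unit(), mode = "monoisotopic")
  expect_equal(wt_m$mass, 8559.617, tolerance = 1e-3)  # frozen oracle value
  expect_lt(wt_m$mass, moiety_mass(ub_unit())$mass)
})

test_that("chain mass equals moiety sum minus one water per linkage", {
  mono <- moiety_mass(ub_unit())$mass
  expect_equal(chain_mass("Ub"), mono)
  expect_equal(chain_mass("Ub-[48]Ub"), 2 * mono - 18.01529,
               tolerance = 1e-5)
  expect_equal(chain_mass("(Ub)2-[48,63]Ub"), 3 * mono - 2 * 18.01529,
               tolerance = 1e-5)
  # additivity across the corpus, both modes
  for (nt in notation_corpus) {
    x <- parse_chain(nt)
    for (mode in c("average", "monoisotopic")) {
      water <- if (mode == "average") 18.01529 else 18.01056
      tab <- released_moieties(x, mode)
      expect_equal(chain_mass(x, mode),
                   sum(tab$mz - 1.00728) - nrow(x$edges) * water,
                   tolerance = 1e-6, label = paste(nt, mode))
    }
  }
})

test_that("released-moiety tables are complete and sorted", {
  x <- ultimat_substrate("branched_48")
  tab <- released_moieties(x)
  expect_setequal(tab$unit, names(x$units))
  expect_false(is.unsorted(tab$mz))
  # homotypic wild-type trimer: identical masses (a design violation that
  # the distinguishability check must surface)
  tri <- released_moieties(parse_chain("48Ub3"))
  expect_length(unique(round(tri$mz, 6)), 1L)
  expect_false(check_distinguishability(tri)$pass)
  expect_identical(check_distinguishability(tri)$min_gap, 0)
})

test_that("distinguishability reports the minimum pairwise gap", {
  # the published four-moiety set plus the heavy standard
  rep_ <- check_distinguishability(c(8181.3, 8565.7, 8622.2, 8729.9),
                                   standard_mz = 8670, threshold = 20)
  expect_true(rep_$pass)
  expect_equal(rep_$min_gap, 47.8, tolerance = 1e-9)
  # identical masses fail
  expect_false(check_distinguishability(c(8565.7, 8565.7),
                                        standard_mz = NULL)$pass)
  # singleton vs standard 60 Da away passes at threshold 20
  expect_true(check_distinguishability(8609.470, threshold = 20)$pass)
})

test_that("substrate design matches the brute-force optimum", {
  skeleton <- parse_chain("(Ub)2-[48,63]Ub-[48]Ub")
  pool <- list(
    ub_unit("p1"),
    ub_unit("p2", substitutions = c("K6R", "K11R")),
    ub_unit("p3", substitutions = c("K6R", "K11R", "K27R", "K29R", "K33R")),
    ub_unit("p4", c_term = 72L),
    ub_unit("p5", substitutions = "K6R")
  )
  des <- design_substrate(skeleton, pool, threshold = 20)
  expect_true(des$pass)
  expect_true(is_isomorphic_topology <- inherits(des$chain, "ub_chain"))

  # independent brute force over all ordered selections of 4 of 5
  positions <- names(skeleton$units)
  needed <- lapply(positions,
                   function(p) skeleton$edges$site[skeleton$edges$proximal == p])
  is_distal <- positions %in% skeleton$edges$distal
  pool_mz <- vapply(pool, function(u) moiety_mass(u)$mz, numeric(1))
  best <- -Inf
  for (sel in all_selections(5L, 4L)) {
    ok <- TRUE
    for (i in seq_along(positions)) {
      u <- pool[[sel[i]]]
      if (is_distal[i] && u$c_term < 76L) { ok <- FALSE; break }
      if (!all(needed[[i]] %in% available_sites(u))) { ok <- FALSE; break }
    }
    if (!ok) next
    gaps <- diff(sort(c(pool_mz[sel], UB15N_CALIBRANT_MZ)))
    best <- max(best, min(gaps))
  }
  expect_equal(des$min_gap, best, tolerance = 1e-9)
  # deterministic: repeated calls give the identical assignment
  expect_identical(des$assignment,
                   design_substrate(skeleton, pool, threshold = 20)$assignment)

  # two identical variants for a 2-unit skeleton fail at any threshold
  expect_error(
    design_substrate("Ub-[48]Ub", list(ub_unit("a"), ub_unit("b")),
                     threshold = 1),
    "infeasible")
  # truncation cannot sit at a distal position
  expect_error(
    design_substrate("Ub-[48]Ub",
                     list(ub_unit("a", c_term = 72L),
                          ub_unit("b", c_term = 70L)),
                     threshold = 1),
    "infeasible")
})

test_that("built-in mass-tagged substrates are distinguishable", {
  for (type in c("branched_48", "branched_63", "48Ub3", "63Ub3")) {
    tab <- released_moieties(ultimat_substrate(type))
    rep_ <- check_distinguishability(tab, threshold = 20)
    expect_true(rep_$pass, label = type)
  }
})
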