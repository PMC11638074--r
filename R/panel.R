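# Panel-level operations: the mass-tagged substrate constructors, replicate
# aggregation and the two normalization modes used for DUB cleavage panels.

#' Mass-tagged substrate chains
#'
#' Ready-made substrate architectures whose moieties are distinct sequence
#' variants, so that every released monoUb (plus the heavy standard) is
#' mass-distinguishable. Positions are named by their role. The variant
#' layout used here: the proximal (root) moiety is C-terminally truncated
#' (Ub 1-72); trunk moieties carry K6R/K11R; the K63-arm moiety carries
#' five K-to-R substitutions (keeping K48 and K63); arm/distal moieties
#' that need no free sites stay wild type.
#'
#' @param type One of `"branched_48"` (`(Ub)2-[48,63]Ub-[48]Ub`),
#'   `"branched_63"` (`(Ub)2-[48,63]Ub-[63]Ub`), `"48Ub3"` or `"63Ub3"`
#'   (mass-tagged homotypic trimers).
#' @return A validated `ub_chain` with role-named units (`proximal`,
#'   `branch`, `k48_arm`, `k63_arm` for tetramers; `proximal`, `middle`,
#'   `distal` for trimers).
#' @export
ultimat_substrate <- function(type = c("branched_48", "branched_63",
                                       "48Ub3", "63Ub3")) {
  type <- match.arg(type)
  root <- ub_unit("proximal", c_term = 72L)
  tagged <- function(id) ub_unit(id, substitutions = c("K6R", "K11R"))
  heavy_arm <- ub_unit("k63_arm",
                       substitutions = c("K6R", "K11R", "K27R", "K29R",
                                         "K33R"))
  if (type %in% c("branched_48", "branched_63")) {
    trunk_site <- if (type == "branched_48") "K48" else "K63"
    units <- list(root, tagged("branch"), ub_unit("k48_arm"), heavy_arm)
    edges <- data.frame(
      distal = c("branch", "k48_arm", "k63_arm"),
      proximal = c("proximal", "branch", "branch"),
      site = c(trunk_site, "K48", "K63"), stringsAsFactors = FALSE)
  } else {
    site <- if (type == "48Ub3") "K48" else "K63"
    units <- list(root, tagged("middle"), ub_unit("distal"))
    edges <- data.frame(distal = c("middle", "distal"),
                        proximal = c("proximal", "middle"),
                        site = site, stringsAsFactors = FALSE)
  }
  ub_chain(units, edges)
}

#' Simulate and quantify a full assay measurement
#'
#' Convenience wrapper tying the generators to the pipeline: builds the
#' expected species for a reaction, simulates one spectrum per technical
#' replicate and runs the complete quantification on each.
#'
#' @param spec A [reaction_spec()].
#' @param params A [spectrum_params()] for the simulation.
#' @param detection A [peak_params()] for the processing.
#' @param seed Integer seed; replicate r uses `seed + r - 1`.
#' @return Data frame with columns `replicate`, `moiety`, `percent`,
#'   `over_100`.
#' @export
ultimat_measurement <- function(spec, params = spectrum_params(),
                                detection = peak_params(), seed = 1L) {
  stopifnot(inherits(spec, "reaction_spec"))
  reaction <- simulate_reaction(spec)
  species <- assay_species(reaction, standard_conc = spec$standard_conc)
  table <- released_moieties(spec$arch)
  out <- lapply(seq_len(spec$replicates), function(r) {
    s <- simulate_spectrum(species, params, seed = seed + r - 1L)
    q <- process_spectrum(s, table, detection,
                          standard_conc = spec$standard_conc,
                          substrate_conc = spec$substrate_conc)
    cbind(replicate = r, q)
  })
  do.call(rbind, out)
}

#' Normalize a cleavage panel
#'
#' A panel is a long-format data frame of percent-cleaved values with one
#' row per (dub, substrate, moiety, replicate). Three modes:
#' `"none"` returns the raw percentages; `"control_substrate"` divides each
#' enzyme's values by that enzyme's mean percent on its control substrate
#' (rows with `is_control == TRUE`); `"distal_48Ub3"` divides by the mean
#' percent of the distal moiety of the homotypic K48 trimer for the same
#' enzyme. Rows whose reference is missing or zero are flagged (`value` set
#' `NA`, `flagged` `TRUE`) rather than dropped.
#'
#' @param panel Data frame with columns `dub`, `substrate`, `moiety`,
#'   `replicate`, `percent`, and `is_control` (logical; required for
#'   `control_substrate` mode).
#' @param mode Normalization mode.
#' @param reference For `distal_48Ub3` mode, a list naming the reference
#'   cell (defaults `substrate = "48Ub3"`, `moiety = "distal"`).
#' @return The panel with columns `value` (normalized) and `flagged` added.
#' @export
normalize_panel <- function(panel,
                            mode = c("none", "control_substrate",
                                     "distal_48Ub3"),
                            reference = list(substrate = "48Ub3",
                                             moiety = "distal")) {
  mode <- match.arg(mode)
  panel <- as.data.frame(panel)
  stopifnot(all(c("dub", "substrate", "moiety", "percent") %in% names(panel)))
  panel$flagged <- FALSE
  if (mode == "none") {
    panel$value <- panel$percent
    return(panel)
  }
  ref_rows <- switch(mode,
    control_substrate = {
      if (!"is_control" %in% names(panel)) {
        stop("control_substrate mode needs an is_control column",
             call. = FALSE)
      }
      panel$is_control
    },
    distal_48Ub3 =
      panel$substrate == reference$substrate &
      panel$moiety == reference$moiety
  )
  ref_mean <- tapply(panel$percent[ref_rows], panel$dub[ref_rows], mean)
  ref <- as.vector(ref_mean[as.character(panel$dub)])
  bad <- is.na(ref) | ref == 0
  panel$value <- ifelse(bad, NA_real_, panel$percent / ref)
  panel$flagged <- as.logical(bad)
  panel
}

#' Aggregate replicate measurements into a heat-map table
#'
#' Computes the per-cell mean over replicates while retaining the
#' individual replicate points (heat maps of this assay display both).
#'
#' @param panel Long-format panel with a `value` column (e.g. from
#'   [normalize_panel()]) or a `percent` column.
#' @param path Optional CSV file to write the wide mean table to.
#' @return List with `table` (wide matrix: dub x substrate:moiety cell
#'   means), `cells` (long data frame with `mean` and `n` per cell) and
#'   `points` (the input replicate-level rows).
#' @export
aggregate_replicates <- function(panel, path = NULL) {
  panel <- as.data.frame(panel)
  val <- if ("value" %in% names(panel)) panel$value else panel$percent
  stopifnot(!is.null(val),
            all(c("dub", "substrate", "moiety") %in% names(panel)))
  cell <- interaction(panel$substrate, panel$moiety, sep = ":",
                      drop = TRUE, lex.order = TRUE)
  agg <- stats::aggregate(
    list(mean = val),
    by = list(dub = panel$dub, cell = cell),
    FUN = mean)
  ns <- stats::aggregate(list(n = val),
                         by = list(dub = panel$dub, cell = cell),
                         FUN = length)
  cells <- merge(agg, ns, by = c("dub", "cell"))
  cells$single_replicate <- cells$n == 1L
  wide <- stats::xtabs(mean ~ dub + cell, data = cells)
  wide <- as.matrix(unclass(wide))
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(wide), path)
  }
  list(table = wide, cells = cells, points = panel)
}
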