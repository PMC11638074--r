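# Mass engine: average/monoisotopic masses and singly protonated m/z of
# ubiquitin variants and whole chains, distinguishability checks for
# mass-tagged substrates, and exhaustive variant-to-position design.
#
# Average mode is the working default: intact ~8.5 kDa proteins in
# reflectron mode are detected as unresolved isotope envelopes, whose
# centroid corresponds to the average mass.

# one-letter residue vector of a unit's actual sequence
unit_residues <- function(unit) {
  res <- strsplit(UB_SEQUENCE, "")[[1]][seq_len(unit$c_term)]
  for (s in unit$substitutions) {
    pos <- as.integer(sub("^K([0-9]+)R$", "\\1", s))
    if (pos <= unit$c_term) res[pos] <- "R"
  }
  for (tag in unit$tags) {
    res <- c(res, strsplit(UB_TAG_SEQUENCES[[tag]], "")[[1]])
  }
  res
}

#' Mass and singly protonated m/z of one ubiquitin moiety
#'
#' Computes the neutral mass of the free (fully released) moiety from its
#' residue composition: canonical ubiquitin modified by the unit's
#' substitutions, C-terminal truncation and appended tags, plus one water.
#' Uniform 15N labelling adds (number of nitrogen atoms) x (per-nitrogen
#' mass shift); wild-type ubiquitin carries 105 nitrogens.
#'
#' @param unit A [ub_unit()] (or a chain notation string for a single
#'   moiety).
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @return List with `mass` (neutral, Da), `mz` (singly protonated) and
#'   `n_nitrogen`.
#' @examples
#' moiety_mass(ub_unit())$mz              # wild type, ~8565.8
#' moiety_mass(ub_unit(isotope = "15N"))  # heavy standard, ~8670
#' @export
moiety_mass <- function(unit, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(unit)) {
    ch <- parse_chain(unit)
    if (length(ch$units) != 1L) {
      stop("notation describes a chain; use chain_mass() or ",
           "released_moieties()", call. = FALSE)
    }
    unit <- ch$units[[1L]]
  }
  stopifnot(inherits(unit, "ub_unit"))
  res <- unit_residues(unit)
  tab <- if (mode == "average") AA_MASS_AVG else AA_MASS_MONO
  water <- if (mode == "average") MASS_WATER_AVG else MASS_WATER_MONO
  mass <- sum(tab[res]) + water
  n_n <- sum(AA_NITROGEN[res])
  if (unit$isotope == "15N") {
    shift <- if (mode == "average") N15_SHIFT_AVG else N15_SHIFT_MONO
    mass <- mass + n_n * shift
  }
  list(mass = mass, mz = mass + MASS_PROTON, n_nitrogen = n_n)
}

#' Neutral mass of an intact (uncleaved) chain
#'
#' Sum of the free moiety masses minus one water per linkage (each
#' isopeptide/peptide bond is a condensation). Intact chain species fall
#' above the usual released-monoUb detection window and are tracked for
#' bookkeeping only.
#'
#' @param x A `ub_chain` or chain notation string.
#' @inheritParams moiety_mass
#' @return Neutral mass in Da.
#' @export
chain_mass <- function(x, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(x)) x <- parse_chain(x)
  stopifnot(inherits(x, "ub_chain"))
  water <- if (mode == "average") MASS_WATER_AVG else MASS_WATER_MONO
  sum(vapply(x$units, function(u) moiety_mass(u, mode)$mass, numeric(1))) -
    nrow(x$edges) * water
}

#' Theoretical m/z table of released moieties
#'
#' For every moiety of the architecture, the singly protonated m/z of that
#' unit fully liberated (all of its linkages cleaved). This is the lookup
#' table that a mass-tagged substrate design must render pairwise
#' distinguishable.
#'
#' @param x A `ub_chain` or notation string.
#' @inheritParams moiety_mass
#' @return Data frame with columns `unit`, `signature` (sequence-variant
#'   description), `mz`, `mode`, sorted by m/z.
#' @export
released_moieties <- function(x, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(x)) x <- parse_chain(x)
  stopifnot(inherits(x, "ub_chain"))
  out <- data.frame(
    unit = names(x$units),
    signature = vapply(x$units, function(u) {
      s <- unit_signature(u); if (nzchar(s)) paste0("Ub", s) else "Ub"
    }, character(1)),
    mz = vapply(x$units, function(u) moiety_mass(u, mode)$mz, numeric(1)),
    mode = mode,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$mz), , drop = FALSE]
}

#' Check pairwise mass distinguishability
#'
#' Computes all pairwise m/z gaps among the released-moiety table plus the
#' internal standard and compares the minimum gap against a threshold. The
#' assay requires every released species (and the standard) to occupy a
#' distinct, well-separated position.
#'
#' @param mz Numeric vector of moiety m/z values, or a table from
#'   [released_moieties()].
#' @param standard_mz m/z of the internal standard ([UB15N_CALIBRANT_MZ] by
#'   default); use `NULL` to check the moieties alone.
#' @param threshold Minimum acceptable gap in Da (default 20, comfortably
#'   above the envelope width at this mass while far below typical tag
#'   spacings of ~30-60 Da).
#' @return List with `min_gap`, `threshold`, `pass`, and `closest` (the
#'   pair of m/z values realizing the minimum gap).
#' @export
check_distinguishability <- function(mz, standard_mz = UB15N_CALIBRANT_MZ,
                                     threshold = 20) {
  if (is.data.frame(mz)) mz <- mz$mz
  stopifnot(is.numeric(mz), length(mz) >= 1L, threshold > 0)
  all_mz <- sort(c(mz, standard_mz))
  if (length(all_mz) < 2L) {
    return(list(min_gap = Inf, threshold = threshold, pass = TRUE,
                closest = numeric()))
  }
  gaps <- diff(all_mz)
  i <- which.min(gaps)
  list(min_gap = gaps[i], threshold = threshold,
       pass = gaps[i] >= threshold, closest = all_mz[c(i, i + 1L)])
}

#' Design a mass-distinguishable substrate
#'
#' Exhaustively assigns sequence variants from a pool to the positions of a
#' chain skeleton so that every released moiety (and the internal standard)
#' is mass-distinguishable. An assignment is admissible when C-terminally
#' truncated variants sit only at positions that are never the distal end
#' of a linkage (the root) and when substitutions do not remove a site the
#' position needs for its distal arms. Among admissible assignments the one
#' maximizing the minimum pairwise m/z gap is returned, with deterministic
#' tie-breaking by enumeration order of pool indices.
#'
#' @param skeleton A `ub_chain` (or notation) giving the required topology;
#'   its unit modifications are ignored, only positions and linkage sites
#'   matter.
#' @param pool List of [ub_unit()] templates (ids ignored); must contain at
#'   least as many variants as the skeleton has positions.
#' @param standard_mz Internal standard m/z included in the gap computation.
#' @param threshold Required minimum gap in Da.
#' @inheritParams moiety_mass
#' @return List with `chain` (the skeleton re-equipped with the chosen
#'   variants), `assignment` (pool index per position id), `min_gap` and
#'   `pass`. Errors when no admissible assignment exists or the best
#'   admissible assignment stays below the threshold.
#' @export
design_substrate <- function(skeleton, pool,
                             standard_mz = UB15N_CALIBRANT_MZ,
                             threshold = 20,
                             mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (is.character(skeleton)) skeleton <- parse_chain(skeleton)
  stopifnot(inherits(skeleton, "ub_chain"))
  if (inherits(pool, "ub_unit")) pool <- list(pool)
  stopifnot(all(vapply(pool, inherits, logical(1), "ub_unit")))
  positions <- names(skeleton$units)
  if (length(pool) < length(positions)) {
    stop("variant pool smaller than the number of positions", call. = FALSE)
  }
  pool_mz <- vapply(pool, function(u) moiety_mass(u, mode)$mz, numeric(1))
  # per-position admissibility of each pool variant
  needed_sites <- lapply(positions, function(p) {
    skeleton$edges$site[skeleton$edges$proximal == p]
  })
  is_distal <- positions %in% skeleton$edges$distal
  admissible <- vapply(seq_along(pool), function(j) {
    vapply(seq_along(positions), function(i) {
      u <- pool[[j]]
      if (is_distal[i] && u$c_term < 76L) return(FALSE)
      all(needed_sites[[i]] %in% available_sites(u))
    }, logical(1))
  }, logical(length(positions)))
  admissible <- matrix(admissible, nrow = length(positions))

  perms <- ordered_selections(length(pool), length(positions))
  best <- NULL; best_gap <- -Inf; any_admissible <- FALSE
  for (r in seq_len(nrow(perms))) {
    sel <- perms[r, ]
    ok <- all(admissible[cbind(seq_along(positions), sel)])
    if (!ok) next
    any_admissible <- TRUE
    gap <- check_distinguishability(pool_mz[sel], standard_mz,
                                    threshold = threshold)$min_gap
    if (gap > best_gap) { best_gap <- gap; best <- sel }
  }
  if (!any_admissible) {
    bad <- which(!apply(admissible, 1L, any))
    stop("infeasible design: no admissible variant for position(s) ",
         paste(positions[bad], collapse = ", "),
         " (truncation at a distal position or required linkage site ",
         "removed)", call. = FALSE)
  }
  if (best_gap < threshold) {
    stop(sprintf(
      "infeasible design: best admissible assignment reaches a minimum gap of %.1f Da (< threshold %.1f Da)",
      best_gap, threshold), call. = FALSE)
  }
  units <- lapply(seq_along(positions), function(i) {
    u <- pool[[best[i]]]
    u$id <- positions[i]
    u
  })
  chain <- ub_chain(units, skeleton$edges)
  list(chain = chain,
       assignment = stats::setNames(best, positions),
       min_gap = best_gap, pass = TRUE)
}

# all ordered selections of k distinct indices out of n, in lexicographic
# order (rows); n^k scan is fine at the design sizes used here
ordered_selections <- function(n, k) {
  grid <- do.call(expand.grid, rev(replicate(k, seq_len(n), simplify = FALSE)))
  grid <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
  dimnames(grid) <- NULL
  keep <- apply(grid, 1L, function(r) !anyDuplicated(r))
  grid[keep, , drop = FALSE]
}
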