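# Data model for polyubiquitin chain architectures.
#
# A chain is a rooted tree of ubiquitin moieties. Edges point from a distal
# unit (whose C-terminal G76 forms the isopeptide/peptide bond) to an
# attachment site on a more proximal unit. The root is the proximal-most
# moiety (the one that would carry the substrate or free C-terminus).

#' Admissible ubiquitin attachment sites
#'
#' The eight sites through which a distal ubiquitin can be conjugated:
#' the N-terminal methionine (M1, written `1` in chain notation) and the
#' seven lysines. The vector is ordered; this order is used throughout for
#' canonicalization.
#'
#' @format Character vector of length 8.
#' @export
UB_SITES <- c("M1", "K6", "K11", "K27", "K29", "K33", "K48", "K63")

# numeric tokens used in notation ("1", "6", ..., "63")
site_token <- function(site) sub("^[MK]", "", site)
site_from_token <- function(tok) {
  site <- UB_SITES[match(tok, site_token(UB_SITES))]
  if (anyNA(site)) {
    stop("unknown attachment site label(s): ",
         paste(tok[is.na(site)], collapse = ", "), call. = FALSE)
  }
  site
}

#' Construct a ubiquitin moiety
#'
#' Describes one ubiquitin unit of a chain: the canonical human 76-residue
#' sequence optionally modified by lysine-to-arginine substitutions (which
#' remove the corresponding attachment site), a C-terminal truncation, short
#' appended sequence tags and a uniform nitrogen-isotope label.
#'
#' @param id Opaque unit identifier (unique within a chain).
#' @param substitutions Character vector of site knockouts written as residue
#'   swaps, e.g. `"K48R"`.
#' @param c_term Last residue retained (76 for full length; e.g. 72 for the
#'   Ub 1-72 truncation, which removes the C-terminal G76 needed to form a
#'   distal bond).
#' @param tags Character vector of appended tags; currently `"AVI"` (the
#'   15-residue biotin-acceptor AviTag) is built in.
#' @param isotope `"natural"` or `"15N"` (uniform nitrogen-15 labelling).
#' @return An object of class `ub_unit`.
#' @export
ub_unit <- function(id = "u1", substitutions = character(), c_term = 76L,
                    tags = character(), isotope = c("natural", "15N")) {
  isotope <- match.arg(isotope)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  c_term <- as.integer(c_term)
  if (is.na(c_term) || c_term < 1L || c_term > 76L) {
    stop("truncation must keep residues within 1-76", call. = FALSE)
  }
  substitutions <- unique(as.character(substitutions))
  bad <- !grepl("^K(6|11|27|29|33|48|63)R$", substitutions)
  if (any(bad)) {
    stop("unrecognized substitution(s): ",
         paste(substitutions[bad], collapse = ", "),
         " (expected e.g. \"K48R\")", call. = FALSE)
  }
  tags <- as.character(tags)
  unknown <- setdiff(tags, names(UB_TAG_SEQUENCES))
  if (length(unknown)) {
    stop("unknown tag(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(id = id, substitutions = sort_substitutions(substitutions),
         c_term = c_term, tags = sort(tags), isotope = isotope),
    class = "ub_unit"
  )
}

sort_substitutions <- function(subs) {
  if (!length(subs)) return(character())
  site <- sub("R$", "", subs)
  subs[order(match(site, UB_SITES))]
}

#' @export
print.ub_unit <- function(x, ...) {
  cat("<ub_unit>", x$id, unit_signature(x), "\n")
  invisible(x)
}

# Sites still available for accepting a distal ubiquitin on this unit.
#' Available attachment sites of a moiety
#'
#' All admissible sites minus those removed by substitutions or truncated
#' away. M1 is always retained (position 1); lysine sites beyond the
#' truncation point are unavailable.
#'
#' @param unit A [ub_unit()].
#' @return Character vector, subset of [UB_SITES].
#' @export
available_sites <- function(unit) {
  stopifnot(inherits(unit, "ub_unit"))
  removed <- sub("R$", "", unit$substitutions)
  pos <- c(M1 = 1L, K6 = 6L, K11 = 11L, K27 = 27L, K29 = 29L, K33 = 33L,
           K48 = 48L, K63 = 63L)
  keep <- UB_SITES[pos[UB_SITES] <= unit$c_term]
  setdiff(keep, removed)
}

# Canonical description of a unit's sequence modifications, ignoring its id.
# Used for isomorphism checks and for rendering the `{...}` modifier block.
unit_signature <- function(unit) {
  mods <- unit$substitutions
  if (unit$c_term < 76L) mods <- c(mods, paste0("1-", unit$c_term))
  mods <- c(mods, unit$tags)
  if (unit$isotope == "15N") mods <- c(mods, "15N")
  if (!length(mods)) "" else paste0("{", paste(mods, collapse = ","), "}")
}

#' Construct a chain architecture
#'
#' Assembles moieties and site-labelled linkage edges into a rooted tree and
#' validates all structural invariants: the edges form a tree with a single
#' root; each (proximal unit, site) pair is used at most once; every edge
#' site is available on its proximal unit; and no truncated unit is the
#' distal end of an edge (its G76 is missing, so it cannot be ligated).
#'
#' @param units List of [ub_unit()] objects with unique ids.
#' @param edges Data frame with character columns `distal`, `proximal`,
#'   `site` (site given as `"K48"` etc.), or `NULL` for a single moiety.
#' @return An object of class `ub_chain` with elements `units` (named list),
#'   `edges` (data frame) and `root` (unit id).
#' @export
ub_chain <- function(units, edges = NULL) {
  if (inherits(units, "ub_unit")) units <- list(units)
  stopifnot(length(units) >= 1L,
            all(vapply(units, inherits, logical(1), "ub_unit")))
  ids <- vapply(units, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate unit ids", call. = FALSE)
  names(units) <- ids
  if (is.null(edges)) {
    edges <- data.frame(distal = character(), proximal = character(),
                        site = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("distal", "proximal", "site") %in% names(edges)))
  edges <- edges[, c("distal", "proximal", "site")]
  x <- structure(list(units = units, edges = edges, root = NA_character_),
                 class = "ub_chain")
  validate_ub_chain(x)
}

#' Validate a chain architecture
#'
#' @param x A `ub_chain`.
#' @return `x` invisibly-checked (with the root slot filled in); errors with
#'   an explicit message when any invariant is violated.
#' @export
validate_ub_chain <- function(x) {
  stopifnot(inherits(x, "ub_chain"))
  ids <- names(x$units)
  e <- x$edges
  if (nrow(e) != length(ids) - 1L) {
    stop("edges must form a tree: need |units| - 1 edges", call. = FALSE)
  }
  if (nrow(e)) {
    if (!all(e$distal %in% ids) || !all(e$proximal %in% ids)) {
      stop("edge references unknown unit id", call. = FALSE)
    }
    if (anyDuplicated(e$distal)) {
      stop("a unit is the distal end of more than one edge", call. = FALSE)
    }
    if (anyDuplicated(paste(e$proximal, e$site))) {
      stop("duplicate (proximal, site) attachment", call. = FALSE)
    }
    for (i in seq_len(nrow(e))) {
      pu <- x$units[[e$proximal[i]]]
      du <- x$units[[e$distal[i]]]
      if (!e$site[i] %in% UB_SITES) {
        stop("unknown site label: ", e$site[i], call. = FALSE)
      }
      if (!e$site[i] %in% available_sites(pu)) {
        stop("site ", e$site[i], " is not available on unit ", pu$id,
             " (substituted or truncated away)", call. = FALSE)
      }
      if (du$c_term < 76L) {
        stop("unit ", du$id, " is C-terminally truncated and cannot be the ",
             "distal end of an edge (no G76 to ligate)", call. = FALSE)
      }
    }
  }
  root <- setdiff(ids, e$distal)
  if (length(root) != 1L) {
    stop("architecture must have exactly one root", call. = FALSE)
  }
  # connectivity/acyclicity: walk from the root
  children <- split(e$distal, factor(e$proximal, levels = ids))
  seen <- character()
  queue <- root
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    if (u %in% seen) stop("cycle detected in edges", call. = FALSE)
    seen <- c(seen, u)
    queue <- c(queue, children[[u]])
  }
  if (length(seen) != length(ids)) {
    stop("edges do not connect all units", call. = FALSE)
  }
  x$root <- root
  x
}

#' @export
print.ub_chain <- function(x, ...) {
  cat("<ub_chain> ", format_chain(x), "\n", sep = "")
  cat("  units: ", length(x$units), ", edges: ", nrow(x$edges),
      ", topology: ", classify_topology(x), "\n", sep = "")
  invisible(x)
}

#' Number of moieties in a chain
#' @param x A `ub_chain`.
#' @return Integer count of ubiquitin units.
#' @export
chain_length <- function(x) {
  stopifnot(inherits(x, "ub_chain"))
  length(x$units)
}

# distal children of `id`, ordered by site for canonical traversal
chain_children <- function(x, id) {
  e <- x$edges[x$edges$proximal == id, , drop = FALSE]
  e[order(match(e$site, UB_SITES)), , drop = FALSE]
}

#' Test two architectures for isomorphism
#'
#' Two chains are isomorphic when there is a relabeling of unit ids mapping
#' one tree onto the other that preserves linkage sites and every unit's
#' sequence modifications. Implemented by recursive comparison of canonical
#' subtree encodings, independently of the notation formatter.
#'
#' @param a,b `ub_chain` objects.
#' @return Logical scalar.
#' @export
is_isomorphic <- function(a, b) {
  stopifnot(inherits(a, "ub_chain"), inherits(b, "ub_chain"))
  encode <- function(x, id) {
    ch <- chain_children(x, id)
    subs <- character()
    if (nrow(ch)) {
      subs <- vapply(seq_len(nrow(ch)), function(i) {
        paste0(ch$site[i], ":", encode(x, ch$distal[i]))
      }, character(1))
      subs <- sort(subs)
    }
    paste0("(", unit_signature(x$units[[id]]), "|",
           paste(subs, collapse = ";"), ")")
  }
  identical(encode(a, a$root), encode(b, b$root))
}
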