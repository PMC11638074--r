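# Topology operations on chain architectures: enumeration, classification,
# in-silico cleavage, linkage composition and JSON serialization.

#' Enumerate branched trimeric architectures
#'
#' One architecture per unordered pair of distinct attachment sites on a
#' single proximal ubiquitin, i.e. the minimal branched chains: two distal
#' moieties on one proximal moiety. Over all 8 admissible sites this yields
#' choose(8, 2) = 28 distinct branched trimers.
#'
#' @param sites Attachment sites to consider (default all of [UB_SITES]);
#'   site labels (`"K48"`) or notation tokens (`"48"`) are accepted.
#' @return List of `ub_chain` objects in canonical (site-ordered) order.
#' @export
enumerate_branched_trimers <- function(sites = UB_SITES) {
  stopifnot(length(sites) >= 2L)
  sites <- ifelse(sites %in% UB_SITES, sites, site_from_token(sites))
  if (anyDuplicated(sites)) stop("duplicate site labels", call. = FALSE)
  sites <- UB_SITES[sort(match(sites, UB_SITES))]
  pairs <- utils::combn(sites, 2L, simplify = FALSE)
  lapply(pairs, function(p) {
    ub_chain(
      list(ub_unit("u1"), ub_unit("u2"), ub_unit("u3")),
      data.frame(distal = c("u2", "u3"), proximal = "u1",
                 site = p, stringsAsFactors = FALSE)
    )
  })
}

#' Classify the topology of an architecture
#'
#' @param x A `ub_chain`.
#' @return One of `"mono"` (single moiety), `"homotypic_unbranched"`
#'   (linear, one linkage type), `"mixed_unbranched"` (linear, several
#'   linkage types) or `"branched"` (some moiety carries two or more distal
#'   arms).
#' @export
classify_topology <- function(x) {
  stopifnot(inherits(x, "ub_chain"))
  if (length(x$units) == 1L) return("mono")
  if (anyDuplicated(x$edges$proximal)) return("branched")
  if (length(unique(x$edges$site)) == 1L) return("homotypic_unbranched")
  "mixed_unbranched"
}

#' Cleave linkages of a chain in silico
#'
#' Removes the given edges (hydrolysis of the isopeptide/peptide bond
#' restores the distal unit's free C-terminus and frees the proximal site)
#' and returns the resulting connected components, each a valid architecture.
#' The total number of moieties is conserved: cutting `m` edges yields
#' `m + 1` components.
#'
#' @param x A `ub_chain`.
#' @param edges Which linkages to cut: integer row indices into `x$edges`,
#'   or a data frame with `distal`/`proximal`/`site` columns matching rows
#'   of `x$edges`.
#' @return List of `ub_chain` components, sorted by canonical notation
#'   (a multiset: repeated products appear repeatedly).
#' @export
cleave_chain <- function(x, edges) {
  stopifnot(inherits(x, "ub_chain"))
  idx <- match_edges(x, edges)
  keep <- x$edges[setdiff(seq_len(nrow(x$edges)), idx), , drop = FALSE]
  comps <- split_components(x, keep)
  ord <- order(vapply(comps, function(c) format_chain(c)[[1]], character(1)))
  comps[ord]
}

match_edges <- function(x, edges) {
  if (is.numeric(edges)) {
    idx <- as.integer(edges)
    if (length(idx) && (anyNA(idx) || any(idx < 1L | idx > nrow(x$edges)))) {
      stop("unknown edge index", call. = FALSE)
    }
    return(unique(idx))
  }
  edges <- as.data.frame(edges)
  if (!nrow(edges)) return(integer())
  key <- function(e) paste(e$distal, e$proximal, e$site, sep = "\r")
  idx <- match(key(edges), key(x$edges))
  if (anyNA(idx)) stop("unknown edge (no matching distal/proximal/site row)",
                       call. = FALSE)
  unique(idx)
}

# connected components of the forest obtained by keeping `keep` edges
split_components <- function(x, keep) {
  ids <- names(x$units)
  comp <- seq_along(ids); names(comp) <- ids
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(keep)) {
    for (k in seq_len(nrow(keep))) {
      a <- find(match(keep$distal[k], ids))
      b <- find(match(keep$proximal[k], ids))
      comp[a] <- b
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  lapply(unique(roots), function(r) {
    members <- ids[roots == r]
    sub_edges <- keep[keep$distal %in% members, , drop = FALSE]
    ub_chain(x$units[members], sub_edges)
  })
}

#' Linkage composition of a chain
#'
#' Counts the linkage edges per attachment site; the counts sum to the
#' number of moieties minus one.
#'
#' @param x A `ub_chain`.
#' @return Named integer vector (sites present in the chain only); empty for
#'   a single moiety.
#' @export
linkage_composition <- function(x) {
  stopifnot(inherits(x, "ub_chain"))
  if (!nrow(x$edges)) return(stats::setNames(integer(), character()))
  tab <- table(factor(x$edges$site, levels = UB_SITES))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0L]
}

#' Serialize / deserialize an architecture as JSON
#'
#' Structured-text form: a `units` array (id, substitutions, c_term, tags,
#' isotope) plus an `edges` array (distal, proximal, site).
#'
#' @param x A `ub_chain`.
#' @param path Optional file to write to / read from.
#' @return `chain_to_json()` returns the JSON string (invisibly when `path`
#'   is given); `chain_from_json()` returns a validated `ub_chain`.
#' @export
chain_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "ub_chain"))
  obj <- list(
    units = lapply(unname(x$units), function(u) {
      list(id = u$id, substitutions = as.list(u$substitutions),
           c_term = u$c_term, tags = as.list(u$tags), isotope = u$isotope)
    }),
    edges = lapply(seq_len(nrow(x$edges)), function(i) {
      as.list(x$edges[i, c("distal", "proximal", "site")])
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname chain_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
chain_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE),
                                    collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  units <- lapply(obj$units, function(u) {
    ub_unit(u$id,
            substitutions = unlist(u$substitutions) %||% character(),
            c_term = u$c_term %||% 76L,
            tags = unlist(u$tags) %||% character(),
            isotope = u$isotope %||% "natural")
  })
  edges <- do.call(rbind, lapply(obj$edges, function(e) {
    data.frame(distal = e$distal, proximal = e$proximal, site = e$site,
               stringsAsFactors = FALSE)
  }))
  ub_chain(units, edges)
}
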