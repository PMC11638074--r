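# ASCII chain nomenclature: parser and canonical formatter.
#
# The dialect reads distal-to-proximal, left to right. A bracketed site list
# before a unit gives the attachment sites, on that unit, of everything
# written to its left: first the chain parsed so far (if any), then any
# parenthesised distal arm groups, in order. Examples:
#
#   "Ub"                          one moiety
#   "Ub-[48]Ub"                   K48-linked dimer (distal-proximal)
#   "(Ub)2-[48,63]Ub"             branched trimer: two arms on K48 and K63
#   "(Ub)2-[48,63]Ub-[48]Ub"      branched tetramer on a K48 trunk
#   "(Ub{K48R,K63R})2-[48,63]Ub{1-72}"  substituted distals, truncated root
#
# Unit modifiers in braces: KnR substitutions, "1-m" C-terminal truncation,
# tag names (AVI), and "15N". A compact alias "<site>Ub<n>" (e.g. "48Ub3")
# denotes the homotypic unbranched chain of n wild-type moieties.
#
# Superscript/subscript renderings common in the literature
# (e.g. subscripted repeat counts, caret superscripts, en-dashes) are
# best-effort basis before parsing.

#' Parse chain notation into an architecture
#'
#' @param notation A single character string in the ASCII chain dialect
#'   (see Details in the package vignette). Superscript, subscript and
#'   en-dash renderings are accepted where unambiguous.
#' @return A validated [ub_chain()].
#' @seealso [format_chain()] for the inverse.
#' @export
parse_chain <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  txt <- normalize_notation(notation)

  # compact homotypic alias, e.g. "48Ub3"
  m <- regmatches(txt, regexec("^(1|6|11|27|29|33|48|63)Ub([0-9]+)$", txt))[[1]]
  if (length(m)) {
    site <- site_from_token(m[2]); n <- as.integer(m[3])
    if (n < 2L) stop("homotypic alias needs chain length >= 2", call. = FALSE)
    units <- lapply(seq_len(n), function(i) ub_unit(paste0("u", i)))
    edges <- data.frame(distal = paste0("u", seq_len(n - 1L)),
                        proximal = paste0("u", seq_len(n - 1L) + 1L),
                        site = site, stringsAsFactors = FALSE)
    return(ub_chain(units, edges))
  }

  st <- new.env(parent = emptyenv())
  st$txt <- txt
  st$pos <- 1L
  st$n_units <- 0L
  res <- p_chain(st)
  if (st$pos <= nchar(st$txt)) {
    p_error(st, "unexpected trailing input")
  }
  ub_chain(res$units, res$edges)
}

p_error <- function(st, msg) {
  stop(sprintf("chain notation syntax error at position %d: %s (in \"%s\")",
               st$pos, msg, st$txt), call. = FALSE)
}

p_peek <- function(st, n = 1L) {
  if (st$pos > nchar(st$txt)) return("")
  substr(st$txt, st$pos, st$pos + n - 1L)
}

p_take <- function(st, lit) {
  if (p_peek(st, nchar(lit)) != lit) return(FALSE)
  st$pos <- st$pos + nchar(lit)
  TRUE
}

p_regex <- function(st, pattern) {
  m <- regmatches(substring(st$txt, st$pos),
                  regexpr(paste0("^(?:", pattern, ")"),
                          substring(st$txt, st$pos), perl = TRUE))
  if (!length(m)) return(NULL)
  st$pos <- st$pos + nchar(m)
  m
}

# chain := first_segment ( "-[" sites "]" segment )*
# first_segment := unit | group+ "-[" sites "]" unit
# segment       := group* unit                      (sites cover prev + groups)
# returns list(units = list of ub_unit, edges = data.frame, root = id)
p_chain <- function(st) {
  acc <- NULL  # subtree carried leftward (list(units, edges, root))
  pending <- list()  # parsed groups awaiting attachment
  repeat {
    while (p_peek(st) == "(") pending <- c(pending, p_group(st))
    if (!is.null(acc) || length(pending)) {
      if (!p_take(st, "-")) p_error(st, "expected \"-[sites]unit\"")
      if (!p_take(st, "[")) p_error(st, "expected \"[\" after \"-\"")
      toks <- p_regex(st, "[0-9]+(,[0-9]+)*")
      if (is.null(toks)) p_error(st, "expected comma-separated site list")
      if (!p_take(st, "]")) p_error(st, "expected \"]\" closing site list")
      sites <- site_from_token(strsplit(toks, ",", fixed = TRUE)[[1]])
      unit <- p_unit(st)
      distals <- c(if (!is.null(acc)) list(acc), pending)
      if (length(sites) != length(distals)) {
        p_error(st, sprintf(
          "site list names %d site(s) but %d distal element(s) precede it",
          length(sites), length(distals)))
      }
      units <- list(unit)
      edges <- data.frame(distal = character(), proximal = character(),
                          site = character(), stringsAsFactors = FALSE)
      for (i in seq_along(distals)) {
        units <- c(units, distals[[i]]$units)
        edges <- rbind(edges, distals[[i]]$edges,
                       data.frame(distal = distals[[i]]$root,
                                  proximal = unit$id, site = sites[i],
                                  stringsAsFactors = FALSE))
      }
      acc <- list(units = units, edges = edges, root = unit$id)
      pending <- list()
    } else {
      unit <- p_unit(st)
      acc <- list(units = list(unit),
                  edges = data.frame(distal = character(),
                                     proximal = character(),
                                     site = character(),
                                     stringsAsFactors = FALSE),
                  root = unit$id)
    }
    nxt <- p_peek(st)
    if (nxt != "-" && nxt != "(") break
  }
  acc
}

# group := "(" chain ")" INT?  -> list of subtree copies
p_group <- function(st) {
  stopifnot(p_take(st, "("))
  sub <- p_chain(st)
  if (!p_take(st, ")")) p_error(st, "expected \")\" closing distal arm")
  count <- p_regex(st, "[0-9]+")
  count <- if (is.null(count)) 1L else as.integer(count)
  if (count < 1L) p_error(st, "repetition count must be >= 1")
  out <- vector("list", count)
  out[[1L]] <- sub
  if (count > 1L) {
    for (i in 2L:count) out[[i]] <- relabel_subtree(st, sub)
  }
  # the first copy keeps its ids; they were drawn from the shared counter
  out
}

# deep-copy a subtree with fresh unit ids
relabel_subtree <- function(st, sub) {
  old <- vapply(sub$units, `[[`, character(1), "id")
  new <- vapply(old, function(.) p_fresh_id(st), character(1))
  units <- lapply(seq_along(sub$units), function(i) {
    u <- sub$units[[i]]; u$id <- new[[i]]; u
  })
  edges <- sub$edges
  if (nrow(edges)) {
    edges$distal <- new[match(edges$distal, old)]
    edges$proximal <- new[match(edges$proximal, old)]
  }
  list(units = units, edges = edges, root = new[match(sub$root, old)])
}

p_fresh_id <- function(st) {
  st$n_units <- st$n_units + 1L
  paste0("u", st$n_units)
}

# unit := "Ub" ( "{" mod ("," mod)* "}" )?
p_unit <- function(st) {
  if (!p_take(st, "Ub")) p_error(st, "expected \"Ub\"")
  subs <- character(); c_term <- 76L; tags <- character(); iso <- "natural"
  if (p_take(st, "{")) {
    repeat {
      mod <- p_regex(st, "K[0-9]+R|1-[0-9]+|15N|[A-Za-z][A-Za-z0-9]*")
      if (is.null(mod)) p_error(st, "expected unit modifier")
      if (grepl("^K[0-9]+R$", mod)) {
        subs <- c(subs, mod)
      } else if (grepl("^1-[0-9]+$", mod)) {
        c_term <- as.integer(sub("^1-", "", mod))
      } else if (mod == "15N") {
        iso <- "15N"
      } else {
        tags <- c(tags, mod)
      }
      if (!p_take(st, ",")) break
    }
    if (!p_take(st, "}")) p_error(st, "expected \"}\" closing modifiers")
  }
  tryCatch(
    ub_unit(p_fresh_id(st), substitutions = subs, c_term = c_term,
            tags = tags, isotope = iso),
    error = function(e) p_error(st, conditionMessage(e))
  )
}

# Best-effort normalization of literature renderings to the ASCII dialect.
normalize_notation <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  # en/em dashes and minus to hyphen
  x <- gsub("[\u2012\u2013\u2014\u2212]", "-", x)
  # superscript digits to ASCII
  sup <- c("\u2070", "\u00b9", "\u00b2", "\u00b3", "\u2074", "\u2075",
           "\u2076", "\u2077", "\u2078", "\u2079")
  sub_ <- c("\u2080", "\u2081", "\u2082", "\u2083", "\u2084", "\u2085",
            "\u2086", "\u2087", "\u2088", "\u2089")
  for (d in 0:9) {
    x <- gsub(sup[d + 1L], as.character(d), x, fixed = TRUE)
    x <- gsub(sub_[d + 1L], as.character(d), x, fixed = TRUE)
  }
  # caret-delimited site superscripts: "-^48,63^Ub" -> "-[48,63]Ub"
  x <- gsub("-\\^([0-9,]+)\\^", "-[\\1]", x)
  # leading homotypic superscript: "^48^Ub_3" -> "48Ub3"
  x <- gsub("\\^([0-9]+)\\^Ub", "\\1Ub", x)
  # subscript markers: ")_2" -> ")2", "Ub_3" -> "Ub3"
  x <- gsub("_([0-9]+)", "\\1", x)
  # bare superscript site lists (carets lost in transcription):
  # "-48,63Ub" -> "-[48,63]Ub"; only when no bracketed form is present
  if (!grepl("[", x, fixed = TRUE)) {
    x <- gsub("-([0-9]+(?:,[0-9]+)*)Ub", "-[\\1]Ub", x, perl = TRUE)
  }
  x
}

#' Render an architecture in canonical notation
#'
#' The canonical form reads distal-to-proximal; distal arms of a unit are
#' ordered by site label and identical arms are collapsed into `(X)n`
#' groups, so that isomorphic architectures (regardless of unit ids) render
#' identically and `parse_chain(format_chain(x))` is isomorphic to `x`.
#'
#' @param x A `ub_chain`.
#' @param compact If `TRUE` and the chain is an unbranched homotypic chain of
#'   unmodified moieties, return the compact alias (e.g. `"48Ub3"`) instead
#'   of the full notation.
#' @return A character scalar. When a compact alias exists it is also
#'   attached as the `"alias"` attribute of the full notation.
#' @export
format_chain <- function(x, compact = FALSE) {
  stopifnot(inherits(x, "ub_chain"))
  render <- function(id) {
    u <- x$units[[id]]
    utxt <- paste0("Ub", unit_signature(u))
    ch <- chain_children(x, id)
    if (!nrow(ch)) return(utxt)
    if (nrow(ch) == 1L) {
      return(paste0(render(ch$distal[1]), "-[", site_token(ch$site[1]), "]",
                    utxt))
    }
    arms <- vapply(ch$distal, render, character(1))
    # collapse adjacent identical arms (children are site-sorted already)
    grp <- character(); i <- 1L
    while (i <= length(arms)) {
      j <- i
      while (j < length(arms) && arms[j + 1L] == arms[i]) j <- j + 1L
      n <- j - i + 1L
      grp <- c(grp, paste0("(", arms[i], ")", if (n > 1L) n else ""))
      i <- j + 1L
    }
    paste0(paste(grp, collapse = ""),
           "-[", paste(site_token(ch$site), collapse = ","), "]", utxt)
  }
  full <- render(x$root)
  alias <- compact_alias(x)
  if (compact && !is.na(alias)) return(alias)
  if (!is.na(alias)) attr(full, "alias") <- alias
  full
}

# "48Ub3"-style alias for unbranched homotypic chains of plain moieties
compact_alias <- function(x) {
  n <- length(x$units)
  if (n < 2L) return(NA_character_)
  if (classify_topology(x) != "homotypic_unbranched") return(NA_character_)
  plain <- all(vapply(x$units, function(u) unit_signature(u) == "", logical(1)))
  if (!plain) return(NA_character_)
  paste0(site_token(x$edges$site[1]), "Ub", n)
}
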