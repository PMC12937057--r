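#' Construct a reaction (directed hyperedge)
#'
#' A reaction connects a multiset of reactant species (the tail of the
#' hyperedge) to a multiset of product species (the head). Species are
#' identified by label only -- typically a canonical SMILES string -- and the
#' core treats labels as opaque text. Stoichiometry is stored as
#' label-to-coefficient maps, so `CO2 + 3 H2 -> CH3OH + H2O` has tail
#' `c("O=C=O" = 1, "[H][H]" = 3)`. A species may appear on both sides
#' (a catalyst); no cancellation is performed.
#'
#' @param reactants named numeric/integer vector or list: species label ->
#'   positive integer stoichiometric coefficient.
#' @param products named numeric/integer vector or list, same convention.
#' @return an object of class `crn_reaction` with fields `tail` and `head`
#'   (named integer vectors, sorted by label).
#' @examples
#' reaction(c("O=C=O" = 1, "[H][H]" = 3), c(CO = 1, O = 1))
#' @export
reaction <- function(reactants, products) {
  tl <- .as_coef_map(reactants, "reactants")
  hd <- .as_coef_map(products, "products")
  structure(list(tail = tl, head = hd), class = "crn_reaction")
}

.as_coef_map <- function(x, what) {
  if (is.list(x)) x <- unlist(x)
  if (length(x) == 0L)
    stop("invalid reaction: ", what, " must be non-empty", call. = FALSE)
  labs <- names(x)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("invalid reaction: every species in ", what, " needs a non-empty label",
         call. = FALSE)
  if (anyDuplicated(labs))
    stop("invalid reaction: duplicated species label in ", what, call. = FALSE)
  co <- as.integer(x)
  if (any(is.na(co)) || any(abs(x - co) > 1e-8) || any(co < 1L))
    stop("invalid reaction: coefficients in ", what,
         " must be positive integers", call. = FALSE)
  ord <- order(labs, method = "radix")
  setNames(co[ord], labs[ord])
}

#' @export
print.crn_reaction <- function(x, ...) {
  cat(format_reaction(x), "\n")
  invisible(x)
}

#' Human-readable arrow form of a reaction
#' @param r a `crn_reaction`.
#' @return a single string like `"O=C=O + 3 [H][H] -> CO + O"`.
#' @export
format_reaction <- function(r) {
  side <- function(m) paste(ifelse(m == 1L, names(m),
                                   paste(m, names(m))), collapse = " + ")
  paste(side(r$tail), "->", side(r$head))
}

## Canonical item encoding ---------------------------------------------------
##
## Each hyperedge is serialized to a single text key:
##   tail-part ">>" head-part,  side = "coef*label" terms joined by "+",
## terms sorted by label (radix order, locale independent). The characters
## \ * + > inside labels are backslash-escaped, which makes the delimiters
## unambiguous and the encoding injective.

.esc <- function(s) gsub("([\\\\*+>])", "\\\\\\1", s)

.encode_side <- function(m) {
  paste0(m, "*", .esc(names(m)), collapse = "+")
}

#' Canonical item key of a reaction
#'
#' Injective, deterministic serialization of a directed hyperedge used for the
#' reduction of subhypergraph mining to itemset mining: two reactions receive
#' the same key exactly when tail, head and all stoichiometric coefficients
#' are identical. Keys are direction-sensitive (tail and head are not
#' interchangeable) and stable across platforms.
#'
#' @param r a `crn_reaction`.
#' @return a single character key, e.g. `"1*O=C=O+3*[H][H]>>1*CO+1*O"`.
#' @seealso [parse_item()] for the inverse.
#' @export
canonical_item <- function(r) {
  if (!inherits(r, "crn_reaction")) stop("not a crn_reaction", call. = FALSE)
  paste0(.encode_side(r$tail), ">>", .encode_side(r$head))
}

## Scanner for the escaped key grammar. Splits at top level on the given
## single-character delimiters; "\" escapes the next character. Escape
## sequences are preserved verbatim unless `unescape` -- outer splits must
## keep them intact for the inner splits to see.
.scan_split <- function(s, delim, unescape = FALSE) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0); buf <- character(0); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\") {
      if (i == n) stop("malformed item key: trailing escape", call. = FALSE)
      buf <- c(buf, if (unescape) chars[i + 1L]
               else c("\\", chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% delim) {
      out <- c(out, paste(buf, collapse = "")); buf <- character(0); i <- i + 1L
    } else {
      buf <- c(buf, ch); i <- i + 1L
    }
  }
  c(out, paste(buf, collapse = ""))
}

.parse_side <- function(s, key) {
  terms <- .scan_split(s, "+")
  if (any(!nzchar(terms)))
    stop("malformed item key: empty term in ", key, call. = FALSE)
  labs <- character(length(terms)); co <- integer(length(terms))
  for (j in seq_along(terms)) {
    parts <- .scan_split(terms[[j]], "*", unescape = TRUE)
    if (length(parts) != 2L)
      stop("malformed item key: bad term in ", key, call. = FALSE)
    co[j] <- suppressWarnings(as.integer(parts[[1]]))
    if (is.na(co[j]) || co[j] < 1L)
      stop("malformed item key: bad coefficient in ", key, call. = FALSE)
    labs[j] <- parts[[2]]
  }
  setNames(co, labs)
}

#' Parse a canonical item key back into a reaction
#' @param key a key produced by [canonical_item()].
#' @return a `crn_reaction`.
#' @export
parse_item <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  sides <- .scan_split(key, ">")
  # ">>" scans to parts ("tail", "", "head"); anything else is malformed
  if (length(sides) != 3L || nzchar(sides[[2]]))
    stop("malformed item key: ", key, call. = FALSE)
  reaction(.parse_side(sides[[1]], key), .parse_side(sides[[3]], key))
}

## Reaction hypergraph -------------------------------------------------------

#' Build a reaction hypergraph from observed reaction events
#'
#' Collects the reactions observed in one simulation into a node-injective
#' directed hypergraph: one vertex per distinct species label, one hyperedge
#' per distinct reaction. Duplicate events are collapsed -- downstream pattern
#' support is per-simulation binary presence, irrespective of how often a
#' reaction fired within the simulation.
#'
#' @param events list of `crn_reaction` objects (may contain duplicates).
#' @param sim_id simulation identifier (single string).
#' @param condition named list/vector of condition values for this simulation
#'   (e.g. `list(T_K = 39)`); may be empty.
#' @return a `crn_hypergraph` with fields `sim_id`, `condition`, `vertices`
#'   (sorted character), `edges` (named list of `crn_reaction`, names are the
#'   canonical item keys, sorted).
#' @examples
#' g <- build_hypergraph(list(
#'   reaction(c("O=C=O" = 1, "[H][H]" = 3), c("CO" = 1, "O" = 1)),
#'   reaction(c("O=C=O" = 1, "N" = 1), c("NC(=O)[O-]" = 1))
#' ), sim_id = "sim1", condition = list(T_K = 39))
#' @export
build_hypergraph <- function(events, sim_id = "sim", condition = list()) {
  stopifnot(is.character(sim_id), length(sim_id) == 1L)
  if (length(events) == 0L) {
    edges <- setNames(list(), character(0))
  } else {
    keys <- vapply(events, canonical_item, character(1))
    keep <- !duplicated(keys)
    edges <- setNames(events[keep], keys[keep])
    edges <- edges[order(names(edges), method = "radix")]
  }
  labs <- unlist(lapply(edges, function(r) c(names(r$tail), names(r$head))))
  verts <- if (is.null(labs)) character(0)
           else sort(unique(labs), method = "radix")
  structure(list(sim_id = sim_id, condition = as.list(condition),
                 vertices = verts, edges = edges),
            class = "crn_hypergraph")
}

#' @export
print.crn_hypergraph <- function(x, ...) {
  cat(sprintf("<crn_hypergraph '%s': %d species, %d reactions>\n",
              x$sim_id, length(x$vertices), length(x$edges)))
  for (r in x$edges) cat(" ", format_reaction(r), "\n")
  invisible(x)
}

#' Edge keys of a hypergraph
#' @param g a `crn_hypergraph`.
#' @return character vector of canonical item keys (sorted).
#' @export
edge_keys <- function(g) names(g$edges)

#' Subhypergraph test for node-injective hypergraphs
#'
#' `p` is a subhypergraph of `g` when there is an injective, label-preserving
#' map of `p`'s vertices into `g`'s vertices that carries every directed
#' hyperedge of `p` (with its stoichiometric labels) onto a hyperedge of `g`.
#' Because both hypergraphs are node-injective (one vertex per label), the
#' only candidate map is forced by the labels, and the relation reduces to
#' containment of canonical edge keys plus vertex labels.
#'
#' @param p,g `crn_hypergraph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_subhypergraph <- function(p, g) {
  all(p$vertices %in% g$vertices) && all(edge_keys(p) %in% edge_keys(g))
}

#' Decode a set of item keys into the pattern hypergraph
#'
#' Inverse of the itemset reduction: rebuilds the directed hypergraph whose
#' hyperedges are the given items, with the induced vertex set. Round-trips
#' exactly: decoding the keys of a hypergraph's edges reproduces its edge set
#' and vertices.
#'
#' @param items character vector of canonical item keys.
#' @param sim_id identifier for the decoded pattern (default `"pattern"`).
#' @return a `crn_hypergraph`.
#' @export
decode_pattern <- function(items, sim_id = "pattern") {
  build_hypergraph(lapply(unique(items), parse_item), sim_id = sim_id)
}
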