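## File formats and reporting: JSON-Lines reaction-event logs, species
## molar-fraction time series, bipartite GraphML / DOT network export, and
## the CSV tables that make every mining / testing decision reproducible.

#' Write a collection of reaction hypergraphs as a JSONL event log
#'
#' One JSON record per reaction: `sim_id`, `condition`, `reactants` and
#' `products` as SMILES -> coefficient maps. Records are streamed to the
#' connection simulation by simulation, so the working set stays bounded for
#' large collections. A schema header record is written first.
#'
#' @param collection list of `crn_hypergraph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(collection, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines('{"crnminer_schema":1}', con)
  for (g in collection) {
    lines <- vapply(g$edges, function(r) jsonlite::toJSON(
      list(sim_id = g$sim_id, condition = g$condition,
           reactants = as.list(r$tail), products = as.list(r$head)),
      auto_unbox = TRUE), character(1))
    if (length(lines)) writeLines(unname(lines), con)
  }
  invisible(path)
}

#' Canonicalize SMILES strings
#'
#' One pass through Open Babel (via the ChemmineOB package) mapping each
#' input SMILES to its canonical form; thereafter the core treats labels as
#' opaque text. Strings Open Babel cannot parse come back as `NA`.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES canonicalization requires the ChemmineOB package",
         call. = FALSE)
  out <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    can <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", smiles[i]),
      error = function(e) "")
    can <- sub("[\t ].*$", "", sub("\n.*$", "", can))
    if (nzchar(can)) out[i] <- can
  }
  out
}

.coef_map_from_json <- function(x, what, line) {
  if (is.null(x) || length(x) == 0L)
    stop(sprintf("line %d: empty %s", line, what), call. = FALSE)
  v <- unlist(x)
  if (is.null(names(v)) || any(!nzchar(names(v))))
    stop(sprintf("line %d: unnamed species in %s", line, what), call. = FALSE)
  v
}

#' Read a JSONL reaction-event log into reaction hypergraphs
#'
#' Parses one event record per line (an optional schema header line is
#' accepted), groups events by `sim_id`, and builds one deduplicated
#' hypergraph per simulation. Malformed lines do not abort the read: they are
#' collected with their line numbers in the `errors` attribute of the result.
#' Identity reactions -- identical species-coefficient multisets on both
#' sides, e.g. pure proton transfers -- are retained in the model but their
#' keys are flagged in each hypergraph's `identity_edges` attribute so
#' reporting can exclude them.
#'
#' @param path JSONL file.
#' @param canonicalize canonicalize SMILES labels at ingest via
#'   [canonicalize_smiles()] (default FALSE: labels used as given). Records
#'   whose SMILES fail to parse are rejected into `errors`.
#' @return list of `crn_hypergraph` (order of first appearance) with
#'   attribute `errors` (data.frame `line`, `message`).
#' @export
read_event_log <- function(path, canonicalize = FALSE) {
  if (!file.exists(path))
    stop("input error: cannot open ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  errors <- list()
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = i, message = paste("JSON parse failure:",
                                  conditionMessage(rec)))
      next
    }
    if (!is.null(rec$crnminer_schema)) next   # header record
    parsed <- tryCatch({
      if (is.null(rec$sim_id) || !nzchar(rec$sim_id))
        stop(sprintf("line %d: missing sim_id", i), call. = FALSE)
      list(sim_id = as.character(rec$sim_id),
           condition = if (is.null(rec$condition)) list() else rec$condition,
           reactants = .coef_map_from_json(rec$reactants, "reactants", i),
           products = .coef_map_from_json(rec$products, "products", i))
    }, error = function(e) e)
    if (inherits(parsed, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = i, message = conditionMessage(parsed))
      next
    }
    parsed$line <- i
    recs[[length(recs) + 1L]] <- parsed
  }

  if (canonicalize && length(recs)) {
    labs <- unique(unlist(lapply(recs, function(r)
      c(names(r$reactants), names(r$products)))))
    can <- setNames(canonicalize_smiles(labs), labs)
    keep <- logical(length(recs))
    for (j in seq_along(recs)) {
      r <- recs[[j]]
      ls <- c(names(r$reactants), names(r$products))
      if (anyNA(can[ls])) {
        errors[[length(errors) + 1L]] <- data.frame(
          line = r$line, message = paste("unparseable SMILES:",
            paste(ls[is.na(can[ls])], collapse = ", ")))
        next
      }
      names(recs[[j]]$reactants) <- unname(can[names(r$reactants)])
      names(recs[[j]]$products) <- unname(can[names(r$products)])
      keep[j] <- TRUE
    }
    recs <- recs[keep]
  }

  sims <- unique(vapply(recs, `[[`, character(1), "sim_id"))
  collection <- vector("list", length(sims))
  for (s in seq_along(sims)) {
    rs <- Filter(function(r) r$sim_id == sims[s], recs)
    evs <- lapply(rs, function(r) {
      # merge duplicate labels (possible after canonicalization) by summing
      tl <- tapply(unlist(r$reactants), names(r$reactants), sum)
      hd <- tapply(unlist(r$products), names(r$products), sum)
      reaction(tl, hd)
    })
    g <- build_hypergraph(evs, sims[s], rs[[1]]$condition)
    ident <- vapply(g$edges, function(r) identical(r$tail, r$head), logical(1))
    attr(g, "identity_edges") <- names(g$edges)[ident]
    collection[[s]] <- g
  }
  errdf <- if (length(errors)) do.call(rbind, errors)
           else data.frame(line = integer(0), message = character(0))
  attr(collection, "errors") <- errdf
  collection
}

#' Binary condition labels from a numeric or categorical condition
#'
#' Derives the two-arm split used by [significant_patterns()] from each
#' simulation's condition map, using a rule string such as `"<=50"`, `">39"`
#' or `"==T39K"` applied to the value under `key`. Simulations satisfying the
#' rule get the first label.
#'
#' @param collection list of `crn_hypergraph`.
#' @param key name in the condition map (e.g. `"T_K"`).
#' @param rule comparison string: an operator `<=, >=, <, >, ==, !=` followed
#'   by a number or label.
#' @param labels two labels for (rule-true, rule-false); default `"A"`, `"B"`.
#' @return named character vector sim_id -> label.
#' @export
split_condition <- function(collection, key, rule, labels = c("A", "B")) {
  m <- regmatches(rule, regexec("^(<=|>=|==|!=|<|>)\\s*(.+)$", rule))[[1]]
  if (length(m) != 3L)
    stop("input error: cannot parse split rule: ", rule, call. = FALSE)
  op <- m[2]; ref <- m[3]
  vals <- lapply(collection, function(g) g$condition[[key]])
  if (any(vapply(vals, is.null, logical(1))))
    stop("input error: condition key '", key, "' missing in some simulations",
         call. = FALSE)
  num <- suppressWarnings(as.numeric(ref))
  hit <- vapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    if (!is.na(num)) do.call(op, list(as.numeric(v), num))
    else do.call(op, list(as.character(v), ref))
  }, logical(1))
  setNames(ifelse(hit, labels[1], labels[2]),
           vapply(collection, function(g) g$sim_id, character(1)))
}

#' Molar-fraction time series from species inventories
#'
#' `fraction(species, t) = count(species, t) / total count(t)` per simulation
#' and checkpoint; fractions over all species sum to 1 at every checkpoint.
#' Checkpoints with zero total count have no defined fractions and are
#' reported as `NA`.
#'
#' @param inventories data.frame with columns `sim_id`, `time`, `species`,
#'   `count` (long format, one row per species per checkpoint).
#' @param targets optional character vector of species to keep (a target
#'   absent from a checkpoint's inventory has fraction 0).
#' @param average average the fractions over simulations at each time point
#'   (default FALSE).
#' @return data.frame `sim_id`, `time`, `species`, `fraction` (or `time`,
#'   `species`, `fraction` when `average = TRUE`).
#' @export
species_fractions <- function(inventories, targets = NULL, average = FALSE) {
  need <- c("sim_id", "time", "species", "count")
  if (!all(need %in% names(inventories)))
    stop("input error: inventories need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(inventories$count < 0))
    stop("input error: negative species count", call. = FALSE)
  tot <- aggregate(count ~ sim_id + time, inventories, sum)
  names(tot)[names(tot) == "count"] <- "total"
  if (!is.null(targets)) {
    # ensure every target appears at every checkpoint (count 0 if absent)
    grid <- merge(tot[c("sim_id", "time")],
                  data.frame(species = targets), by = NULL)
    inventories <- merge(grid, inventories, all.x = TRUE,
                         by = c("sim_id", "time", "species"))
    inventories$count[is.na(inventories$count)] <- 0
  }
  df <- merge(inventories, tot, by = c("sim_id", "time"))
  df$fraction <- ifelse(df$total > 0, df$count / df$total, NA_real_)
  df <- df[order(df$sim_id, df$time, df$species, method = "radix"),
           c("sim_id", "time", "species", "fraction")]
  rownames(df) <- NULL
  if (average) {
    df <- aggregate(fraction ~ time + species, df, mean, na.action = NULL)
    df <- df[order(df$time, df$species, method = "radix"), ]
    rownames(df) <- NULL
  }
  df
}

## Network export ------------------------------------------------------------

#' Union hypergraph of mined patterns
#'
#' Decodes all item keys occurring in a mining result into one hypergraph
#' (the union reaction network) and returns per-reaction annotation: the
#' support of the best-supported pattern containing each reaction and, when
#' `results` is given, the smallest p-value among patterns containing it.
#'
#' @param patterns data.frame from [mine_frequent()].
#' @param results optional data.frame from [significant_patterns()].
#' @return list with `graph` (a `crn_hypergraph`) and `annotations`
#'   (data.frame `key`, `support`, and `p_value` if available).
#' @export
patterns_to_network <- function(patterns, results = NULL) {
  keys <- sort(unique(unlist(patterns$items)), method = "radix")
  g <- decode_pattern(keys, sim_id = "pattern_union")
  ann <- data.frame(key = keys, support = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    inpat <- vapply(patterns$items, function(ii) keys[i] %in% ii, logical(1))
    ann$support[i] <- max(patterns$support[inpat])
    if (!is.null(results)) {
      pv <- results$p_value[match(patterns$pattern_key[inpat],
                                  results$pattern_key)]
      ann$p_value[i] <- suppressWarnings(min(pv, na.rm = TRUE))
    }
  }
  list(graph = g, annotations = ann)
}

#' Export a reaction network as a bipartite GraphML (or DOT) file
#'
#' Species become one node class (attribute `label` = SMILES), reactions the
#' other (attributes: `key`, and any of `barrier_kcal_mol`, `k_per_s`,
#' `support`, `p_value` provided via `annotations`/`barriers`); incidence
#' edges carry the stoichiometric coefficient and the role (`tail` for
#' reactant membership, `head` for product). A catalyst contributes one tail
#' and one head edge. Layout is left to the viewer.
#'
#' @param g a `crn_hypergraph` (e.g. from [patterns_to_network()]).
#' @param path output file.
#' @param format `"graphml"` (default) or `"dot"`.
#' @param annotations optional data.frame with column `key` plus any of
#'   `support`, `p_value` to attach to reaction nodes.
#' @param barriers optional data.frame `key`, `dg` (kcal/mol), `temp` (K):
#'   attaches the barrier and its Eyring rate to matching reaction nodes.
#' @param include_identity keep identity reactions (same species multiset on
#'   both sides); default FALSE, matching the usual reporting convention.
#' @return `path`, invisibly.
#' @export
export_network <- function(g, path, format = c("graphml", "dot"),
                           annotations = NULL, barriers = NULL,
                           include_identity = FALSE) {
  format <- match.arg(format)
  edges <- g$edges
  if (!include_identity)
    edges <- edges[!vapply(edges, function(r)
      identical(r$tail, r$head), logical(1))]
  labs <- unlist(lapply(edges, function(r) c(names(r$tail), names(r$head))))
  species <- if (is.null(labs)) character(0)
             else sort(unique(labs), method = "radix")

  nr <- length(edges)
  rx <- data.frame(key = names(edges) %||% character(0),
                   support = rep(NA_real_, nr), p_value = rep(NA_real_, nr),
                   barrier_kcal_mol = rep(NA_real_, nr),
                   k_per_s = rep(NA_real_, nr), stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(rx)) {
    i <- match(rx$key, annotations$key)
    if ("support" %in% names(annotations)) rx$support <- annotations$support[i]
    if ("p_value" %in% names(annotations)) rx$p_value <- annotations$p_value[i]
  }
  if (!is.null(barriers) && nrow(rx)) {
    i <- match(rx$key, barriers$key)
    rx$barrier_kcal_mol <- barriers$dg[i]
    hit <- !is.na(i)
    rx$k_per_s[hit] <- eyring_rate(barriers$dg[i[hit]], barriers$temp[i[hit]])
  }

  if (format == "dot") return(.write_dot(edges, species, rx, path))
  .write_graphml(edges, species, rx, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_graphml <- function(edges, species, rx, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    c("d_type", "node", "type", "string"),
    c("d_label", "node", "label", "string"),
    c("d_key", "node", "reaction_key", "string"),
    c("d_support", "node", "support", "double"),
    c("d_p", "node", "p_value", "double"),
    c("d_dg", "node", "barrier_kcal_mol", "double"),
    c("d_k", "node", "k_per_s", "double"),
    c("d_coef", "edge", "coefficient", "int"),
    c("d_role", "edge", "role", "string"))
  for (k in keydefs)
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  gr <- xml2::xml_add_child(doc, "graph", id = "crn", edgedefault = "directed")
  dat <- function(node, key, val) {
    if (is.na(val)) return(invisible())
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- as.character(val)
  }
  sid <- setNames(paste0("s", seq_along(species)), species)
  for (sp in species) {
    nd <- xml2::xml_add_child(gr, "node", id = sid[[sp]])
    dat(nd, "d_type", "species"); dat(nd, "d_label", sp)
  }
  for (j in seq_along(edges)) {
    rid <- paste0("r", j)
    nd <- xml2::xml_add_child(gr, "node", id = rid)
    dat(nd, "d_type", "reaction"); dat(nd, "d_key", rx$key[j])
    dat(nd, "d_support", rx$support[j]); dat(nd, "d_p", rx$p_value[j])
    dat(nd, "d_dg", rx$barrier_kcal_mol[j]); dat(nd, "d_k", rx$k_per_s[j])
    r <- edges[[j]]
    for (sp in names(r$tail)) {
      e <- xml2::xml_add_child(gr, "edge", source = sid[[sp]], target = rid)
      dat(e, "d_coef", r$tail[[sp]]); dat(e, "d_role", "tail")
    }
    for (sp in names(r$head)) {
      e <- xml2::xml_add_child(gr, "edge", source = rid, target = sid[[sp]])
      dat(e, "d_coef", r$head[[sp]]); dat(e, "d_role", "head")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.write_dot <- function(edges, species, rx, path) {
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  ln <- c("digraph crn {", "  rankdir=LR;")
  sid <- setNames(paste0("s", seq_along(species)), species)
  for (sp in species)
    ln <- c(ln, sprintf("  %s [shape=ellipse,label=%s];", sid[[sp]], q(sp)))
  for (j in seq_along(edges)) {
    rid <- paste0("r", j)
    ln <- c(ln, sprintf("  %s [shape=box,label=%s];", rid,
                        q(rx$key[j])))
    r <- edges[[j]]
    for (sp in names(r$tail))
      ln <- c(ln, sprintf("  %s -> %s [label=\"%d\"];", sid[[sp]], rid,
                          r$tail[[sp]]))
    for (sp in names(r$head))
      ln <- c(ln, sprintf("  %s -> %s [label=\"%d\"];", rid, sid[[sp]],
                          r$head[[sp]]))
  }
  writeLines(c(ln, "}"), path)
  invisible(path)
}

#' Re-read an exported GraphML network as a set of reactions
#'
#' Reconstructs the hyperedges (reaction key per reaction node, coefficients
#' from the incidence edges) from a file written by [export_network()]; used
#' to verify round-trip fidelity.
#'
#' @param path GraphML file.
#' @return a `crn_hypergraph`.
#' @export
read_graphml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  getdat <- function(nd, key) {
    d <- xml2::xml_find_first(nd, sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  ids <- xml2::xml_attr(nodes, "id")
  types <- vapply(nodes, getdat, character(1), "d_type")
  labels <- vapply(nodes, getdat, character(1), "d_label")
  sp_lab <- setNames(labels[types == "species"], ids[types == "species"])
  rids <- ids[types == "reaction"]
  eds <- xml2::xml_find_all(doc, ".//g:edge", ns)
  esrc <- xml2::xml_attr(eds, "source"); etgt <- xml2::xml_attr(eds, "target")
  ecoef <- vapply(eds, getdat, character(1), "d_coef")
  reactions <- lapply(rids, function(rid) {
    tl_i <- which(etgt == rid); hd_i <- which(esrc == rid)
    reaction(setNames(as.integer(ecoef[tl_i]), sp_lab[esrc[tl_i]]),
             setNames(as.integer(ecoef[hd_i]), sp_lab[etgt[hd_i]]))
  })
  build_hypergraph(reactions, sim_id = "graphml")
}

## CSV reporting -------------------------------------------------------------

#' Write mined patterns to CSV
#'
#' One row per pattern: `pattern_id`, `n_edges`, `support`, `frequency`,
#' `pattern_key` (item keys joined by `" ; "`), `supporting_sims` (joined by
#' `"|"`). Deterministic given the (already deterministic) mining order.
#'
#' @param patterns data.frame from [mine_frequent()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_patterns_csv <- function(patterns, path) {
  out <- patterns[c("pattern_id", "n_edges", "support", "frequency",
                    "pattern_key")]
  out$supporting_sims <- vapply(patterns$supporting_sims, paste, character(1),
                                collapse = "|")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write significance results to CSV
#'
#' Columns (`pattern_id`, `pattern_key`, `a`, `b`, `c`, `d`, `support`,
#' `p_value`, `min_p`, `testable`, `significant`, `odds_ratio`, `ci_low`,
#' `ci_high`, `method`, `alpha`, `delta`) fully determine the reproduction of
#' every testing decision.
#'
#' @param results data.frame from [significant_patterns()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_significance_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
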