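#' Mining configuration
#'
#' @param sigma minimum frequency threshold in (0, 1]: a pattern is frequent
#'   when it occurs in at least `ceiling(sigma * N)` of the `N` simulations.
#'   The presets used in practice for exploratory reactive MD are 0.10
#'   (patterns in at least 10% of simulations) and 0.25.
#' @param mode `"closed"` (default) reports only closed patterns -- patterns
#'   with no strict super-pattern of equal support -- which represent all
#'   frequent patterns compactly; `"all"` enumerates every frequent pattern.
#' @param max_pattern_edges optional cap on the number of reactions per
#'   pattern, bounding worst-case enumeration blow-up (mining is NP-hard in
#'   general); `Inf` (default) means unlimited.
#' @return a `mining_config` list.
#' @export
mining_config <- function(sigma = 0.10, mode = c("closed", "all"),
                          max_pattern_edges = Inf) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 || sigma > 1)
    stop("config error: sigma must be in (0, 1]", call. = FALSE)
  mode <- match.arg(mode)
  if (!(is.numeric(max_pattern_edges) && max_pattern_edges >= 1))
    stop("config error: max_pattern_edges must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, mode = mode,
                 max_pattern_edges = max_pattern_edges),
            class = "mining_config")
}

#' Transform a collection of reaction hypergraphs into transactions
#'
#' Each node-injective hypergraph is uniquely represented by the set of
#' canonical item keys of its hyperedges; mining frequent directed
#' subhypergraphs then reduces exactly to frequent itemset mining over these
#' transactions (one transaction per simulation).
#'
#' @param collection list of `crn_hypergraph` objects with distinct `sim_id`s.
#' @return a named list (sim_id -> character vector of item keys) of class
#'   `crn_transactions`.
#' @export
to_transactions <- function(collection) {
  ids <- vapply(collection, function(g) g$sim_id, character(1))
  if (anyDuplicated(ids))
    stop("input error: duplicate sim_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(setNames(lapply(collection, edge_keys), ids),
            class = "crn_transactions")
}

#' Support of a pattern over a transaction collection
#'
#' Counts the simulations whose transaction (item set) contains every item of
#' the pattern -- equivalently, the simulations whose CRN contains the decoded
#' pattern as a subhypergraph.
#'
#' @param items character vector of item keys (empty pattern allowed: it is
#'   contained in every transaction).
#' @param transactions a `crn_transactions` (or named list of key vectors).
#' @return list with `support` (integer) and `supporting_sims` (character).
#' @export
pattern_support <- function(items, transactions) {
  hit <- vapply(transactions, function(tx) all(items %in% tx), logical(1))
  list(support = sum(hit), supporting_sims = names(transactions)[hit])
}

#' Mine frequent reactive patterns
#'
#' Enumerates the itemsets (reactive patterns) occurring in at least
#' `ceiling(sigma * N)` of the `N` transactions. In `mode = "all"` a
#' depth-first search over item tid-sets (Eclat-style) enumerates every
#' frequent itemset; in `mode = "closed"` an LCM-style prefix-preserving
#' closure-extension search enumerates exactly the closed frequent itemsets,
#' each exactly once, without materializing the full frequent family.
#'
#' Output is deterministic: patterns are sorted by support (descending), then
#' number of reactions (descending), then the lexicographic pattern key.
#'
#' @param transactions a `crn_transactions` from [to_transactions()].
#' @param config a [mining_config()].
#' @return data.frame with columns `pattern_id`, `n_edges`, `support`,
#'   `frequency`, `pattern_key` (item keys joined by `" ; "`), and
#'   list-columns `items` and `supporting_sims`.
#' @examples
#' g1 <- build_hypergraph(list(reaction(c(A = 1), c(B = 1))), "s1")
#' g2 <- build_hypergraph(list(reaction(c(A = 1), c(B = 1))), "s2")
#' mine_frequent(to_transactions(list(g1, g2)), mining_config(sigma = 1))
#' @export
mine_frequent <- function(transactions, config = mining_config()) {
  if (!inherits(config, "mining_config")) stop("config error", call. = FALSE)
  n <- length(transactions)
  if (n == 0L) stop("input error: empty transaction list", call. = FALSE)
  # tolerate representable sigma like 0.3 * N hitting exactly an integer
  minsup <- max(1L, as.integer(ceiling(config$sigma * n - 1e-9)))

  universe <- sort(unique(unlist(transactions, use.names = FALSE)),
                   method = "radix")
  m <- length(universe)
  txi <- lapply(transactions, function(tx)
    sort(match(unique(tx), universe)))           # transactions as item ids
  tids <- vector("list", m)                      # item id -> transaction ids
  for (t in seq_len(n)) for (i in txi[[t]]) tids[[i]] <- c(tids[[i]], t)

  res_items <- list(); res_tids <- list()
  emit <- function(iset, tv) {
    res_items[[length(res_items) + 1L]] <<- iset
    res_tids[[length(res_tids) + 1L]] <<- tv
  }
  cap <- config$max_pattern_edges

  if (config$mode == "all") {
    dfs <- function(prefix, ptids, from) {
      if (length(prefix) >= cap) return(invisible())
      for (i in seq_len(m)[seq_len(m) >= from]) {
        tv <- intersect(ptids, tids[[i]])
        if (length(tv) >= minsup) {
          emit(c(prefix, i), tv)
          dfs(c(prefix, i), tv, i + 1L)
        }
      }
    }
    dfs(integer(0), seq_len(n), 1L)
  } else {
    # closure of an itemset given its tid-set: items present in all its tids
    closure <- function(tv) Reduce(intersect, txi[tv])
    # prefix-preserving closure extension (LCM): from closed set P extend
    # with item i > core; accept closure Q only if Q agrees with P below i
    ppc <- function(P, ptids, core) {
      cand <- setdiff(seq_len(m)[seq_len(m) > core], P)
      for (i in cand) {
        tv <- intersect(ptids, tids[[i]])
        if (length(tv) < minsup) next
        Q <- closure(tv)
        if (!identical(Q[Q < i], sort(c(P[P < i], integer(0))))) next
        if (length(Q) > cap) next   # cap: closures beyond it are not reported
        emit(Q, tv)
        if (length(Q) < cap) ppc(Q, tv, i)
      }
    }
    root <- closure(seq_len(n))
    if (length(root) > 0L && length(root) <= cap) emit(root, seq_len(n))
    ppc(root, seq_len(n), 0L)
  }

  sims <- names(transactions)
  items <- lapply(res_items, function(ii) universe[sort(ii)])
  keys <- vapply(items, paste, character(1), collapse = " ; ")
  support <- vapply(res_tids, length, integer(1))
  nedge <- lengths(items)
  ord <- order(-support, -nedge, keys, method = "radix")
  out <- data.frame(
    pattern_id = sprintf("P%d", seq_along(ord)),
    n_edges = nedge[ord],
    support = support[ord],
    frequency = support[ord] / n,
    pattern_key = keys[ord],
    stringsAsFactors = FALSE
  )
  out$items <- items[ord]
  out$supporting_sims <- lapply(res_tids[ord], function(tv) sims[sort(tv)])
  out
}
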