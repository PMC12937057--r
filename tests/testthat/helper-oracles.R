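# Independent oracles and random-instance generators used across the suite.
# These deliberately avoid the package's own code paths wherever they are
# used to check one.

# random species alphabet: plain letters, plus labels exercising the escaping
oracle_alphabet <- c(LETTERS[1:8], "[NH4+]", "a*b", "x>y", "p+q", "back\\slash")

# random reaction over a species alphabet
random_reaction <- function(alphabet = oracle_alphabet, max_side = 3,
                            max_coef = 3) {
  repeat {
    nt <- sample.int(max_side, 1); nh <- sample.int(max_side, 1)
    tl <- sample(alphabet, nt)
    hd <- sample(alphabet, nh)
    return(reaction(setNames(sample.int(max_coef, nt, replace = TRUE), tl),
                    setNames(sample.int(max_coef, nh, replace = TRUE), hd)))
  }
}

random_hypergraph <- function(sim_id, n_edges, alphabet = oracle_alphabet) {
  build_hypergraph(replicate(n_edges, random_reaction(alphabet),
                             simplify = FALSE), sim_id)
}

# Brute-force subhypergraph oracle: exhaustive backtracking search over all
# injective label-preserving vertex maps phi, accepting if some phi carries
# every directed hyperedge of p (with coefficients) onto a hyperedge of g.
# Independent of canonical_item and of the edge-key shortcut.
oracle_subhypergraph <- function(p, g) {
  pv <- p$vertices
  # candidate images per p-vertex: g-vertices with the same label
  cands <- lapply(pv, function(v) g$vertices[g$vertices == v])
  edges_ok <- function(phi) {
    # phi: named map p-vertex label -> g-vertex label
    map_side <- function(m) setNames(unname(m), unname(phi[names(m)]))
    for (ep in p$edges) {
      tl <- map_side(ep$tail); hd <- map_side(ep$head)
      found <- FALSE
      for (eg in g$edges) {
        if (setequal(names(tl), names(eg$tail)) &&
            setequal(names(hd), names(eg$head)) &&
            all(tl[names(eg$tail)] == eg$tail) &&
            all(hd[names(eg$head)] == eg$head)) { found <- TRUE; break }
      }
      if (!found) return(FALSE)
    }
    TRUE
  }
  search <- function(i, phi, used) {
    if (i > length(pv)) return(edges_ok(phi))
    for (img in setdiff(cands[[i]], used)) {
      phi2 <- c(phi, setNames(img, pv[i]))
      if (search(i + 1L, phi2, c(used, img))) return(TRUE)
    }
    FALSE
  }
  search(1L, setNames(character(0), character(0)), character(0))
}

# Exhaustive frequent-itemset oracle: enumerates every subset of the item
# universe and counts supersets among the transactions.
oracle_frequent_itemsets <- function(transactions, minsup) {
  universe <- sort(unique(unlist(transactions)), method = "radix")
  out <- list()
  for (mask in seq_len(2^length(universe) - 1L)) {
    iset <- universe[bitwAnd(mask, 2^(seq_along(universe) - 1L)) > 0]
    sup <- sum(vapply(transactions, function(tx) all(iset %in% tx), logical(1)))
    if (sup >= minsup)
      out[[length(out) + 1L]] <- list(items = iset, support = sup)
  }
  out
}

oracle_closed_itemsets <- function(transactions, minsup) {
  freq <- oracle_frequent_itemsets(transactions, minsup)
  keep <- vapply(seq_along(freq), function(i) {
    !any(vapply(seq_along(freq), function(j) {
      i != j && freq[[j]]$support == freq[[i]]$support &&
        length(freq[[j]]$items) > length(freq[[i]]$items) &&
        all(freq[[i]]$items %in% freq[[j]]$items)
    }, logical(1)))
  }, logical(1))
  freq[keep]
}

# canonical form for comparing itemset families
itemset_family_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s, method = "radix"),
                                      collapse = " ; "), character(1)))
}

# Exhaustive two-sided Fisher p-value built directly from binomial
# coefficients (no dhyper, no package code): point-probability convention.
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + c; n2 <- b + d; x <- a + b; n <- n1 + n2
  if (x == 0 || x == n || n1 == 0 || n2 == 0) return(1)
  ks <- max(0, x - n2):min(x, n1)
  pk <- choose(n1, ks) * choose(n2, x - ks) / choose(n, x)
  pobs <- choose(n1, a) * choose(n2, x - a) / choose(n, x)
  sum(pk[pk <= pobs * (1 + 1e-7)])
}

oracle_min_p <- function(n1, n2, x) {
  ks <- max(0, x - n2):min(x, n1)
  min(vapply(ks, function(a) oracle_fisher(a, x - a, n1 - a, n2 - (x - a)),
             numeric(1)))
}

# tiny transaction collections as plain named lists of character vectors
as_tx <- function(lst) structure(lst, class = "crn_transactions")
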