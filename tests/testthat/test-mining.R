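# Frequent reactive-pattern mining by reduction to itemset mining.

test_that("to_transactions maps hypergraphs to their edge-key itemsets", {
  r1 <- reaction(c("O=C=O" = 1, "[H][H]" = 3), c("CO" = 1, "O" = 1))
  r2 <- reaction(c("O=C=O" = 1, "N" = 1), c("[NH3+]C(=O)[O-]" = 1))
  r3 <- reaction(c("N" = 1, "O" = 1), c("[NH4+]" = 1, "[OH-]" = 1))
  g <- build_hypergraph(list(r1, r2, r3), "s1")
  tx <- to_transactions(list(g, build_hypergraph(list(), "s2"),
                             build_hypergraph(list(r2), "s3")))
  expect_length(tx[["s1"]], 3)
  expect_length(tx[["s2"]], 0)
  # shared reaction appears as the same item in both transactions
  expect_true(canonical_item(r2) %in% tx[["s1"]])
  expect_identical(tx[["s3"]], canonical_item(r2))
  expect_error(to_transactions(list(g, g)), "duplicate sim_id")
})

test_that("mine_frequent(mode = 'all') equals exhaustive enumeration on
           random small collections", {
  set.seed(3)
  for (rep in 1:12) {
    n_tx <- sample(3:12, 1)
    universe <- paste0(sample(LETTERS[1:8], sample(4:8, 1)), ">>x")
    tx <- as_tx(setNames(lapply(seq_len(n_tx), function(i)
      sample(universe, sample(0:length(universe), 1))),
      paste0("s", seq_len(n_tx))))
    sigma <- sample(c(0.2, 0.34, 0.5, 1), 1)
    got <- mine_frequent(tx, mining_config(sigma = sigma, mode = "all"))
    minsup <- ceiling(sigma * n_tx - 1e-9)
    want <- oracle_frequent_itemsets(tx, minsup)
    expect_identical(itemset_family_key(got$items),
                     itemset_family_key(lapply(want, `[[`, "items")))
    # supports agree with the oracle, matched by pattern key
    gs <- setNames(got$support, got$pattern_key)
    ws <- setNames(vapply(want, `[[`, integer(1), "support"),
                   vapply(want, function(w)
                     paste(sort(w$items, method = "radix"), collapse = " ; "),
                     character(1)))
    expect_identical(gs[sort(names(gs))], ws[sort(names(gs))])
  }
})

test_that("mine_frequent(mode = 'closed') returns exactly the closed sets", {
  # hand-checkable case: transactions {AB, AB, A}, threshold 2
  tx <- as_tx(list(s1 = c("A", "B"), s2 = c("A", "B"), s3 = "A"))
  got <- mine_frequent(tx, mining_config(sigma = 2 / 3, mode = "closed"))
  expect_identical(itemset_family_key(got$items), c("A", "A ; B"))
  expect_identical(got$support[match(c("A", "A ; B"), got$pattern_key)],
                   c(3L, 2L))
  # random instances against the exhaustive closed oracle
  set.seed(5)
  for (rep in 1:12) {
    n_tx <- sample(3:12, 1)
    universe <- paste0(sample(LETTERS[1:7], sample(4:7, 1)), ">>y")
    tx <- as_tx(setNames(lapply(seq_len(n_tx), function(i)
      sample(universe, sample(0:length(universe), 1))),
      paste0("s", seq_len(n_tx))))
    sigma <- sample(c(0.25, 0.4), 1)
    got <- mine_frequent(tx, mining_config(sigma = sigma, mode = "closed"))
    want <- oracle_closed_itemsets(tx, ceiling(sigma * n_tx - 1e-9))
    expect_identical(itemset_family_key(got$items),
                     itemset_family_key(lapply(want, `[[`, "items")))
  }
})

test_that("planted pattern is recovered with its exact support", {
  # 2-item pattern planted in 6 of 10 transactions over a disjoint background
  set.seed(9)
  planted <- c("P1>>q", "P2>>q")
  bg <- paste0("bg", 1:6, ">>z")
  tx <- as_tx(setNames(lapply(1:10, function(i) {
    items <- sample(bg, sample(0:3, 1))
    if (i <= 6) items <- c(items, planted)
    items
  }), paste0("s", 1:10)))
  got <- mine_frequent(tx, mining_config(sigma = 0.5, mode = "all"))
  hit <- vapply(got$items, function(ii) setequal(ii, planted), logical(1))
  expect_true(any(hit))
  expect_identical(got$support[hit], 6L)
  expect_setequal(got$supporting_sims[hit][[1]], paste0("s", 1:6))
  # its sub-itemsets are reported too in mode = "all"
  expect_true(any(vapply(got$items, function(ii)
    identical(ii, planted[1]), logical(1))))
})

test_that("sigma = 1 keeps only items present in every transaction", {
  tx <- as_tx(list(a = c("X", "Y"), b = c("X", "Z"), c = c("X", "Y")))
  got <- mine_frequent(tx, mining_config(sigma = 1, mode = "all"))
  expect_identical(itemset_family_key(got$items), "X")
  expect_identical(got$frequency, 1)
})

test_that("mining output is deterministically ordered and anti-monotone", {
  set.seed(13)
  tx <- as_tx(setNames(lapply(1:10, function(i)
    sample(paste0(LETTERS[1:6], ">>w"), sample(1:6, 1))), paste0("s", 1:10)))
  a <- mine_frequent(tx, mining_config(sigma = 0.2, mode = "all"))
  b <- mine_frequent(tx, mining_config(sigma = 0.2, mode = "all"))
  expect_identical(a, b)
  # sorted by support desc, then size desc, then key
  expect_true(all(diff(a$support) <= 0))
  # anti-monotonicity: support of any sub-pattern >= support of the pattern
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (i != j && all(a$items[[i]] %in% a$items[[j]]))
      expect_gte(a$support[i], a$support[j])
  }
})

test_that("pattern_support equals the subhypergraph-oracle count", {
  set.seed(21)
  alphabet <- LETTERS[1:6]
  coll <- lapply(1:50, function(i)
    random_hypergraph(paste0("s", i), sample(1:5, 1), alphabet))
  tx <- to_transactions(coll)
  for (rep in 1:100) {
    src <- coll[[sample(50, 1)]]
    items <- if (length(src$edges) == 0) character(0)
             else sample(edge_keys(src), sample(length(src$edges), 1))
    got <- pattern_support(items, tx)
    pat <- decode_pattern(items)
    oracle_n <- sum(vapply(coll, function(g)
      oracle_subhypergraph(pat, g), logical(1)))
    expect_identical(got$support, oracle_n)
  }
  # empty pattern is contained in everything
  expect_identical(pattern_support(character(0), tx)$support, 50L)
})

test_that("mined patterns decode to subhypergraphs of exactly their
           supporting simulations", {
  set.seed(17)
  pool <- replicate(6, random_reaction(LETTERS[1:5]), simplify = FALSE)
  coll <- lapply(1:12, function(i)
    build_hypergraph(sample(pool, sample(1:4, 1)), paste0("s", i)))
  tx <- to_transactions(coll)
  pats <- mine_frequent(tx, mining_config(sigma = 0.25, mode = "closed"))
  expect_gt(nrow(pats), 0)
  for (i in seq_len(nrow(pats))) {
    pat <- decode_pattern(pats$items[[i]])
    inside <- vapply(coll, function(g) oracle_subhypergraph(pat, g),
                     logical(1))
    expect_setequal(vapply(coll, function(g) g$sim_id, character(1))[inside],
                    pats$supporting_sims[[i]])
  }
})

test_that("max_pattern_edges caps reported pattern size in both modes", {
  tx <- as_tx(list(a = c("A", "B", "C"), b = c("A", "B", "C"),
                   c = c("A", "B", "C")))
  for (mode in c("all", "closed")) {
    got <- mine_frequent(tx, mining_config(sigma = 1, mode = mode,
                                           max_pattern_edges = 2))
    expect_true(all(got$n_edges <= 2))
  }
})

test_that("configuration and input errors are rejected", {
  expect_error(mining_config(sigma = 0), "sigma")
  expect_error(mining_config(sigma = 1.2), "sigma")
  expect_error(mine_frequent(as_tx(list()), mining_config()), "empty")
})
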