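# Fisher's exact test, minimum attainable p-values, Tarone's correction,
# odds ratios.

test_that("build_contingency cross-tabulates presence against condition", {
  tx <- as_tx(list(a1 = c("X", "Y"), a2 = "X", a3 = character(0),
                   b1 = c("X", "Y"), b2 = character(0)))
  labels <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  t1 <- build_contingency("X", tx, labels)
  expect_identical(t1, c(a = 2L, b = 1L, c = 1L, d = 1L))
  # pattern absent everywhere
  t0 <- build_contingency("Z", tx, labels)
  expect_identical(t0, c(a = 0L, b = 0L, c = 3L, d = 2L))
  # margins: a+b is the support, a+c the arm size
  t2 <- build_contingency(c("X", "Y"), tx, labels)
  expect_identical(t2[["a"]] + t2[["b"]],
                   pattern_support(c("X", "Y"), tx)$support)
  expect_identical(t2[["a"]] + t2[["c"]], 3L)
  # direction control
  t3 <- build_contingency("X", tx, labels, condition_a = "B")
  expect_identical(t3, c(a = 1L, b = 2L, c = 1L, d = 1L))
  expect_error(build_contingency("X", tx, labels[-1]), "unlabeled")
  expect_error(build_contingency("X", tx,
                                 setNames(rep("A", 5), names(labels))),
               "2 distinct")
})

test_that("random planted collections: table cells match direct recounts", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 30L
    tx <- as_tx(setNames(lapply(1:n, function(i)
      sample(c("u", "v", "w"), sample(0:3, 1))), paste0("s", 1:n)))
    labels <- setNames(sample(c("A", "B"), n, replace = TRUE),
                       names(tx))
    if (length(unique(labels)) < 2) next
    items <- sample(c("u", "v"), sample(1:2, 1))
    t <- build_contingency(items, tx, labels)
    present <- vapply(tx, function(s) all(items %in% s), logical(1))
    expect_identical(t[["a"]], sum(present & labels == "A"))
    expect_identical(t[["b"]], sum(present & labels == "B"))
    expect_identical(sum(t), n)
  }
})

test_that("fisher_two_sided equals hypergeometric enumeration and the
           stats::fisher.test reference on a margin sweep", {
  # exhaustive sweep over all tables with n <= 16 here (the full n <= 30
  # sweep runs in the acceptance suite)
  for (n1 in 0:8) for (n2 in 0:8) for (x in 0:(n1 + n2)) {
    if (n1 + n2 == 0) next
    for (a in max(0, x - n2):min(x, n1)) {
      t <- c(a = a, b = x - a, c = n1 - a, d = n2 - (x - a))
      p <- fisher_two_sided(t)
      expect_equal(p, oracle_fisher(a, x - a, n1 - a, n2 - (x - a)),
                   tolerance = 1e-12)
      if (n1 > 0 && n2 > 0)
        expect_equal(p, stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                     tolerance = 1e-9)
    }
  }
})

test_that("fisher_two_sided handles the documented special cases", {
  expect_identical(fisher_two_sided(c(a = 3, b = 3, c = 3, d = 3)), 1)
  # degenerate margins give exactly 1
  expect_identical(fisher_two_sided(c(a = 0, b = 0, c = 5, d = 5)), 1)
  expect_identical(fisher_two_sided(c(a = 5, b = 5, c = 0, d = 0)), 1)
  expect_identical(fisher_two_sided(c(a = 0, b = 5, c = 0, d = 5)), 1)
  # fully separated 10/10 table: the two extreme tables out of C(20,10)
  p <- fisher_two_sided(c(a = 10, b = 0, c = 0, d = 10))
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  # does not underflow at a few hundred per arm
  big <- fisher_two_sided(c(a = 200, b = 5, c = 50, d = 245))
  expect_gt(big, 0)
  expect_lt(big, 1e-50)
})

test_that("min_attainable_p equals exhaustive minimization and bounds the
           p-value at shared margins", {
  for (n1 in 0:8) for (n2 in 0:8) for (x in 0:(n1 + n2)) {
    if (n1 + n2 == 0) next
    psi <- min_attainable_p(n1, n2, x)
    expect_equal(psi, oracle_min_p(n1, n2, x), tolerance = 1e-12)
    for (a in max(0, x - n2):min(x, n1)) {
      p <- fisher_two_sided(c(a = a, b = x - a, c = n1 - a, d = n2 - (x - a)))
      expect_gte(p, psi - 1e-12)
    }
  }
  # x = 0: only one feasible table
  expect_identical(min_attainable_p(10, 10, 0), 1)
  # psi is non-increasing in x for x <= min(n1, n2) at equal arms
  psis <- vapply(0:10, function(x) min_attainable_p(10, 10, x), numeric(1))
  expect_true(all(diff(psis) <= 1e-12))
})

test_that("tarone_fwer computes the K(alpha) threshold", {
  # 5 strongly testable + 95 untestable hypotheses at alpha = 0.05
  tar <- tarone_fwer(c(rep(1e-6, 5), rep(0.9, 95)), 0.05)
  expect_identical(tar$k_alpha, 5L)
  expect_equal(tar$delta, 0.01)
  expect_identical(tar$testable, 1:5)
  # all psis above alpha: nothing testable
  tar0 <- tarone_fwer(rep(0.9, 50), 0.05)
  expect_length(tar0$testable, 0)
  # never more stringent than Bonferroni over all m
  set.seed(41)
  for (rep in 1:20) {
    m <- sample(5:200, 1)
    psis <- runif(m)^sample(1:4, 1)
    tar <- tarone_fwer(psis, 0.05)
    expect_lte(tar$k_alpha, m)
    expect_gte(tar$delta, 0.05 / m)
    # definition check: K is the smallest k with |{psi <= alpha/k}| <= k
    expect_lte(sum(psis <= 0.05 / tar$k_alpha), tar$k_alpha)
    if (tar$k_alpha > 1)
      expect_gt(sum(psis <= 0.05 / (tar$k_alpha - 1)), tar$k_alpha - 1)
  }
  # empty input
  empty <- tarone_fwer(numeric(0), 0.05)
  expect_length(empty$testable, 0)
  expect_equal(empty$delta, 0.05)
})

test_that("odds_ratio_ci follows the Haldane-Anscombe / Woolf formulas", {
  r <- odds_ratio_ci(c(a = 3, b = 3, c = 3, d = 3))
  expect_equal(r[["odds_ratio"]], 1)
  expect_true(r[["ci_low"]] < 1 && 1 < r[["ci_high"]])
  r2 <- odds_ratio_ci(c(a = 4, b = 2, c = 2, d = 4))
  expect_equal(r2[["odds_ratio"]], 4)
  se <- sqrt(1 / 4 + 1 / 2 + 1 / 2 + 1 / 4)
  expect_equal(r2[["ci_low"]], 4 * exp(-qnorm(0.975) * se))
  expect_equal(r2[["ci_high"]], 4 * exp(qnorm(0.975) * se))
  # zero cells: +0.5 on every cell keeps the estimate finite
  r3 <- odds_ratio_ci(c(a = 5, b = 0, c = 0, d = 5))
  expect_equal(r3[["odds_ratio"]], (5.5 * 5.5) / (0.5 * 0.5))
  se3 <- sqrt(2 / 5.5 + 2 / 0.5)
  expect_equal(r3[["ci_low"]], r3[["odds_ratio"]] * exp(-qnorm(0.975) * se3))
  expect_true(is.finite(r3[["ci_high"]]))
})

test_that("significant_patterns applies the three corrections coherently", {
  set.seed(51)
  # one strongly enriched pattern among independent nuisance patterns
  n <- 60
  sims <- paste0("s", 1:n)
  labels <- setNames(rep(c("A", "B"), each = n / 2), sims)
  tx <- as_tx(setNames(lapply(1:n, function(i) {
    items <- paste0("noise", which(runif(8) < 0.4), ">>z")
    pa <- if (labels[i] == "A") 0.9 else 0.1
    if (runif(1) < pa) items <- c(items, "planted>>z")
    items
  }), sims))
  pats <- mine_frequent(tx, mining_config(sigma = 0.1, mode = "all",
                                          max_pattern_edges = 2))
  res_fwer <- significant_patterns(pats, tx, labels,
                                   test_config(method = "tarone_fwer"))
  res_bonf <- significant_patterns(pats, tx, labels,
                                   test_config(method = "bonferroni"))
  res_fdr <- significant_patterns(pats, tx, labels,
                                  test_config(method = "tarone_fdr"))
  # the planted singleton is discovered by all three procedures
  for (res in list(res_fwer, res_bonf, res_fdr)) {
    expect_true(res$significant[res$pattern_key == "planted>>z"])
    # significant implies testable
    expect_true(all(res$testable[res$significant]))
    # results are sorted by p-value
    expect_true(all(diff(res$p_value) >= 0))
  }
  # Tarone discoveries contain the Bonferroni discoveries
  expect_true(all(res_bonf$pattern_key[res_bonf$significant] %in%
                  res_fwer$pattern_key[res_fwer$significant]))
  # consistency of the decision rule with the reported threshold
  expect_identical(res_fwer$significant,
                   res_fwer$testable & res_fwer$p_value <= res_fwer$delta)
  expect_identical(res_bonf$significant,
                   res_bonf$p_value <= res_bonf$alpha / nrow(res_bonf))
  # single pattern, Bonferroni with m = 1 reduces to the raw test
  one <- pats[pats$pattern_key == "planted>>z", ]
  res1 <- significant_patterns(one, tx, labels,
                               test_config(method = "bonferroni"))
  expect_identical(res1$significant, res1$p_value <= 0.05)
})

test_that("under the null the FWER of tarone_fwer stays at alpha", {
  # 60 replicates here as a smoke check; the >= 1000-replicate version runs
  # in the acceptance suite
  set.seed(61)
  n1 <- 25; n2 <- 25
  false_pos <- vapply(1:60, function(rep) {
    x <- rbinom(40, n1 + n2, runif(40, 0.05, 0.95))
    a <- vapply(x, function(xi) sum(sample(c(rep(TRUE, xi),
      rep(FALSE, n1 + n2 - xi)))[1:n1]), integer(1))
    p <- vapply(seq_along(x), function(i) fisher_two_sided(
      c(a = a[i], b = x[i] - a[i], c = n1 - a[i], d = n2 - (x[i] - a[i]))),
      numeric(1))
    psi <- vapply(x, function(xi) min_attainable_p(n1, n2, xi), numeric(1))
    tar <- tarone_fwer(psi, 0.05)
    any(p[tar$testable] <= tar$delta)
  }, logical(1))
  expect_lte(mean(false_pos), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("log odds-ratio estimates recover a planted effect", {
  set.seed(71)
  n <- 120
  pa <- 0.7; pb <- 0.3
  planted_lor <- log((pa / (1 - pa)) / (pb / (1 - pb)))
  lors <- vapply(1:500, function(rep) {
    a <- rbinom(1, n, pa); b <- rbinom(1, n, pb)
    log(odds_ratio_ci(c(a = a, b = b, c = n - a, d = n - b))[["odds_ratio"]])
  }, numeric(1))
  expect_lt(abs(mean(lors) - planted_lor), 2 * sd(lors) / sqrt(length(lors)))
})
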