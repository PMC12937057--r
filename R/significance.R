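## Enrichment testing: Fisher's exact test per reactive pattern, minimum
## attainable p-values, Tarone's correction (FWER), BH-on-testable (FDR),
## plain Bonferroni, and odds-ratio effect sizes.

#' Test configuration for pattern enrichment
#'
#' @param alpha significance level in (0, 1); default 0.05.
#' @param method multiple-testing procedure: `"tarone_fwer"` (default)
#'   controls the family-wise error rate using Tarone's correction, which
#'   discards untestable hypotheses (minimum attainable p-value above the
#'   corrected level) before a Bonferroni-style adjustment; `"tarone_fdr"`
#'   applies Benjamini-Hochberg step-up restricted to the Tarone-testable
#'   hypotheses (an interpretation -- see the methods vignette);
#'   `"bonferroni"` is the plain alpha/m correction over all m patterns.
#' @return a `test_config` list.
#' @export
test_config <- function(alpha = 0.05,
                        method = c("tarone_fwer", "tarone_fdr", "bonferroni")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("config error: alpha must be in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, method = match.arg(method)),
            class = "test_config")
}

#' 2x2 contingency table of pattern presence vs binary condition
#'
#' Cross-tabulates, over all simulations, the Bernoulli indicator "pattern
#' present in the simulation's CRN" against the binary condition label:
#' `a` = present under condition A, `b` = present under B, `c` = absent under
#' A, `d` = absent under B.
#'
#' @param items character vector of item keys defining the pattern.
#' @param transactions a `crn_transactions`.
#' @param labels named character vector (sim_id -> label) with exactly two
#'   distinct values covering every transaction.
#' @param condition_a which label plays the role of condition A (rows `a`,
#'   `c`); default the lexicographically first label. Determines the
#'   direction of the odds ratio.
#' @return named integer vector `c(a =, b =, c =, d =)`.
#' @export
build_contingency <- function(items, transactions, labels,
                              condition_a = NULL) {
  sims <- names(transactions)
  if (!all(sims %in% names(labels)))
    stop("input error: unlabeled simulation(s): ",
         paste(head(setdiff(sims, names(labels)), 5), collapse = ", "),
         call. = FALSE)
  lab <- as.character(labels[sims])
  lev <- sort(unique(lab), method = "radix")
  if (length(lev) != 2L)
    stop("input error: need exactly 2 distinct condition labels, got ",
         length(lev), call. = FALSE)
  if (is.null(condition_a)) condition_a <- lev[1]
  if (!condition_a %in% lev)
    stop("input error: condition_a not among labels", call. = FALSE)
  inA <- lab == condition_a
  present <- vapply(transactions, function(tx) all(items %in% tx), logical(1))
  c(a = sum(present & inA), b = sum(present & !inA),
    c = sum(!present & inA), d = sum(!present & !inA))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value under the hypergeometric null with fixed margins, using the
#' point-probability convention: the sum of the probabilities of all tables
#' (with the same margins) whose point probability does not exceed that of
#' the observed table. Computed in log-space so tables with a few hundred
#' simulations per arm do not underflow. Degenerate margins (pattern present
#' everywhere/nowhere, or a condition arm empty) give p = 1 exactly.
#'
#' @param t named vector `c(a, b, c, d)` as from [build_contingency()].
#' @return p-value in (0, 1].
#' @export
fisher_two_sided <- function(t) {
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  if (min(a, b, cc, d) < 0) stop("negative count", call. = FALSE)
  n1 <- a + cc; n2 <- b + d; x <- a + b; n <- n1 + n2
  if (n == 0L) stop("empty table", call. = FALSE)
  if (x == 0L || x == n || n1 == 0L || n2 == 0L) return(1)
  lo <- max(0L, x - n2); hi <- min(x, n1)
  k <- lo:hi
  lp <- dhyper(k, n1, n2, x, log = TRUE)
  lobs <- dhyper(a, n1, n2, x, log = TRUE)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

.psi_cache <- new.env(parent = emptyenv())

#' Minimum attainable p-value for given margins and pattern support
#'
#' The smallest two-sided Fisher p-value achievable by any feasible 2x2 table
#' with `n1` condition-A simulations, `n2` condition-B simulations and total
#' pattern support `x`. Because the test is discrete, patterns with low (or
#' near-saturating) support cannot reach small p-values no matter how the
#' support splits across conditions; this quantity is the basis of Tarone
#' testability. Computed by exact minimization over all feasible splits and
#' memoized on `(n1, n2, x)`.
#'
#' @param n1,n2 arm sizes; `x` total support, `0 <= x <= n1 + n2`.
#' @return the minimum attainable p-value in (0, 1].
#' @export
min_attainable_p <- function(n1, n2, x) {
  stopifnot(n1 >= 0, n2 >= 0, x >= 0, x <= n1 + n2)
  if (n1 + n2 == 0) return(1)
  key <- paste(n1, n2, x)
  hit <- .psi_cache[[key]]
  if (!is.null(hit)) return(hit)
  lo <- max(0L, x - n2); hi <- min(x, n1)
  ps <- vapply(lo:hi, function(a)
    fisher_two_sided(c(a = a, b = x - a, c = n1 - a, d = n2 - (x - a))),
    numeric(1))
  psi <- min(ps)
  .psi_cache[[key]] <- psi
  psi
}

#' Tarone's correction for FWER control over discrete tests
#'
#' Given the minimum attainable p-values `psis` of `m` hypotheses, finds the
#' smallest integer `K` such that the number of hypotheses with
#' `psi <= alpha / K` is at most `K`. Hypotheses with `psi` above the
#' corrected level `alpha / K` can never be rejected and are discarded as
#' untestable; Bonferroni over the remaining (testable) hypotheses then
#' controls the FWER at `alpha` with strictly better power than alpha/m.
#'
#' @param psis numeric vector of minimum attainable p-values in (0, 1].
#' @param alpha target FWER level.
#' @return list with `delta` (corrected per-test level alpha/K), `k_alpha`
#'   (the integer K), and `testable` (indices with `psi <= delta`).
#' @export
tarone_fwer <- function(psis, alpha = 0.05) {
  if (length(psis) == 0L)
    return(list(delta = alpha, k_alpha = 1L, testable = integer(0)))
  stopifnot(all(psis > 0), all(psis <= 1), alpha > 0, alpha < 1)
  k <- 1L
  while (sum(psis <= alpha / k) > k) k <- k + 1L
  list(delta = alpha / k, k_alpha = k, testable = which(psis <= alpha / k))
}

#' Odds ratio with 95% confidence interval for a 2x2 table
#'
#' Sample odds ratio `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell, keeping the estimate
#' finite. The 95% CI is the log-normal (Woolf) interval
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` on the (corrected)
#' counts.
#'
#' @param t named vector `c(a, b, c, d)`.
#' @return named numeric `c(odds_ratio, ci_low, ci_high)`.
#' @export
odds_ratio_ci <- function(t) {
  x <- as.numeric(t[c("a", "b", "c", "d")])
  if (any(x == 0)) x <- x + 0.5
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  z <- qnorm(0.975)
  c(odds_ratio = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

#' Test mined patterns for association with a binary condition
#'
#' For every mined reactive pattern, builds the 2x2 presence-by-condition
#' table, computes the two-sided Fisher exact p-value and the minimum
#' attainable p-value, applies the configured multiple-testing procedure, and
#' reports odds ratios with 95% CIs. With `method = "tarone_fwer"` a pattern
#' is significant iff it is testable and `p <= delta`; with `"bonferroni"`
#' iff `p <= alpha/m`; with `"tarone_fdr"` iff it survives BH step-up at
#' level alpha within the testable set.
#'
#' @param patterns data.frame from [mine_frequent()] (columns `pattern_key`,
#'   `items`, `supporting_sims` are used).
#' @param transactions the `crn_transactions` the patterns were mined from.
#' @param labels named character vector sim_id -> condition label (2 levels).
#' @param config a [test_config()].
#' @param condition_a see [build_contingency()].
#' @return data.frame sorted by p-value then pattern key, with columns
#'   `pattern_id`, `pattern_key`, `a`, `b`, `c`, `d`, `support`, `p_value`,
#'   `min_p`, `testable`, `significant`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `method`, `alpha`, `delta`, and attributes `n_testable`/`n_significant`.
#' @export
significant_patterns <- function(patterns, transactions, labels,
                                 config = test_config(),
                                 condition_a = NULL) {
  if (!inherits(config, "test_config")) stop("config error", call. = FALSE)
  m <- nrow(patterns)
  if (m == 0L) stop("input error: no patterns to test", call. = FALSE)
  tabs <- lapply(patterns$items, build_contingency, transactions = transactions,
                 labels = labels, condition_a = condition_a)
  p <- vapply(tabs, fisher_two_sided, numeric(1))
  n1 <- tabs[[1]][["a"]] + tabs[[1]][["c"]]
  n2 <- tabs[[1]][["b"]] + tabs[[1]][["d"]]
  psi <- vapply(tabs, function(t)
    min_attainable_p(n1, n2, t[["a"]] + t[["b"]]), numeric(1))

  alpha <- config$alpha
  if (config$method == "bonferroni") {
    delta <- alpha / m
    testable <- rep(TRUE, m)
    signif <- p <= delta
  } else {
    tar <- tarone_fwer(psi, alpha)
    delta <- tar$delta
    testable <- seq_len(m) %in% tar$testable
    if (config$method == "tarone_fwer") {
      signif <- testable & p <= delta
    } else {                                   # tarone_fdr: BH on testable
      signif <- rep(FALSE, m)
      if (any(testable))
        signif[testable] <- p.adjust(p[testable], method = "BH") <= alpha
    }
  }

  or <- t(vapply(tabs, odds_ratio_ci, numeric(3)))
  out <- data.frame(
    pattern_id = patterns$pattern_id,
    pattern_key = patterns$pattern_key,
    a = vapply(tabs, `[[`, integer(1), "a"),
    b = vapply(tabs, `[[`, integer(1), "b"),
    c = vapply(tabs, `[[`, integer(1), "c"),
    d = vapply(tabs, `[[`, integer(1), "d"),
    support = patterns$support,
    p_value = p, min_p = psi, testable = testable, significant = signif,
    odds_ratio = or[, 1], ci_low = or[, 2], ci_high = or[, 3],
    method = config$method, alpha = alpha, delta = delta,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$pattern_key, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "n_testable") <- sum(testable)
  attr(out, "n_significant") <- sum(signif)
  out
}
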