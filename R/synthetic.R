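## Synthetic labeled collections of reaction hypergraphs with known ground
## truth, for end-to-end validation of mining and enrichment testing.
##
## The generative model mirrors the statistical assumptions of the analysis:
## simulations are independent; each background reaction enters a
## simulation's CRN independently with a fixed probability; each planted
## pattern enters atomically (all of its reactions at once) with a
## condition-specific Bernoulli probability. Chemistry plays no role in the
## generation -- the species are small real SMILES from the ammonia / carbon
## dioxide / water system so examples read naturally.

.species_pool <- c("N", "O=C=O", "O", "[NH4+]", "[OH-]", "NC(=O)O",
                   "NC(=O)[O-]", "OC(=O)O", "OC(=O)[O-]", "[H][H]", "CO",
                   "C=O", "OCO", "NCO", "NC=O")

#' Deterministic pool of background reactions
#'
#' Enumerates simple two-reactant one-product reactions over a fixed species
#' alphabet, in a fixed order, and returns the first `n`. Used as the default
#' background of [generator_spec()].
#'
#' @param n number of reactions (at most 200).
#' @return list of `crn_reaction`.
#' @export
default_background_pool <- function(n = 20) {
  sp <- .species_pool
  out <- list()
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j <= i) next
      for (k in seq_along(sp)) {
        if (k == i || k == j) next
        out[[length(out) + 1L]] <-
          reaction(setNames(c(1L, 1L), sp[c(i, j)]), setNames(1L, sp[k]))
        if (length(out) == n) return(out)
      }
    }
  }
  if (length(out) < n) stop("background pool exhausted", call. = FALSE)
  out
}

.default_planted <- function() {
  list(list(
    reactions = list(
      # carbamate formation with a second ammonia as proton acceptor,
      # then proton back-transfer yielding carbamic acid
      reaction(c("N" = 2, "O=C=O" = 1), c("NC(=O)[O-]" = 1, "[NH4+]" = 1)),
      reaction(c("NC(=O)[O-]" = 1, "[NH4+]" = 1), c("N" = 1, "NC(=O)O" = 1))
    ),
    prob_a = 0.8, prob_b = 0.1
  ))
}

#' Specification of a synthetic collection
#'
#' Defines two equally sized arms of independent simulations under a binary
#' condition (by default the two equilibrium temperatures 39 K and 62 K).
#' Each simulation's CRN is the union of (i) background reactions drawn
#' independently with probability `background_prob` each and (ii) planted
#' patterns, each included atomically with probability `prob_a` under
#' condition A and `prob_b` under condition B.
#'
#' @param n_sims_per_condition simulations per arm (default 100, the scale at
#'   which binary per-simulation presence is a stable frequency estimate).
#' @param background_pool list of `crn_reaction` (default
#'   [default_background_pool()] of size 20).
#' @param background_prob scalar or per-reaction inclusion probability
#'   (default 0.3).
#' @param planted_patterns list of `list(reactions =, prob_a =, prob_b =)`;
#'   default one two-step carbamic-acid pattern at (0.8, 0.1).
#' @param condition_labels two labels, A then B (default `"T39K"`, `"T62K"`).
#' @param condition_values named list of two numeric condition values written
#'   into each record's condition map (default `T_K = c(39, 62)`).
#' @param seed integer RNG seed.
#' @param allow_overlap permit planted reactions to coincide with background
#'   reactions (default FALSE: overlap is an error).
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_sims_per_condition = 100,
                           background_pool = default_background_pool(20),
                           background_prob = 0.3,
                           planted_patterns = .default_planted(),
                           condition_labels = c("T39K", "T62K"),
                           condition_values = list(T_K = c(39, 62)),
                           seed = 1L,
                           allow_overlap = FALSE) {
  stopifnot(n_sims_per_condition >= 1, length(condition_labels) == 2L)
  bp <- rep_len(background_prob, length(background_pool))
  probs <- c(bp, unlist(lapply(planted_patterns, function(pp)
    c(pp$prob_a, pp$prob_b))))
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must be in [0, 1]", call. = FALSE)
  bg_keys <- vapply(background_pool, canonical_item, character(1))
  pl_keys <- unlist(lapply(planted_patterns, function(pp)
    vapply(pp$reactions, canonical_item, character(1))))
  if (!allow_overlap && any(pl_keys %in% bg_keys))
    stop("config error: planted reactions overlap the background pool",
         call. = FALSE)
  structure(list(n_sims_per_condition = as.integer(n_sims_per_condition),
                 background_pool = background_pool, background_prob = bp,
                 planted_patterns = planted_patterns,
                 condition_labels = condition_labels,
                 condition_values = condition_values,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a labeled collection of reaction hypergraphs
#'
#' Draws the collection described by a [generator_spec()], fully reproducibly
#' for a given seed. The returned ground truth records, per planted pattern,
#' the realized per-condition supports and both the implied (from the
#' Bernoulli probabilities) and realized odds ratios.
#'
#' @param spec a [generator_spec()].
#' @return list with `collection` (list of `crn_hypergraph`), `labels` (named
#'   character vector sim_id -> condition label), and `ground_truth`
#'   (data.frame: pattern_key, prob_a, prob_b, support_a, support_b,
#'   implied_odds_ratio, realized_odds_ratio).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_sims_per_condition
  labs <- spec$condition_labels
  npat <- length(spec$planted_patterns)
  support <- matrix(0L, nrow = max(npat, 1L), ncol = 2L)

  collection <- vector("list", 2L * n)
  labels <- character(2L * n)
  idx <- 0L
  for (arm in 1:2) {
    cond <- c(list(label = labs[arm]),
              lapply(spec$condition_values, `[`, arm))
    for (s in seq_len(n)) {
      idx <- idx + 1L
      sim_id <- sprintf("%s_%03d", labs[arm], s)
      events <- spec$background_pool[
        runif(length(spec$background_pool)) < spec$background_prob]
      if (npat > 0L) {
        for (q in seq_len(npat)) {
          pp <- spec$planted_patterns[[q]]
          pq <- if (arm == 1L) pp$prob_a else pp$prob_b
          if (runif(1) < pq) {
            events <- c(events, pp$reactions)
            support[q, arm] <- support[q, arm] + 1L
          }
        }
      }
      collection[[idx]] <- build_hypergraph(events, sim_id, cond)
      labels[idx] <- labs[arm]
    }
  }
  names(labels) <- vapply(collection, function(g) g$sim_id, character(1))

  gt <- NULL
  if (npat > 0L) {
    odds <- function(p) p / (1 - p)
    gt <- data.frame(
      pattern_key = vapply(spec$planted_patterns, function(pp)
        paste(sort(vapply(pp$reactions, canonical_item, character(1)),
                   method = "radix"), collapse = " ; "), character(1)),
      prob_a = vapply(spec$planted_patterns, `[[`, numeric(1), "prob_a"),
      prob_b = vapply(spec$planted_patterns, `[[`, numeric(1), "prob_b"),
      support_a = support[, 1], support_b = support[, 2],
      stringsAsFactors = FALSE
    )
    gt$implied_odds_ratio <- odds(gt$prob_a) / odds(gt$prob_b)
    gt$realized_odds_ratio <- (gt$support_a * (n - gt$support_b)) /
      pmax(1e-12, gt$support_b * (n - gt$support_a))
  }
  list(collection = collection, labels = labels, ground_truth = gt)
}
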