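# The site-substitution null model: the probability that k spatially
# independent populations acquire the *same* substitution (same original base,
# same variant base) at the same site through random mutation alone. Each
# population contributes an ordered (original, variant) assignment from the
# 4 x 4 = 16 base combinations; of the 16^k joint assignments, exactly 12
# (the 16 equal pairs minus the 4 no-change cases) have all k populations
# matching on a true change. Hence p = 12 / 16^k, the 12/256 pair and
# 12/4,096 triplet probabilities.

#' Exact convergence probability for k populations
#'
#' Returns 12 / 16^k as an exact rational (integer numerator and
#' denominator; no floating-point construction).
#'
#' @param k number of populations (>= 1).
#' @return object of class `convergence_prob` with fields `numerator`,
#'   `denominator`, `k`; `as.numeric()` gives the probability.
#' @export
convergence_probability <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  den <- prod(rep(16, k))  # exact in double precision for any sane k
  if (den > 2^53) stop("k too large for exact integer arithmetic")
  structure(list(numerator = 12, denominator = den, k = k),
            class = "convergence_prob")
}

#' @export
as.double.convergence_prob <- function(x, ...) x$numerator / x$denominator

#' @export
print.convergence_prob <- function(x, ...) {
  cat(sprintf("convergence probability (k = %d): %s/%s = %.6g\n", x$k,
              format(x$numerator, big.mark = ","),
              format(x$denominator, big.mark = ","), as.numeric(x)))
  invisible(x)
}

#' Brute-force enumeration of matching substitution assignments
#'
#' Enumerates all 16^k ordered (original, variant) assignments for k
#' populations and counts those where every population has original !=
#' variant and all k share the identical (original, variant) pair. This is
#' the exhaustive count the closed form 12/16^k summarizes, kept independent
#' of [convergence_probability()] so each can check the other.
#'
#' @param k number of populations, in 1..5 (combinatorial explosion guard).
#' @return named integer vector `c(n_matching, n_total)`.
#' @export
enumerate_matches <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 5 || k != as.integer(k))
    stop("k must be a single integer in 1..5")
  k <- as.integer(k)
  combos <- as.matrix(do.call(expand.grid, rep(list(1:16), k)))
  orig <- (combos - 1L) %/% 4L
  var <- (combos - 1L) %% 4L
  changed <- orig != var
  all_changed <- rowSums(changed) == k
  same_pair <- matrixStats_all_equal(combos)
  c(n_matching = sum(all_changed & same_pair), n_total = nrow(combos))
}

matrixStats_all_equal <- function(m) {
  if (ncol(m) == 1) return(rep(TRUE, nrow(m)))
  out <- rep(TRUE, nrow(m))
  for (j in 2:ncol(m)) out <- out & (m[, j] == m[, 1])
  out
}

#' Expected number of convergent same-substitution SNVs
#'
#' `p_convergent(k) * n_same_site`: the number of shared same-site SNVs
#' expected to carry the same substitution through convergent (random)
#' mutation alone, in the absence of gene flow or shared ancestry.
#'
#' @param n_same_site number of SNVs shared at the same homologous site.
#' @param k number of populations in the comparison (2 for pairs, 3 for
#'   triplets).
#' @return numeric expectation (unrounded; see [format_expected()] for the
#'   reporting convention).
#' @export
expected_convergent <- function(n_same_site, k = 2) {
  if (any(is.na(n_same_site)) || any(n_same_site < 0))
    stop("n_same_site must be >= 0")
  p <- convergence_probability(k)
  p$numerator * n_same_site / p$denominator
}

#' Classify gene-flow evidence for a MAG group
#'
#' Evidence for gene flow or shared ancestry is called when the observed
#' same-substitution count strictly exceeds the (unrounded) convergent
#' expectation; otherwise "none".
#'
#' @param observed_same_substitution observed shared same-substitution count.
#' @param expected expected convergent count ([expected_convergent()]).
#' @return "gene_flow_or_ancestry" or "none" (vectorized).
#' @export
classify_evidence <- function(observed_same_substitution, expected) {
  if (any(observed_same_substitution < 0) || any(expected < 0))
    stop("counts must be >= 0")
  ifelse(observed_same_substitution > expected, "gene_flow_or_ancestry", "none")
}

#' Monte-Carlo check of the convergence probability
#'
#' Simulates `n_sites` sites; at each, k populations independently draw an
#' ordered (original, variant) assignment uniformly over the 4 x 4 = 16 base
#' combinations - the model's sample space, which deliberately includes the
#' four no-change assignments in the denominator. A site converges when all k
#' assignments are identical *and* are a true change (original != variant).
#' Returns the convergent fraction with an exact (Clopper-Pearson) confidence
#' interval, per replicate.
#'
#' @param n_sites sites per replicate.
#' @param k populations per site.
#' @param reps number of replicates (default 1).
#' @param seed RNG seed (deterministic output).
#' @param conf confidence level for the interval (default 0.99).
#' @return data.frame with rep, fraction, lower, upper, n_sites.
#' @export
monte_carlo_convergence <- function(n_sites, k = 2, reps = 1, seed = 1,
                                    conf = 0.99) {
  if (n_sites <= 0 || reps <= 0) stop("n_sites and reps must be positive")
  set.seed(seed)
  out <- lapply(seq_len(reps), function(r) {
    orig <- matrix(sample.int(4L, n_sites * k, replace = TRUE), n_sites, k)
    var <- matrix(sample.int(4L, n_sites * k, replace = TRUE), n_sites, k)
    pair <- (orig - 1L) * 4L + var
    same <- orig[, 1] != var[, 1]           # a true change...
    if (k > 1) for (j in 2:k) same <- same & (pair[, j] == pair[, 1])
    x <- sum(same)                          # ...shared by all k
    alpha <- 1 - conf
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n_sites - x + 1)
    upper <- if (x == n_sites) 1 else stats::qbeta(1 - alpha / 2, x + 1,
                                                   n_sites - x)
    data.frame(rep = r, fraction = x / n_sites, lower = lower, upper = upper,
               n_sites = n_sites)
  })
  do.call(rbind, out)
}

#' Build the convergence evidence table for pair/triplet summaries
#'
#' Adds, per [summarize_groups()] row, the exact null probability, the
#' expected convergent count, and the evidence call - the shape of the
#' study's per-pair shared-SNV evidence table.
#'
#' @param group_summaries data.frame from [summarize_groups()] (mag_set, kind,
#'   n_same_site, n_same_substitution).
#' @return the input with p_convergent, expected_convergent,
#'   expected_display (the "<1" convention) and evidence columns.
#' @export
convergence_table <- function(group_summaries) {
  g <- group_summaries
  k <- ifelse(g$kind == "triplet", 3L, 2L)
  g$p_convergent <- vapply(k, function(kk)
    as.numeric(convergence_probability(kk)), numeric(1))
  g$expected_convergent <- g$p_convergent * g$n_same_site
  g$expected_display <- vapply(seq_len(nrow(g)), function(i)
    format_expected(g$expected_convergent[i],
                    digits = if (g$kind[i] == "triplet") 3L else 2L),
    character(1))
  g$evidence <- classify_evidence(g$n_same_substitution, g$expected_convergent)
  g
}

#' Display rule for expected convergent counts
#'
#' Positive expectations below one are rendered `"<1 (x)"` with the numeric
#' value alongside; zero is "0"; otherwise the value rounded to `digits`.
#'
#' @param x numeric expectation.
#' @param digits decimals for the rounded display (2 for pairs, 3 for
#'   triplets by convention).
#' @return character.
#' @export
format_expected <- function(x, digits = 2L) {
  if (is.na(x)) return(NA_character_)
  if (x == 0) return("0")
  if (x < 1) return(sprintf("<1 (%s)", format(round(x, max(digits, 2L)),
                                              nsmall = 0)))
  format(round(x, digits), nsmall = digits)
}
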