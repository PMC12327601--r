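# Reaction-likelihood scoring.
#
# Per-atom site-of-metabolism scores (a pluggable input: a CSV exported
# from an external predictor, or a built-in heuristic baseline used only
# for pipeline testing) are restricted to the reaction center — the
# substrate atoms whose bonding changes between substrate and product —
# and the maximum score within the center is the reaction likelihood.
# Score populations (e.g., known vs random enzyme-substrate pairs) are
# compared with a tie-aware Mann-Whitney U test, exact for small samples.

#' Reaction center of a substrate -> product transformation
#'
#' Substrate atom indices (0-based, heavy atoms) whose bonding changes:
#' bonds formed, broken, or changed in order. Primary route: the rule's own
#' atom-mapped reaction template, located on the substrate via the template
#' match that reproduces the given product. Fallback (no template, or no
#' reproducing match): atoms outside the maximum common substructure of
#' substrate and product, plus their attachment atoms. An identity
#' transformation has no center and is an error.
#'
#' @param substrate,product SMILES strings.
#' @param rule optional `ReactionRule` providing the mapped template.
#' @return integer vector of 0-based substrate atom indices, with
#'   attribute `method` ("template" or "mcs").
#' @export
reaction_center <- function(substrate, product, rule = NULL) {
  res <- chem_call(list(op = "reaction_center", substrate = substrate,
                        product = product,
                        rxn_smarts = if (!is.null(rule)) rule$smarts))
  if (!is.null(res$error)) stop2("reaction_center: %s", res$error)
  atoms <- as.integer(unlist(res$atoms))
  attr(atoms, "method") <- res$method
  atoms
}

#' Reaction likelihood from atom scores and a reaction center
#'
#' The maximum site-of-metabolism score over the reaction-center atoms.
#' Raising any center atom's score can never lower the likelihood.
#'
#' @param scores numeric vector of per-atom scores in \[0, 1\], named or
#'   indexed by 0-based atom index (unnamed vectors are taken as atoms
#'   0..length-1).
#' @param center integer vector of 0-based center atom indices.
#' @return likelihood in \[0, 1\].
#' @export
reaction_likelihood <- function(scores, center) {
  if (is.null(names(scores))) {
    names(scores) <- as.character(seq_along(scores) - 1L)
  }
  key <- as.character(center)
  missing <- key[!key %in% names(scores)]
  if (length(missing) > 0) {
    stop2("no atom score for center atom(s): %s",
          paste(missing, collapse = ", "))
  }
  max(scores[key])
}

#' Read per-atom site-of-metabolism scores
#'
#' CSV with columns `structure_id`, `atom_index` (0-based heavy-atom
#' index), `score` in \[0, 1\].
#'
#' @param path CSV path.
#' @return named list: structure_id -> named score vector.
#' @export
read_atom_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "atom_index", "score")
  if (!all(need %in% names(df))) {
    stop2("atom-score table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$score < 0 | df$score > 1)) stop2("scores must lie in [0, 1]")
  lapply(split(df, df$structure_id), function(d) {
    stats::setNames(d$score, as.character(d$atom_index))
  })
}

#' Heuristic baseline atom scores
#'
#' For pipeline testing only (the package deliberately does not bundle a
#' trained site-of-metabolism model): `"degree"` scores each heavy atom by
#' its degree divided by the maximum degree; `"uniform"` scores every atom
#' 0.5.
#'
#' @param smiles character vector of structures.
#' @param method `"degree"` or `"uniform"`.
#' @return named list: smiles -> named score vector (0-based indices).
#' @export
heuristic_atom_scores <- function(smiles, method = c("degree", "uniform")) {
  method <- match.arg(method)
  res <- chem_call(list(op = "atom_scores", smiles = as.list(smiles),
                        method = method))
  out <- lapply(res$scores, function(s) {
    if (is.null(s)) return(NULL)
    v <- unlist(s)
    stats::setNames(v, as.character(seq_along(v) - 1L))
  })
  names(out) <- smiles
  out
}

# ---- tie-aware rank-sum machinery -----------------------------------------

# Exact null distribution of the doubled rank sum of group 1 (size n1) over
# the pooled average ranks, by dynamic programming. Average ranks are
# half-integers, so doubling makes every achievable sum an integer; the DP
# table counts subsets by (size, doubled sum) and is equivalent to full
# enumeration of all choose(n1+n2, n1) assignments.
rank_sum_null <- function(ranks2, n1) {
  total <- sum(ranks2)
  counts <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  counts[1, 1] <- 1
  for (d in ranks2) {
    kmax <- n1
    counts[2:(kmax + 1), (d + 1):(total + 1)] <-
      counts[2:(kmax + 1), (d + 1):(total + 1)] +
      counts[1:kmax, 1:(total + 1 - d)]
  }
  counts[n1 + 1, ]  # index s+1 = number of subsets with doubled sum s
}

# One- or two-sided rank-sum test. Exact when n1*n2 <= max_exact,
# otherwise normal approximation with tie correction and continuity
# correction. Returns list(U, W, p, exact).
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater"),
                          max_exact = 400) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop2("empty sample")
  n1 <- length(x)
  n2 <- length(y)
  ranks <- rank(c(x, y), ties.method = "average")
  w_obs <- sum(ranks[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (n1 * n2 <= max_exact) {
    dist <- rank_sum_null(as.integer(round(2 * ranks)), n1)
    total <- sum(dist)
    s <- seq_along(dist) - 1  # doubled rank sums
    w2 <- round(2 * w_obs)
    if (alternative == "greater") {
      p <- sum(dist[s >= w2 - 1e-9]) / total
    } else {
      mu2 <- n1 * (n1 + n2 + 1)  # doubled mean rank sum
      dev <- abs(w2 - mu2)
      p <- sum(dist[abs(s - mu2) >= dev - 1e-9]) / total
    }
    return(list(U = u_obs, W = w_obs, p = min(p, 1), exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(ranks)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = u_obs, W = w_obs, p = 1, exact = FALSE))
  z <- w_obs - mu
  cc <- 0.5
  if (alternative == "greater") {
    p <- stats::pnorm((z - cc) / sqrt(sigma2), lower.tail = FALSE)
  } else {
    p <- 2 * stats::pnorm((abs(z) - cc) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(U = u_obs, W = w_obs, p = min(max(p, 0), 1), exact = FALSE)
}

#' Compare two reaction-likelihood score populations
#'
#' Two-sided Mann-Whitney U test with tie correction; the null
#' distribution is computed exactly (equivalent to full enumeration of all
#' group assignments) when `n1 * n2 <= 400`, and by normal approximation
#' otherwise. U is reported for the first sample
#' (`U = W1 - n1 (n1 + 1) / 2`), so `U(x, y) + U(y, x) = n1 * n2`.
#'
#' @param known,random numeric score vectors (both nonempty).
#' @return list with `U`, `p`, `exact`, and the two sample sizes.
#' @export
compare_score_sets <- function(known, random) {
  res <- rank_sum_test(known, random, alternative = "two.sided")
  list(U = res$U, p = res$p, exact = res$exact,
       n_known = length(known), n_random = length(random))
}
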