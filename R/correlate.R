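# Transcript-feature correlation, mutual ranks, and decay-weighted networks.
#
# Pairwise Pearson correlations between every transcript and mass feature
# are converted to mutual ranks (geometric mean of the two directed
# correlation ranks) and then to edge weights in (0, 1] with an exponential
# decay transform, one network per decay rate. Low mutual rank = strong
# association; the decay rate tunes how quickly weight falls off with rank.

#' Median absolute deviation (raw, unscaled)
#'
#' `median(|x - median(x)|)` without the consistency constant, the robust
#' spread used to rescale rows before correlation.
#'
#' @param x numeric vector, length >= 1.
#' @return nonnegative scalar.
#' @export
median_abs_dev <- function(x) {
  if (length(x) == 0) stop2("median_abs_dev: empty vector")
  stats::mad(x, constant = 1)
}

#' MAD-rescale the rows of an omics container
#'
#' Each row x becomes `(x - median(x)) / MAD(x)`, a robust analogue of
#' z-scoring that resists single-sample spikes. Rows with zero MAD carry no
#' usable signal for rank correlation and are dropped (count logged).
#'
#' @param x a `FeatureTable` or `ExpressionMatrix`.
#' @return the same type, rescaled, possibly with fewer rows.
#' @export
mad_rescale <- function(x) UseMethod("mad_rescale")

rescale_rows <- function(m, what) {
  med <- apply(m, 1, stats::median)
  madv <- apply(m, 1, median_abs_dev)
  keep <- madv > 0
  if (!any(keep)) stop2("no variable rows after MAD rescaling")
  if (any(!keep)) {
    pk_log("mad_rescale: dropped %d constant-MAD %s row(s)",
           sum(!keep), what)
  }
  list(values = (m[keep, , drop = FALSE] - med[keep]) / madv[keep],
       keep = keep)
}

#' @export
mad_rescale.ExpressionMatrix <- function(x) {
  r <- rescale_rows(x$values, "transcript")
  expression_matrix(r$values)
}

#' @export
mad_rescale.FeatureTable <- function(x) {
  r <- rescale_rows(x$abundance, "feature")
  out <- x
  out$feature_id <- x$feature_id[r$keep]
  out$mz <- x$mz[r$keep]
  if (!is.null(x$rt)) out$rt <- x$rt[r$keep]
  out$abundance <- r$values
  # rescaled abundances may be negative by construction; bypass constructor
  class(out) <- "FeatureTable"
  out
}

#' Pearson correlation for all transcript x feature pairs
#'
#' Two-sided p-values come from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (the
#' test that the true correlation is zero); `|r| = 1` gives p = 0. Pairs
#' below the minimum absolute correlation are dropped.
#'
#' @param expr an `ExpressionMatrix`, sample-aligned with `feats`.
#' @param feats a `FeatureTable`.
#' @param min_abs_r minimum |Pearson r| to keep an edge (default 0.1).
#' @return data.frame with columns `transcript_id`, `feature_id`, `r`, `p`.
#' @export
correlate_pairs <- function(expr, feats, min_abs_r = 0.1) {
  if (!identical(samples(expr), samples(feats))) {
    stop2("samples not aligned; call align_samples() first")
  }
  n <- length(samples(expr))
  if (n < 3) stop2("need at least 3 samples")
  cm <- suppressWarnings(stats::cor(t(expr$values), t(feats$abundance)))
  idx <- which(!is.na(cm) & abs(cm) >= min_abs_r, arr.ind = TRUE)
  if (any(is.na(cm))) {
    pk_log("correlate_pairs: %d pair(s) skipped (zero variance)",
           sum(is.na(cm)))
  }
  r <- cm[idx]
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tt), df = n - 2))
  out <- data.frame(
    transcript_id = rownames(cm)[idx[, 1]],
    feature_id = colnames(cm)[idx[, 2]],
    r = r, p = p, stringsAsFactors = FALSE)
  out <- out[lex_order(out$transcript_id, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert correlations to mutual ranks
#'
#' For an edge (t, f): rank_t(f) is the rank of f among all features paired
#' with t, by descending |r| (average ranks on ties); rank_f(t) is the
#' analogous rank of t among transcripts paired with f. The mutual rank is
#' their geometric mean, `sqrt(rank_t(f) * rank_f(t))`; 1 means both ends
#' are each other's top partner.
#'
#' @param edges data.frame from [correlate_pairs()].
#' @return the same data.frame with an `mr` column added.
#' @export
mutual_rank <- function(edges) {
  if (nrow(edges) == 0) {
    edges$mr <- numeric(0)
    return(edges)
  }
  rank_t <- stats::ave(-abs(edges$r), edges$transcript_id,
                       FUN = function(v) rank(v, ties.method = "average"))
  rank_f <- stats::ave(-abs(edges$r), edges$feature_id,
                       FUN = function(v) rank(v, ties.method = "average"))
  edges$mr <- sqrt(rank_t * rank_f)
  edges
}

#' Exponential decay weight of a mutual rank
#'
#' `w = exp(-(mr - 1) / decay_rate)`, so mutual rank 1 maps to weight 1 and
#' weight decreases in mr, more slowly at larger decay rates.
#'
#' @param mr mutual ranks (>= 1).
#' @param decay_rate positive decay rate.
#' @return weights in (0, 1].
#' @export
decay_weight <- function(mr, decay_rate) {
  if (any(decay_rate <= 0)) stop2("decay_rate must be positive")
  exp(-(mr - 1) / decay_rate)
}

#' Build decay-weighted networks at several decay rates
#'
#' One network per decay rate; edges whose weight falls below the cutoff
#' are excluded, so networks at smaller decay rates are nested inside
#' networks at larger ones.
#'
#' @param edges data.frame with an `mr` column (see [mutual_rank()]).
#' @param decay_rates decay rates to use (default 5, 10, 25, 50).
#' @param cutoff minimum edge weight retained (default 0.01).
#' @return named list (one element per decay rate) of edge data.frames with
#'   a `weight` column.
#' @export
decay_weights <- function(edges, decay_rates = c(5, 10, 25, 50),
                          cutoff = 0.01) {
  if (any(decay_rates <= 0)) stop2("decay rates must be positive")
  if (is.null(edges$mr)) stop2("edges lack mutual ranks; run mutual_rank()")
  out <- lapply(decay_rates, function(dr) {
    w <- decay_weight(edges$mr, dr)
    keep <- w >= cutoff
    net <- edges[keep, , drop = FALSE]
    net$weight <- w[keep]
    rownames(net) <- NULL
    net
  })
  names(out) <- as.character(decay_rates)
  out
}

#' Transcript-transcript coexpression network
#'
#' Expression-only variant of the same mutual-rank / decay-weight pipeline,
#' used to merge functional clusters through coexpressed member genes.
#'
#' @param expr an `ExpressionMatrix`.
#' @param min_abs_r minimum |r|.
#' @param decay_rate decay rate for the weights.
#' @param cutoff minimum retained weight.
#' @return data.frame `transcript_a`, `transcript_b`, `r`, `mr`, `weight`
#'   (each unordered pair once, a < b lexicographically).
#' @export
coexpression_network <- function(expr, min_abs_r = 0.1, decay_rate = 10,
                                 cutoff = 0.01) {
  cm <- suppressWarnings(stats::cor(t(expr$values)))
  diag(cm) <- NA
  idx <- which(!is.na(cm) & abs(cm) >= min_abs_r, arr.ind = TRUE)
  ed <- data.frame(transcript_a = rownames(cm)[idx[, 1]],
                   transcript_b = colnames(cm)[idx[, 2]],
                   r = cm[idx], stringsAsFactors = FALSE)
  if (nrow(ed) == 0) {
    ed$mr <- numeric(0); ed$weight <- numeric(0)
    return(ed)
  }
  rank_a <- stats::ave(-abs(ed$r), ed$transcript_a,
                       FUN = function(v) rank(v, ties.method = "average"))
  rank_b <- stats::ave(-abs(ed$r), ed$transcript_b,
                       FUN = function(v) rank(v, ties.method = "average"))
  ed$mr <- sqrt(rank_a * rank_b)
  ed$weight <- decay_weight(ed$mr, decay_rate)
  ed <- ed[ed$transcript_a < ed$transcript_b & ed$weight >= cutoff, ,
           drop = FALSE]
  ed <- ed[lex_order(ed$transcript_a, ed$transcript_b), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}
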