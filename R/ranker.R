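# Listwise ranking core: permutation-probability distributions over scored
# figure lists, cross-entropy losses, and their analytic gradients.
#
# With scores z_1..z_n and the exponential potential, the probability that
# figure j tops the list is softmax: P1(j) = exp(z_j) / sum_l exp(z_l).
# The top-2 probability of the ordered pair (j, k), j != k, marginalizes
# the Plackett-Luce permutation model over all permutations starting
# (j, k):
#   P2(j, k) = [exp(z_j)/S] * [exp(z_k) / (S - exp(z_j))],  S = sum exp(z_l)
# which sums to 1 over the n(n-1) ordered pairs.

#' Linear ranking score
#'
#' @param w weight vector.
#' @param x feature vector (or matrix with one row per figure).
#' @return inner product(s).
#' @export
score_figures <- function(w, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(w)) stop("dimension mismatch: ", ncol(x),
                                   " features vs ", length(w), " weights")
    return(as.numeric(x %*% w))
  }
  if (length(x) != length(w)) stop("dimension mismatch")
  sum(w * x)
}

#' Top-1 permutation probability distribution
#'
#' Overflow-safe softmax of the score list; shift-invariant and strictly
#' positive, summing to 1.
#'
#' @param z numeric score list (n >= 1).
#' @return probability vector of length n.
#' @export
top1_distribution <- function(z) {
  stopifnot(length(z) >= 1L, all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Top-2 permutation probability distribution
#'
#' Probability of each ordered figure pair occupying the first two rank
#' positions under the Plackett-Luce model induced by the scores.
#'
#' @param z numeric score list (n >= 2).
#' @return an `n x n` matrix `P` with `P[j, k] = P(top-2 = (j, k))`,
#'   `NA` on the diagonal; off-diagonal entries sum to 1.
#' @export
top2_distribution <- function(z) {
  n <- length(z)
  if (n < 2L)
    stop("top-2 probabilities need n >= 2 figures; use the top-1 loss for ",
         "single-figure lists")
  stopifnot(all(is.finite(z)))
  p <- top1_distribution(z)
  out <- outer(p / pmax(1 - p, .Machine$double.xmin), p)
  diag(out) <- NA_real_
  out
}

#' Top-1 listwise cross-entropy loss
#'
#' Cross entropy between the top-1 distributions induced by the reference
#' scores `y` and the model scores `z`; minimized (at the entropy of
#' `P_y`) when the distributions coincide.
#'
#' @param y reference score list (e.g. reciprocal gold ranks).
#' @param z model score list of the same length.
#' @return non-negative loss.
#' @export
loss_top1 <- function(y, z) {
  if (length(y) != length(z)) stop("length mismatch between y and z")
  py <- top1_distribution(y)
  lz <- z - max(z)
  logpz <- lz - log(sum(exp(lz)))
  -sum(py * logpz)
}

#' Top-2 listwise cross-entropy loss
#'
#' Cross entropy between the top-2 pair distributions of `y` and `z`.
#'
#' @inheritParams loss_top1
#' @return non-negative loss.
#' @export
loss_top2 <- function(y, z) {
  if (length(y) != length(z)) stop("length mismatch between y and z")
  py <- top2_distribution(y)
  lz <- z - max(z)
  S <- sum(exp(lz))
  # log P2(j,k) = z_j + z_k - log S - log(S - exp(z_j)), row j, column k
  logrest <- log(pmax(S - exp(lz), .Machine$double.xmin))
  logp2 <- outer(lz, lz, "+") - log(S) - matrix(logrest, length(z), length(z))
  diag(logp2) <- NA_real_
  -sum(py * logp2, na.rm = TRUE)
}

# Gradient of the loss w.r.t. the score list z (length n).
.grad_z_top1 <- function(y, z) {
  top1_distribution(z) - top1_distribution(y)
}

.grad_z_top2 <- function(y, z) {
  n <- length(z)
  py <- top2_distribution(y)
  p <- top1_distribution(z)
  q1 <- rowSums(py, na.rm = TRUE)   # P_y(first = j)
  q2 <- colSums(py, na.rm = TRUE)   # P_y(second = t)
  rest <- pmax(1 - p, .Machine$double.xmin)
  # dL/dz_t = p_t - q1_t - q2_t + p_t * sum_{j != t} q1_j / (1 - p_j)
  s <- sum(q1 / rest)
  p - q1 - q2 + p * (s - q1 / rest)
}

#' Analytic gradient of the listwise loss
#'
#' Gradient of [loss_top1()] or [loss_top2()] with respect to the weight
#' vector of the linear scorer, for one figure list.  Agrees with central
#' finite differences.
#'
#' @param x feature matrix (`n x d`).
#' @param y reference scores (length n).
#' @param w weight vector (length d).
#' @param loss `"top1"` or `"top2"`.
#' @return gradient vector of length d.
#' @export
loss_gradient <- function(x, y, w, loss = c("top2", "top1")) {
  loss <- match.arg(loss)
  z <- score_figures(w, x)
  gz <- if (loss == "top1") .grad_z_top1(y, z) else .grad_z_top2(y, z)
  as.numeric(crossprod(x, gz))
}

#' Ground-truth scores from gold ranks
#'
#' Reciprocal of the dense gold rank; tied figures get equal scores.
#'
#' @param ranks dense integer ranks.
#' @return numeric scores in `(0, 1]`.
#' @export
gold_scores <- function(ranks) {
  ranks <- dense_ranks(ranks)
  1 / ranks
}

#' Predicted ranking from scores
#'
#' Figures sorted by descending score; exact ties broken by ascending
#' figure position so the output is always a strict permutation.
#'
#' @param scores numeric vector.
#' @return integer system ranks `s_1..s_n` (rank 1 = best).
#' @export
ranks_from_scores <- function(scores) {
  n <- length(scores)
  ord <- order(-scores, seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}
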