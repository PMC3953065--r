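#' Dense (tie-aware) rank normalization
#'
#' Rewrites a vector of positive ranks so that rank groups are numbered
#' densely: the rank after a tied group increments by one (1, 2, 2, 3 rather
#' than 1, 2, 2, 4).  Order (and therefore every pairwise preference) is
#' preserved; ties stay tied.
#'
#' @param ranks integer vector of positive ranks, ties allowed.
#' @return integer vector of the same length with `min(ranks) == 1` and
#'   consecutive group numbers.
#' @examples
#' dense_ranks(c(1, 3, 3))  # 1 2 2
#' @export
dense_ranks <- function(ranks) {
  if (length(ranks) == 0L) return(integer(0))
  if (any(!is.finite(ranks)) || any(ranks <= 0))
    stop("ranks must be positive finite numbers")
  match(ranks, sort(unique(ranks)))
}

#' All permutations of 1..n
#'
#' Exhaustive permutation matrix used by the brute-force metric expectations
#' and the Plackett-Luce enumeration oracle.  Grows as n!, so n is capped.
#'
#' @param n number of elements (n <= 9).
#' @return an `n! x n` integer matrix, one permutation per row, in
#'   lexicographic order.
#' @export
permutations <- function(n) {
  if (n > 9L) stop("refusing to enumerate ", n, "! permutations; use sampling")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Kendall rank correlation between two rankings
#'
#' Plain pairwise tau (tau-a) over the pairs untied in both inputs; used to
#' check whether a predicted order reproduces a planted one.
#'
#' @param a,b numeric vectors of equal length (ranks or scores).
#' @return tau in `[-1, 1]`; 1 when every comparable pair agrees.
#' @export
kendall_tau <- function(a, b) {
  m <- length(a)
  stopifnot(length(b) == m)
  if (m < 2L) return(1)
  conc <- disc <- 0L
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) {
      pa <- sign(a[j] - a[k])
      pb <- sign(b[j] - b[k])
      if (pa == 0 || pb == 0) next
      if (pa == pb) conc <- conc + 1L else disc <- disc + 1L
    }
  }
  if (conc + disc == 0L) return(1)
  (conc - disc) / (conc + disc)
}

# Run code under a local, seeded RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Population (not sample) standard deviation, the convention used in the
# "mean +/- sd" report cells.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
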