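# Tie-aware ranking-quality metrics: rank-weighted pair error (WER-RK),
# NDCG, first-rank weighted error (WER-FR), tie statistics, brute-force
# permutation expectations, and dataset-level aggregation.
#
# All three metrics compare a strict system ranking s_1..s_m (a
# permutation of 1..m) with a dense, possibly tied reference ranking
# r_1..r_m.  They are reported in their "higher is better" forms
# ~WER-RK = 1 - WER-RK, NDCG, and ~WER-FR = 1 - WER-FR.

.check_ranking <- function(system_ranks, ref_ranks) {
  m <- length(ref_ranks)
  if (length(system_ranks) != m)
    stop("system and reference rankings differ in length")
  if (!setequal(system_ranks, seq_len(m)))
    stop("system ranks must be a permutation of 1..m")
  if (m > 0L && min(ref_ranks) != 1L)
    stop("reference ranks must be dense with minimum 1")
  m
}

#' Rank-weighted pair error (WER-RK)
#'
#' Weighted fraction of discordant figure pairs.  A pair (j, k) is
#' discordant when the system orders it against the reference; its penalty
#' is `1/r_j + 1/r_k`, so errors on pairs containing important (low
#' reference rank) figures cost more.  Reference-tied pairs express no
#' preference and can never be error pairs, but remain in the normalizing
#' total, so heavily tied references bound the attainable error below 1.
#'
#' \deqn{WER = \frac{\sum_{j<k} I[(s_j-s_k)(r_j-r_k)<0]\,(1/r_j+1/r_k)}
#'                  {\sum_{j<k} (1/r_j+1/r_k)}}
#'
#' @param system_ranks strict system ranking (permutation of 1..m).
#' @param ref_ranks dense reference ranks, ties allowed.
#' @return error in `[0, 1]`; 0 for m < 2.
#' @export
wer_rk <- function(system_ranks, ref_ranks) {
  m <- .check_ranking(system_ranks, ref_ranks)
  if (m < 2L) return(0)
  num <- den <- 0
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) {
      w <- 1 / ref_ranks[j] + 1 / ref_ranks[k]
      den <- den + w
      if ((system_ranks[j] - system_ranks[k]) *
          (ref_ranks[j] - ref_ranks[k]) < 0) num <- num + w
    }
  }
  num / den
}

#' @rdname wer_rk
#' @details `wer_rk_score()` returns the "higher is better" form
#'   `1 - WER-RK`.
#' @export
wer_rk_score <- function(system_ranks, ref_ranks) {
  1 - wer_rk(system_ranks, ref_ranks)
}

#' Normalized discounted cumulative gain
#'
#' Gain of the figure placed at system position k is `2^-(r-1)` for its
#' reference rank r (halving per rank step), discounted by `1/log2(k+1)`;
#' the normalizer is the DCG of an ideal ordering (reference ranks
#' ascending), so a perfect ordering scores exactly 1 for any tie
#' structure.
#'
#' @inheritParams wer_rk
#' @return NDCG in `[0, 1]`; 1 for m = 1.
#' @export
ndcg <- function(system_ranks, ref_ranks) {
  m <- .check_ranking(system_ranks, ref_ranks)
  if (m <= 1L) return(1)
  gain <- function(r) 2^(-(r - 1))
  disc <- 1 / log2(seq_len(m) + 1)
  # reference rank of the figure at each system position
  r_at_pos <- ref_ranks[order(system_ranks)]
  dcg <- sum(gain(r_at_pos) * disc)
  ideal <- sum(gain(sort(ref_ranks)) * disc)
  dcg / ideal
}

#' First-rank weighted error (WER-FR)
#'
#' Deviation of the system rank of the human-top figure from 1, scaled by
#' the worst possible deviation: `WER-FR = (s(x_1) - 1) / (m - 1)`.  When
#' several figures tie at reference rank 1, the best (minimum) system rank
#' within the tied top group is used, so placing any of them first gives a
#' perfect score.
#'
#' @inheritParams wer_rk
#' @return error in `[0, 1]`; 0 for m = 1.
#' @export
wer_fr <- function(system_ranks, ref_ranks) {
  m <- .check_ranking(system_ranks, ref_ranks)
  if (m < 2L) return(0)
  top <- which(ref_ranks == 1L)
  (min(system_ranks[top]) - 1) / (m - 1)
}

#' @rdname wer_fr
#' @details `wer_fr_score()` returns `1 - WER-FR`.
#' @export
wer_fr_score <- function(system_ranks, ref_ranks) {
  1 - wer_fr(system_ranks, ref_ranks)
}

#' @rdname ndcg
#' @details `ndcg_score()` is `ndcg()` itself (provided for a uniform
#'   metric interface).
#' @export
ndcg_score <- ndcg

#' Tie pair percentage of a reference ranking
#'
#' Number of unordered figure pairs annotated equally important, divided
#' by the total number of pairs `m(m-1)/2`.
#'
#' @param ref_ranks dense reference ranks.
#' @return fraction in `[0, 1]`; 0 for m < 2.
#' @examples
#' tie_pair_percentage(c(2, 1, 2))  # 1/3
#' @export
tie_pair_percentage <- function(ref_ranks) {
  m <- length(ref_ranks)
  if (m < 2L) return(0)
  ties <- 0L
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) if (ref_ranks[j] == ref_ranks[k]) ties <- ties + 1L
  }
  ties / (m * (m - 1L) / 2L)
}

#' Random-permutation expectation of a metric
#'
#' The mean of a ranking metric over uniformly random system permutations
#' of a fixed reference ranking: exact (full enumeration, m <= 9) or
#' sampled (the 100-repeat random baseline by default).
#'
#' @param metric function `(system_ranks, ref_ranks) -> value`, e.g.
#'   [wer_rk_score()].
#' @param ref_ranks dense reference ranks (m >= 2).
#' @param mode `"exact"` or `"sampled"`.
#' @param repeats permutations drawn in sampled mode (default 100).
#' @param seed RNG seed for sampled mode.
#' @return the expectation.
#' @export
random_expectation <- function(metric, ref_ranks,
                               mode = c("exact", "sampled"),
                               repeats = 100L, seed = 1L) {
  mode <- match.arg(mode)
  m <- length(ref_ranks)
  stopifnot(m >= 2L)
  if (mode == "exact") {
    if (m > 9L)
      stop("exact enumeration is limited to m <= 9; use mode = \"sampled\"")
    pm <- permutations(m)
    mean(vapply(seq_len(nrow(pm)), function(i)
      metric(pm[i, ], ref_ranks), 0))
  } else {
    with_seed(seed, {
      mean(vapply(seq_len(repeats), function(i)
        metric(sample.int(m), ref_ranks), 0))
    })
  }
}

#' Evaluate predicted rankings against gold
#'
#' Per-article ~WER-RK, NDCG and ~WER-FR plus the overall mean and
#' population standard deviation of each, optionally grouped by figure
#' count.
#'
#' @param predictions named list of system rank vectors.
#' @param gold named list of dense reference rank vectors covering the
#'   same articles.
#' @param by_figure_count also aggregate by number of figures?
#' @return an object of class `fr_report`: list with `per_article` (data
#'   frame), `summary` (mean/sd per metric) and optionally `by_count`.
#' @export
evaluate_rankings <- function(predictions, gold, by_figure_count = FALSE) {
  ids <- names(predictions)
  if (is.null(ids) || !setequal(ids, names(gold)))
    stop("prediction and gold article sets differ")
  per <- do.call(rbind, lapply(ids, function(id) {
    s <- predictions[[id]]; r <- gold[[id]]
    data.frame(article_id = id, m = length(r),
               wer_rk = wer_rk_score(s, r),
               ndcg = ndcg(s, r),
               wer_fr = wer_fr_score(s, r),
               stringsAsFactors = FALSE)
  }))
  summ <- data.frame(
    metric = c("wer_rk", "ndcg", "wer_fr"),
    mean = vapply(c("wer_rk", "ndcg", "wer_fr"),
                  function(mname) mean(per[[mname]]), 0),
    sd = vapply(c("wer_rk", "ndcg", "wer_fr"),
                function(mname) pop_sd(per[[mname]]), 0),
    row.names = NULL)
  out <- list(per_article = per, summary = summ)
  if (by_figure_count) {
    out$by_count <- do.call(rbind, lapply(sort(unique(per$m)), function(mm) {
      sub <- per[per$m == mm, ]
      data.frame(m = mm, n_articles = nrow(sub),
                 wer_rk = mean(sub$wer_rk), ndcg = mean(sub$ndcg),
                 wer_fr = mean(sub$wer_fr))
    }))
  }
  class(out) <- "fr_report"
  out
}

#' @export
print.fr_report <- function(x, ...) {
  s <- x$summary
  cat("Ranking evaluation over ", nrow(x$per_article), " articles\n",
      sep = "")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s %.3f+/-%.3f\n",
                c(wer_rk = "~WER-RK", ndcg = "NDCG",
                  wer_fr = "~WER-FR")[s$metric[i]],
                s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Paired comparison of two systems
#'
#' One-tailed paired t-test on per-article metric values (does system A
#' exceed system B?).  Thin wrapper over [stats::t.test()].
#'
#' @param a,b numeric vectors of per-article scores, same article order.
#' @return the `htest` object.
#' @export
compare_systems <- function(a, b) {
  stats::t.test(a, b, paired = TRUE, alternative = "greater")
}

#' Write an evaluation report to TSV
#'
#' @param report an `fr_report`.
#' @param path output path (per-article rows; summary rows appended with
#'   article_id `"MEAN"` / `"SD"`).
#' @export
write_report <- function(report, path) {
  per <- report$per_article
  s <- report$summary
  extra <- data.frame(
    article_id = c("MEAN", "SD"), m = NA_integer_,
    wer_rk = c(s$mean[s$metric == "wer_rk"], s$sd[s$metric == "wer_rk"]),
    ndcg = c(s$mean[s$metric == "ndcg"], s$sd[s$metric == "ndcg"]),
    wer_fr = c(s$mean[s$metric == "wer_fr"], s$sd[s$metric == "wer_fr"]))
  utils::write.table(rbind(per, extra), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
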