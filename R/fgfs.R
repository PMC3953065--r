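# Forward greedy feature selection over the feature registry, plus the
# two comparison selectors (top-individual pooling and FGFS set union).

# Cross-validated mean metric of a feature subset: train on k-1 folds,
# evaluate held-out articles, average over all articles.  Folds split
# articles, never figures.
.cv_score <- function(dataset, cols, metric, folds = 5L, seed = 1L,
                      trainer = list()) {
  n <- length(dataset$x)
  folds <- min(folds, n)
  fold_of <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  sub <- ranking_dataset(lapply(dataset$x, function(m) m[, cols, drop = FALSE]),
                         dataset$gold, dataset$ids)
  vals <- numeric(n)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    model <- do.call(figrank, c(list(dataset = sub[train_idx]), trainer))
    preds <- predict(model, sub[test_idx])
    vals[test_idx] <- vapply(seq_along(test_idx), function(i)
      metric(preds[[i]], sub$gold[[test_idx[i]]]), 0)
  }
  mean(vals)
}

# Resolve a metric given as name or function.
.resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(metric,
         wer_rk = wer_rk_score, ndcg = ndcg, wer_fr = wer_fr_score,
         stop("unknown metric: ", metric))
}

#' Forward greedy feature selection
#'
#' Starts from the empty feature set; at each iteration every unselected
#' feature is appended in turn, the candidate set is scored under the
#' evaluation protocol (k-fold cross-validated training by default), and
#' the best feature is added (ties broken by lowest registry index).
#' Stops when all features are selected or `patience` iterations pass
#' without improving the best score; returns the best prefix.
#'
#' @param dataset an `fr_dataset` (>= 2 features).
#' @param metric metric name (`"wer_rk"`, `"ndcg"`, `"wer_fr"`) or a
#'   function `(system_ranks, ref_ranks) -> value`, larger is better.
#' @param folds inner cross-validation folds (default 5).
#' @param seed seed for the fold split.
#' @param trainer named list of [figrank()] arguments for the inner fits.
#' @param patience iterations without gain before stopping (default 10).
#' @param max_features optional cap on iterations.
#' @param audit_path optional TSV path logging every candidate evaluation
#'   (iteration, feature, score).
#' @return an object of class `fr_fgfs`: `selected` (best prefix, in
#'   selection order), `path` (full selection order), `scores`
#'   (per-iteration best score), `opt` (best score), `iter` (iteration of
#'   the best score).
#' @export
fgfs <- function(dataset, metric = "wer_rk", folds = 5L, seed = 1L,
                 trainer = list(), patience = 10L, max_features = Inf,
                 audit_path = NULL) {
  stopifnot(inherits(dataset, "fr_dataset"))
  metric_fn <- .resolve_metric(metric)
  feat <- colnames(dataset$x[[1]])
  if (length(feat) < 2L) stop("need at least 2 features for selection")
  if (all(vapply(dataset$gold, function(g) max(g) == 1L, TRUE)))
    stop("degenerate dataset: every gold ranking is fully tied")
  audit <- if (!is.null(audit_path)) file(audit_path, "w") else NULL
  if (!is.null(audit)) {
    writeLines("iteration\tfeature\tscore", audit)
    on.exit(close(audit))
  }
  selected <- integer(0)
  best_scores <- numeric(0)
  opt <- -Inf; opt_iter <- 0L
  stall <- 0L
  it <- 0L
  while (length(selected) < length(feat) && it < max_features) {
    it <- it + 1L
    cand <- setdiff(seq_along(feat), selected)
    scores <- vapply(cand, function(ci)
      .cv_score(dataset, c(selected, ci), metric_fn, folds, seed, trainer), 0)
    if (!is.null(audit)) {
      writeLines(sprintf("%d\t%s\t%.6f", it, feat[cand], scores), audit)
    }
    pick <- cand[which.max(scores)]   # which.max: lowest index wins ties
    selected <- c(selected, pick)
    best_scores <- c(best_scores, max(scores))
    if (max(scores) > opt) {
      opt <- max(scores); opt_iter <- it; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(selected = feat[selected[seq_len(opt_iter)]],
                 path = feat[selected],
                 scores = best_scores,
                 opt = opt, iter = opt_iter,
                 metric = if (is.character(metric)) metric else "custom"),
            class = "fr_fgfs")
}

#' @export
print.fr_fgfs <- function(x, ...) {
  cat("FGFS: best ", x$metric, " = ", round(x$opt, 4), " at iteration ",
      x$iter, " (", length(x$selected), " features)\n", sep = "")
  invisible(x)
}

#' Top individually-scoring features
#'
#' Scores every feature alone under the same cross-validated protocol and
#' returns the best `count` — the naive pooling baseline against which
#' greedy selection is compared.
#'
#' @inheritParams fgfs
#' @param count number of features to keep.
#' @return character vector of feature names, best first.
#' @export
select_top_individual <- function(dataset, metric = "wer_rk", count,
                                  folds = 5L, seed = 1L, trainer = list()) {
  metric_fn <- .resolve_metric(metric)
  feat <- colnames(dataset$x[[1]])
  stopifnot(count <= length(feat))
  scores <- vapply(seq_along(feat), function(ci)
    .cv_score(dataset, ci, metric_fn, folds, seed, trainer), 0)
  feat[order(-scores, seq_along(feat))[seq_len(count)]]
}

#' Union of FGFS-selected feature sets
#'
#' Combines the feature sets selected by several FGFS runs (one per
#' metric, typically) into their set union, in registry order.
#'
#' @param results list of `fr_fgfs` objects (or character vectors).
#' @param registry feature name ordering (default the shipped registry).
#' @return character vector of feature names.
#' @export
combine_fgfs_sets <- function(results, registry = feature_registry()$name) {
  stopifnot(length(results) >= 1L)
  sets <- lapply(results, function(r)
    if (inherits(r, "fr_fgfs")) r$selected else as.character(r))
  u <- unique(unlist(sets))
  inreg <- intersect(registry, u)
  c(inreg, setdiff(u, inreg))
}
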