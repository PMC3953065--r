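# Gradient-descent training of the linear listwise ranker, and the S3
# model object returned to users.

#' Ranking dataset constructor
#'
#' Bundles per-article figure feature matrices with their gold rankings
#' into the list-of-instances form used by the trainer and the evaluation
#' helpers.
#'
#' @param x list of feature matrices (one per article, `n_j x d`, shared
#'   column names).
#' @param gold list of dense gold rank vectors, same order and lengths.
#' @param ids optional article ids.
#' @return an object of class `fr_dataset`.
#' @export
ranking_dataset <- function(x, gold, ids = NULL) {
  stopifnot(length(x) == length(gold))
  if (is.null(ids)) ids <- paste0("a", seq_along(x))
  d <- unique(vapply(x, ncol, 0L))
  if (length(d) != 1L) stop("inconsistent feature dimension across articles")
  for (i in seq_along(x)) {
    if (nrow(x[[i]]) != length(gold[[i]]))
      stop("article ", ids[i], ": ", nrow(x[[i]]), " figures but ",
           length(gold[[i]]), " gold ranks")
    gold[[i]] <- dense_ranks(gold[[i]])
  }
  structure(list(x = x, gold = gold, ids = as.character(ids)),
            class = "fr_dataset")
}

#' @export
print.fr_dataset <- function(x, ...) {
  cat("<ranking dataset> ", length(x$x), " articles, ",
      ncol(x$x[[1]]), " features, ",
      sum(vapply(x$x, nrow, 0L)), " figures\n", sep = "")
  invisible(x)
}

#' @export
`[.fr_dataset` <- function(x, i) {
  ranking_dataset(x$x[i], x$gold[i], x$ids[i])
}

# Mean ~WER-RK of the model over a dataset (the default training metric
# for the adaptive learning-rate rule).
.train_metric <- function(w, dataset, metric) {
  vals <- vapply(seq_along(dataset$x), function(i) {
    s <- ranks_from_scores(as.numeric(dataset$x[[i]] %*% w))
    metric(s, dataset$gold[[i]])
  }, 0)
  mean(vals)
}

#' Fit a listwise linear ranking model
#'
#' Trains a linear scorer by gradient descent on the listwise
#' cross-entropy loss, with per-article updates in fixed dataset order.
#' The reference distribution of each article comes from the reciprocal of
#' its dense gold ranks.  After each full pass the training metric
#' (mean ~WER-RK by default) is evaluated and the learning rate is decayed
#' by `lr_decay` whenever the metric improved or stayed equal and the rate
#' is still above `lr_floor` (`adapt = "on_improve"`); `adapt =
#' "on_worse"` decays on non-improvement instead, and `adapt = "none"`
#' keeps the rate fixed.
#'
#' Features are standardized (z-scored per column over the training data)
#' before training unless `standardize = FALSE`; the scaling is stored in
#' the model and applied automatically at prediction time.  Single-figure
#' articles contribute no gradient (their ordering is trivial) and
#' articles must have n >= 2 under the top-2 loss, where single-figure
#' lists are skipped.
#'
#' @param dataset an `fr_dataset` (or list of feature matrices via
#'   `ranking_dataset()`).
#' @param loss `"top2"` (default) or `"top1"` listwise loss.
#' @param lr initial learning rate (default 0.0009).
#' @param iterations training passes (default 200).
#' @param lr_decay multiplicative decay constant (default 0.875).
#' @param lr_floor learning-rate threshold below which decay stops
#'   (default 1e-6).
#' @param adapt learning-rate schedule, see above.
#' @param batch accumulate the gradient over all articles and apply one
#'   update per pass (full-batch mode) instead of per-article updates?
#' @param standardize z-score features before training?
#' @param metric training metric for the adaptive rule (function of
#'   `(system_ranks, ref_ranks)`), default [wer_rk_score()].
#' @return an object of class `figrank` with components `w` (named
#'   weights), `center`/`scale`, `loss`, `trace` (per-iteration data
#'   frame) and the call configuration.
#' @seealso [predict.figrank()], [loss_top2()], [loss_gradient()]
#' @export
figrank <- function(dataset, loss = c("top2", "top1"), lr = 9e-4,
                    iterations = 200L, lr_decay = 0.875, lr_floor = 1e-6,
                    adapt = c("on_improve", "on_worse", "none"),
                    batch = FALSE, standardize = TRUE,
                    metric = wer_rk_score) {
  loss <- match.arg(loss)
  adapt <- match.arg(adapt)
  stopifnot(inherits(dataset, "fr_dataset"), lr > 0, iterations >= 1L)
  d <- ncol(dataset$x[[1]])
  feat_names <- colnames(dataset$x[[1]])

  xs <- dataset$x
  if (standardize) {
    all_rows <- do.call(rbind, xs)
    center <- colMeans(all_rows)
    scale_ <- apply(all_rows, 2L, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    xs <- lapply(xs, function(m) sweep(sweep(m, 2L, center), 2L, scale_, "/"))
  } else {
    center <- rep(0, d); scale_ <- rep(1, d)
  }
  std_data <- ranking_dataset(xs, dataset$gold, dataset$ids)

  ys <- lapply(dataset$gold, gold_scores)
  usable <- if (loss == "top2") {
    vapply(xs, nrow, 0L) >= 2L
  } else {
    vapply(xs, nrow, 0L) >= 2L  # n = 1 gives zero top-1 gradient anyway
  }

  w <- rep(0, d)
  r <- lr
  trace <- data.frame(iteration = integer(0), loss = numeric(0),
                      metric = numeric(0), lr = numeric(0))
  prev_metric <- -Inf
  for (it in seq_len(iterations)) {
    if (batch) {
      g <- rep(0, d)
      for (i in which(usable)) g <- g + loss_gradient(xs[[i]], ys[[i]], w, loss)
      w <- w - r * g
    } else {
      for (i in which(usable)) {
        g <- loss_gradient(xs[[i]], ys[[i]], w, loss)
        w <- w - r * g
      }
    }
    total_loss <- sum(vapply(which(usable), function(i) {
      z <- as.numeric(xs[[i]] %*% w)
      if (loss == "top1") loss_top1(ys[[i]], z) else loss_top2(ys[[i]], z)
    }, 0))
    if (!is.finite(total_loss))
      stop("training diverged: non-finite loss at iteration ", it,
           " (learning rate ", r, ")")
    mval <- .train_metric(w, std_data, metric)
    trace <- rbind(trace, data.frame(iteration = it, loss = total_loss,
                                     metric = mval, lr = r))
    decay <- switch(adapt,
                    on_improve = mval >= prev_metric,
                    on_worse = mval < prev_metric,
                    none = FALSE)
    if (decay && r > lr_floor) r <- r * lr_decay
    prev_metric <- mval
  }

  structure(list(w = stats::setNames(w, feat_names),
                 center = center, scale = scale_,
                 loss = loss, lr = lr, iterations = iterations,
                 lr_decay = lr_decay, lr_floor = lr_floor, adapt = adapt,
                 batch = batch, standardize = standardize,
                 trace = trace,
                 n_articles = length(xs)),
            class = "figrank")
}

#' @export
print.figrank <- function(x, ...) {
  cat("Listwise linear figure ranker (", x$loss, " loss)\n", sep = "")
  cat("  articles: ", x$n_articles, "   features: ", length(x$w),
      "   iterations: ", x$iterations, "\n", sep = "")
  tr <- x$trace
  cat(sprintf("  final training loss %.4f, metric %.4f, lr %.2e\n",
              tr$loss[nrow(tr)], tr$metric[nrow(tr)], tr$lr[nrow(tr)]))
  invisible(x)
}

#' @export
summary.figrank <- function(object, n_top = 10L, ...) {
  ord <- order(abs(object$w), decreasing = TRUE)
  top <- object$w[ord[seq_len(min(n_top, length(object$w)))]]
  out <- list(loss = object$loss, trace = object$trace, top_weights = top)
  class(out) <- "summary.figrank"
  out
}

#' @export
print.summary.figrank <- function(x, ...) {
  cat("Listwise ranker (", x$loss, " loss); largest |weights|:\n", sep = "")
  print(round(x$top_weights, 4))
  tr <- x$trace
  cat(sprintf("training metric: %.4f -> %.4f over %d iterations\n",
              tr$metric[1], tr$metric[nrow(tr)], nrow(tr)))
  invisible(x)
}

#' @export
coef.figrank <- function(object, ...) object$w

#' Predict figure rankings
#'
#' Scores each figure with the fitted weights (after applying the stored
#' standardization) and converts scores to system ranks, ties broken by
#' figure position.
#'
#' @param object a fitted `figrank` model.
#' @param newdata a feature matrix (`n x d`) for one article, or an
#'   `fr_dataset`.
#' @param type `"ranks"` (default) or `"scores"`.
#' @param ... unused.
#' @return for a single matrix, a vector of ranks (or scores); for a
#'   dataset, a list of such vectors.
#' @export
predict.figrank <- function(object, newdata, type = c("ranks", "scores"),
                            ...) {
  type <- match.arg(type)
  one <- function(m) {
    m <- sweep(sweep(m, 2L, object$center), 2L, object$scale, "/")
    z <- as.numeric(m %*% object$w)
    if (type == "scores") z else ranks_from_scores(z)
  }
  if (inherits(newdata, "fr_dataset"))
    return(stats::setNames(lapply(newdata$x, one), newdata$ids))
  one(newdata)
}

#' Save / load a fitted model as JSON
#'
#' @param model a `figrank` object.
#' @param path file path.
#' @return `read_model()` returns the restored `figrank` object.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  obj$w <- as.list(model$w)
  obj$center <- as.list(model$center)
  obj$scale <- as.list(model$scale)
  obj$trace <- as.list(model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$trace <- as.data.frame(obj$trace)
  obj$w <- unlist(obj$w)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  structure(obj, class = "figrank")
}
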