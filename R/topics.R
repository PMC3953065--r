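# Latent Dirichlet allocation over the paragraphs of one article, and the
# topic-similarity features computed from it.
#
# The sampler is a small collapsed Gibbs implementation: with symmetric
# priors alpha (document-topic) and beta (topic-word), each token's topic
# assignment is resampled from
#   p(z = k) prop. (n_dk + alpha) * (n_kw + beta) / (n_k + V*beta).
# Point estimates of theta (paragraph-topic) and phi (topic-word) are the
# smoothed count ratios after the final sweep.

#' Fit an LDA topic model over paragraphs
#'
#' Each paragraph is one document.  Deterministic given the seed.  `k`
#' larger than the paragraph count is clamped with a warning.
#'
#' @param paragraphs character vector of paragraph texts (>= 1 non-empty).
#' @param k number of topics (>= 1).
#' @param seed RNG seed.
#' @param alpha,beta symmetric Dirichlet priors; defaults `1/k` and 0.01.
#' @param iterations Gibbs sweeps (default 500).
#' @return an object of class `fr_lda` with `k`, `theta` (paragraphs x k,
#'   rows sum to 1), `phi` (k x vocabulary, rows sum to 1), `vocab`,
#'   `assignments` (argmax topic per paragraph) and `seed`.
#' @export
fit_lda <- function(paragraphs, k, seed = 1L, alpha = NULL, beta = 0.01,
                    iterations = 500L) {
  paragraphs <- as.character(paragraphs)
  toks <- lapply(paragraphs, tokenize)
  keep <- lengths(toks) > 0L
  if (!any(keep)) stop("no non-empty paragraphs to model")
  if (k < 1L) stop("k must be >= 1")
  ndoc <- length(paragraphs)
  if (k > sum(keep)) {
    warning("k = ", k, " exceeds the number of non-empty paragraphs (",
            sum(keep), "); clamping")
    k <- sum(keep)
  }
  if (is.null(alpha)) alpha <- 1 / k
  vocab <- sort(unique(unlist(toks[keep])))
  V <- length(vocab)
  wid <- lapply(toks, function(t) match(t, vocab))

  theta <- matrix(0, ndoc, k)
  nkw <- matrix(0, k, V)
  nk <- numeric(k)
  ndk <- matrix(0, ndoc, k)
  z <- vector("list", ndoc)

  with_seed(seed, {
    for (d in seq_len(ndoc)) {
      w <- wid[[d]]
      if (length(w) == 0L) next
      zd <- sample.int(k, length(w), replace = TRUE)
      z[[d]] <- zd
      for (i in seq_along(w)) {
        nkw[zd[i], w[i]] <- nkw[zd[i], w[i]] + 1
        nk[zd[i]] <- nk[zd[i]] + 1
        ndk[d, zd[i]] <- ndk[d, zd[i]] + 1
      }
    }
    if (k > 1L) {
      for (it in seq_len(iterations)) {
        for (d in seq_len(ndoc)) {
          w <- wid[[d]]
          if (length(w) == 0L) next
          zd <- z[[d]]
          for (i in seq_along(w)) {
            kk <- zd[i]; ww <- w[i]
            nkw[kk, ww] <- nkw[kk, ww] - 1
            nk[kk] <- nk[kk] - 1
            ndk[d, kk] <- ndk[d, kk] - 1
            p <- (ndk[d, ] + alpha) * (nkw[, ww] + beta) / (nk + V * beta)
            kk <- sample.int(k, 1L, prob = p)
            zd[i] <- kk
            nkw[kk, ww] <- nkw[kk, ww] + 1
            nk[kk] <- nk[kk] + 1
            ndk[d, kk] <- ndk[d, kk] + 1
          }
          z[[d]] <- zd
        }
      }
    }
  })

  theta <- (ndk + alpha) / (rowSums(ndk) + k * alpha)
  phi <- (nkw + beta) / (nk + V * beta)
  colnames(phi) <- vocab
  assignments <- apply(theta, 1L, which.max)
  structure(list(k = k, theta = theta, phi = phi, vocab = vocab,
                 assignments = assignments, paragraphs = paragraphs,
                 alpha = alpha, beta = beta, seed = seed),
            class = "fr_lda")
}

#' @export
print.fr_lda <- function(x, ...) {
  cat("<LDA model> ", x$k, " topics over ", length(x$paragraphs),
      " paragraphs, ", length(x$vocab), " terms\n", sep = "")
  invisible(x)
}

#' Text representations of one topic
#'
#' `WORDS` mode: the `top_n` highest-probability words of the topic.
#' `PARAGRAPHS` mode: the concatenation of the paragraphs whose argmax
#' topic is this topic (may be empty).
#'
#' @param model an `fr_lda`.
#' @param topic topic index.
#' @param mode `"WORDS"` or `"PARAGRAPHS"`.
#' @param top_n words kept in `WORDS` mode (default 20).
#' @return character scalar.
#' @export
topic_representation <- function(model, topic, mode = c("WORDS", "PARAGRAPHS"),
                                 top_n = 20L) {
  mode <- match.arg(mode)
  if (mode == "WORDS") {
    ord <- order(model$phi[topic, ], decreasing = TRUE)
    paste(model$vocab[ord[seq_len(min(top_n, length(ord)))]], collapse = " ")
  } else {
    paste(model$paragraphs[model$assignments == topic], collapse = " ")
  }
}

#' Rank topics by relevance to the article
#'
#' Topics are ordered by descending cosine similarity between their WORDS
#' representation and the concatenated title + abstract; a secondary order
#' against the abstract alone drives the cumulative context features.  The
#' top 4 topics are retained (all of them when `k < 4`; the missing slots
#' produce zero features downstream).
#'
#' @param model an `fr_lda`.
#' @param title,abstract article fields.
#' @param space an `fr_space`.
#' @return list with `top` (topic indices, relevance order, length <= 4),
#'   `top_abstract` (indices by abstract-only relevance), and the cached
#'   representation texts `words`/`paras` per topic.
#' @export
rank_topics <- function(model, title, abstract, space) {
  kk <- model$k
  words <- vapply(seq_len(kk), function(t)
    topic_representation(model, t, "WORDS"), "")
  paras <- vapply(seq_len(kk), function(t)
    topic_representation(model, t, "PARAGRAPHS"), "")
  rel <- vapply(seq_len(kk), function(t)
    cosine(words[t], paste(title, abstract), space), 0)
  rel_abs <- vapply(seq_len(kk), function(t)
    cosine(words[t], abstract, space), 0)
  list(top = order(rel, decreasing = TRUE)[seq_len(min(4L, kk))],
       top_abstract = order(rel_abs, decreasing = TRUE)[seq_len(min(2L, kk))],
       words = words, paras = paras)
}

#' Topic features of a figure
#'
#' 24 similarities ({caption, context, caption+context} x top-4 topics x
#' {WORDS, PARAGRAPHS}) plus 2 cumulative values: the summed similarity of
#' the figure's associated context with the top-2 topics by
#' abstract-relevance, one per representation mode.  Missing topic slots
#' (k < 4) and empty figure texts give 0.
#'
#' @param article an `fr_article`.
#' @param figure one of its figures (context attached).
#' @param ranked result of [rank_topics()].
#' @param space an `fr_space`.
#' @return named numeric vector of 26 values.
#' @export
topic_features <- function(article, figure, ranked, space) {
  reps <- list(caption = figure$caption,
               context = figure$associated_context,
               capctx = .capctx(figure))
  out <- stats::setNames(numeric(length(.topic_names)), .topic_names)
  for (slot in 1:4) {
    topic <- if (slot <= length(ranked$top)) ranked$top[slot] else NA_integer_
    for (mode in c("words", "paras")) {
      rep_text <- if (is.na(topic)) "" else ranked[[mode]][topic]
      for (rn in names(reps)) {
        nm <- paste0("topic", slot, "_", mode, "_", rn)
        out[nm] <- if (nzchar(rep_text)) cosine(reps[[rn]], rep_text, space)
                   else 0
      }
    }
  }
  for (mode in c("words", "paras")) {
    s <- 0
    for (topic in ranked$top_abstract) {
      rep_text <- ranked[[mode]][topic]
      if (nzchar(rep_text)) s <- s + cosine(reps$context, rep_text, space)
    }
    out[paste0("topic_cum2_", mode, "_context")] <- s
  }
  out
}

#' Dump a topic model for inspection
#'
#' JSON with the per-topic top words and the per-paragraph topic
#' distribution.
#'
#' @param model an `fr_lda`.
#' @param path output path.
#' @param top_n words per topic.
#' @export
write_topic_model <- function(model, path, top_n = 20L) {
  obj <- list(
    k = model$k, seed = model$seed,
    topics = lapply(seq_len(model$k), function(t)
      list(topic = t,
           top_words = strsplit(topic_representation(model, t, "WORDS",
                                                     top_n), " ")[[1]])),
    theta = apply(model$theta, 1L, as.numeric, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
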