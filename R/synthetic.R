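# Synthetic data generation: (a) numeric ranking datasets from a known
# linear model, for trainer and feature-selection tests; (b) full
# articles with planted figure-importance structure, for end-to-end
# pipeline tests.  Everything is deterministic given the seed.


# Collapse each adjacent pair of rank groups into a tie with probability
# tie_prob; merges cascade, so tie_prob = 1 collapses every figure into a
# single rank group.
.collapse_ties <- function(ranks, tie_prob) {
  top <- max(ranks)
  if (tie_prob <= 0 || top == 1L) return(ranks)
  merge <- stats::runif(top - 1L) < tie_prob
  group <- cumsum(c(1L, !merge))
  dense_ranks(group[ranks])
}

#' Default figures-per-article distribution
#'
#' Discrete distribution over 2..9 figures peaked at 4-6, emulating the
#' shape typical of experimental biology articles (most articles carry
#' 4-6 figures and almost none carry more than 9).
#'
#' @return named numeric vector of probabilities.
#' @export
figure_count_distribution <- function() {
  stats::setNames(c(0.05, 0.12, 0.21, 0.23, 0.18, 0.10, 0.06, 0.05), 2:9)
}

#' Generate a numeric ranking dataset from a planted linear model
#'
#' Features are i.i.d. standard normal; the true score of each figure is
#' `w* . x` plus Gaussian noise; gold ranks are the dense ranks of the
#' true scores (descending), with optional ties injected by collapsing
#' adjacent rank pairs.
#'
#' @param n_articles number of lists.
#' @param n_features feature dimension.
#' @param figure_counts vector of possible figure counts per article
#'   (sampled uniformly), or a single count.
#' @param noise_sd standard deviation of the score noise (0 = noise-free).
#' @param tie_prob probability that each adjacent rank pair is collapsed
#'   into a tie.
#' @param w_star planted weight vector (default: drawn standard normal).
#' @param seed RNG seed.
#' @return list with `dataset` (an `fr_dataset`) and `w_star`.
#' @export
generate_ranking_dataset <- function(n_articles = 200L, n_features = 10L,
                                     figure_counts = 2:6, noise_sd = 0,
                                     tie_prob = 0, w_star = NULL,
                                     seed = 1L) {
  with_seed(seed, {
    if (is.null(w_star)) w_star <- stats::rnorm(n_features)
    stopifnot(length(w_star) == n_features)
    xs <- gold <- vector("list", n_articles)
    for (i in seq_len(n_articles)) {
      n <- if (length(figure_counts) == 1L) figure_counts else
        sample(figure_counts, 1L)
      x <- matrix(stats::rnorm(n * n_features), n, n_features,
                  dimnames = list(NULL, paste0("f", seq_len(n_features))))
      true <- as.numeric(x %*% w_star) + stats::rnorm(n, sd = noise_sd)
      ranks <- dense_ranks(rank(-true, ties.method = "first"))
      ranks <- .collapse_ties(ranks, tie_prob)
      xs[[i]] <- x
      gold[[i]] <- ranks
    }
    list(dataset = ranking_dataset(xs, gold), w_star = w_star)
  })
}

# Deterministic pseudo-word pools: a shared background vocabulary plus one
# pool per latent topic, so topic models and tf-idf cosines have real
# co-occurrence structure to find.
.make_vocab <- function(n_topics = 4L, pool = 40L, background = 60L) {
  syll <- c("ba", "co", "de", "fi", "ge", "lu", "mi", "no", "pra", "qui",
            "ra", "sta", "tri", "vo", "zy")
  words <- as.vector(outer(syll, syll, paste0))
  words <- as.vector(outer(words, c("n", "l", "x", "s", "t"), paste0))
  stopifnot(length(words) >= background + n_topics * pool)
  list(background = words[seq_len(background)],
       topics = lapply(seq_len(n_topics), function(t)
         words[background + (t - 1L) * pool + seq_len(pool)]))
}

.sample_sentence <- function(topic_pool, background, n_words = 9L,
                             mix = 0.7) {
  n_t <- stats::rbinom(1L, n_words, mix)
  w <- c(sample(topic_pool, n_t, replace = TRUE),
         sample(background, n_words - n_t, replace = TRUE))
  paste0(paste(sample(w), collapse = " "), ".")
}

#' Generate a synthetic article with planted figure importance
#'
#' Builds an IMRAD article whose figures differ in importance by
#' construction: more important figures (lower gold rank) receive more
#' mention sentences in RESULTS and DISCUSSION, captions sharing more
#' vocabulary with the title and abstract, and more sub-figure markers —
#' so centrality, frequency and structural features all correlate with
#' the gold ranking.  With `importance_gradient = FALSE` all figures are
#' generated symmetrically and the gold ranking is fully tied.
#'
#' @param article_id identifier.
#' @param n_figures figure count (default drawn from
#'   [figure_count_distribution()]).
#' @param tie_prob probability of collapsing each adjacent gold rank pair.
#' @param importance_gradient plant an importance signal?
#' @param seed RNG seed.
#' @return list with `article` (an `fr_article`) and `gold` (dense ranks).
#' @export
generate_article <- function(article_id = "synth1", n_figures = NULL,
                             tie_prob = 0.2, importance_gradient = TRUE,
                             seed = 1L) {
  with_seed(seed, {
    vocab <- .make_vocab()
    if (is.null(n_figures)) {
      pc <- figure_count_distribution()
      n_figures <- as.integer(sample(names(pc), 1L, prob = pc))
    }
    n <- n_figures
    # importance 1 = most important; figure positions shuffled so position
    # itself is informative but not identical to the gold order
    importance <- if (importance_gradient) sample(n) else rep(1L, n)
    topic_of_fig <- sample(length(vocab$topics), n, replace = TRUE)
    main_topic <- vocab$topics[[1]]

    title <- paste(sample(main_topic, 6), collapse = " ")
    abstract <- paste(vapply(1:3, function(i)
      .sample_sentence(main_topic, vocab$background), ""), collapse = " ")

    captions <- vapply(seq_len(n), function(j) {
      imp <- importance[j]
      # important figures borrow title/abstract vocabulary
      n_main <- if (importance_gradient) max(0L, 6L - 2L * (imp - 1L)) else 2L
      subfig <- if (importance_gradient) min(4L, max(0L, 5L - imp)) else 1L
      markers <- if (subfig > 0)
        paste0("(", LETTERS[seq_len(subfig)], ")", collapse = " ") else ""
      paste(markers,
            paste(sample(c(sample(main_topic, n_main, replace = TRUE),
                           sample(vocab$topics[[topic_of_fig[j]]], 5,
                                  replace = TRUE))), collapse = " "),
            ".")
    }, "")

    mention_sentence <- function(j) {
      paste0("Figure ", j, " shows ",
             paste(sample(vocab$topics[[topic_of_fig[j]]], 5,
                          replace = TRUE), collapse = " "), ".")
    }
    filler_par <- function(pool, k = 3L) {
      paste(vapply(seq_len(k), function(i)
        .sample_sentence(pool, vocab$background), ""), collapse = " ")
    }
    # mentions per figure in RESULTS/DISCUSSION grow with importance
    mentions_of <- function(j) {
      if (!importance_gradient) return(2L)
      max(1L, n - importance[j] + 1L)
    }
    results_pars <- lapply(seq_len(n), function(j) {
      sents <- c(vapply(seq_len(mentions_of(j)), function(i)
        mention_sentence(j), ""),
        .sample_sentence(vocab$topics[[topic_of_fig[j]]], vocab$background))
      paste(sample(sents), collapse = " ")
    })
    disc_mentions <- which(if (importance_gradient) importance <= ceiling(n / 2)
                           else rep(TRUE, n))
    discussion_pars <- c(
      list(filler_par(main_topic)),
      lapply(disc_mentions, function(j) mention_sentence(j)))

    sections <- list(
      list(heading = "Introduction", paragraphs = c(filler_par(main_topic),
                                                    filler_par(main_topic))),
      list(heading = "Materials and Methods",
           paragraphs = c(filler_par(vocab$topics[[min(2L, length(vocab$topics))]]),
                          filler_par(vocab$background))),
      list(heading = "Results", paragraphs = unlist(results_pars)),
      list(heading = "Discussion", paragraphs = unlist(discussion_pars)))

    figures <- lapply(seq_len(n), function(j)
      list(label = as.character(j), caption = captions[j]))

    gold <- .collapse_ties(dense_ranks(importance), tie_prob)
    list(article = new_article(article_id, title, abstract, sections,
                               figures),
         gold = gold)
  })
}

#' Generate and write a synthetic corpus
#'
#' Writes one article JSON per file, the gold TSV, and a manifest JSON
#' recording the seed and generator settings.
#'
#' @param dir output directory (created if needed).
#' @param n_articles corpus size.
#' @param tie_prob adjacent-rank tie probability per article.
#' @param seed root seed; article i uses `seed + i`.
#' @return invisibly, the list of `(article, gold)` pairs.
#' @export
simulate_corpus <- function(dir, n_articles = 20L, tie_prob = 0.2,
                            seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gold <- list()
  arts <- vector("list", n_articles)
  for (i in seq_len(n_articles)) {
    id <- sprintf("synth%03d", i)
    ag <- generate_article(id, tie_prob = tie_prob, seed = seed + i)
    write_article_json(ag$article, file.path(dir, paste0(id, ".json")))
    gold[[id]] <- ag$gold
    arts[[i]] <- ag
  }
  write_gold_rankings(gold, file.path(dir, "gold.tsv"))
  jsonlite::write_json(list(n_articles = n_articles, tie_prob = tie_prob,
                            seed = seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(arts)
}
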