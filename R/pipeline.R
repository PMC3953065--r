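# Corpus-level pipeline: feature extraction over a directory of articles,
# cross-validated system comparison, and the random baseline.  These
# functions are also the backend of the command-line dispatcher shipped
# under inst/cli/.

#' Extract features for a corpus of article JSON files
#'
#' Reads every `*.json` article in `corpus_dir` (skipping unreadable files
#' with a warning), attaches figure contexts, builds one shared tf-idf
#' space over all articles' text units, fits a per-article topic model,
#' and extracts the full feature matrix per figure.
#'
#' @param corpus_dir directory of article JSON files.
#' @param gold_path gold ranking TSV covering the articles.
#' @param k_topics topics per article (default 10).
#' @param lda_iterations Gibbs sweeps per article (default 500).
#' @param seed root seed (article i's topic model uses `seed + i`).
#' @return an `fr_dataset` with registry-ordered feature columns.
#' @export
extract_corpus <- function(corpus_dir, gold_path, k_topics = 10L,
                           lda_iterations = 500L, seed = 1L) {
  files <- sort(list.files(corpus_dir, pattern = "\\.json$",
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  if (length(files) == 0L) stop("no article JSON files in ", corpus_dir)
  gold_all <- read_gold_rankings(gold_path)
  articles <- list()
  for (f in files) {
    art <- tryCatch(read_article_json(f), error = function(e) {
      warning("skipping unreadable article ", basename(f), ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(art)) articles[[art$article_id]] <- art
  }
  if (length(articles) == 0L) stop("no readable articles in ", corpus_dir)
  missing <- setdiff(names(articles), names(gold_all))
  if (length(missing) > 0L)
    stop("articles without gold rankings: ", paste(missing, collapse = ", "))
  articles <- lapply(articles, attach_contexts)
  # one space over the whole collection: all paragraphs, captions,
  # titles and abstracts are indexing units
  units <- unlist(lapply(articles, function(a) c(
    unlist(lapply(a$sections, function(s) s$paragraphs)),
    vapply(a$figures, function(f) f$caption, ""),
    a$title, a$abstract)), use.names = FALSE)
  space <- build_vector_space(units[nzchar(units)])
  xs <- vector("list", length(articles))
  gold <- vector("list", length(articles))
  for (i in seq_along(articles)) {
    art <- articles[[i]]
    paras <- unlist(lapply(art$sections, function(s) s$paragraphs),
                    use.names = FALSE)
    lda <- fit_lda(paras, k = k_topics, seed = seed + i,
                   iterations = lda_iterations)
    xs[[i]] <- extract_all(art, space, lda)
    g <- gold_all[[art$article_id]]
    if (length(g) != length(art$figures))
      stop("gold ranking length mismatch for ", art$article_id)
    gold[[i]] <- g
  }
  ranking_dataset(xs, gold, names(articles))
}

#' Random ranking baseline
#'
#' For each article draws `repeats` uniform permutations, evaluates each,
#' and averages — the sampled lower-bound system.
#'
#' @param gold named list of dense reference rank vectors.
#' @param repeats permutations per article (default 100).
#' @param seed RNG seed.
#' @return an `fr_report` whose per-article values are the per-article
#'   means over the random permutations.
#' @export
random_baseline <- function(gold, repeats = 100L, seed = 1L) {
  per <- do.call(rbind, lapply(seq_along(gold), function(i) {
    r <- gold[[i]]
    m <- length(r)
    vals <- with_seed(seed + i, {
      vapply(seq_len(repeats), function(rep) {
        s <- sample.int(m)
        c(wer_rk_score(s, r), ndcg(s, r), wer_fr_score(s, r))
      }, numeric(3))
    })
    data.frame(article_id = names(gold)[i], m = m,
               wer_rk = mean(vals[1, ]), ndcg = mean(vals[2, ]),
               wer_fr = mean(vals[3, ]), stringsAsFactors = FALSE)
  }))
  summ <- data.frame(
    metric = c("wer_rk", "ndcg", "wer_fr"),
    mean = c(mean(per$wer_rk), mean(per$ndcg), mean(per$wer_fr)),
    sd = c(pop_sd(per$wer_rk), pop_sd(per$ndcg), pop_sd(per$wer_fr)))
  structure(list(per_article = per, summary = summ), class = "fr_report")
}

#' Cross-validated comparison of ranking systems
#'
#' Seeded article-level K-fold cross-validation: for each fold the
#' learners are trained on the remaining folds and evaluated on the
#' held-out articles; the random baseline is sampled per article.
#' Figures of one article never straddle folds.
#'
#' @param dataset an `fr_dataset`.
#' @param systems subset of `c("random", "top1", "top2")`.
#' @param folds fold count (default 10; must not exceed the article
#'   count).
#' @param seed seed for the fold split and the random baseline.
#' @param repeats random-baseline permutations per article.
#' @param trainer named list of extra [figrank()] arguments.
#' @return named list of `fr_report` objects, one per system.
#' @export
crossval_systems <- function(dataset, systems = c("random", "top1", "top2"),
                             folds = 10L, seed = 1L, repeats = 100L,
                             trainer = list()) {
  systems <- match.arg(systems, several.ok = TRUE)
  n <- length(dataset$x)
  if (n < folds) stop("need at least ", folds, " articles for ", folds,
                      "-fold cross-validation")
  fold_of <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  gold <- stats::setNames(dataset$gold, dataset$ids)
  out <- list()
  for (sys in systems) {
    if (sys == "random") {
      out$random <- random_baseline(gold, repeats = repeats, seed = seed)
      next
    }
    preds <- vector("list", n)
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      model <- do.call(figrank, c(list(dataset = dataset[-test_idx],
                                       loss = sys), trainer))
      preds[test_idx] <- predict(model, dataset[test_idx])
    }
    out[[sys]] <- evaluate_rankings(stats::setNames(preds, dataset$ids),
                                    gold)
  }
  out
}

#' Format a system-comparison table
#'
#' One row per system, `mean+/-sd` cells for ~WER-RK, NDCG and ~WER-FR.
#'
#' @param reports named list of `fr_report` objects
#'   (from [crossval_systems()]).
#' @return data frame of formatted cells.
#' @export
comparison_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    cell <- function(metric) {
      sprintf("%.3f±%.3f", s$mean[s$metric == metric],
              s$sd[s$metric == metric])
    }
    data.frame(system = nm, wer_rk = cell("wer_rk"), ndcg = cell("ndcg"),
               wer_fr = cell("wer_fr"), stringsAsFactors = FALSE)
  }))
}
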