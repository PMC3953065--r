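# Figure feature extraction: centrality, frequency and structural
# categories, plus the registry that fixes feature order.
#
# Registry layout (names sorted lexicographically within each category,
# categories in the order centrality, frequency, topic, structural):
#   centrality : 15   frequency : 12   topic : 26   structural : 4
# giving 57 features in total.  The registry, with the per-category
# inventory, can be dumped with write_feature_registry().

.imrad_main <- c("INTRO", "METHODS", "RESULTS", "DISCUSSION")

.centrality_names <- sort(c(
  paste0("cent_caption_", tolower(.imrad_main)),
  paste0("cent_context_", tolower(.imrad_main)),
  paste0("cent_capctx_", tolower(.imrad_main)),
  "cent_capctx_title", "cent_capctx_abstract", "cent_capctx_fulltext"))

.frequency_names <- sort(c(
  paste0("freq_", tolower(.imrad_main)),
  paste0("nfreq_", tolower(.imrad_main)),
  paste0("wfreq_title_", c("results", "discussion")),
  paste0("wfreq_abstract_", c("results", "discussion"))))

.topic_names <- sort(c(
  as.vector(outer(
    paste0("topic", 1:4),
    as.vector(outer(c("words", "paras"), c("caption", "context", "capctx"),
                    function(a, b) paste0("_", a, "_", b))),
    paste0)),
  "topic_cum2_words_context", "topic_cum2_paras_context"))

.structural_names <- c("struct_position", "struct_link_mean",
                       "struct_link_std", "struct_subfig")

#' The feature registry
#'
#' Fixed, platform-independent ordering of all figure features.
#'
#' @return data frame with columns `name`, `category`, `index`.
#' @export
feature_registry <- function() {
  nm <- c(.centrality_names, .frequency_names, .topic_names,
          .structural_names)
  data.frame(name = nm,
             category = rep(c("centrality", "frequency", "topic",
                              "structural"),
                            c(length(.centrality_names),
                              length(.frequency_names),
                              length(.topic_names),
                              length(.structural_names))),
             index = seq_along(nm),
             stringsAsFactors = FALSE)
}

#' Dump the feature registry as YAML
#'
#' Writes name, category and index for every feature, plus the per-category
#' counts.  The shipped inventory has 57 features; reported figure-feature
#' sets in the literature quote larger totals without itemizing them, so
#' the registry documents this package's inventory explicitly.
#'
#' @param path output path.
#' @export
write_feature_registry <- function(path) {
  reg <- feature_registry()
  obj <- list(
    total = nrow(reg),
    categories = as.list(table(reg$category)[unique(reg$category)]),
    features = lapply(seq_len(nrow(reg)), function(i)
      list(name = reg$name[i], category = reg$category[i],
           index = reg$index[i])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

# Concatenated text of all paragraphs of an article in one IMRAD category
# ("" when the category is absent).
.imrad_text <- function(article, imrad) {
  paras <- unlist(lapply(article$sections, function(s)
    if (s$imrad == imrad) s$paragraphs else character(0)),
    use.names = FALSE)
  paste(paras, collapse = " ")
}

.full_text <- function(article) {
  paste(unlist(lapply(article$sections, function(s) s$paragraphs),
               use.names = FALSE), collapse = " ")
}

# caption + associated context representation of a figure
.capctx <- function(figure) {
  paste(figure$caption, figure$associated_context)
}

#' Centrality features of a figure
#'
#' How central the figure is to the article, measured by cosine similarity
#' in the shared vector space: the figure (as caption, associated context,
#' and caption+context) against each IMRAD section, and caption+context
#' against the title, the abstract and the full text.  Missing sections or
#' empty figure text give 0.
#'
#' @param article an `fr_article` with contexts attached.
#' @param figure one of its figures.
#' @param space an `fr_space`.
#' @return named numeric vector of 15 values in `[0, 1]`.
#' @export
centrality_features <- function(article, figure, space) {
  reps <- list(caption = figure$caption,
               context = figure$associated_context,
               capctx = .capctx(figure))
  out <- numeric(0)
  for (rn in names(reps)) {
    for (im in .imrad_main) {
      out[paste0("cent_", rn, "_", tolower(im))] <-
        cosine(reps[[rn]], .imrad_text(article, im), space)
    }
  }
  out["cent_capctx_title"] <- cosine(reps$capctx, article$title, space)
  out["cent_capctx_abstract"] <- cosine(reps$capctx, article$abstract, space)
  out["cent_capctx_fulltext"] <- cosine(reps$capctx, .full_text(article),
                                        space)
  out[.centrality_names]
}

#' Frequency features of a figure
#'
#' Mention counts per IMRAD section; the same counts normalized by section
#' token length; and weighted counts for RESULTS and DISCUSSION where each
#' paragraph's mentions are weighted by the paragraph's cosine similarity
#' with the title (resp. the abstract).
#'
#' @inheritParams centrality_features
#' @return named numeric vector of 12 values.
#' @export
frequency_features <- function(article, figure, space) {
  raw <- stats::setNames(numeric(4), .imrad_main)
  wtitle <- wabs <- stats::setNames(numeric(2), c("RESULTS", "DISCUSSION"))
  seclen <- stats::setNames(numeric(4), .imrad_main)
  for (sec in article$sections) {
    im <- sec$imrad
    if (!(im %in% .imrad_main)) next
    for (par in sec$paragraphs) {
      seclen[im] <- seclen[im] + .token_count(par, space)
      cnt <- sum(vapply(split_sentences(par), detect_figure_mentions, 0L,
                        label = figure$label))
      if (cnt == 0L) next
      raw[im] <- raw[im] + cnt
      if (im %in% c("RESULTS", "DISCUSSION")) {
        wtitle[im] <- wtitle[im] + cnt * cosine(par, article$title, space)
        wabs[im] <- wabs[im] + cnt * cosine(par, article$abstract, space)
      }
    }
  }
  norm <- ifelse(seclen > 0, raw / seclen, 0)
  out <- c(stats::setNames(raw, paste0("freq_", tolower(.imrad_main))),
           stats::setNames(norm, paste0("nfreq_", tolower(.imrad_main))),
           stats::setNames(wtitle, paste0("wfreq_title_",
                                          tolower(names(wtitle)))),
           stats::setNames(wabs, paste0("wfreq_abstract_",
                                        tolower(names(wabs)))))
  out[.frequency_names]
}

#' Count sub-figure markers in a caption
#'
#' Recognizes sub-captions of the forms "a.", "A:", "c," and "(A)" for the
#' letters a-f, case-insensitively; each distinct letter is counted once.
#'
#' @param caption caption text.
#' @return non-negative integer.
#' @examples
#' count_subfigures("A. control. B. treated. C. merged.")  # 3
#' @export
count_subfigures <- function(caption) {
  if (is.null(caption) || !nzchar(caption)) return(0L)
  m1 <- regmatches(caption,
                   gregexpr("(?<![A-Za-z0-9])([a-fA-F])[.:,]", caption,
                            perl = TRUE))[[1]]
  m2 <- regmatches(caption,
                   gregexpr("\\(([a-fA-F])\\)", caption, perl = TRUE))[[1]]
  letters_found <- tolower(c(substr(m1, 1L, 1L),
                             gsub("[()]", "", m2)))
  length(unique(letters_found))
}

#' Structural features of all figures of an article
#'
#' Per figure: the 1-based position; the mean and standard deviation of its
#' caption+context cosine similarity with every other figure (0 for a
#' single-figure article); and the sub-figure marker count.
#'
#' @param article an `fr_article` with contexts attached.
#' @param space an `fr_space`.
#' @return matrix `n_figures x 4` with columns `struct_position`,
#'   `struct_link_mean`, `struct_link_std`, `struct_subfig`.
#' @export
structural_features <- function(article, space) {
  n <- length(article$figures)
  stopifnot(n >= 1L)
  texts <- vapply(article$figures, .capctx, "")
  sim <- diag(1, n)
  if (n >= 2L) {
    for (j in seq_len(n - 1L)) {
      for (k in (j + 1L):n) {
        sim[j, k] <- sim[k, j] <- cosine(texts[j], texts[k], space)
      }
    }
  }
  out <- matrix(0, n, 4L,
                dimnames = list(NULL, .structural_names))
  for (j in seq_len(n)) {
    others <- sim[j, -j]
    out[j, "struct_position"] <- j
    out[j, "struct_link_mean"] <- if (n >= 2L) mean(others) else 0
    out[j, "struct_link_std"] <- if (n >= 2L) pop_sd(others) else 0
    out[j, "struct_subfig"] <- count_subfigures(article$figures[[j]]$caption)
  }
  out
}

#' Extract the full feature matrix for one article
#'
#' Concatenates the centrality (15), frequency (12), topic (26) and
#' structural (4) categories under the stable registry order.
#'
#' @param article an `fr_article` (contexts attached automatically if
#'   absent).
#' @param space an `fr_space` built over the corpus.
#' @param topic_model an `fr_lda` from [fit_lda()] for this article, or
#'   `NULL` to fit one from the article's paragraphs.
#' @param seed seed used when `topic_model` must be fitted here.
#' @return numeric matrix `n_figures x 57`, columns in registry order.
#' @export
extract_all <- function(article, space, topic_model = NULL, seed = 1L) {
  if (any(vapply(article$figures,
                 function(f) identical(f$associated_context, ""), TRUE))) {
    article <- attach_contexts(article)
  }
  if (is.null(topic_model)) {
    paras <- unlist(lapply(article$sections, function(s) s$paragraphs),
                    use.names = FALSE)
    topic_model <- fit_lda(paras, k = 10L, seed = seed)
  }
  ranked <- rank_topics(topic_model, article$title, article$abstract, space)
  struct <- structural_features(article, space)
  n <- length(article$figures)
  reg <- feature_registry()
  out <- matrix(NA_real_, n, nrow(reg), dimnames = list(NULL, reg$name))
  for (j in seq_len(n)) {
    fig <- article$figures[[j]]
    out[j, .centrality_names] <- centrality_features(article, fig, space)
    out[j, .frequency_names] <- frequency_features(article, fig, space)
    out[j, .topic_names] <- topic_features(article, fig, ranked, space)
    out[j, .structural_names] <- struct[j, ]
  }
  stopifnot(all(is.finite(out)))
  out
}
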