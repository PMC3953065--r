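# Term vector space shared by all cosine-similarity features.

#' Build a tf-idf vector space
#'
#' Constructs the vocabulary and inverse-document-frequency weights from a
#' corpus of text units (one document per element).  Identical inputs give
#' identical spaces.  Weighting is tf-idf by default, with
#' `idf = log(N / df)`; raw term frequency is available via
#' `weighting = "tf"`.
#'
#' @param texts character vector of documents (non-empty).
#' @param weighting `"tfidf"` (default) or `"tf"`.
#' @param stopwords drop function words during tokenization?
#' @return an object of class `fr_space` with `vocabulary` (term -> index),
#'   `idf` (non-negative weights) and the preprocessing spec.
#' @export
build_vector_space <- function(texts, weighting = c("tfidf", "tf"),
                               stopwords = TRUE) {
  weighting <- match.arg(weighting)
  texts <- as.character(texts)
  if (length(texts) == 0L) stop("empty corpus: no texts to index")
  toks <- lapply(texts, tokenize, stopwords = stopwords)
  if (all(lengths(toks) == 0L)) stop("empty corpus: no tokens after preprocessing")
  vocab <- sort(unique(unlist(toks)))
  df <- integer(length(vocab))
  names(df) <- vocab
  for (tk in toks) {
    u <- unique(tk)
    df[u] <- df[u] + 1L
  }
  n <- length(texts)
  idf <- if (weighting == "tfidf") log(n / pmax(df, 1L)) else
    rep(1, length(vocab))
  # Terms present in every document get idf 0 under the plain log form;
  # that is intended: they carry no discriminative weight.
  names(idf) <- vocab
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 idf = idf,
                 weighting = weighting,
                 stopwords = stopwords),
            class = "fr_space")
}

#' @export
print.fr_space <- function(x, ...) {
  cat("<vector space> ", length(x$vocabulary), " terms, ", x$weighting,
      " weighting\n", sep = "")
  invisible(x)
}

# Weighted term-frequency vector of a text in the space (named numeric,
# terms outside the vocabulary dropped).
.space_vector <- function(text, space) {
  toks <- tokenize(text, stopwords = space$stopwords)
  toks <- toks[toks %in% names(space$vocabulary)]
  if (length(toks) == 0L) return(numeric(0))
  tf <- table(toks)
  w <- as.numeric(tf) * space$idf[names(tf)]
  stats::setNames(as.numeric(w), names(tf))
}

#' Cosine similarity of two texts in a vector space
#'
#' Symmetric, in `[0, 1]`; defined as 0 whenever either text maps to the
#' zero vector (empty, out-of-vocabulary or stopword-only text).
#'
#' @param text_a,text_b character scalars.
#' @param space an `fr_space` from [build_vector_space()].
#' @return cosine similarity.
#' @export
cosine <- function(text_a, text_b, space) {
  va <- .space_vector(text_a, space)
  vb <- .space_vector(text_b, space)
  cosine_vec(va, vb)
}

# Cosine between two named weight vectors; 0 for degenerate input.
cosine_vec <- function(va, vb) {
  if (length(va) == 0L || length(vb) == 0L) return(0)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  shared <- intersect(names(va), names(vb))
  if (length(shared) == 0L) return(0)
  min(1, max(0, sum(va[shared] * vb[shared]) / (na * nb)))
}

# Token count of a text under the space's preprocessing (section length).
.token_count <- function(text, space) {
  length(tokenize(text, stopwords = space$stopwords))
}
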