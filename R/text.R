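# Text utilities shared by the corpus and feature modules: tokenization,
# sentence splitting, and the figure-mention grammar.

# A compact English stopword list (function words only; domain terms are
# never filtered).
.stopwords <- c(
  "a", "about", "above", "after", "again", "all", "also", "an", "and", "any",
  "are", "as", "at", "be", "because", "been", "before", "being", "below",
  "between", "both", "but", "by", "can", "could", "did", "do", "does",
  "doing", "down", "during", "each", "few", "for", "from", "further", "had",
  "has", "have", "having", "here", "how", "if", "in", "into", "is", "it",
  "its", "itself", "just", "more", "most", "no", "nor", "not", "now", "of",
  "off", "on", "once", "only", "or", "other", "our", "out", "over", "own",
  "same", "should", "so", "some", "such", "than", "that", "the", "their",
  "them", "then", "there", "these", "they", "this", "those", "through", "to",
  "too", "under", "until", "up", "very", "was", "we", "were", "what", "when",
  "where", "which", "while", "who", "whom", "why", "will", "with", "would")

#' Tokenize text
#'
#' Lowercases and extracts alphanumeric word tokens (a token starts with a
#' letter).  Stopword removal is optional and on by default for the
#' vector-space machinery.
#'
#' @param text character scalar (or vector, concatenated).
#' @param stopwords drop function words?
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, stopwords = TRUE) {
  text <- paste(text, collapse = " ")
  if (!nzchar(text)) return(character(0))
  toks <- regmatches(tolower(text),
                     gregexpr("[a-z][a-z0-9]*", tolower(text)))[[1]]
  if (stopwords) toks <- toks[!(toks %in% .stopwords)]
  toks
}

# Abbreviations whose trailing period must not end a sentence.
.abbrev <- c("fig", "figs", "al", "e\\.g", "i\\.e", "cf", "vs", "etc", "dr",
             "no", "ref", "eq", "eqs", "approx", "ca", "St")

#' Split text into sentences
#'
#' Rule-based splitter: sentences end at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter, digit or opening parenthesis.
#' Common abbreviations ("Fig.", "et al.", "e.g.") are protected so that
#' figure citations survive intact.  The concatenation of the returned
#' sentences reproduces the input text up to the inter-sentence whitespace.
#'
#' @param text character scalar.
#' @return character vector of sentences, in order; empty input gives
#'   `character(0)`.
#' @export
split_sentences <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  text <- gsub("[[:space:]]+", " ", trimws(text))
  # Mask protected periods with a placeholder that cannot occur in text.
  ph <- "\x01"
  masked <- text
  for (ab in .abbrev) {
    masked <- gsub(paste0("(?i)\\b(", ab, ")\\."), paste0("\\1", ph), masked,
                   perl = TRUE)
  }
  # Protect periods inside decimal numbers (e.g. "p = 0.05").
  masked <- gsub("(?<=[0-9])\\.(?=[0-9])", ph, masked, perl = TRUE)
  parts <- strsplit(masked, "(?<=[.!?])\\s+(?=[A-Z0-9(])", perl = TRUE)[[1]]
  parts <- gsub(ph, ".", parts, fixed = TRUE)
  parts[nzchar(trimws(parts))]
}

# Expand the item list of one figure-mention group ("3", "2A", "2-4",
# "3 and 4") into the figure labels it covers.  Panel suffixes are dropped:
# "2A" mentions figure "2".  Numeric ranges include interior labels.
.expand_mention_items <- function(items) {
  out <- character(0)
  for (it in items) {
    it <- trimws(it)
    if (!nzchar(it)) next
    range <- regmatches(it, regexec("^([0-9]+)[A-Za-z]?\\s*[-–—]\\s*([0-9]+)[A-Za-z]?$", it))[[1]]
    if (length(range) == 3L) {
      lo <- as.integer(range[2]); hi <- as.integer(range[3])
      if (lo <= hi && hi - lo <= 50L) out <- c(out, as.character(lo:hi))
      next
    }
    num <- regmatches(it, regexec("^([0-9]+)[A-Za-z]{0,2}$", it))[[1]]
    if (length(num) == 2L) out <- c(out, num[2])
  }
  out
}

# Regex for one mention group: the "Figure" keyword plus its item list.
.mention_group_re <- paste0(
  "\\bfig(?:ure)?s?\\.?\\s*",
  "([0-9]+[A-Za-z]{0,2}",
  "(?:\\s*(?:[-–—]|,|and|&)\\s*[0-9]+[A-Za-z]{0,2})*)")

#' Count mentions of a figure in a sentence
#'
#' Matches the mention grammar case-insensitively: "Figure 2", "Fig. 2",
#' "Figs. 2 and 3", "Figures 2-4" (ranges include interior labels).  Panel
#' suffixes count as mentions of the parent figure ("Figure 2A" mentions
#' "2").  Bare numbers without the Figure keyword never match.
#'
#' @param sentence character scalar.
#' @param label figure label as referenced in text (e.g. `"3"`).
#' @return non-negative integer count of mention groups covering `label`.
#' @export
detect_figure_mentions <- function(sentence, label) {
  if (!nzchar(sentence)) return(0L)
  m <- gregexpr(.mention_group_re, sentence, perl = TRUE, ignore.case = TRUE)
  groups <- regmatches(sentence, m)[[1]]
  if (length(groups) == 0L) return(0L)
  label <- as.character(label)
  n <- 0L
  for (g in groups) {
    body <- sub("(?i)^fig(?:ure)?s?\\.?\\s*", "", g, perl = TRUE)
    items <- strsplit(body, "\\s*(?:,|and|&)\\s*", perl = TRUE)[[1]]
    covered <- .expand_mention_items(items)
    n <- n + sum(covered == label)
  }
  n
}
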