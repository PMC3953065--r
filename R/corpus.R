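# Domain types and readers for full-text articles, figures and gold
# rankings, plus the figure/text association procedures.

.imrad_levels <- c("INTRO", "METHODS", "RESULTS", "DISCUSSION", "OTHER")

#' Map a section heading to its IMRAD category
#'
#' Deterministic, case-insensitive mapping through a shipped synonym table.
#' Combined "Results and Discussion" headings resolve to `RESULTS` so that
#' the shared text is counted once by the section-based features.  Unknown
#' headings map to `OTHER`.
#'
#' @param heading section heading text.
#' @return one of `"INTRO"`, `"METHODS"`, `"RESULTS"`, `"DISCUSSION"`,
#'   `"OTHER"`.
#' @examples
#' map_imrad("Materials and Methods")   # METHODS
#' map_imrad("RESULTS AND DISCUSSION")  # RESULTS
#' @export
map_imrad <- function(heading) {
  if (is.null(heading) || is.na(heading) || !nzchar(heading)) return("OTHER")
  h <- tolower(gsub("[^a-z ]", " ", tolower(heading)))
  h <- gsub("[[:space:]]+", " ", trimws(h))
  has <- function(p) grepl(p, h)
  if (has("result") && has("discussion")) return("RESULTS")
  if (has("method") || has("procedur") || has("experimental design") ||
      has("study design") || has("materials?$") || has("^materials"))
    return("METHODS")
  if (has("introduction") || has("background")) return("INTRO")
  if (has("result") || has("finding")) return("RESULTS")
  if (has("discussion") || has("conclusion") || has("concluding"))
    return("DISCUSSION")
  "OTHER"
}

new_figure <- function(position, label, caption, associated_context = "") {
  stopifnot(position >= 1L, !is.null(caption))
  structure(list(position = as.integer(position),
                 label = as.character(label),
                 caption = as.character(caption),
                 associated_context = as.character(associated_context)),
            class = "fr_figure")
}

#' Construct an article object
#'
#' The in-memory form of a sectioned full-text article: title, abstract,
#' ordered sections of paragraphs (each tagged with an IMRAD category), and
#' the ordered list of figures.  Figure positions are forced consecutive
#' from 1 in document order.
#'
#' @param article_id opaque identifier.
#' @param title,abstract text fields (`""` when absent).
#' @param sections list of `list(heading=, imrad=, paragraphs=)`; `imrad`
#'   is filled by [map_imrad()] when missing.
#' @param figures list of `list(label=, caption=)` in document order.
#' @return an object of class `fr_article`.
#' @export
new_article <- function(article_id, title = "", abstract = "",
                        sections = list(), figures = list()) {
  sections <- lapply(sections, function(s) {
    imrad <- s$imrad
    if (is.null(imrad) || is.na(imrad) || !nzchar(imrad))
      imrad <- map_imrad(s$heading)
    imrad <- toupper(imrad)
    if (!imrad %in% .imrad_levels)
      stop("unknown imrad label: ", imrad)
    list(heading = as.character(s$heading %||% ""),
         imrad = imrad,
         paragraphs = as.character(unlist(s$paragraphs, use.names = FALSE)))
  })
  figs <- vector("list", length(figures))
  for (i in seq_along(figures)) {
    f <- figures[[i]]
    figs[[i]] <- new_figure(i, f$label %||% as.character(i), f$caption %||% "")
  }
  structure(list(article_id = as.character(article_id),
                 title = as.character(title %||% ""),
                 abstract = as.character(abstract %||% ""),
                 sections = sections,
                 figures = figs),
            class = "fr_article")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.fr_article <- function(x, ...) {
  cat("<article ", x$article_id, "> ", length(x$sections), " sections, ",
      length(x$figures), " figures\n", sep = "")
  invisible(x)
}

#' Read an article from the JSON schema
#'
#' Expects one UTF-8 JSON object per file:
#' `{"article_id", "title", "abstract", "sections":[{"heading", "imrad"?,
#' "paragraphs":[...]}], "figures":[{"label","caption"}]}`.
#' IMRAD labels are assigned from the heading when the `imrad` key is
#' absent.  A missing abstract defaults to `""` with a warning; zero
#' figures is an error because the article cannot be ranked.
#'
#' @param path file path.
#' @return an `fr_article`.
#' @export
read_article_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  for (key in c("article_id", "sections", "figures")) {
    if (is.null(obj[[key]]))
      stop("article schema error in ", path, ": missing key '", key, "'")
  }
  if (length(obj$figures) == 0L)
    stop("empty-article error: ", path, " has no figures")
  if (is.null(obj$abstract))
    warning("article ", obj$article_id, " has no abstract; using \"\"")
  for (s in obj$sections) {
    if (is.null(s$heading) && is.null(s$imrad))
      stop("article schema error in ", path,
           ": section without 'heading' or 'imrad'")
    if (is.null(s$paragraphs))
      stop("article schema error in ", path, ": section missing 'paragraphs'")
  }
  for (f in obj$figures) {
    if (is.null(f$caption))
      stop("article schema error in ", path, ": figure missing 'caption'")
  }
  new_article(obj$article_id, obj$title %||% "", obj$abstract %||% "",
              obj$sections, obj$figures)
}

#' Serialize an article back to the JSON schema
#'
#' Inverse of [read_article_json()]; round-tripping preserves all fields
#' (canonical key order).
#'
#' @param article an `fr_article`.
#' @param path output path.
#' @export
write_article_json <- function(article, path) {
  obj <- list(
    article_id = article$article_id,
    title = article$title,
    abstract = article$abstract,
    sections = lapply(article$sections, function(s)
      list(heading = s$heading, imrad = s$imrad,
           paragraphs = as.list(s$paragraphs))),
    figures = lapply(article$figures, function(f)
      list(label = f$label, caption = f$caption)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an article from JATS-like XML
#'
#' Minimal reader for the NXML dialect: title from
#' `front//article-meta//title-group/article-title`, abstract from
#' `front//abstract`, sections from `body/sec` (heading = `title` child),
#' figures from `fig` elements in document order (caption = concatenated
#' text of the `caption` element; `label` text provides the display
#' number).  A `fig` without a caption yields `caption = ""` with a
#' warning; a missing `body` is a structural error.
#'
#' @param path path to the XML file.
#' @param article_id identifier to assign; defaults to the file name.
#' @return an `fr_article`.
#' @export
read_jats_xml <- function(path, article_id = NULL) {
  doc <- xml2::read_xml(path)
  if (is.null(article_id)) {
    article_id <- xml2::xml_text(
      xml2::xml_find_first(doc, ".//front//article-id"))
    if (is.na(article_id) || !nzchar(article_id))
      article_id <- sub("\\.[^.]*$", "", basename(path))
  }
  title <- xml2::xml_text(xml2::xml_find_first(
    doc, ".//front//title-group/article-title"))
  abstract <- xml2::xml_text(xml2::xml_find_first(doc, ".//front//abstract"))
  body <- xml2::xml_find_first(doc, ".//body")
  if (inherits(body, "xml_missing"))
    stop("structural error: ", path, " has no <body>")
  secs <- xml2::xml_find_all(body, "./sec")
  sections <- lapply(secs, function(sec) {
    heading <- xml2::xml_text(xml2::xml_find_first(sec, "./title"))
    paras <- vapply(xml2::xml_find_all(sec, ".//p"), xml2::xml_text, "")
    list(heading = if (is.na(heading)) "" else heading, paragraphs = paras)
  })
  figs <- xml2::xml_find_all(doc, ".//fig")
  figures <- lapply(seq_along(figs), function(i) {
    fig <- figs[[i]]
    label <- xml2::xml_text(xml2::xml_find_first(fig, "./label"))
    label <- if (is.na(label)) as.character(i) else
      sub("^.*?([0-9]+).*$", "\\1", label)
    capnode <- xml2::xml_find_first(fig, "./caption")
    if (inherits(capnode, "xml_missing")) {
      warning("fig ", i, " in ", path, " has no caption; using \"\"")
      caption <- ""
    } else {
      caption <- paste(vapply(xml2::xml_find_all(capnode, ".//text()"),
                              xml2::xml_text, ""), collapse = " ")
      caption <- gsub("[[:space:]]+", " ", trimws(caption))
    }
    list(label = label, caption = caption)
  })
  if (length(figures) == 0L)
    stop("empty-article error: ", path, " has no figures")
  new_article(article_id,
              if (is.na(title)) "" else title,
              if (is.na(abstract)) "" else abstract,
              sections, figures)
}

#' Extract the associated context of a figure
#'
#' The figure's textual neighborhood: every body sentence that mentions the
#' figure plus up to two sentences before and after each mention, windows
#' clipped at paragraph boundaries and overlapping windows merged, each
#' sentence kept once in document order.  The abstract is not searched.
#' A never-mentioned figure yields `""`.
#'
#' @param article an `fr_article`.
#' @param figure one element of `article$figures` (or its position).
#' @param window sentences kept on each side of a mention (default 2).
#' @return character scalar: the concatenated context sentences.
#' @export
extract_associated_context <- function(article, figure, window = 2L) {
  if (is.numeric(figure)) figure <- article$figures[[figure]]
  out <- character(0)
  for (sec in article$sections) {
    for (par in sec$paragraphs) {
      sents <- split_sentences(par)
      if (length(sents) == 0L) next
      hits <- which(vapply(sents, detect_figure_mentions, 0L,
                           label = figure$label) > 0L)
      if (length(hits) == 0L) next
      keep <- sort(unique(unlist(lapply(hits, function(i)
        max(1L, i - window):min(length(sents), i + window)))))
      out <- c(out, sents[keep])
    }
  }
  paste(out, collapse = " ")
}

#' Attach associated context to every figure of an article
#'
#' @param article an `fr_article`.
#' @inheritParams extract_associated_context
#' @return the article with each figure's `associated_context` filled.
#' @export
attach_contexts <- function(article, window = 2L) {
  article$figures <- lapply(article$figures, function(f) {
    f$associated_context <- extract_associated_context(article, f, window)
    f
  })
  article
}

#' Read gold figure rankings
#'
#' TSV format, one article per line: `article_id <TAB> r1,r2,...` with the
#' ranks in figure-position order.  Ranks are normalized to dense numbering
#' ([dense_ranks()]); ties are preserved.
#'
#' @param path file path.
#' @return named list of integer rank vectors, one per article id.
#' @export
read_gold_rankings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("gold ranking format error: expected 'id<TAB>ranks' in: ", ln)
    ranks <- suppressWarnings(as.numeric(strsplit(parts[2], ",")[[1]]))
    if (any(is.na(ranks)) || any(ranks <= 0))
      stop("gold ranking format error: non-positive or non-numeric rank in: ",
           ln)
    out[[parts[1]]] <- dense_ranks(ranks)
  }
  out
}

#' Write gold rankings in the TSV format read by [read_gold_rankings()]
#' @param gold named list of integer rank vectors.
#' @param path output path.
#' @export
write_gold_rankings <- function(gold, path) {
  lines <- vapply(names(gold), function(id)
    paste0(id, "\t", paste(gold[[id]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
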