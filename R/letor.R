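# LETOR / SVM-rank "qid" text serialization of ranking datasets.
#
# Line format:  rel qid:<list-id> 1:v1 2:v2 ... # <figure-id>
# Relevance is the reversed dense gold rank (most important figure gets
# the largest relevance, least important gets 0), so generic LETOR
# tooling reads the file with its usual "larger relevance = better"
# convention.  write_letor() followed by read_letor() is the identity.

#' Write a ranking dataset in LETOR format
#'
#' @param dataset an `fr_dataset`.
#' @param path output path.
#' @export
write_letor <- function(dataset, path) {
  stopifnot(inherits(dataset, "fr_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(dataset$x)) {
    m <- dataset$x[[i]]
    g <- dataset$gold[[i]]
    rel <- max(g) - g
    for (j in seq_len(nrow(m))) {
      feats <- paste0(seq_len(ncol(m)), ":",
                      sprintf("%.12g", m[j, ]), collapse = " ")
      writeLines(sprintf("%d qid:%s %s # %s_f%d", rel[j], dataset$ids[i],
                         feats, dataset$ids[i], j), con)
    }
  }
  invisible(path)
}

#' Read a ranking dataset from LETOR format
#'
#' @param path input path.
#' @param feature_names optional column names (defaults to `f1..fd`).
#' @return an `fr_dataset`; gold ranks are recovered from the relevance
#'   column by dense-ranking its negation.
#' @export
read_letor <- function(path, feature_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty LETOR file: ", path)
  rel <- numeric(length(lines))
  qid <- character(length(lines))
  feats <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- sub("\\s*#.*$", "", lines[i])
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 3L || !grepl("^qid:", parts[2]))
      stop("LETOR format error at line ", i)
    rel[i] <- as.numeric(parts[1])
    qid[i] <- sub("^qid:", "", parts[2])
    kv <- strsplit(parts[-(1:2)], ":", fixed = TRUE)
    idx <- vapply(kv, function(p) as.integer(p[1]), 0L)
    val <- vapply(kv, function(p) as.numeric(p[2]), 0)
    if (any(is.na(idx)) || any(is.na(val)) ||
        !identical(idx, seq_along(idx)))
      stop("LETOR format error at line ", i, ": bad feature block")
    feats[[i]] <- val
  }
  d <- unique(lengths(feats))
  if (length(d) != 1L)
    stop("LETOR format error: inconsistent feature count (",
         paste(d, collapse = ", "), ")")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d))
  ids <- unique(qid)
  xs <- gold <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- which(qid == ids[k])
    m <- do.call(rbind, feats[rows])
    colnames(m) <- feature_names
    xs[[k]] <- m
    gold[[k]] <- dense_ranks(max(rel[rows]) - rel[rows] + 1)
  }
  ranking_dataset(xs, gold, ids)
}
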