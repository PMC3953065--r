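test_that("cosine matches a hand-computed tf-idf value", {
  sp <- tiny_space()
  # documents: "alpha beta beta", "alpha gamma", "delta delta"; N = 3
  # idf: alpha log(3/2); beta, gamma, delta log(3)
  ia <- log(3 / 2); ib <- log(3)
  num <- 1 * ia * 1 * ia
  den <- sqrt(ia^2 + (2 * ib)^2) * sqrt(ia^2 + ib^2)
  expect_equal(cosine("alpha beta beta", "alpha gamma", sp), num / den,
               tolerance = 1e-12)
  expect_equal(cosine("alpha beta beta", "alpha beta beta", sp), 1)
  expect_equal(cosine("alpha beta", "delta", sp), 0)
  expect_equal(cosine("", "alpha", sp), 0)   # zero vector rule
})

test_that("degenerate vector-space inputs are rejected or zeroed", {
  expect_error(build_vector_space(character(0)), "empty corpus")
  sp <- build_vector_space(c("the of and", "alpha beta"))
  expect_equal(cosine("the of and", "alpha beta", sp), 0)
})

test_that("registry is stable, rectangular and category-ordered", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 57L)
  expect_identical(unique(reg$category),
                   c("centrality", "frequency", "topic", "structural"))
  expect_identical(as.integer(table(reg$category)[unique(reg$category)]),
                   c(15L, 12L, 26L, 4L))
  expect_identical(reg$index, seq_len(57L))
  p <- tempfile(fileext = ".yaml")
  write_feature_registry(p)
  dumped <- yaml::read_yaml(p)
  expect_identical(dumped$total, 57L)
  expect_identical(length(dumped$features), 57L)
})

test_that("centrality features hit their anchors", {
  par <- "the kinase pathway controls growth in cells"
  art <- new_article("c1", title = "kinase growth", abstract = "",
    sections = list(list(heading = "Results", paragraphs = par)),
    figures = list(list(label = "1", caption = par)))
  art <- attach_contexts(art)
  sp <- build_vector_space(c(par, "unrelated words entirely"),
                           stopwords = FALSE)
  f <- centrality_features(art, art$figures[[1]], sp)
  expect_length(f, 15L)
  # caption verbatim equal to the single RESULTS paragraph
  expect_equal(unname(f["cent_caption_results"]), 1)
  # article has no METHODS section: all xMETHODS features are 0
  expect_true(all(f[grepl("_methods$", names(f))] == 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("frequency features count, weight and normalize mentions", {
  par <- paste("Figure 1 shows growth. Figure 1 is central.",
               "Controls were stable.")
  art <- new_article("f1", title = "growth control",
                     abstract = "growth was measured",
    sections = list(list(heading = "Results", paragraphs = par)),
    figures = list(list(label = "1", caption = "growth"),
                   list(label = "2", caption = "other")))
  art <- attach_contexts(art)
  sp <- build_vector_space(c(par, art$title, art$abstract),
                           stopwords = FALSE)
  f1 <- frequency_features(art, art$figures[[1]], sp)
  f2 <- frequency_features(art, art$figures[[2]], sp)
  expect_length(f1, 12L)
  expect_equal(unname(f1["freq_results"]), 2)
  expect_true(all(f1[c("freq_intro", "freq_methods", "freq_discussion")]
                  == 0))
  expect_equal(unname(f1["nfreq_results"]),
               2 / length(tokenize(par, stopwords = FALSE)))
  # weighted frequency = mentions x cosine(paragraph, title)
  expect_equal(unname(f1["wfreq_title_results"]),
               2 * cosine(par, art$title, sp))
  expect_true(all(f2[grepl("^freq|^wfreq", names(f2))] == 0))
})

test_that("sub-figure markers are counted once per letter", {
  expect_identical(count_subfigures("A. control. B. treated. C. merged."), 3L)
  expect_identical(count_subfigures("(A) before (B) after"), 2L)
  expect_identical(count_subfigures("Overview of the pathway"), 0L)
  expect_identical(count_subfigures("a, then a. again A:"), 1L)
  expect_identical(count_subfigures(""), 0L)
})

test_that("structural features cover position, links and spread", {
  texts <- c("alpha beta shared", "alpha beta shared", "omega distinct")
  art <- new_article("s1", sections = list(),
    figures = lapply(1:3, function(i)
      list(label = as.character(i), caption = texts[i])))
  art$figures <- lapply(art$figures, function(f) {
    f$associated_context <- ""
    f
  })
  sp <- build_vector_space(texts, stopwords = FALSE)
  st <- structural_features(art, sp)
  expect_identical(dim(st), c(3L, 4L))
  expect_identical(st[, "struct_position"], c(1, 2, 3))
  s12 <- cosine(texts[1], texts[2], sp)
  s13 <- cosine(texts[1], texts[3], sp)
  expect_equal(unname(st[1, "struct_link_mean"]), mean(c(s12, s13)))
  # identical caption+context pair: zero spread for the distinct one
  expect_equal(unname(st[3, "struct_link_std"]), 0)

  one <- new_article("s2", sections = list(),
    figures = list(list(label = "1", caption = "solo")))
  one$figures[[1]]$associated_context <- ""
  st1 <- structural_features(one, sp)
  expect_identical(st1[1, c("struct_link_mean", "struct_link_std")],
                   c(struct_link_mean = 0, struct_link_std = 0))
})

test_that("extract_all is deterministic and matches a scripted recompute", {
  art <- attach_contexts(tiny_article())
  units <- c(unlist(lapply(art$sections, function(s) s$paragraphs)),
             vapply(art$figures, function(f) f$caption, ""),
             art$title, art$abstract)
  sp <- build_vector_space(units)
  lda <- fit_lda(unlist(lapply(art$sections, function(s) s$paragraphs)),
                 k = 3, seed = 5, iterations = 60)
  m1 <- extract_all(art, sp, lda)
  m2 <- extract_all(art, sp, lda)
  expect_identical(m1, m2)
  expect_identical(dim(m1), c(3L, 57L))
  expect_identical(colnames(m1), feature_registry()$name)
  expect_true(all(is.finite(m1)))
  # independent recomputation of a feature from each category
  fig <- art$figures[[2]]
  expect_equal(unname(m1[2, "cent_capctx_title"]),
               cosine(paste(fig$caption, fig$associated_context),
                      art$title, sp), tolerance = 1e-9)
  expect_equal(unname(m1[2, "struct_subfig"]), count_subfigures(fig$caption))
  results_txt <- art$sections[[3]]$paragraphs
  nmention <- sum(vapply(unlist(lapply(results_txt, split_sentences)),
                         detect_figure_mentions, 0L, label = "2"))
  expect_equal(unname(m1[2, "freq_results"]), nmention)
  ranked <- rank_topics(lda, art$title, art$abstract, sp)
  expect_equal(unname(m1[2, "topic1_words_caption"]),
               cosine(fig$caption, ranked$words[ranked$top[1]], sp),
               tolerance = 1e-9)
})
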