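test_that("LDA fitting is seeded-deterministic and normalized", {
  paras <- c("alpha beta alpha kinase", "beta kinase pathway alpha",
             "omega gamma omega signal", "gamma signal omega gamma")
  m1 <- fit_lda(paras, k = 2, seed = 3, iterations = 80)
  m2 <- fit_lda(paras, k = 2, seed = 3, iterations = 80)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$phi, m2$phi)
  expect_equal(rowSums(m1$theta), rep(1, 4), tolerance = 1e-8)
  expect_equal(unname(rowSums(m1$phi)), rep(1, 2), tolerance = 1e-8)
  expect_true(all(m1$theta >= 0) && all(m1$phi >= 0))
})

test_that("k = 1 gives a degenerate single-topic model", {
  m <- fit_lda(c("alpha beta", "beta gamma"), k = 1, seed = 1,
               iterations = 10)
  expect_equal(as.numeric(m$theta), c(1, 1))
})

test_that("k above the paragraph count is clamped with a warning", {
  expect_warning(m <- fit_lda(c("alpha beta", "gamma delta"), k = 5,
                              seed = 1, iterations = 10), "clamp")
  expect_identical(m$k, 2L)
})

test_that("disjoint vocabulary groups separate into distinct topics", {
  g1 <- replicate(4, paste(sample(c("kinase", "phospho", "signal", "growth"),
                                  8, replace = TRUE), collapse = " "))
  g2 <- replicate(4, paste(sample(c("membrane", "lipid", "vesicle", "fusion"),
                                  8, replace = TRUE), collapse = " "))
  m <- fit_lda(c(g1, g2), k = 2, seed = 7, iterations = 150)
  a1 <- m$assignments[1:4]
  a2 <- m$assignments[5:8]
  expect_identical(length(unique(a1)), 1L)
  expect_identical(length(unique(a2)), 1L)
  expect_false(unique(a1) == unique(a2))
})

test_that("topic ranking prefers abstract-like topics and pads below k=4", {
  paras <- c("kinase signal growth kinase signal", "kinase growth signal",
             "membrane lipid vesicle fusion", "lipid vesicle membrane")
  sp <- build_vector_space(paras, stopwords = FALSE)
  m <- fit_lda(paras, k = 2, seed = 7, iterations = 150)
  ranked <- rank_topics(m, "kinase signal", "growth kinase", sp)
  expect_length(ranked$top, 2L)
  first_words <- ranked$words[ranked$top[1]]
  expect_match(first_words, "kinase")
  art <- new_article("t1", title = "kinase signal",
                     abstract = "growth kinase",
    sections = list(list(heading = "Results", paragraphs = paras)),
    figures = list(list(label = "1", caption = "kinase signal growth")))
  art <- attach_contexts(art)
  f <- topic_features(art, art$figures[[1]], ranked, sp)
  expect_length(f, 26L)
  # slots 3 and 4 are padded with zeros when k = 2
  expect_true(all(f[grepl("^topic[34]_", names(f))] == 0))
  expect_true(all(f[grepl("^topic[12]_", names(f))] >= 0))
  expect_true(all(f[!grepl("cum2", names(f))] <= 1))
  expect_true(all(f[grepl("cum2", names(f))] <= 2))
})

test_that("empty context zeroes the context-based topic features", {
  paras <- c("alpha beta gamma", "beta gamma alpha")
  sp <- build_vector_space(paras, stopwords = FALSE)
  m <- fit_lda(paras, k = 2, seed = 2, iterations = 50)
  ranked <- rank_topics(m, "alpha", "beta", sp)
  art <- new_article("t2", sections = list(),
                     figures = list(list(label = "1", caption = "alpha")))
  art$figures[[1]]$associated_context <- ""
  f <- topic_features(art, art$figures[[1]], ranked, sp)
  expect_true(all(f[grepl("_context$", names(f)) &
                      !grepl("cum2", names(f))] == 0))
  expect_true(all(f[grepl("cum2", names(f))] == 0))
})

test_that("topic model dump writes inspectable JSON", {
  m <- fit_lda(c("alpha beta alpha", "gamma delta gamma"), k = 2, seed = 1,
               iterations = 30)
  p <- tempfile(fileext = ".json")
  write_topic_model(m, p)
  dumped <- jsonlite::read_json(p)
  expect_identical(dumped$k, 2L)
  expect_length(dumped$topics, 2L)
})
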