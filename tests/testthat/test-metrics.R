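test_that("all metrics are perfect on the identity ranking", {
  set.seed(13)
  for (m in 1:7) {
    for (rep in 1:4) {
      r <- random_ref(m)
      s <- ranks_from_scores(-r)   # a system ranking matching the reference
      expect_equal(wer_rk_score(s, r), 1)
      expect_equal(ndcg(s, r), 1)
      expect_equal(wer_fr_score(s, r), 1)
    }
  }
})

test_that("weighted pair error hits its two-figure anchors", {
  expect_equal(wer_rk_score(c(2, 1), c(1, 2)), 0)   # swapped pair
  expect_equal(wer_rk_score(c(1, 2), c(1, 2)), 1)
  # reference-tied pairs are never error pairs
  expect_equal(wer_rk(c(2, 1), c(1, 1)), 0)
  expect_equal(wer_rk(c(1, 2, 3), c(1, 1, 1)), 0)
  # m < 2 is zero error by definition
  expect_equal(wer_rk(1L, 1L), 0)
})

test_that("weighted pair error weights important pairs more", {
  r <- c(1L, 2L, 3L)
  # swapping the (1,2) pair costs more than swapping the (2,3) pair
  e_top <- wer_rk(c(2, 1, 3), r)
  e_bottom <- wer_rk(c(1, 3, 2), r)
  expect_gt(e_top, e_bottom)
  # hand evaluation: weights 1/r_j + 1/r_k
  w12 <- 1 + 1 / 2; w13 <- 1 + 1 / 3; w23 <- 1 / 2 + 1 / 3
  expect_equal(e_top, w12 / (w12 + w13 + w23))
})

test_that("wer_rk is invariant under figure relabeling", {
  set.seed(41)
  for (rep in 1:10) {
    m <- sample(3:6, 1)
    r <- random_ref(m)
    s <- sample.int(m)
    perm <- sample.int(m)
    expect_equal(wer_rk(s[perm], r[perm]), wer_rk(s, r))
  }
})

test_that("NDCG matches a hand evaluation on the reversed strict ranking", {
  # m = 3, reference 1,2,3, system fully reversed
  dcg <- 2^-2 / log2(2) + 2^-1 / log2(3) + 2^0 / log2(4)
  ideal <- 2^0 / log2(2) + 2^-1 / log2(3) + 2^-2 / log2(4)
  expect_equal(ndcg(c(3, 2, 1), c(1L, 2L, 3L)), dcg / ideal,
               tolerance = 1e-12)
  expect_equal(ndcg(1L, 1L), 1)
})

test_that("first-rank error tracks the top figure's displacement", {
  expect_equal(wer_fr_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wer_fr_score(c(2, 1), c(1, 2)), 0)  # human-top placed last
  # mean over both orders at m = 2 is 0.5 by enumeration
  expect_equal(mean(c(wer_fr_score(c(1, 2), c(1, 2)),
                      wer_fr_score(c(2, 1), c(1, 2)))), 0.5)
  # tied top group: hitting any member of the group scores perfectly
  expect_equal(wer_fr_score(c(3, 1, 2), c(1, 1, 2)), 1)
})

test_that("metric values stay in [0,1] over exhaustive enumeration", {
  set.seed(99)
  for (m in 2:5) {
    pm <- permutations(m)
    for (rep in 1:3) {
      r <- random_ref(m)
      for (i in seq_len(nrow(pm))) {
        s <- pm[i, ]
        for (v in c(wer_rk(s, r), ndcg(s, r), wer_fr(s, r))) {
          expect_gte(v, 0)
          expect_lte(v, 1)
        }
      }
    }
  }
})

test_that("tie pair percentage counts equally-ranked pairs", {
  expect_equal(tie_pair_percentage(c(2, 1, 2)), 1 / 3)
  expect_equal(tie_pair_percentage(c(1, 1, 1)), 1)
  expect_equal(tie_pair_percentage(c(1, 2, 3)), 0)
  expect_equal(tie_pair_percentage(1L), 0)
})

test_that("sampled random expectation converges to the exact one", {
  r <- c(1L, 2L, 3L, 4L)
  exact <- random_expectation(wer_rk_score, r, "exact")
  big <- random_expectation(wer_rk_score, r, "sampled", repeats = 4000,
                            seed = 2)
  # ~WER-RK per trial is bounded in [0,1]; 3 standard errors of the mean
  expect_lt(abs(big - exact), 3 * 0.5 / sqrt(4000))
  expect_error(random_expectation(ndcg, rep(1L, 10), "exact"), "sampled")
})

test_that("evaluation reports aggregate with population sd", {
  preds <- list(a = c(1L, 2L, 3L), b = c(2L, 1L))
  gold <- list(a = c(1L, 2L, 3L), b = c(1L, 2L))
  rep_ <- evaluate_rankings(preds, gold)
  per <- rep_$per_article
  expect_equal(per$wer_rk, c(1, 0))
  s <- rep_$summary
  expect_equal(s$mean[s$metric == "wer_rk"], 0.5)
  expect_equal(s$sd[s$metric == "wer_rk"], 0.5)   # population sd of (1, 0)
  perfect <- evaluate_rankings(list(a = c(1L, 2L)), list(a = c(1L, 2L)))
  expect_equal(perfect$summary$mean, c(1, 1, 1))
  expect_equal(perfect$summary$sd, c(0, 0, 0))
  expect_error(evaluate_rankings(preds, gold["a"]), "differ")
  grouped <- evaluate_rankings(preds, gold, by_figure_count = TRUE)
  expect_identical(grouped$by_count$m, c(2L, 3L))
})

test_that("report files round-trip the per-article table", {
  preds <- list(a = c(1L, 3L, 2L), b = c(2L, 1L))
  gold <- list(a = c(1L, 2L, 3L), b = c(1L, 2L))
  p <- tempfile(fileext = ".tsv")
  write_report(evaluate_rankings(preds, gold), p)
  tab <- utils::read.delim(p)
  expect_identical(nrow(tab), 4L)   # 2 articles + MEAN + SD rows
  expect_identical(tab$article_id, c("a", "b", "MEAN", "SD"))
})
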