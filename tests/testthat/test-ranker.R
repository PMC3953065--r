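test_that("top-1 distribution has its closed forms and invariances", {
  expect_equal(top1_distribution(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(top1_distribution(c(log(2), 0)), c(2 / 3, 1 / 3))
  z <- rnorm(5)
  expect_equal(top1_distribution(z), top1_distribution(z + 17.3))
  expect_equal(sum(top1_distribution(z)), 1)
  p_extreme <- top1_distribution(c(1000, -1000, 0))   # overflow-safe
  expect_true(all(is.finite(p_extreme)))
  expect_equal(sum(p_extreme), 1)
})

test_that("top-2 distribution equals the permutation-enumeration oracle", {
  set.seed(101)
  P <- top2_distribution(c(0, 0, 0))
  expect_equal(as.numeric(P[!is.na(P)]), rep(1 / 6, 6))
  expect_equal(top2_distribution(log(c(2, 1, 1)))[1, 2], 0.25)
  for (n in 2:6) {
    for (rep in 1:3) {
      z <- rnorm(n, sd = 1.5)
      P <- top2_distribution(z)
      expect_equal(sum(P, na.rm = TRUE), 1, tolerance = 1e-12)
      expect_equal(P, brute_top2(z), tolerance = 1e-10)
      # first-element marginal equals the top-1 distribution
      expect_equal(rowSums(P, na.rm = TRUE), top1_distribution(z),
                   tolerance = 1e-10)
      expect_equal(top2_distribution(z + 3.7), P, tolerance = 1e-12)
    }
  }
  expect_error(top2_distribution(1.0), "top-1")
})

test_that("losses satisfy the Gibbs equality and inequality", {
  entropy <- function(p) -sum(p * log(p))
  y <- c(2, 0.5, 1)
  expect_equal(loss_top1(y, y), entropy(top1_distribution(y)))
  expect_equal(loss_top1(c(100, 0), c(0, 0)), log(2), tolerance = 1e-10)
  expect_equal(loss_top2(c(0, 0, 0), c(0, 0, 0)), log(6))
  P2 <- top2_distribution(y)
  expect_equal(loss_top2(y, y), -sum(P2 * log(P2), na.rm = TRUE))
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    y <- rnorm(n); z <- rnorm(n)
    expect_gte(loss_top1(y, z), loss_top1(y, y) - 1e-12)
    expect_gte(loss_top2(y, z), loss_top2(y, y) - 1e-12)
    # brute-force cross entropy of the pair distributions
    py <- top2_distribution(y); pz <- top2_distribution(z)
    expect_equal(loss_top2(y, z), -sum(py * log(pz), na.rm = TRUE),
                 tolerance = 1e-10)
  }
  expect_error(loss_top1(c(1, 2), c(1, 2, 3)), "length")
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:6, 1); d <- sample(1:10, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n); w <- rnorm(d)
    for (loss in c("top1", "top2")) {
      g <- loss_gradient(x, y, w, loss)
      gn <- numeric_gradient(x, y, w, loss)
      expect_lt(max(abs(g - gn) / pmax(abs(gn), 1e-6)), 1e-5)
    }
  }
})

test_that("gradient vanishes at the optimum and respects symmetry", {
  set.seed(5)
  x <- matrix(rnorm(8), 4, 2)
  w <- c(0.3, -0.8)
  y <- as.numeric(x %*% w)            # P_z == P_y at w
  for (loss in c("top1", "top2")) {
    expect_lt(sqrt(sum(loss_gradient(x, y, w, loss)^2)), 1e-8)
  }
  # duplicated figure: symmetric contributions
  xd <- rbind(c(1, 2), c(1, 2), c(0, -1))
  yd <- c(0.5, 0.5, 0.1)
  g <- loss_gradient(xd, yd, c(0.2, 0.1), "top2")
  gswap <- loss_gradient(xd[c(2, 1, 3), ], yd, c(0.2, 0.1), "top2")
  expect_equal(g, gswap, tolerance = 1e-12)
})

test_that("score, gold-score and rank conversions behave", {
  expect_equal(score_figures(rep(0, 4), rnorm(4)), 0)
  w <- c(0, 1, 0)
  expect_equal(score_figures(w, c(5, 7, 9)), 7)
  set.seed(2)
  x <- rnorm(6); wv <- rnorm(6)
  expect_equal(score_figures(wv, x), sum(wv * x))
  expect_error(score_figures(c(1, 2), c(1, 2, 3)), "dimension")

  expect_equal(gold_scores(c(1, 2, 3)), c(1, 1 / 2, 1 / 3))
  expect_equal(gold_scores(c(1, 1)), c(1, 1))
  expect_equal(gold_scores(c(2, 1, 2)), c(0.5, 1, 0.5))

  expect_identical(ranks_from_scores(c(0.9, 0.1, 0.5)), c(1L, 3L, 2L))
  expect_identical(ranks_from_scores(rep(0, 4)), 1:4)  # position tie-break
  for (i in 1:10) {
    r <- ranks_from_scores(rnorm(7))
    expect_setequal(r, 1:7)
  }
})
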