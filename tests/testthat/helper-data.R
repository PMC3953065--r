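# Shared fixture builders.  Everything is constructed in code; the only
# on-disk fixtures are the tiny reader examples under inst/extdata.

extdata <- function(f) system.file("extdata", f, package = "figrank")

# A deterministic three-figure article with known mention structure.
tiny_article <- function() {
  read_article_json(extdata("example-article.json"))
}

# A vector space over a handful of hand-chosen documents.
tiny_space <- function() {
  build_vector_space(c("alpha beta beta", "alpha gamma", "delta delta"),
                     stopwords = FALSE)
}

# Small planted-model dataset for trainer tests.
tiny_dataset <- function(n_articles = 30L, seed = 11L, ...) {
  generate_ranking_dataset(n_articles = n_articles, n_features = 5L,
                           figure_counts = 2:5, seed = seed, ...)
}

# Plackett-Luce probability of one full permutation given scores z.
pl_perm_prob <- function(z, perm) {
  s <- exp(z - max(z))
  rem <- sum(s)
  p <- 1
  for (i in perm) {
    p <- p * s[i] / rem
    rem <- rem - s[i]
  }
  p
}

# Brute-force top-2 pair distribution by enumerating all n! permutations.
brute_top2 <- function(z) {
  n <- length(z)
  pm <- permutations(n)
  out <- matrix(0, n, n)
  for (r in seq_len(nrow(pm))) {
    out[pm[r, 1], pm[r, 2]] <- out[pm[r, 1], pm[r, 2]] +
      pl_perm_prob(z, pm[r, ])
  }
  diag(out) <- NA_real_
  out
}

# Central finite-difference gradient of a listwise loss w.r.t. w.
numeric_gradient <- function(x, y, w, loss, h = 1e-6) {
  f <- if (loss == "top1") loss_top1 else loss_top2
  vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- w[i] + h
    wm[i] <- w[i] - h
    (f(y, as.numeric(x %*% wp)) - f(y, as.numeric(x %*% wm))) / (2 * h)
  }, 0)
}

# Random dense reference ranks with ties for property tests.
random_ref <- function(m) {
  dense_ranks(sample.int(max(1L, m - sample(0:(m - 1L), 1L)), m,
                         replace = TRUE))
}
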