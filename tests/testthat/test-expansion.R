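test_that("nearest neighbours follow cosine geometry on a toy 2-d model", {
  vec <- rbind(a = c(1, 0), b = c(0.99, 0.1), c = c(0, 1))
  model <- embedding_model(vec)
  nn <- nearest_neighbors(model, "a", 1)
  expect_equal(nn$word, "b")
  expect_equal(nn$similarity, 0.99 / sqrt(0.99^2 + 0.1^2), tolerance = 1e-12)

  # out-of-vocabulary query gives an empty result with a notice
  expect_message(oov <- nearest_neighbors(model, "zzz", 3), "not in")
  expect_equal(nrow(oov), 0)

  # k >= |vocabulary| - 1 returns all other words, fully ranked
  nn_all <- nearest_neighbors(model, "a", 10)
  expect_equal(nn_all$word, c("b", "c"))
  expect_true(all(diff(nn_all$similarity) <= 0))

  # similarity is symmetric and 1 on the diagonal
  expect_equal(embedding_similarity(model, "a", "b"),
               embedding_similarity(model, "b", "a"))
  expect_equal(embedding_similarity(model, "a", "a"), 1)
})

test_that("nearest neighbours agree with an exhaustive cosine oracle", {
  set.seed(55)
  for (trial in 1:3) {
    n <- sample(20:60, 1); d <- sample(3:8, 1)
    words <- paste0("w", sample(1000:9999, n))
    vec <- matrix(stats::rnorm(n * d), n, d, dimnames = list(words, NULL))
    model <- embedding_model(vec)
    for (w in sample(words, 5)) {
      k <- sample(1:6, 1)
      got <- nearest_neighbors(model, w, k)
      # oracle: plain cosine against every other word, ranked
      cosine <- vapply(words, function(v)
        sum(vec[w, ] * vec[v, ]) /
          sqrt(sum(vec[w, ]^2) * sum(vec[v, ]^2)), numeric(1))
      cosine <- cosine[names(cosine) != w]
      want <- names(cosine)[order(-cosine, names(cosine), method = "radix")]
      expect_equal(got$word, utils::head(want, k))
      expect_equal(got$similarity,
                   unname(cosine[got$word]), tolerance = 1e-12)
    }
  }
})

test_that("word2vec text files round-trip", {
  lex <- make_lexicon(n = 8, seed = 3)
  emb <- make_embeddings(lex, synonyms_per_word = 1, n_distractors = 5,
                         dim = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb$model, path)
  first <- readLines(path, n = 1, encoding = "UTF-8")
  expect_equal(first, paste(nrow(emb$model$vectors), 4))
  back <- read_embeddings(path)
  expect_equal(rownames(back$vectors), rownames(emb$model$vectors))
  expect_equal(back$vectors, emb$model$vectors, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("proposed expansions inherit seed category/weight and are deduplicated", {
  lex <- tiny_lexicon(c("s1", "s2"),
                      categories = c("psychache", "stress"),
                      weights = c(2, 3))
  # planted geometry: c1 close to s1; shared close to both, closer to s2
  vec <- rbind(s1 = c(1, 0, 0), c1 = c(0.98, 0.2, 0),
               s2 = c(0, 1, 0), c2 = c(0.1, 0.97, 0),
               shared = c(0.5, 0.85, 0), far = c(0, 0, 1))
  model <- embedding_model(vec)
  cand <- propose_expansions(lex, model, k = 2)
  expect_s3_class(cand, "expansion_candidates")
  # no candidate is a lexicon word; no duplicate candidates
  expect_false(any(cand$candidate_word %in% lex$entries$word))
  expect_false(any(duplicated(cand$candidate_word)))
  # inheritance from the proposing seed
  expect_equal(cand$category[cand$candidate_word == "c1"], "psychache")
  expect_equal(cand$weight[cand$candidate_word == "c1"], 2)
  # the shared candidate is kept once, under its most similar seed (s2)
  expect_equal(cand$seed_word[cand$candidate_word == "shared"], "s2")
  expect_equal(cand$category[cand$candidate_word == "shared"], "stress")
  # default neighbourhood size is 4
  expect_equal(formals(propose_expansions)$k, 4)

  # corpus-frequency filtering drops rare candidates
  cf <- c(c1 = 100L, c2 = 1L, shared = 100L, far = 100L)
  cand2 <- propose_expansions(lex, model, k = 2, min_corpus_freq = 5,
                              corpus_freq = cf)
  expect_false("c2" %in% cand2$candidate_word)

  # a lexicon word absent from the vocabulary contributes nothing
  lex3 <- tiny_lexicon(c("s1", "missing"))
  cand3 <- propose_expansions(lex3, model, k = 1)
  expect_true(all(cand3$seed_word == "s1"))
})

test_that("planted synonyms are recovered end-to-end", {
  lex <- make_lexicon(n = 12, seed = 6)
  emb <- make_embeddings(lex, synonyms_per_word = 3, n_distractors = 60,
                         dim = 25, seed = 6)
  cand <- propose_expansions(lex, emb$model, k = 3)
  got <- paste(cand$seed_word, cand$candidate_word)
  want <- paste(emb$synonyms$seed_word, emb$synonyms$synonym)
  expect_setequal(got, want)
  # inherited fields match the seed entries
  j <- match(cand$seed_word, lex$entries$word)
  expect_equal(cand$category, lex$entries$category[j])
  expect_equal(cand$weight, lex$entries$weight[j])
})

test_that("review votes reject on quorum and apply agreed overrides", {
  cand <- data.frame(
    seed_word = "s", candidate_word = c("k1", "k2", "k3", "k4"),
    similarity = c(0.9, 0.8, 0.7, 0.6),
    category = "psychache", weight = 3L, status = "proposed",
    stringsAsFactors = FALSE)
  votes <- data.frame(
    word = c("k1", "k1", "k2", "k2", "k3", "k3"),
    coder_id = c("c1", "c2", "c1", "c2", "c1", "c2"),
    decision = c("eliminate", "eliminate", "keep", "keep", "keep", "keep"),
    proposed_category = c(NA, NA, NA, NA, "stress", "hopeless"),
    proposed_weight = c(NA, NA, 2L, 2L, NA, NA),
    stringsAsFactors = FALSE)
  expect_message(acc <- apply_review(cand, votes, quorum = 2), "conflicting")
  # k1 rejected by 2 eliminate votes
  expect_false("k1" %in% acc$word)
  # k2 accepted with the agreed weight override 3 -> 2
  expect_equal(acc$weight[acc$word == "k2"], 2)
  # k3: conflicting category proposals without quorum keep inherited values
  expect_equal(acc$category[acc$word == "k3"], "psychache")
  # k4: no votes, accepted unchanged
  expect_equal(acc$weight[acc$word == "k4"], 3)
  expect_true(all(acc$source == "expanded"))
  # accepted entries merge into a seed lexicon
  merged <- merge(tiny_lexicon("s"), acc)
  expect_equal(length(merged), 1 + nrow(acc))
})
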