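test_that("synthetic lexicons honour requested shape and are seed-deterministic", {
  lex <- make_lexicon(seed = 5)
  s <- summary(lex)
  expect_equal(s$total, 2168)
  expect_equal(unname(s$category_counts), unname(reference_category_counts()))
  expect_false(any(duplicated(lex$entries$word)))

  # rescaling to the seed size reproduces the seed weight classes exactly
  seed_lex <- make_lexicon(n = 1862, seed = 5)
  expect_equal(unname(summary(seed_lex)$weight_counts), c(990, 505, 367))

  expect_identical(make_lexicon(n = 40, seed = 8), make_lexicon(n = 40, seed = 8))
  expect_false(identical(make_lexicon(n = 40, seed = 8)$entries$word,
                         make_lexicon(n = 40, seed = 9)$entries$word))

  # all-zero category counts give an empty lexicon
  empty <- make_lexicon(category_counts = stats::setNames(
    rep(0L, 13), lexicon_categories()))
  expect_equal(length(empty), 0)

  # ascii vocabulary style for readable fixtures
  a <- make_lexicon(n = 10, vocabulary_style = "ascii", seed = 2)
  expect_true(all(grepl("^[a-z]+$", a$entries$word)))
})

test_that("largest-remainder apportionment is exact and total-preserving", {
  expect_equal(sum(apportion_counts(c(3, 3, 3), 10)), 10)
  expect_equal(apportion_counts(c(990, 505, 367), 1862),
               stats::setNames(c(990L, 505L, 367L), NULL),
               ignore_attr = TRUE)
  expect_equal(sum(apportion_counts(reference_category_counts(), 306)), 306)
})

test_that("corpus emission probabilities are recovered by the matcher", {
  lex <- make_lexicon(n = 60, seed = 10)
  m <- build_matcher(lex)

  # p = 0 in both groups: no lexicon matches anywhere (this also verifies
  # that filler tokens never collide with lexicon words)
  sim0 <- make_corpus(lex, corpus_spec(n_users_high = 2, n_users_non_high = 2,
                                       posts_per_user = 10,
                                       p_risk_word_high = 0,
                                       p_risk_word_low = 0, seed = 10))
  sc0 <- score_posts(m, sim0$posts)
  expect_true(all(sc0$n_matches == 0))

  # p = 1 with a weight-3-only lexicon: every post is risky
  heavy <- make_lexicon(n = 20, weight_mix = c(0, 0, 1), seed = 11)
  mh <- build_matcher(heavy)
  sim1 <- make_corpus(heavy, corpus_spec(n_users_high = 2, n_users_non_high = 2,
                                         posts_per_user = 10,
                                         p_risk_word_high = 1,
                                         p_risk_word_low = 1, seed = 11))
  expect_true(all(score_posts(mh, sim1$posts)$is_risky))

  # binomial sampling check: per-token match rate within 3 Monte-Carlo
  # standard errors of the planted probability, per group, n >= 10,000
  spec <- corpus_spec(n_users_high = 12, n_users_non_high = 12,
                      posts_per_user = 40, seed = 12)
  sim <- make_corpus(lex, spec)
  sc <- score_posts(m, sim$posts)
  grp <- sim$ground_truth$group[match(sc$user_id, sim$ground_truth$user_id)]
  for (g in c("high", "non_high")) {
    n_tok <- sum(sim$posts$n_tokens[grp == g])
    p <- if (g == "high") spec$p_risk_word_high else spec$p_risk_word_low
    expect_gte(n_tok, 10000)
    rate <- sum(sc$n_matches[grp == g]) / n_tok
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n_tok))
  }

  # determinism and ground-truth alignment
  sim_b <- make_corpus(lex, spec)
  expect_identical(sim$posts, sim_b$posts)
  expect_equal(sort(unique(sim$posts$user_id)), sort(sim$ground_truth$user_id))
  # timestamps fall in (anchor - span, anchor]
  win <- select_window(sim$posts, spec$anchor, spec$time_span)
  expect_equal(nrow(win), nrow(sim$posts))
})

test_that("synthetic SPS responses decompose exactly and hit the pooled mean", {
  gt <- data.frame(user_id = sprintf("u%03d", 1:10),
                   group = rep(c("high", "non_high"), each = 5),
                   stringsAsFactors = FALSE)
  # sd = 0 with explicit group means: totals exactly 100 and 60
  sps0 <- make_sps(gt, mean_high = 100, mean_low = 60, sd = 0, seed = 1)
  expect_equal(sps0$total, rep(c(100L, 60L), each = 5))
  # items reconstruct the total and stay in range
  items <- as.matrix(sps0[sprintf("item_%02d", 1:36)])
  expect_true(all(items >= 1 & items <= 4))
  expect_equal(unname(rowSums(items)), as.numeric(sps0$total))

  # defaults: pooled sample mean within 3 SE of 69.35 at n = 788
  gt_big <- data.frame(user_id = sprintf("u%03d", 1:788),
                       group = rep(c("high", "non_high"), c(126, 662)),
                       stringsAsFactors = FALSE)
  sps <- make_sps(gt_big, seed = 2)
  se <- stats::sd(sps$total) / sqrt(788)
  expect_lt(abs(mean(sps$total) - 69.35), 3 * se)
  expect_true(all(sps$total >= 36 & sps$total <= 144))
  # high group scores higher on average (planted correlation with group)
  expect_gt(mean(sps$total[gt_big$group == "high"]),
            mean(sps$total[gt_big$group == "non_high"]))

  expect_identical(make_sps(gt, seed = 3), make_sps(gt, seed = 3))
})

test_that("expert ratings are a monotone map of content, degrading with noise", {
  # fabricated scored posts with known category content
  set.seed(20)
  n <- 1000
  cats <- lexicon_categories()
  counts <- matrix(stats::rpois(n * 13, 0.4), n, 13,
                   dimnames = list(NULL, paste0("n_", cats)))
  scores <- cbind(
    data.frame(user_id = rep(sprintf("u%02d", 1:20), each = n / 20),
               timestamp = NA_character_,
               n_matches = rowSums(counts),
               total_score = rowSums(counts),
               is_risky = rowSums(counts) >= 3, stringsAsFactors = FALSE),
    as.data.frame(counts))

  # noiseless limit: ratings are deterministic and linear in content
  r0 <- make_expert_ratings(scores, expert_rating_spec(noise_sd = 0), seed = 1)
  expect_equal(pearson(r0$post_ratings$overall, rowSums(counts)), 1)
  expect_true(all(r0$post_ratings$overall >= 1 & r0$post_ratings$overall <= 7))
  # user-level ratings track the risky-post proportion exactly
  pr <- user_risk_levels(scores)
  expect_equal(pearson(r0$user_ratings$rating, pr$risk_level), 1)

  # very large noise: correlation with content collapses
  r_big <- make_expert_ratings(scores, expert_rating_spec(noise_sd = 50),
                               seed = 2)
  expect_lt(abs(pearson(r_big$post_ratings$overall, rowSums(counts))), 0.15)

  # 3-point noise grid: correlation decreases as coder noise grows
  rs <- vapply(c(0.2, 1.5, 6), function(ns) {
    r <- make_expert_ratings(scores, expert_rating_spec(noise_sd = ns),
                             seed = 3)
    pearson(r$post_ratings$overall, rowSums(counts))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))

  expect_identical(make_expert_ratings(scores, seed = 4),
                   make_expert_ratings(scores, seed = 4))
})

test_that("toy embeddings verifiably plant synonyms next to their seeds", {
  lex <- make_lexicon(n = 10, seed = 14)
  emb <- make_embeddings(lex, synonyms_per_word = 2, n_distractors = 40,
                         dim = 20, seed = 14)
  v <- emb$model$normalized
  for (w in lex$entries$word) {
    syn <- emb$synonyms$synonym[emb$synonyms$seed_word == w]
    other <- setdiff(rownames(v), c(w, syn))
    expect_gt(min(v[syn, , drop = FALSE] %*% v[w, ]),
              max(v[other, , drop = FALSE] %*% v[w, ]))
  }
  expect_identical(make_embeddings(lex, 2, 40, dim = 20, seed = 14)$model$vectors,
                   emb$model$vectors)

  # with no synonyms and no distractors the vocabulary is the lexicon itself
  bare <- make_embeddings(lex, synonyms_per_word = 0, n_distractors = 0,
                          dim = 5, seed = 15)
  nn <- nearest_neighbors(bare$model, lex$entries$word[1], 100)
  expect_setequal(nn$word, setdiff(lex$entries$word, lex$entries$word[1]))
})
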