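# Shared fixtures and independent brute-force oracles.

# small hand-built lexicon; ASCII by default so expectations are readable
tiny_lexicon <- function(words,
                         categories = rep("psychache", length(words)),
                         weights = rep(1, length(words)),
                         source = "seed") {
  suicide_lexicon(data.frame(word = words, category = categories,
                             weight = weights, source = source,
                             stringsAsFactors = FALSE))
}

# random lexicon over a small alphabet so matches are dense
random_small_lexicon <- function(n_words = 10, alphabet = c("a", "b", "c"),
                                 max_len = 3, seed = 1) {
  set.seed(seed)
  words <- character(0)
  while (length(words) < n_words) {
    len <- sample(seq_len(max_len), 1)
    w <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    words <- unique(c(words, w))
  }
  tiny_lexicon(words,
               categories = sample(lexicon_categories(), n_words,
                                   replace = TRUE),
               weights = sample(1:3, n_words, replace = TRUE))
}

# brute-force oracle: every substring of `text` equal to a lexicon word,
# by direct substring comparison (independent of the matcher's index scan)
oracle_all_occurrences <- function(lexicon, text) {
  e <- lexicon$entries
  ltext <- tolower(text)
  n <- nchar(ltext, type = "chars")
  hits <- list()
  for (i in seq_len(nrow(e))) {
    w <- tolower(e$word[i])
    len <- nchar(w, type = "chars")
    if (len > n) next
    starts <- seq_len(n - len + 1)
    ok <- substring(ltext, starts, starts + len - 1) == w
    if (any(ok))
      hits[[length(hits) + 1]] <- data.frame(
        word = e$word[i], category = e$category[i], weight = e$weight[i],
        start = starts[ok] - 1L, end = starts[ok] - 1L + len,
        stringsAsFactors = FALSE)
  }
  out <- if (length(hits) == 0)
    data.frame(word = character(0), category = character(0),
               weight = integer(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, hits)
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force oracle for the leftmost-longest rule, replayed from the
# all-occurrences oracle output
oracle_leftmost_longest <- function(lexicon, text) {
  all <- oracle_all_occurrences(lexicon, text)
  keep <- logical(nrow(all))
  pos <- 0L
  i <- 1L
  while (i <= nrow(all)) {
    if (all$start[i] >= pos) {
      # candidates at the leftmost available start; longest wins
      at <- which(all$start == all$start[i] & all$start >= pos)
      best <- at[which.max(all$end[at] - all$start[at])]
      keep[best] <- TRUE
      pos <- all$end[best]
    }
    i <- i + 1L
  }
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_same_occurrences <- function(got, want) {
  expect_equal(got[c("word", "start", "end")], want[c("word", "start", "end")])
}

# posts data frame shorthand
make_posts <- function(texts, user_id = "u1", timestamp = "2014-07-01") {
  data.frame(user_id = user_id, timestamp = timestamp, text = texts,
             stringsAsFactors = FALSE)
}
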