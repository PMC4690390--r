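#' Build a dictionary matcher over raw (unsegmented) text
#'
#' Indexes the lexicon words for repeated scanning of post text. No word
#' segmentation is performed: the scan works directly on the character
#' sequence, which is the natural choice for Chinese microblog text where
#' lexicon entries are multi-character words. Matching is exact for CJK
#' characters and case-insensitive for Latin letters; input text is assumed
#' to be NFC-normalised UTF-8.
#'
#' Two matching modes are supported:
#' \describe{
#'   \item{`leftmost_longest`}{scan left to right; at each position emit the
#'     longest lexicon word starting there and resume after its end.
#'     Occurrences never overlap and nested words (e.g. a single character
#'     inside a longer matched word) are not double counted. This is the
#'     default.}
#'   \item{`all_occurrences`}{emit every substring equal to a lexicon word,
#'     overlaps allowed (LIWC-style counting of every hit).}
#' }
#'
#' @param lexicon a non-empty [suicide_lexicon()].
#' @param mode matching mode, see Details.
#' @return An immutable object of class `suilex_matcher`. Results of
#'   [find_matches()] are a pure function of (lexicon, mode, text).
#' @export
build_matcher <- function(lexicon,
                          mode = c("leftmost_longest", "all_occurrences")) {
  stopifnot(inherits(lexicon, "suicide_lexicon"))
  mode <- match.arg(mode)
  e <- lexicon$entries
  if (nrow(e) == 0) stop("cannot build a matcher from an empty lexicon")
  key <- tolower(e$word)
  if (anyDuplicated(key))
    stop("lexicon words collide after Latin case folding: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  index <- new.env(parent = emptyenv(), size = nrow(e))
  for (i in seq_len(nrow(e))) assign(key[i], i, envir = index)
  lens <- sort(unique(nchar(e$word, type = "chars")), decreasing = TRUE)
  structure(list(index = index,
                 words = e$word, category = e$category, weight = e$weight,
                 lengths = lens, mode = mode),
            class = "suilex_matcher")
}

#' @export
print.suilex_matcher <- function(x, ...) {
  cat("<suilex_matcher>", length(x$words), "words, mode", x$mode,
      "- word lengths", paste(rev(x$lengths), collapse = ","), "\n")
  invisible(x)
}

#' Find lexicon-word occurrences in a text
#'
#' @param matcher a [build_matcher()] object.
#' @param text a UTF-8 string (may be empty).
#' @return Data frame of occurrences with columns `word` (the lexicon form),
#'   `category`, `weight`, `start` (0-based character offset) and `end`
#'   (exclusive character offset), sorted by `start` with ties broken by
#'   descending length. `end - start` equals the word length and the text
#'   slice `[start, end)` equals the matched word (up to Latin case).
#' @export
find_matches <- function(matcher, text) {
  stopifnot(inherits(matcher, "suilex_matcher"), is.character(text),
            length(text) == 1)
  empty <- data.frame(word = character(0), category = character(0),
                      weight = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  ltext <- tolower(enc2utf8(text))
  n <- nchar(ltext, type = "chars")
  lens <- matcher$lengths
  idx_hits <- integer(0)
  start_hits <- integer(0)
  i <- 1L
  if (matcher$mode == "leftmost_longest") {
    while (i <= n) {
      adv <- 1L
      for (len in lens) {
        if (i + len - 1L > n) next
        hit <- matcher$index[[substr(ltext, i, i + len - 1L)]]
        if (!is.null(hit)) {
          idx_hits <- c(idx_hits, hit)
          start_hits <- c(start_hits, i)
          adv <- len
          break
        }
      }
      i <- i + adv
    }
  } else {
    while (i <= n) {
      for (len in lens) {
        if (i + len - 1L > n) next
        hit <- matcher$index[[substr(ltext, i, i + len - 1L)]]
        if (!is.null(hit)) {
          idx_hits <- c(idx_hits, hit)
          start_hits <- c(start_hits, i)
        }
      }
      i <- i + 1L
    }
  }
  if (length(idx_hits) == 0) return(empty)
  wlen <- nchar(matcher$words[idx_hits], type = "chars")
  out <- data.frame(word = matcher$words[idx_hits],
                    category = matcher$category[idx_hits],
                    weight = matcher$weight[idx_hits],
                    start = start_hits - 1L,
                    end = start_hits - 1L + wlen,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, -wlen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one post from its lexicon-word occurrences
#'
#' The post risk score is the sum of the weights of all lexicon-word
#' occurrences in the post; a post whose score reaches `threshold` is
#' flagged as carrying suicide risk. The default threshold of 3 means a
#' single weight-3 ("heavy") word is enough to flag a post.
#'
#' @param occurrences occurrence data frame from [find_matches()].
#' @param threshold integer risk threshold (>= 1, default 3); a post is
#'   risky when `total_score >= threshold`.
#' @param unique_words if `TRUE`, each distinct word contributes its weight
#'   once regardless of how often it occurs (sensitivity-analysis mode);
#'   the default counts every occurrence.
#' @return Object of class `post_score`: list with `total_score`,
#'   `is_risky`, `n_matches`, and `category_counts` (named integer vector
#'   over the 13 categories, tallied per occurrence).
#' @export
score_post <- function(occurrences, threshold = 3, unique_words = FALSE) {
  if (threshold < 1) stop("threshold must be >= 1")
  occ <- occurrences
  scored <- if (unique_words) occ[!duplicated(occ$word), , drop = FALSE] else occ
  total <- as.integer(sum(scored$weight))
  structure(list(
    total_score = total,
    is_risky = total >= threshold,
    n_matches = nrow(occ),
    category_counts = c(table(factor(occ$category,
                                     levels = lexicon_categories())))
  ), class = "post_score")
}

#' @export
print.post_score <- function(x, ...) {
  cat("<post_score> total", x$total_score,
      if (x$is_risky) "(risky)" else "(not risky)",
      "-", x$n_matches, "occurrence(s)\n")
  invisible(x)
}

#' Match and score a collection of posts
#'
#' Convenience wrapper: runs [find_matches()] and [score_post()] over every
#' post and returns one row per post.
#'
#' @param matcher a [build_matcher()] object.
#' @param posts data frame with columns `user_id`, `timestamp`, `text`.
#' @param threshold risk threshold passed to [score_post()].
#' @param unique_words passed to [score_post()].
#' @return Data frame with columns `user_id`, `timestamp`, `n_matches`,
#'   `total_score`, `is_risky`, followed by one occurrence-count column per
#'   category (prefixed `n_`).
#' @export
score_posts <- function(matcher, posts, threshold = 3, unique_words = FALSE) {
  stopifnot(is.data.frame(posts),
            all(c("user_id", "timestamp", "text") %in% names(posts)))
  cats <- lexicon_categories()
  m <- nrow(posts)
  counts <- matrix(0L, nrow = m, ncol = length(cats),
                   dimnames = list(NULL, paste0("n_", cats)))
  total <- integer(m); nm <- integer(m)
  for (i in seq_len(m)) {
    occ <- find_matches(matcher, posts$text[i])
    sc <- score_post(occ, threshold = threshold, unique_words = unique_words)
    total[i] <- sc$total_score
    nm[i] <- sc$n_matches
    counts[i, ] <- sc$category_counts
  }
  cbind(data.frame(user_id = posts$user_id, timestamp = posts$timestamp,
                   n_matches = nm, total_score = total,
                   is_risky = total >= threshold,
                   stringsAsFactors = FALSE),
        as.data.frame(counts))
}
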