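#' Observation-window lengths in days
#'
#' Named window lengths used for windowed analyses: `1_week` = 7 days,
#' `1_month` = 30, `2_months` = 60, `3_months` = 90. Calendar phrases are
#' pinned to fixed day counts so results are reproducible.
#'
#' @param length a window name (one of the four above) or a positive number
#'   of days.
#' @return The window length in days (numeric).
#' @export
window_days <- function(length) {
  if (is.numeric(length)) {
    if (length <= 0) stop("window length must be > 0 days")
    return(as.numeric(length))
  }
  lens <- c("1_week" = 7, "1_month" = 30, "2_months" = 60, "3_months" = 90)
  if (!length %in% names(lens))
    stop("unknown window '", length, "'; use one of ",
         paste(names(lens), collapse = ", "), " or a day count")
  unname(lens[length])
}

parse_timestamps <- function(ts, id = NULL) {
  out <- tryCatch(
    as.POSIXct(ts, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), length(ts)))
  bad <- is.na(out) & !is.na(ts)
  if (any(bad)) {
    which_bad <- if (!is.null(id)) id[bad][1] else which(bad)[1]
    stop("unparseable timestamp (row ", which_bad, "): ", ts[bad][1])
  }
  out
}

#' Select posts inside an observation window
#'
#' Keeps posts whose timestamp lies in the half-open interval
#' `(anchor - length, anchor]`: a post exactly at the anchor is included, a
#' post exactly at `anchor - length` is excluded. Original post order is
#' preserved.
#'
#' @param posts data frame with columns `user_id`, `timestamp` (ISO-8601),
#'   `text`.
#' @param anchor anchor datetime (POSIXct or ISO-8601 string); the study
#'   start or questionnaire date.
#' @param length window length: a name accepted by [window_days()] or a day
#'   count. Use `Inf` to keep all posts up to the anchor.
#' @return The subset of `posts` inside the window.
#' @export
select_window <- function(posts, anchor, length = "1_month") {
  stopifnot(is.data.frame(posts), "timestamp" %in% names(posts))
  anchor <- parse_timestamps(as.character(anchor))
  ts <- parse_timestamps(posts$timestamp, id = posts$user_id)
  days <- window_days(length)
  keep <- if (is.infinite(days)) ts <= anchor
  else ts > (anchor - days * 86400) & ts <= anchor
  out <- posts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' User-level risk levels from scored posts
#'
#' A user's risk level is the proportion of their posts (within the window
#' that produced `scores`) flagged as risky. Users must have at least one
#' post; callers working from a user roster can pass `users` to have
#' post-less users reported as unprofiled.
#'
#' @param scores per-post score data frame from [score_posts()] (columns
#'   `user_id`, `is_risky`).
#' @param users optional character vector of expected user ids; ids with no
#'   posts are excluded from the result and listed in the `"unprofiled"`
#'   attribute (with a message).
#' @return Data frame with one row per user: `user_id`, `n_posts`,
#'   `n_risky`, `risk_level` (= `n_risky / n_posts`, in \[0, 1\]).
#' @export
user_risk_levels <- function(scores, users = NULL) {
  stopifnot(is.data.frame(scores),
            all(c("user_id", "is_risky") %in% names(scores)))
  if (nrow(scores) == 0 && is.null(users))
    stop("no scored posts: risk level is undefined without posts")
  n_posts <- tapply(scores$is_risky, scores$user_id, length)
  n_risky <- tapply(scores$is_risky, scores$user_id, sum)
  out <- data.frame(user_id = names(n_posts),
                    n_posts = as.integer(n_posts),
                    n_risky = as.integer(n_risky),
                    stringsAsFactors = FALSE)
  out$risk_level <- out$n_risky / out$n_posts
  rownames(out) <- NULL
  if (!is.null(users)) {
    unprofiled <- setdiff(users, out$user_id)
    if (length(unprofiled) > 0)
      message(length(unprofiled),
              " user(s) excluded: no posts in window (unprofiled)")
    out <- out[match(intersect(users, out$user_id), out$user_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "unprofiled") <- unprofiled
  }
  out
}

#' Aggregate per-category occurrence frequencies across posts
#'
#' @param scores per-post score data frame from [score_posts()] (the `n_*`
#'   category-count columns are summed).
#' @return List with `category_counts` (named integer vector over the 13
#'   categories) and `overall` (their sum, the overall dictionary-word
#'   frequency).
#' @export
category_frequencies <- function(scores) {
  cats <- lexicon_categories()
  cols <- paste0("n_", cats)
  stopifnot(is.data.frame(scores), all(cols %in% names(scores)))
  counts <- vapply(cols, function(cl) as.integer(sum(scores[[cl]])),
                   integer(1))
  names(counts) <- cats
  list(category_counts = counts, overall = sum(counts))
}

#' Character tokenizer (dependency-free fallback)
#'
#' Splits text into individual characters, dropping whitespace. Any
#' deterministic tokenizer can be injected into [extract_features()]; this
#' character fallback gives a reproducible denominator without a word
#' segmenter.
#'
#' @param text a UTF-8 string.
#' @return Character vector of tokens.
#' @export
tokenize_characters <- function(text) {
  toks <- strsplit(enc2utf8(text), "", fixed = FALSE)[[1]]
  toks[!grepl("^[[:space:]]$", toks)]
}

#' Whitespace tokenizer
#'
#' Splits text on runs of whitespace; suitable for corpora whose posts are
#' already space-delimited token sequences.
#'
#' @param text a UTF-8 string.
#' @return Character vector of tokens.
#' @export
tokenize_whitespace <- function(text) {
  toks <- strsplit(enc2utf8(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Extract per-user category-ratio feature vectors
#'
#' For each user, the feature vector X = (X1, ..., X13) holds, per lexicon
#' category, the number of matched occurrences across the user's posts
#' divided by the user's total token count (the tokenizer defines the
#' denominator). Vectors are invariant under duplicating a user's content
#' and under post reordering.
#'
#' @param posts data frame with columns `user_id`, `timestamp`, `text`
#'   (typically already windowed via [select_window()]).
#' @param matcher a [build_matcher()] object.
#' @param tokenizer function mapping one text to a character vector of
#'   tokens; default [tokenize_characters()].
#' @return Data frame with one row per user: `user_id`, `denominator`
#'   (total token count), then one ratio column per category. Users whose
#'   windowed posts contain zero tokens are excluded and listed in the
#'   `"excluded"` attribute (with a message).
#' @export
extract_features <- function(posts, matcher, tokenizer = tokenize_characters) {
  stopifnot(is.data.frame(posts),
            all(c("user_id", "text") %in% names(posts)))
  cats <- lexicon_categories()
  users <- unique(posts$user_id)
  feat <- matrix(NA_real_, nrow = length(users), ncol = length(cats),
                 dimnames = list(NULL, cats))
  denom <- integer(length(users))
  for (u in seq_along(users)) {
    texts <- posts$text[posts$user_id == users[u]]
    n_tok <- sum(vapply(texts, function(t) length(tokenizer(t)), integer(1)))
    denom[u] <- n_tok
    if (n_tok == 0) next
    counts <- stats::setNames(integer(length(cats)), cats)
    for (t in texts) {
      occ <- find_matches(matcher, t)
      if (nrow(occ) > 0) {
        tab <- table(factor(occ$category, levels = cats))
        counts <- counts + as.integer(tab)
      }
    }
    feat[u, ] <- counts / n_tok
  }
  keep <- denom > 0
  if (any(!keep))
    message(sum(!keep), " user(s) excluded from feature extraction: ",
            "zero tokens in window")
  out <- cbind(data.frame(user_id = users[keep], denominator = denom[keep],
                          stringsAsFactors = FALSE),
               as.data.frame(feat[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "excluded") <- users[!keep]
  out
}
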