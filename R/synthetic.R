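#' Apportion a total into integer counts proportional to weights
#'
#' Largest-remainder apportionment: counts are `floor(total * w / sum(w))`
#' plus one unit for the largest fractional remainders until the counts sum
#' to `total`. Exact inputs (weights already integer counts summing to
#' `total`) are returned unchanged.
#'
#' @param weights non-negative numeric weights.
#' @param total integer total to distribute.
#' @return Integer vector summing to `total`, same names as `weights`.
#' @export
apportion_counts <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# unique synthetic words: CJK code points (multi-byte, exercises UTF-8
# handling in the matcher) or ASCII fallback
generate_words <- function(n, style = c("cjk", "ascii"), exclude = character(0),
                           min_len = 2, max_len = 4) {
  style <- match.arg(style)
  seen <- new.env(parent = emptyenv())
  for (w in exclude) assign(w, TRUE, envir = seen)
  out <- character(n)
  got <- 0L
  while (got < n) {
    k <- max(2L * (n - got), 64L)
    lens <- sample(min_len:max_len, k, replace = TRUE)
    if (style == "cjk") {
      cps <- sample(0x4E00:0x9FA5, sum(lens), replace = TRUE)
    } else {
      cps <- sample(97:122, sum(lens), replace = TRUE)  # a-z
    }
    stops <- cumsum(lens)
    starts <- c(1L, utils::head(stops, -1) + 1L)
    for (i in seq_len(k)) {
      w <- intToUtf8(cps[starts[i]:stops[i]])
      if (is.null(seen[[w]])) {
        assign(w, TRUE, envir = seen)
        got <- got + 1L
        out[got] <- w
        if (got == n) break
      }
    }
  }
  out
}

#' Generate a synthetic weighted lexicon
#'
#' Builds a lexicon with a prescribed per-category shape and weight-class
#' mix. Defaults reproduce the reference dictionary's bookkeeping: the 13
#' published category counts (total 2,168) and the seed weight mix
#' 990/505/367. Words are synthetic unique strings (CJK code points by
#' default so the matcher is exercised on multi-byte text).
#'
#' @param n optional total size; when given, `category_counts` is rescaled
#'   to sum to `n` by largest-remainder apportionment.
#' @param category_counts named integer vector over [lexicon_categories()];
#'   default [reference_category_counts()].
#' @param weight_mix relative sizes of the weight classes 1/2/3; default
#'   [reference_weight_counts()] (exact counts when they already sum to the
#'   lexicon size, proportions otherwise).
#' @param vocabulary_style `"cjk"` (default) or `"ascii"` word shapes.
#' @param source provenance flag for all entries (default `"seed"`).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A [suicide_lexicon()].
#' @examples
#' lex <- make_lexicon(seed = 1)
#' length(lex)  # 2168
#' @export
make_lexicon <- function(n = NULL, category_counts = reference_category_counts(),
                         weight_mix = reference_weight_counts(),
                         vocabulary_style = c("cjk", "ascii"),
                         source = "seed", seed = 1) {
  vocabulary_style <- match.arg(vocabulary_style)
  stopifnot(all(category_counts >= 0), all(weight_mix >= 0))
  if (!is.null(n))
    category_counts <- apportion_counts(category_counts, n)
  total <- sum(category_counts)
  if (total == 0) {
    return(suicide_lexicon(data.frame(
      word = character(0), category = character(0), weight = integer(0),
      source = character(0), corpus_frequency = integer(0)),
      version = "synthetic"))
  }
  set.seed(seed)
  weight_counts <- apportion_counts(weight_mix, total)
  weights <- sample(rep(1:3, times = weight_counts))
  words <- generate_words(total, style = vocabulary_style)
  entries <- data.frame(
    word = words,
    category = rep(names(category_counts), times = category_counts),
    weight = weights,
    source = source,
    corpus_frequency = NA_integer_,
    stringsAsFactors = FALSE
  )
  suicide_lexicon(entries, version = "synthetic")
}

#' Specification of a synthetic post corpus
#'
#' Defaults define the standard simulated study: two groups of 60 users, 50
#' posts per user of 5-40 tokens, risk-word emission probabilities 0.08
#' (high group) vs 0.02 (non-high), posts timestamped uniformly over the 90
#' days up to the anchor date.
#'
#' @param n_users_high,n_users_non_high group sizes.
#' @param posts_per_user posts per user (single count or `c(min, max)`).
#' @param tokens_per_post token-count range per post, `c(min, max)`.
#' @param p_risk_word_high,p_risk_word_low per-token probability that a
#'   token is a lexicon word, per group; `p_risk_word_high >=
#'   p_risk_word_low`.
#' @param anchor anchor datetime (ISO-8601 string).
#' @param time_span days before the anchor over which timestamps spread.
#' @param n_filler size of the filler (non-lexicon) vocabulary.
#' @param token_sep separator used when joining tokens into post text;
#'   default `""` (unsegmented text, as on Chinese microblogs).
#' @param seed integer seed.
#' @return List of class `corpus_spec`.
#' @export
corpus_spec <- function(n_users_high = 60, n_users_non_high = 60,
                        posts_per_user = 50, tokens_per_post = c(5, 40),
                        p_risk_word_high = 0.08, p_risk_word_low = 0.02,
                        anchor = "2014-07-13", time_span = 90,
                        n_filler = 2000, token_sep = "", seed = 1) {
  stopifnot(n_users_high >= 0, n_users_non_high >= 0,
            all(posts_per_user >= 0), all(tokens_per_post >= 1),
            p_risk_word_high >= 0, p_risk_word_high <= 1,
            p_risk_word_low >= 0, p_risk_word_low <= 1,
            p_risk_word_high >= p_risk_word_low, time_span > 0)
  structure(list(n_users_high = n_users_high,
                 n_users_non_high = n_users_non_high,
                 posts_per_user = posts_per_user,
                 tokens_per_post = tokens_per_post,
                 p_risk_word_high = p_risk_word_high,
                 p_risk_word_low = p_risk_word_low,
                 anchor = anchor, time_span = time_span,
                 n_filler = n_filler, token_sep = token_sep, seed = seed),
            class = "corpus_spec")
}

#' Generate a synthetic post corpus with a planted group effect
#'
#' Each token of each post is, with the user's group-specific emission
#' probability, a uniformly drawn lexicon word, and otherwise a filler token
#' drawn from a vocabulary verified to be disjoint from the lexicon. The
#' group effect is therefore planted at the token-emission level, so both
#' the user risk-level statistic and the category-ratio classifier have a
#' recoverable signal chain. A ground-truth table (group and true emission
#' propensity per user) is returned alongside the posts.
#'
#' @param lexicon a [suicide_lexicon()].
#' @param spec a [corpus_spec()].
#' @return List with `posts` (data frame: `user_id`, `timestamp`, `text`,
#'   `n_tokens`, `n_planted`) and `ground_truth` (data frame: `user_id`,
#'   `group`, `emission_propensity`). Deterministic given `spec$seed`.
#' @export
make_corpus <- function(lexicon, spec = corpus_spec()) {
  stopifnot(inherits(lexicon, "suicide_lexicon"),
            inherits(spec, "corpus_spec"))
  lex_words <- lexicon$entries$word
  if (length(lex_words) == 0) stop("corpus generation needs a non-empty lexicon")
  style <- if (any(grepl("[^\x01-\x7f]", lex_words))) "cjk" else "ascii"
  set.seed(spec$seed)
  filler <- generate_words(spec$n_filler, style = style, exclude = lex_words)
  stopifnot(!any(filler %in% lex_words))  # explicit disjointness check

  n_users <- spec$n_users_high + spec$n_users_non_high
  user_id <- sprintf("u%04d", seq_len(n_users))
  group <- c(rep("high", spec$n_users_high),
             rep("non_high", spec$n_users_non_high))
  p <- ifelse(group == "high", spec$p_risk_word_high, spec$p_risk_word_low)
  ppu <- spec$posts_per_user
  n_posts_u <- if (length(ppu) == 1) rep(ppu, n_users)
  else sample(ppu[1]:ppu[2], n_users, replace = TRUE)

  anchor <- parse_timestamps(spec$anchor)
  rows <- vector("list", n_users)
  for (u in seq_len(n_users)) {
    m <- n_posts_u[u]
    if (m == 0) next
    texts <- character(m); n_tok <- integer(m); n_plant <- integer(m)
    for (j in seq_len(m)) {
      L <- sample(spec$tokens_per_post[1]:spec$tokens_per_post[2], 1)
      risky <- stats::runif(L) < p[u]
      toks <- character(L)
      if (any(risky))
        toks[risky] <- sample(lex_words, sum(risky), replace = TRUE)
      if (any(!risky))
        toks[!risky] <- sample(filler, sum(!risky), replace = TRUE)
      texts[j] <- paste(toks, collapse = spec$token_sep)
      n_tok[j] <- L
      n_plant[j] <- sum(risky)
    }
    offs <- stats::runif(m, min = 0, max = spec$time_span * 86400)
    ts <- format(anchor - offs, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    rows[[u]] <- data.frame(user_id = user_id[u], timestamp = ts,
                            text = texts, n_tokens = n_tok,
                            n_planted = n_plant, stringsAsFactors = FALSE)
  }
  posts <- do.call(rbind, rows)
  rownames(posts) <- NULL
  list(posts = posts,
       ground_truth = data.frame(user_id = user_id, group = group,
                                 emission_propensity = p,
                                 stringsAsFactors = FALSE))
}

#' Generate synthetic SPS questionnaire responses
#'
#' Draws each user's SPS total from a normal distribution around their
#' group's mean (rounded and clipped to the valid 36-144 range), then
#' decomposes the total into 36 item responses in 1-4. By default the group
#' means are placed symmetrically around the pooled mean 69.35 (separation
#' `group_effect`), weighted by the group proportions so the pooled mean is
#' preserved; the common SD defaults to 11.66.
#'
#' @param ground_truth data frame with `user_id` and `group` (from
#'   [make_corpus()]).
#' @param mean_high,mean_low explicit group means; when `NULL` they are
#'   derived from `mean`, `group_effect` and the group proportions.
#' @param mean pooled target mean (default 69.35).
#' @param sd within-group standard deviation (default 11.66).
#' @param group_effect separation between group means (default 18, about
#'   1.5 SD — a strong but realistic questionnaire group difference).
#' @param seed integer seed.
#' @return Data frame: `user_id`, `item_01` ... `item_36`, `total`.
#' @export
make_sps <- function(ground_truth, mean_high = NULL, mean_low = NULL,
                     mean = 69.35, sd = 11.66, group_effect = 18, seed = 1) {
  stopifnot(is.data.frame(ground_truth),
            all(c("user_id", "group") %in% names(ground_truth)))
  n <- nrow(ground_truth)
  ph <- base::mean(ground_truth$group == "high")
  if (is.null(mean_high)) mean_high <- mean + group_effect * (1 - ph)
  if (is.null(mean_low)) mean_low <- mean - group_effect * ph
  mu <- ifelse(ground_truth$group == "high", mean_high, mean_low)
  set.seed(seed)
  totals <- round(stats::rnorm(n, mu, sd))
  totals <- pmin(144, pmax(36, totals))
  items <- matrix(1L, nrow = n, ncol = 36,
                  dimnames = list(NULL, sprintf("item_%02d", 1:36)))
  slots <- rep(1:36, times = 3)  # each item can absorb up to 3 increments
  for (i in seq_len(n)) {
    inc <- totals[i] - 36L
    if (inc > 0) {
      pick <- sample(slots, inc)
      add <- tabulate(pick, nbins = 36)
      items[i, ] <- items[i, ] + add
    }
  }
  out <- cbind(data.frame(user_id = ground_truth$user_id,
                          stringsAsFactors = FALSE),
               as.data.frame(items))
  out$total <- as.integer(rowSums(items))
  stopifnot(identical(out$total, as.integer(totals)))
  out
}

#' Specification of the synthetic expert-rating process
#'
#' @param noise_sd standard deviation of the Gaussian rating noise each
#'   simulated coder adds (on the 1-7 scale; default 1).
#' @param aggregation how the overall per-post rating aggregates the 13
#'   per-category ratings: `"sum"` (default) or `"mean"`.
#' @param n_coders number of simulated coders averaged (default 3).
#' @return List of class `expert_rating_spec`.
#' @export
expert_rating_spec <- function(noise_sd = 1, aggregation = c("sum", "mean"),
                               n_coders = 3) {
  stopifnot(noise_sd >= 0, n_coders >= 1)
  structure(list(noise_sd = noise_sd, aggregation = match.arg(aggregation),
                 n_coders = n_coders),
            class = "expert_rating_spec")
}

scale_to_likert <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(4, length(x)))
  1 + 6 * (x - rng[1]) / (rng[2] - rng[1])
}

#' Generate synthetic expert ratings from scored posts
#'
#' Emulates a panel of coders rating (i) each post's consistency with each
#' of the 13 categories and (ii) each user's overall suicide risk, on 1-7
#' scales. The true rating is a deterministic monotone (linear, within the
#' observed range) map of the actual lexicon content — per-category
#' occurrence counts for category ratings, their sum or mean for the
#' overall post rating, and the proportion of risky posts for the user
#' rating. Each simulated coder adds Gaussian noise (`noise_sd`); ratings
#' are clipped to \[1, 7\] and averaged over coders.
#'
#' @param scores per-post score data frame from [score_posts()].
#' @param spec an [expert_rating_spec()].
#' @param seed integer seed.
#' @return List with `post_ratings` (data frame: `user_id`, `timestamp`,
#'   `rating_<category>` columns, `overall`) and `user_ratings` (data
#'   frame: `user_id`, `rating`).
#' @export
make_expert_ratings <- function(scores, spec = expert_rating_spec(),
                                seed = 1) {
  stopifnot(is.data.frame(scores), inherits(spec, "expert_rating_spec"))
  cats <- lexicon_categories()
  cols <- paste0("n_", cats)
  stopifnot(all(c("user_id", "is_risky", cols) %in% names(scores)))
  counts <- as.matrix(scores[cols])
  set.seed(seed)
  coder_avg <- function(true) {
    sim <- replicate(spec$n_coders,
                     pmin(7, pmax(1, true + stats::rnorm(length(true),
                                                         0, spec$noise_sd))))
    rowMeans(matrix(sim, nrow = length(true)))
  }
  post_cat <- vapply(seq_along(cats),
                     function(j) coder_avg(scale_to_likert(counts[, j])),
                     numeric(nrow(scores)))
  colnames(post_cat) <- paste0("rating_", cats)
  agg <- switch(spec$aggregation, sum = rowSums(counts),
                mean = rowMeans(counts))
  overall <- coder_avg(scale_to_likert(agg))
  profiles <- user_risk_levels(scores)
  user_rating <- coder_avg(scale_to_likert(profiles$risk_level))
  list(
    post_ratings = cbind(
      data.frame(user_id = scores$user_id,
                 timestamp = if ("timestamp" %in% names(scores))
                   scores$timestamp else NA_character_,
                 stringsAsFactors = FALSE),
      as.data.frame(post_cat),
      data.frame(overall = overall)),
    user_ratings = data.frame(user_id = profiles$user_id,
                              rating = user_rating,
                              stringsAsFactors = FALSE)
  )
}

#' Generate a toy embedding model with planted synonyms
#'
#' Every lexicon word receives a random unit vector; each of its
#' `synonyms_per_word` planted synonyms receives a small perturbation of
#' that vector, and `n_distractors` unrelated words receive independent
#' random unit vectors. The construction is verified at generation time:
#' for every lexicon word, each planted synonym's cosine similarity to it
#' strictly exceeds that of every other vocabulary word; if verification
#' fails the perturbation is halved and generation retried.
#'
#' @param lexicon a [suicide_lexicon()].
#' @param synonyms_per_word planted synonyms per lexicon word (default 4).
#' @param n_distractors unrelated vocabulary words (default 500).
#' @param dim embedding dimension (>= 2, default 50).
#' @param noise perturbation scale for synonym vectors (default 0.1).
#' @param max_tries verification retries before giving up (default 8).
#' @param seed integer seed.
#' @return List with `model` (an [embedding_model()]) and `synonyms` (data
#'   frame: `seed_word`, `synonym`).
#' @export
make_embeddings <- function(lexicon, synonyms_per_word = 4,
                            n_distractors = 500, dim = 50, noise = 0.1,
                            max_tries = 8, seed = 1) {
  stopifnot(inherits(lexicon, "suicide_lexicon"), dim >= 2,
            synonyms_per_word >= 0, n_distractors >= 0)
  lex_words <- lexicon$entries$word
  n <- length(lex_words)
  if (n == 0) stop("embedding generation needs a non-empty lexicon")
  style <- if (any(grepl("[^\x01-\x7f]", lex_words))) "cjk" else "ascii"
  set.seed(seed)
  extra <- generate_words(n * synonyms_per_word + n_distractors,
                          style = style, exclude = lex_words)
  syn_words <- if (synonyms_per_word > 0)
    utils::head(extra, n * synonyms_per_word) else character(0)
  dis_words <- utils::tail(extra, n_distractors)
  unit <- function(v) v / sqrt(sum(v^2))
  for (attempt in seq_len(max_tries)) {
    seed_vec <- t(vapply(seq_len(n), function(i) unit(stats::rnorm(dim)),
                         numeric(dim)))
    syn_vec <- if (synonyms_per_word > 0)
      t(vapply(seq_len(n * synonyms_per_word), function(i) {
        s <- (i - 1) %/% synonyms_per_word + 1
        unit(seed_vec[s, ] + noise * stats::rnorm(dim))
      }, numeric(dim)))
    else matrix(numeric(0), ncol = dim)
    dis_vec <- if (n_distractors > 0)
      t(vapply(seq_len(n_distractors), function(i) unit(stats::rnorm(dim)),
               numeric(dim)))
    else matrix(numeric(0), ncol = dim)
    vectors <- rbind(seed_vec, syn_vec, dis_vec)
    rownames(vectors) <- c(lex_words, syn_words, dis_words)
    ok <- TRUE
    if (synonyms_per_word > 0) {
      sims <- vectors %*% t(seed_vec)  # all rows are unit vectors
      for (s in seq_len(n)) {
        syn_idx <- n + ((s - 1) * synonyms_per_word + 1):(s * synonyms_per_word)
        other <- setdiff(seq_len(nrow(vectors)), c(s, syn_idx))
        if (min(sims[syn_idx, s]) <= max(sims[other, s])) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      return(list(
        model = embedding_model(vectors),
        synonyms = data.frame(
          seed_word = rep(lex_words, each = synonyms_per_word),
          synonym = syn_words, stringsAsFactors = FALSE)))
    }
    noise <- noise / 2
  }
  stop("make_embeddings: could not verify planted-synonym geometry after ",
       max_tries, " tries; lower `noise` or raise `dim`")
}
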