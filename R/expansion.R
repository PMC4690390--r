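#' Construct an embedding model from a word-vector matrix
#'
#' @param vectors numeric matrix, one row per word, rownames = vocabulary.
#' @return Object of class `embedding_model` holding the raw vectors and a
#'   row-normalised copy used for cosine similarity.
#' @export
embedding_model <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate words in embedding vocabulary")
  norms <- sqrt(rowSums(vectors^2))
  normalized <- vectors / ifelse(norms > 0, norms, 1)
  structure(list(vectors = vectors, normalized = normalized),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model>", nrow(x$vectors), "words x", ncol(x$vectors),
      "dimensions\n")
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' The format is a header line `vocab_size dim` followed by one line per
#' word: `word v1 v2 ... vd`, space-separated, UTF-8.
#'
#' @param path path to the vector file.
#' @return An [embedding_model()].
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty embedding file: ", path)
  header <- as.integer(strsplit(trimws(lines[1]), " +")[[1]])
  if (length(header) != 2 || any(is.na(header)))
    stop("bad word2vec header in ", path)
  n <- header[1]; d <- header[2]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop("embedding file declares ", n, " words but has ", length(body))
  parts <- strsplit(body, " ", fixed = TRUE)
  if (any(lengths(parts) != d + 1))
    stop("embedding row with wrong dimension at line ",
         which(lengths(parts) != d + 1)[1] + 1)
  words <- vapply(parts, `[`, character(1), 1)
  vecs <- matrix(as.numeric(unlist(lapply(parts, `[`, -1))),
                 nrow = n, ncol = d, byrow = TRUE,
                 dimnames = list(words, NULL))
  embedding_model(vecs)
}

#' Write word vectors in word2vec text format
#'
#' @param model an [embedding_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  v <- model$vectors
  lines <- c(paste(nrow(v), ncol(v)),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], sprintf("%.8g", v[i, ])),
                     collapse = " "),
               character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Cosine similarity between two in-vocabulary words
#'
#' @param model an [embedding_model()].
#' @param a,b words in the model vocabulary.
#' @return Cosine similarity in \[-1, 1\].
#' @export
embedding_similarity <- function(model, a, b) {
  stopifnot(inherits(model, "embedding_model"))
  voc <- rownames(model$normalized)
  if (!(a %in% voc) || !(b %in% voc))
    stop("word not in embedding vocabulary")
  sum(model$normalized[a, ] * model$normalized[b, ])
}

#' k nearest embedding neighbours of a word
#'
#' Returns the `k` in-vocabulary words (excluding the query itself) with
#' highest cosine similarity to the query, in descending order; similarity
#' ties are broken by lexicographic (byte) word order. Out-of-vocabulary
#' queries produce an empty result with a logged notice.
#'
#' @param model an [embedding_model()].
#' @param word query word.
#' @param k number of neighbours (>= 1); when fewer candidates exist, all
#'   are returned.
#' @return Data frame with columns `word` and `similarity`.
#' @export
nearest_neighbors <- function(model, word, k) {
  stopifnot(inherits(model, "embedding_model"))
  if (k < 1) stop("k must be >= 1")
  voc <- rownames(model$normalized)
  empty <- data.frame(word = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!(word %in% voc)) {
    message("nearest_neighbors: '", word, "' not in embedding vocabulary")
    return(empty)
  }
  sims <- drop(model$normalized %*% model$normalized[word, ])
  keep <- voc != word
  sims <- sims[keep]; cand <- voc[keep]
  ord <- order(-sims, cand, method = "radix")
  take <- utils::head(ord, k)
  data.frame(word = cand[take], similarity = unname(sims[take]),
             stringsAsFactors = FALSE)
}

#' Propose lexicon expansion candidates from embedding neighbours
#'
#' For each lexicon word found in the embedding vocabulary, its `k` most
#' similar corpus words are proposed as expansion candidates, each
#' inheriting the seed word's category and weight. Candidates already in
#' the lexicon are skipped, as are candidates whose corpus frequency (when
#' supplied) falls below `min_corpus_freq` — mirroring the review rule that
#' drops rare words. A candidate reachable from several seeds is kept once,
#' under the seed with the highest similarity (ties: lexicographically
#' smaller seed).
#'
#' @param lexicon a [suicide_lexicon()].
#' @param model an [embedding_model()].
#' @param k neighbours per seed word (default 4).
#' @param min_corpus_freq minimum corpus frequency for a candidate
#'   (default 5); only enforced when `corpus_freq` is supplied.
#' @param corpus_freq optional named integer vector of corpus frequencies
#'   for candidate words; candidates absent from it are treated as
#'   unfiltered.
#' @return Data frame of class `expansion_candidates` with columns
#'   `seed_word`, `candidate_word`, `similarity`, `category`, `weight`,
#'   `status` (all `"proposed"`), sorted by descending similarity.
#' @export
propose_expansions <- function(lexicon, model, k = 4, min_corpus_freq = 5,
                               corpus_freq = NULL) {
  stopifnot(inherits(lexicon, "suicide_lexicon"),
            inherits(model, "embedding_model"))
  if (k < 1) stop("k must be >= 1")
  if (min_corpus_freq < 0) stop("min_corpus_freq must be >= 0")
  e <- lexicon$entries
  voc <- rownames(model$normalized)
  seeds <- e$word[e$word %in% voc]
  rows <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    nn <- nearest_neighbors(model, seeds[i], k)
    nn <- nn[!(nn$word %in% e$word), , drop = FALSE]
    if (!is.null(corpus_freq)) {
      f <- corpus_freq[nn$word]
      nn <- nn[is.na(f) | f >= min_corpus_freq, , drop = FALSE]
    }
    if (nrow(nn) == 0) next
    j <- match(seeds[i], e$word)
    rows[[i]] <- data.frame(seed_word = seeds[i], candidate_word = nn$word,
                            similarity = nn$similarity,
                            category = e$category[j], weight = e$weight[j],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seed_word = character(0), candidate_word = character(0),
                      similarity = numeric(0), category = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  # deduplicate candidates proposed by several seeds: best similarity wins,
  # similarity ties go to the lexicographically smaller seed
  ord <- order(out$candidate_word, -out$similarity, out$seed_word,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$candidate_word), , drop = FALSE]
  out <- out[order(-out$similarity, out$candidate_word, method = "radix"), ,
             drop = FALSE]
  out$status <- rep("proposed", nrow(out))
  rownames(out) <- NULL
  class(out) <- c("expansion_candidates", "data.frame")
  out
}

#' Apply reviewer votes to expansion candidates
#'
#' Candidates receiving at least `quorum` distinct `eliminate` votes are
#' rejected. Among the survivors, a proposed category or weight override is
#' applied if and only if at least `quorum` coders proposed the identical
#' value; conflicting proposals without a quorum keep the inherited values
#' (the conflict is logged). Accepted entries carry `source = "expanded"`.
#'
#' @param candidates an [propose_expansions()] data frame.
#' @param votes vote data frame (see [read_votes()]); `word` refers to the
#'   candidate word.
#' @param quorum agreement threshold (default 2, the 2-of-3 panel rule).
#' @return Data frame of accepted lexicon entries (`word`, `category`,
#'   `weight`, `source`, `corpus_frequency`), ready for
#'   [merge.suicide_lexicon()].
#' @export
apply_review <- function(candidates, votes, quorum = 2) {
  if (quorum < 1) stop("quorum must be >= 1")
  votes <- validate_votes(votes)
  cand <- as.data.frame(candidates)
  elim_n <- function(w) {
    v <- votes[votes$word == w & votes$decision == "eliminate", , drop = FALSE]
    length(unique(v$coder_id))
  }
  keep <- vapply(cand$candidate_word, elim_n, integer(1)) < quorum
  cand <- cand[keep, , drop = FALSE]
  override <- function(w, values, coders) {
    ok <- !is.na(values)
    if (!any(ok)) return(NA)
    tab <- tapply(coders[ok], values[ok], function(x) length(unique(x)))
    winners <- names(tab)[tab >= quorum]
    if (length(winners) == 1) return(winners)
    if (length(tab) > 1)
      message("apply_review: conflicting overrides on '", w,
              "' without quorum; inherited values kept")
    NA
  }
  for (i in seq_len(nrow(cand))) {
    w <- cand$candidate_word[i]
    v <- votes[votes$word == w, , drop = FALSE]
    if (nrow(v) == 0) next
    oc <- override(w, v$proposed_category, v$coder_id)
    if (!is.na(oc)) cand$category[i] <- oc
    ow <- override(w, as.character(v$proposed_weight), v$coder_id)
    if (!is.na(ow)) cand$weight[i] <- as.integer(ow)
  }
  data.frame(word = cand$candidate_word, category = cand$category,
             weight = cand$weight, source = rep("expanded", nrow(cand)),
             corpus_frequency = rep(NA_integer_, nrow(cand)),
             stringsAsFactors = FALSE)
}
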