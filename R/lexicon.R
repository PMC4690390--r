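#' Category labels of the suicide-risk lexicon framework
#'
#' The 13 fixed category labels used throughout the package, as ASCII
#' identifiers. They correspond to: suicide ideation, suicide behavior,
#' psychache, mental illness, hopelessness, somatic complaints,
#' self-regulation, (negative) personality, stress, trauma/hurt, talk about
#' others, shame/guilt and anger/hostility.
#'
#' @return Character vector of length 13, in the canonical order used for
#'   summaries and feature vectors.
#' @export
lexicon_categories <- function() {
  c("suicide_ideation", "suicide_behavior", "psychache", "mental_illness",
    "hopeless", "somatic_complaints", "self_regulation", "personality",
    "stress", "trauma_hurt", "talk_about_others", "shame_guilt",
    "anger_hostility")
}

#' Canonical per-category entry counts of the reference suicide lexicon
#'
#' Published outline counts for the 13 categories of the Chinese suicide
#' dictionary (total 2,168 words). Used as the default shape for synthetic
#' lexicons.
#'
#' @return Named integer vector over [lexicon_categories()].
#' @export
reference_category_counts <- function() {
  stats::setNames(
    c(586L, 88L, 403L, 48L, 188L, 183L, 36L, 72L, 83L, 182L, 47L, 72L, 180L),
    lexicon_categories()
  )
}

#' Canonical seed weight-class counts of the reference suicide lexicon
#'
#' The 1,862 seed words split into weight classes: 990 words of weight 1
#' (light), 505 of weight 2, and 367 of weight 3 (heavy).
#'
#' @return Named integer vector `c("1" = 990, "2" = 505, "3" = 367)`.
#' @export
reference_weight_counts <- function() {
  stats::setNames(c(990L, 505L, 367L), c("1", "2", "3"))
}

lexicon_entry_columns <- function() {
  c("word", "category", "weight", "source", "corpus_frequency")
}

#' Validate a data frame of lexicon entries
#'
#' @param entries data frame with columns `word`, `category`, `weight`,
#'   `source` and optionally `corpus_frequency`.
#' @return The entries, normalised (columns coerced and ordered), invisibly
#'   usable as the `entries` slot of a [suicide_lexicon()].
#' @keywords internal
validate_entries <- function(entries) {
  if (!is.data.frame(entries)) stop("entries must be a data frame")
  needed <- c("word", "category", "weight")
  missing <- setdiff(needed, names(entries))
  if (length(missing) > 0)
    stop("entries missing required column(s): ", paste(missing, collapse = ", "))
  if (!"source" %in% names(entries)) entries$source <- "seed"
  if (!"corpus_frequency" %in% names(entries))
    entries$corpus_frequency <- NA_integer_

  entries$word <- enc2utf8(as.character(entries$word))
  entries$category <- as.character(entries$category)
  entries$source <- as.character(entries$source)

  if (nrow(entries) > 0) {
    bad_word <- !nzchar(entries$word) | grepl("[\t[:space:]]", entries$word)
    if (any(bad_word))
      stop("invalid word(s) (empty or containing whitespace) at row(s): ",
           paste(which(bad_word), collapse = ", "))
    bad_cat <- !(entries$category %in% lexicon_categories())
    if (any(bad_cat))
      stop("unknown category '", entries$category[which(bad_cat)[1]],
           "' at row ", which(bad_cat)[1])
    w <- suppressWarnings(as.integer(entries$weight))
    if (any(is.na(w)) || any(w != entries$weight) || !all(w %in% 1:3))
      stop("weight must be an integer in {1, 2, 3}; offending row(s): ",
           paste(which(is.na(w) | !(w %in% 1:3))[1], collapse = ", "))
    entries$weight <- w
    bad_src <- !(entries$source %in% c("seed", "expanded"))
    if (any(bad_src))
      stop("source must be 'seed' or 'expanded'; offending row ",
           which(bad_src)[1])
    cf <- suppressWarnings(as.integer(entries$corpus_frequency))
    if (any(!is.na(entries$corpus_frequency) & (is.na(cf) | cf < 0)))
      stop("corpus_frequency must be a non-negative integer or missing")
    entries$corpus_frequency <- cf
    dup <- duplicated(entries$word)
    if (any(dup))
      stop("duplicate word(s) in lexicon: ",
           paste(unique(entries$word[dup]), collapse = ", "))
  } else {
    entries$weight <- integer(0)
    entries$corpus_frequency <- integer(0)
  }
  entries[lexicon_entry_columns()]
}

#' Construct a weighted suicide-risk lexicon
#'
#' A lexicon is a set of unique words, each carrying one of the 13 category
#' labels, an integer sensitivity weight in 1-3 (1 = light, 3 = heavy), a
#' provenance flag (`seed` for reviewed initial words, `expanded` for
#' accepted embedding-based expansions) and an optional corpus frequency.
#'
#' @param entries data frame with columns `word`, `category`, `weight`, and
#'   optionally `source` (default `"seed"`) and `corpus_frequency`.
#' @param version character version tag stored with the lexicon.
#' @return An object of class `suicide_lexicon`: a list with elements
#'   `entries` (validated data frame) and `version`.
#' @examples
#' lex <- suicide_lexicon(data.frame(
#'   word = c("a1", "b2"), category = c("psychache", "stress"),
#'   weight = c(1, 3)))
#' nrow(lex$entries)
#' @export
suicide_lexicon <- function(entries, version = "0") {
  structure(list(entries = validate_entries(entries),
                 version = as.character(version)),
            class = "suicide_lexicon")
}

#' @export
print.suicide_lexicon <- function(x, ...) {
  cat("<suicide_lexicon> version", x$version, "-", nrow(x$entries),
      "entries\n")
  if (nrow(x$entries) > 0) {
    wt <- table(factor(x$entries$weight, levels = 1:3))
    cat("  weights 1/2/3:", paste(wt, collapse = "/"), "\n")
    cat("  sources:", paste(sprintf("%s=%d", names(table(x$entries$source)),
                                    table(x$entries$source)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.suicide_lexicon <- function(x) nrow(x$entries)

#' Summarise a lexicon: per-category, per-weight and total counts
#'
#' @param object a [suicide_lexicon()].
#' @param ... ignored.
#' @return A list of class `suicide_lexicon_summary` with elements
#'   `category_counts` (named integer vector over all 13 categories),
#'   `weight_counts` (named vector over weights 1-3), `source_counts`
#'   and `total`. Per-category and per-weight counts each sum to `total`.
#' @export
summary.suicide_lexicon <- function(object, ...) {
  e <- object$entries
  res <- list(
    category_counts = c(table(factor(e$category, levels = lexicon_categories()))),
    weight_counts = c(table(factor(e$weight, levels = 1:3))),
    source_counts = c(table(factor(e$source, levels = c("seed", "expanded")))),
    total = nrow(e)
  )
  class(res) <- "suicide_lexicon_summary"
  res
}

#' @export
print.suicide_lexicon_summary <- function(x, ...) {
  cat("Lexicon summary:", x$total, "entries\n")
  cat("Per category:\n")
  print(x$category_counts)
  cat("Per weight:\n")
  print(x$weight_counts)
  invisible(x)
}

#' Read a lexicon from a TSV file
#'
#' The file format is UTF-8 TSV with LF line endings, no quoting, and the
#' header `word<TAB>category<TAB>weight<TAB>source<TAB>corpus_frequency`.
#' An empty `corpus_frequency` field round-trips to `NA`.
#'
#' @param path path to the lexicon TSV file.
#' @param version version tag for the loaded lexicon (default the file name).
#' @return A [suicide_lexicon()].
#' @export
read_lexicon <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty lexicon file (missing header): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, lexicon_entry_columns()))
    stop("bad lexicon header in ", path, ": expected '",
         paste(lexicon_entry_columns(), collapse = "\\t"), "'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(suicide_lexicon(
      data.frame(word = character(0), category = character(0),
                 weight = integer(0), source = character(0),
                 corpus_frequency = integer(0)),
      version = version))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty corpus_frequency field is dropped by strsplit
  bad <- which(nf < 4 | nf > 5)
  if (length(bad) > 0)
    stop("malformed lexicon row at line ", bad[1] + 1, " of ", path,
         " (expected 5 tab-separated fields, got ", nf[bad[1]], ")")
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else ""
  }, character(1))
  weight_raw <- get(3)
  weight_num <- suppressWarnings(as.numeric(weight_raw))
  if (any(is.na(weight_num)))
    stop("malformed weight at line ", which(is.na(weight_num))[1] + 1,
         " of ", path)
  cf_raw <- get(5)
  entries <- data.frame(
    word = get(1), category = get(2), weight = weight_num,
    source = get(4),
    corpus_frequency = ifelse(nzchar(cf_raw),
                              suppressWarnings(as.integer(cf_raw)),
                              NA_integer_),
    stringsAsFactors = FALSE
  )
  suicide_lexicon(entries, version = version)
}

#' Write a lexicon to a TSV file
#'
#' Inverse of [read_lexicon()]: `read_lexicon(write_lexicon(lex, path))`
#' recovers `lex$entries` field-for-field.
#'
#' @param lexicon a [suicide_lexicon()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "suicide_lexicon"))
  e <- lexicon$entries
  cf <- ifelse(is.na(e$corpus_frequency), "", as.character(e$corpus_frequency))
  lines <- c(paste(lexicon_entry_columns(), collapse = "\t"),
             if (nrow(e) > 0)
               paste(e$word, e$category, e$weight, e$source, cf, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a vote manifest from a TSV file
#'
#' Vote manifests record reviewer decisions on words: the columns are
#' `word`, `coder_id`, `decision` (`eliminate` or `keep`) and the optional
#' `proposed_category` and `proposed_weight` override fields.
#'
#' @param path path to the vote TSV file.
#' @return Data frame with the five vote columns; empty override fields are
#'   `NA`.
#' @export
read_votes <- function(path) {
  if (!file.exists(path)) stop("vote file not found: ", path)
  v <- utils::read.delim(path, quote = "", stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8",
                         na.strings = "")
  needed <- c("word", "coder_id", "decision")
  missing <- setdiff(needed, names(v))
  if (length(missing) > 0)
    stop("vote manifest missing column(s): ", paste(missing, collapse = ", "))
  if (!"proposed_category" %in% names(v)) v$proposed_category <- NA_character_
  if (!"proposed_weight" %in% names(v)) v$proposed_weight <- NA_character_
  v$proposed_weight <- suppressWarnings(as.integer(v$proposed_weight))
  validate_votes(v)
}

validate_votes <- function(votes) {
  if (!is.data.frame(votes)) stop("votes must be a data frame")
  if (!"proposed_category" %in% names(votes))
    votes$proposed_category <- rep(NA_character_, nrow(votes))
  if (!"proposed_weight" %in% names(votes))
    votes$proposed_weight <- rep(NA_integer_, nrow(votes))
  if (nrow(votes) > 0) {
    bad <- !(votes$decision %in% c("eliminate", "keep"))
    if (any(bad))
      stop("vote decision must be 'eliminate' or 'keep'; offending row ",
           which(bad)[1])
    pw <- votes$proposed_weight
    if (any(!is.na(pw) & !(pw %in% 1:3)))
      stop("proposed_weight must be in {1, 2, 3} when present")
    pc <- votes$proposed_category
    if (any(!is.na(pc) & !(pc %in% lexicon_categories())))
      stop("unknown proposed_category in votes")
  }
  votes
}

#' Apply the coder elimination vote rule to lexicon entries
#'
#' An entry is removed if and only if at least `quorum` distinct coders
#' voted `eliminate` on its word (the reference review panel used 2 of 3
#' coders). Entries with no votes are retained; input order is preserved.
#' Votes referencing words not present in `entries` raise a warning and are
#' ignored.
#'
#' @param entries data frame of lexicon entries (columns `word`, `category`,
#'   `weight`, ...), or a [suicide_lexicon()] whose entries are filtered.
#' @param votes data frame of vote records (see [read_votes()]).
#' @param quorum minimum number of distinct `eliminate` voters required to
#'   drop a word (default 2).
#' @return The retained entries, same type as the input (`suicide_lexicon`
#'   in, `suicide_lexicon` out).
#' @export
apply_vote_filter <- function(entries, votes, quorum = 2) {
  if (quorum < 1) stop("quorum must be >= 1")
  is_lex <- inherits(entries, "suicide_lexicon")
  e <- if (is_lex) entries$entries else entries
  votes <- validate_votes(votes)
  if (nrow(votes) > 0) {
    unknown <- setdiff(unique(votes$word), e$word)
    if (length(unknown) > 0)
      warning("ignoring vote(s) on word(s) absent from entries: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    elim <- votes[votes$decision == "eliminate" & votes$word %in% e$word, ,
                  drop = FALSE]
    if (nrow(elim) > 0) {
      n_voters <- tapply(elim$coder_id, elim$word,
                         function(x) length(unique(x)))
      drop_words <- names(n_voters)[n_voters >= quorum]
      e <- e[!(e$word %in% drop_words), , drop = FALSE]
      rownames(e) <- NULL
    }
  }
  if (is_lex) suicide_lexicon(e, version = entries$version) else e
}

#' Merge accepted expansion entries into a seed lexicon
#'
#' Appends expansion entries whose words are not already in the seed
#' lexicon. On a word collision the seed entry wins and the skipped
#' expansion is reported via a message and the `"skipped"` attribute.
#'
#' @param x the seed [suicide_lexicon()].
#' @param y data frame of accepted expansion entries (must carry
#'   `source = "expanded"`), e.g. the output of [apply_review()].
#' @param ... ignored.
#' @return A [suicide_lexicon()] of size
#'   `length(x) + number of non-colliding expansions`, with attribute
#'   `"skipped"` listing colliding expansion words.
#' @export
merge.suicide_lexicon <- function(x, y, ...) {
  if (inherits(y, "suicide_lexicon")) y <- y$entries
  if (nrow(y) > 0 && !all(y$source == "expanded"))
    stop("expansion entries must carry source = 'expanded'")
  collide <- y$word %in% x$entries$word
  if (any(collide))
    message("merge: skipping ", sum(collide),
            " expansion word(s) already present in the seed lexicon")
  keep <- y[!collide, , drop = FALSE]
  out <- suicide_lexicon(rbind(x$entries, keep[names(x$entries)]),
                         version = x$version)
  attr(out, "skipped") <- y$word[collide]
  out
}
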