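Package: suilex
Title: Weighted Suicide-Risk Lexicons for Chinese Social-Media Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building, maintaining and validating weighted
    psycholinguistic risk lexicons for unsegmented Chinese microblog text.
    Provides a 13-category weighted lexicon data model with a TSV file
    format and vote-based review filtering, a dictionary matcher for raw
    (unsegmented) text with post-level risk scoring, windowed user-level
    risk profiling and category-ratio feature extraction, embedding-based
    nearest-neighbour lexicon expansion with category and weight
    inheritance, questionnaire-based screening (SPS scoring, mean + SD
    cutoff, SVM classification with cross-validated precision, recall and
    F-measure), and seeded synthetic-data generators (lexicons, post
    corpora with planted group effects, questionnaire responses, expert
    ratings and toy word embeddings) so the full pipeline can be exercised
    and tested without access to the original social-media data.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
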