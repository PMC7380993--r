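#' Three-way sentiment label from a valence score
#'
#' Thresholds a compound valence score in \[-1, 1\] into
#' negative/neutral/positive: scores in \[-1.00, -0.05\] are negative,
#' scores strictly inside (-0.05, +0.05) are neutral, and scores in
#' \[+0.05, +1.00\] are positive — both boundary values are assigned
#' outward, never neutral. The three intervals partition \[-1, 1\].
#'
#' @param score Numeric vector of valence scores in \[-1, 1\].
#' @param threshold Half-width of the neutral band (default 0.05).
#' @return Character vector: `"negative"`, `"neutral"` or `"positive"`.
#' @export
sentiment_label <- function(score, threshold = 0.05) {
  if (any(is.na(score)) || any(score < -1) || any(score > 1)) {
    rlang::abort("scorer contract violation: scores must be in [-1, 1]")
  }
  dplyr::case_when(
    score <= -threshold ~ "negative",
    score >= threshold ~ "positive",
    TRUE ~ "neutral")
}

#' Score posts with an injectable valence scorer
#'
#' Applies a valence scorer — any function mapping a character vector of
#' texts to compound scores in \[-1, 1\] — and labels each score via
#' [sentiment_label()]. The scorer is a contract, not a fixed model: a
#' lexicon-and-rules analyzer for real corpora, or the deterministic
#' [stub_valence_scorer()] that reads valences planted by the synthetic
#' generator, so pipeline tests never depend on a particular lexicon's
#' weights.
#'
#' @param posts Post tibble (or character vector of texts).
#' @param scorer Function `character -> numeric in [-1, 1]`.
#' @param threshold Neutral band half-width.
#' @return Tibble `post_id`, `score`, `label`.
#' @export
score_posts <- function(posts, scorer = lexicon_valence_scorer(),
                        threshold = 0.05) {
  if (is.data.frame(posts)) {
    texts <- posts$text
    ids <- posts$id
  } else {
    texts <- as.character(posts)
    ids <- as.character(seq_along(texts))
  }
  score <- as.numeric(scorer(texts))
  if (length(score) != length(texts)) {
    rlang::abort("scorer contract violation: one score per text required")
  }
  tibble::tibble(post_id = ids, score = score,
                 label = sentiment_label(score, threshold = threshold))
}

#' @rdname score_posts
#' @param post A single post (one-row tibble or a length-1 character).
#' @export
score_post <- function(post, scorer = lexicon_valence_scorer(),
                       threshold = 0.05) {
  score_posts(post, scorer = scorer, threshold = threshold)
}

#' Aggregate sentiment per flavor category
#'
#' Per-category score statistics and label proportions for posts attributed
#' to a single flavor category (see [single_flavor_subset()]): post count,
#' mean and sample (n-1) standard deviation of the scores, and the
#' positive/neutral/negative proportions normalized by the category's post
#' count. Categories below `min_count` posts are flagged — miscellaneous
#' low-volume categories give unstable proportions and are conventionally
#' dropped from testing.
#'
#' @param scores Tibble from [score_posts()].
#' @param categories Tibble `post_id`, `category` (e.g. the
#'   `flavor_category` column produced by [single_flavor_subset()]).
#' @param min_count Minimum post count for an unflagged category
#'   (default 300).
#' @return Tibble `category`, `n_posts`, `mean_score`, `sd_score`, `n_pos`,
#'   `n_neu`, `n_neg`, `prop_pos`, `prop_neu`, `prop_neg`, `flagged`.
#' @export
aggregate_category <- function(scores, categories, min_count = 300) {
  joined <- dplyr::inner_join(scores, categories, by = "post_id")
  if (nrow(joined) == 0) {
    rlang::abort("no scored posts with category attribution")
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$category),
    n_posts = dplyr::n(),
    mean_score = mean(.data$score),
    sd_score = stats::sd(.data$score),
    n_pos = sum(.data$label == "positive"),
    n_neu = sum(.data$label == "neutral"),
    n_neg = sum(.data$label == "negative"),
    .groups = "drop")
  out$prop_pos <- out$n_pos / out$n_posts
  out$prop_neu <- out$n_neu / out$n_posts
  out$prop_neg <- out$n_neg / out$n_posts
  out$flagged <- out$n_posts < min_count
  dplyr::arrange(out, dplyr::desc(.data$n_posts))
}
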