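#' Topic-keyword matching
#'
#' Tests each post text for at least one topic keyword at token boundaries,
#' case-insensitively, with leading `#` stripped from tokens (so
#' `"#vaping"` matches the keyword `vaping` but `"grapevine"` does not match
#' `vape`).
#'
#' @param posts Post tibble (or a character vector of texts).
#' @param keywords Character vector of topic keywords; defaults to the
#'   bundled e-cigarette keyword list.
#' @return Logical vector, one element per post.
#' @export
match_topic <- function(posts, keywords = default_topic_keywords()) {
  texts <- if (is.data.frame(posts)) posts$text else as.character(posts)
  if (length(keywords) == 0) rlang::abort("keyword set is empty")
  detect_any_keyword(texts, norm_keyword(keywords))
}

#' Two-step promotion filtering
#'
#' Removes promotional posts in two observable steps: first any post whose
#' author handle contains a promotion-related keyword as a case-insensitive
#' substring (promotional accounts advertise in their handle, e.g.
#' `BestVapeStore`), then any remaining post whose body matches a promotion
#' keyword (`customer`, `promotion`, `discount`, `sale`, `free shipping` by
#' default) at token boundaries.
#'
#' @param posts Post tibble.
#' @param id_keywords Handle substrings for step 1.
#' @param body_keywords Body keywords for step 2.
#' @return List with elements `posts` (retained tibble), `removed_step1` and
#'   `removed_step2` (removed tibbles, in step order). Counts are conserved:
#'   `nrow(posts in)` = retained + removed_step1 + removed_step2.
#' @export
filter_promotions <- function(posts,
                              id_keywords = default_promo_id_keywords(),
                              body_keywords = default_promo_body_keywords()) {
  id_keywords <- norm_keyword(id_keywords)
  body_keywords <- norm_keyword(body_keywords)
  handle <- stringr::str_to_lower(posts$author)
  step1 <- rep(FALSE, nrow(posts))
  for (kw in id_keywords) {
    step1 <- step1 | stringr::str_detect(handle, stringr::fixed(kw))
  }
  after1 <- posts[!step1, , drop = FALSE]
  step2 <- detect_any_keyword(after1$text, body_keywords)
  list(posts = after1[!step2, , drop = FALSE],
       removed_step1 = posts[step1, , drop = FALSE],
       removed_step2 = after1[step2, , drop = FALSE])
}

#' Extract flavor-keyword mentions
#'
#' Finds every flavor keyword (or alias) of the taxonomy in each post text
#' at token boundaries, case-insensitively, resolving overlaps
#' longest-match-first (so `"cotton candy"` yields one mention, not
#' `candy`). Keywords in the exclusion set — typically the output of the
#' denoise procedure — are never matched. Each match is resolved to its
#' taxonomy path via [classify_term()].
#'
#' A post mentioning keywords in several categories contributes one mention
#' per match; mention counts are therefore keyword occurrences, not posts.
#'
#' @param posts Post tibble (or a character vector of texts, in which case
#'   `post_id` is the element index as character).
#' @param tax A `flavor_taxonomy`.
#' @param excluded Character vector of canonical keywords to exclude.
#' @return Tibble with columns `post_id`, `keyword` (matched surface),
#'   `canonical` (standardized keyword), `category`, `subcategory`, `start`,
#'   `end` (0-based half-open character span in the original text).
#' @export
extract_mentions <- function(posts, tax, excluded = character()) {
  stopifnot(inherits(tax, "flavor_taxonomy"))
  if (is.data.frame(posts)) {
    texts <- posts$text
    ids <- posts$id
  } else {
    texts <- as.character(posts)
    ids <- as.character(seq_along(texts))
  }
  surf <- taxonomy_surfaces(tax, excluded = excluded)
  empty <- tibble::tibble(post_id = character(), keyword = character(),
                          canonical = character(), category = character(),
                          subcategory = character(),
                          start = integer(), end = integer())
  if (length(texts) == 0 || nrow(surf) == 0) return(empty)
  hits <- locate_keywords(texts, surf$surface)
  if (nrow(hits) == 0) return(empty)
  kept <- dplyr::group_modify(
    dplyr::group_by(hits, .data$text_idx),
    function(g, key) g[resolve_overlaps(g$start, g$end), , drop = FALSE])
  kept <- dplyr::arrange(dplyr::ungroup(kept), .data$text_idx, .data$start)
  canon <- surf$keyword[match(kept$keyword, surf$surface)]
  path <- tax$table[match(canon, tax$table$keyword),
                    c("category", "subcategory")]
  tibble::tibble(
    post_id = ids[kept$text_idx],
    keyword = kept$keyword,
    canonical = canon,
    category = path$category,
    subcategory = path$subcategory,
    start = as.integer(kept$start),
    end = as.integer(kept$end))
}

#' Evaluate one flavor keyword against labeled samples
#'
#' Scores a potentially noisy flavor keyword on manually labeled sample
#' posts: a true positive is a labeled-relevant post where the extractor
#' found the keyword, a false positive a labeled-irrelevant post where it
#' did, a false negative a labeled-relevant post where it did not. The
#' keyword is kept only when sample precision is at least `precision_min`
#' (default 0.90) and recall at least `recall_min` (default 0.75); an
#' undefined precision or recall (zero denominator) excludes it.
#'
#' @param keyword Canonical keyword under evaluation.
#' @param labels Tibble with columns `post_id`, `keyword`, `is_relevant`
#'   (0/1 or logical); rows for other keywords are ignored.
#' @param mentions Mentions over the labeled posts, from
#'   [extract_mentions()].
#' @param precision_min,recall_min Keep thresholds.
#' @return One-row tibble: `keyword`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `decision` (`"keep"`/`"exclude"`).
#' @export
evaluate_keyword <- function(keyword, labels, mentions,
                             precision_min = 0.90, recall_min = 0.75) {
  keyword <- norm_keyword(keyword)
  lab <- labels[norm_keyword(labels$keyword) == keyword, , drop = FALSE]
  if (nrow(lab) == 0) rlang::abort("labeled sample is empty for this keyword")
  rel <- as.logical(as.integer(lab$is_relevant))
  pred_ids <- unique(mentions$post_id[mentions$canonical == keyword])
  pred <- lab$post_id %in% pred_ids
  tp <- sum(pred & rel)
  fp <- sum(pred & !rel)
  fn <- sum(!pred & rel)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  keep <- !is.na(precision) && !is.na(recall) &&
    precision >= precision_min && recall >= recall_min
  tibble::tibble(keyword = keyword, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 decision = if (keep) "keep" else "exclude")
}

#' Denoise flavor keywords against labeled samples
#'
#' Runs [evaluate_keyword()] for every keyword present in the labeled
#' sample and collects the exclusion set: keywords whose sample precision
#' falls below 0.90 or recall below 0.75 are excluded from further
#' analysis.
#'
#' @param posts Post tibble covering the labeled post ids.
#' @param tax A `flavor_taxonomy`.
#' @param labels Labeled samples: tibble `post_id`, `keyword`,
#'   `is_relevant`.
#' @param precision_min,recall_min Keep thresholds.
#' @return List with `evaluations` (one row per keyword) and `excluded`
#'   (character vector of keywords to exclude).
#' @export
denoise_keywords <- function(posts, tax, labels,
                             precision_min = 0.90, recall_min = 0.75) {
  mentions <- extract_mentions(posts, tax)
  kws <- unique(norm_keyword(labels$keyword))
  evals <- dplyr::bind_rows(lapply(kws, function(kw) {
    evaluate_keyword(kw, labels, mentions,
                     precision_min = precision_min, recall_min = recall_min)
  }))
  list(evaluations = evals,
       excluded = evals$keyword[evals$decision == "exclude"])
}

#' Single-flavor subset
#'
#' Retains posts mentioning exactly one distinct flavor keyword (repeated
#' mentions of the same keyword count once), so each retained post can be
#' attributed unambiguously to one flavor category — the precondition for
#' per-category sentiment aggregation.
#'
#' @param posts Post tibble.
#' @param tax A `flavor_taxonomy`.
#' @param excluded Keywords excluded by the denoise procedure.
#' @return The retained posts with added columns `flavor_keyword`
#'   (canonical) and `flavor_category`.
#' @export
single_flavor_subset <- function(posts, tax, excluded = character()) {
  mentions <- extract_mentions(posts, tax, excluded = excluded)
  per_post <- dplyr::summarise(
    dplyr::group_by(mentions, .data$post_id),
    n_distinct_kw = dplyr::n_distinct(.data$canonical),
    flavor_keyword = .data$canonical[[1]],
    flavor_category = .data$category[[1]],
    .groups = "drop")
  singles <- per_post[per_post$n_distinct_kw == 1, , drop = FALSE]
  out <- posts[posts$id %in% singles$post_id, , drop = FALSE]
  idx <- match(out$id, singles$post_id)
  out$flavor_keyword <- singles$flavor_keyword[idx]
  out$flavor_category <- singles$flavor_category[idx]
  out
}
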