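#' Pipeline configurations
#'
#' Bundle the tunable constants of the two workflows so nothing is
#' hard-coded inline: keyword lists, the denoise exclusion set, the neutral
#' sentiment band (+/- 0.05), the minimum category size (300), the
#' family-wise alpha (0.05), the month range, and whether promotion
#' filtering applies (off by default for the trend workflow, which targets
#' Reddit-style corpora; always on for the sentiment workflow, which
#' targets Twitter-style corpora).
#'
#' @param topic_keywords,promo_id_keywords,promo_body_keywords Keyword
#'   sets; bundled defaults.
#' @param excluded_keywords Denoise exclusion set (canonical keywords).
#' @param apply_promo_filter Apply promotion filtering in the trend
#'   workflow?
#' @param from,to Optional `"YYYY-MM"` month range for trend tables.
#' @param threshold Neutral band half-width for sentiment labels.
#' @param min_count Minimum category post count for sentiment testing.
#' @param alpha Family-wise significance level.
#' @return A config list.
#' @export
trend_config <- function(topic_keywords = default_topic_keywords(),
                         apply_promo_filter = FALSE,
                         promo_id_keywords = default_promo_id_keywords(),
                         promo_body_keywords = default_promo_body_keywords(),
                         excluded_keywords = character(),
                         from = NULL, to = NULL) {
  list(topic_keywords = topic_keywords,
       apply_promo_filter = apply_promo_filter,
       promo_id_keywords = promo_id_keywords,
       promo_body_keywords = promo_body_keywords,
       excluded_keywords = excluded_keywords,
       from = from, to = to)
}

#' @rdname trend_config
#' @export
sentiment_config <- function(topic_keywords = default_topic_keywords(),
                             promo_id_keywords = default_promo_id_keywords(),
                             promo_body_keywords = default_promo_body_keywords(),
                             excluded_keywords = character(),
                             threshold = 0.05,
                             min_count = 300,
                             alpha = 0.05) {
  list(topic_keywords = topic_keywords,
       promo_id_keywords = promo_id_keywords,
       promo_body_keywords = promo_body_keywords,
       excluded_keywords = excluded_keywords,
       threshold = threshold, min_count = min_count, alpha = alpha)
}

new_manifest <- function(stages, config) {
  structure(list(stages = stages, config = config,
                 package_version = as.character(utils::packageVersion("flavorwatch")),
                 started = attr(stages, "started"),
                 finished = Sys.time()),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> flavorwatch", x$package_version, "\n")
  print(as.data.frame(x$stages))
  invisible(x)
}

stage_row <- function(stage, n_in, n_out) {
  tibble::tibble(stage = stage, n_in = n_in, n_out = n_out,
                 n_removed = n_in - n_out)
}

#' Trend workflow: topic filter, mention extraction, monthly normalization
#'
#' Runs the longitudinal-trend analysis end to end: topic-keyword filter,
#' optional promotion filter, flavor-mention extraction with the denoise
#' exclusion set, monthly per-category counting and per-month
#' normalization, plus a subcategory percentage table per category. Every
#' stage's input/output counts are recorded in the run manifest, so the
#' corpus funnel is fully attributable. An empty corpus after a filter
#' stage is an error naming the stage; a filtered corpus with no flavor
#' mentions yields an all-zero table with a warning.
#'
#' @param posts Post tibble (see [read_posts()]).
#' @param tax A `flavor_taxonomy`.
#' @param config A [trend_config()].
#' @return List: `trend` (normalized monthly table), `subcategories`
#'   (named list of per-category percentage tables), `mentions`,
#'   `manifest`.
#' @export
run_trends <- function(posts, tax = load_taxonomy(),
                       config = trend_config()) {
  started <- Sys.time()
  stages <- stage_row("input", nrow(posts), nrow(posts))

  on_topic <- posts[match_topic(posts, config$topic_keywords), , drop = FALSE]
  stages <- dplyr::bind_rows(stages,
    stage_row("topic_filter", nrow(posts), nrow(on_topic)))
  if (nrow(on_topic) == 0) {
    rlang::abort("no posts remain after stage 'topic_filter'")
  }

  if (isTRUE(config$apply_promo_filter)) {
    pf <- filter_promotions(on_topic, config$promo_id_keywords,
                            config$promo_body_keywords)
    stages <- dplyr::bind_rows(stages,
      stage_row("promo_filter_handle", nrow(on_topic),
                nrow(on_topic) - nrow(pf$removed_step1)),
      stage_row("promo_filter_body",
                nrow(on_topic) - nrow(pf$removed_step1), nrow(pf$posts)))
    on_topic <- pf$posts
    if (nrow(on_topic) == 0) {
      rlang::abort("no posts remain after stage 'promo_filter'")
    }
  }

  mentions <- extract_mentions(on_topic, tax,
                               excluded = config$excluded_keywords)
  stages <- dplyr::bind_rows(stages,
    stage_row("mention_extraction", nrow(on_topic),
              length(unique(mentions$post_id))))
  if (nrow(mentions) == 0) {
    rlang::warn("no flavor mentions found; trend table is all zeros")
  }

  counts <- monthly_counts(mentions, on_topic,
                           from = config$from, to = config$to)
  trend <- normalize_trends(counts)
  subcats <- lapply(stats::setNames(nm = flavor_categories()),
                    function(cat) subcategory_percentages(mentions, cat))

  attr(stages, "started") <- started
  list(trend = trend, subcategories = subcats, mentions = mentions,
       manifest = new_manifest(stages, config))
}

#' Sentiment workflow: filtering, scoring, aggregation, proportion tests
#'
#' Runs the per-category sentiment analysis end to end: topic-keyword
#' filter, two-step promotion filter, single-flavor subsetting (posts with
#' exactly one distinct flavor keyword), valence scoring through the
#' injected scorer, per-category aggregation with the minimum-count flag,
#' and positive-vs-negative pooled two-proportion z-tests with Bonferroni
#' adjustment across the tested categories. Stage counts go to the run
#' manifest; an empty corpus after any stage is an error naming the stage.
#'
#' @param posts Post tibble.
#' @param tax A `flavor_taxonomy`.
#' @param scorer Valence scorer function (see [score_posts()]).
#' @param config A [sentiment_config()].
#' @return List: `categories` (per-category sentiment summary), `tests`
#'   (proportion-test table), `scores` (per-post scores), `manifest`.
#' @export
run_sentiment <- function(posts, tax = load_taxonomy(),
                          scorer = stub_valence_scorer(),
                          config = sentiment_config()) {
  started <- Sys.time()
  stages <- stage_row("input", nrow(posts), nrow(posts))

  on_topic <- posts[match_topic(posts, config$topic_keywords), , drop = FALSE]
  stages <- dplyr::bind_rows(stages,
    stage_row("topic_filter", nrow(posts), nrow(on_topic)))
  if (nrow(on_topic) == 0) {
    rlang::abort("no posts remain after stage 'topic_filter'")
  }

  pf <- filter_promotions(on_topic, config$promo_id_keywords,
                          config$promo_body_keywords)
  stages <- dplyr::bind_rows(stages,
    stage_row("promo_filter_handle", nrow(on_topic),
              nrow(on_topic) - nrow(pf$removed_step1)),
    stage_row("promo_filter_body",
              nrow(on_topic) - nrow(pf$removed_step1), nrow(pf$posts)))
  if (nrow(pf$posts) == 0) {
    rlang::abort("no posts remain after stage 'promo_filter'")
  }

  singles <- single_flavor_subset(pf$posts, tax,
                                  excluded = config$excluded_keywords)
  stages <- dplyr::bind_rows(stages,
    stage_row("single_flavor_subset", nrow(pf$posts), nrow(singles)))
  if (nrow(singles) == 0) {
    rlang::abort("no posts remain after stage 'single_flavor_subset'")
  }

  scores <- score_posts(singles, scorer = scorer,
                        threshold = config$threshold)
  categories <- aggregate_category(
    scores,
    tibble::tibble(post_id = singles$id, category = singles$flavor_category),
    min_count = config$min_count)
  tests <- proportion_tests(categories, alpha = config$alpha)

  attr(stages, "started") <- started
  list(categories = categories, tests = tests, scores = scores,
       manifest = new_manifest(stages, config))
}
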