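#' Configuration for the synthetic corpus generator
#'
#' Defines the statistical structure of a generated post corpus: how many
#' posts, over which calendar months, the multinomial distribution of
#' flavor categories, the per-category positive/neutral/negative sentiment
#' mix, and the fractions of promotional, multi-flavor and noisy-keyword
#' posts. Defaults emulate the corpus structure the pipeline is built for:
#' the category distribution follows the published Reddit flavor-mention
#' shares (fruit ~0.58, sweets ~0.15, ...), and the sentiment mixes are
#' positive-leaning for fruit/sweets/menthol-mint and negative-leaning for
#' beverage/tobacco, mirroring the reported direction of Twitter sentiment.
#'
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @param n_posts Number of posts.
#' @param date_range Character `c("YYYY-MM", "YYYY-MM")`, first and last
#'   month (inclusive).
#' @param category_distribution Named probabilities over the seven
#'   categories; must sum to 1.
#' @param monthly_trend Optional named per-category linear drift: the
#'   category's probability moves by +/- `trend/2` from the first to the
#'   last month (renormalized per month).
#' @param promo_fraction Fraction of promotional posts (half detectable by
#'   handle, half by body keywords).
#' @param noisy_keyword_fraction Fraction of posts that mention
#'   `noisy_keyword`.
#' @param noisy_keyword,noisy_category An ambiguous keyword and the
#'   category it belongs to; it must be present in the taxonomy passed to
#'   [generate_corpus()] for extraction to see it.
#' @param noisy_precision Probability that a noisy-keyword post uses the
#'   word in its flavor sense (the planted labeling precision).
#' @param sentiment_mix Named list mapping each category to
#'   `c(pos, neu, neg)` probabilities summing to 1.
#' @param multi_flavor_fraction Fraction of flavor posts carrying a second
#'   keyword from a different category.
#' @param platform `"reddit"`, `"twitter"` or `"other"`.
#' @return A validated `generator_config` object (list).
#' @export
generator_config <- function(seed = 1L,
                             n_posts = 1000L,
                             date_range = c("2013-01", "2019-04"),
                             category_distribution = c(
                               fruit = 0.5821, sweets = 0.1469,
                               beverage = 0.1016, menthol_or_mint = 0.0843,
                               tobacco = 0.0599, others = 0.0161,
                               mixed = 0.0091),
                             monthly_trend = NULL,
                             promo_fraction = 0.1,
                             noisy_keyword_fraction = 0,
                             noisy_keyword = "punch",
                             noisy_category = "beverage",
                             noisy_precision = 0.8,
                             sentiment_mix = default_sentiment_mix(),
                             multi_flavor_fraction = 0.05,
                             platform = "reddit") {
  cfg <- list(seed = as.integer(seed), n_posts = as.integer(n_posts),
              date_range = date_range,
              category_distribution = category_distribution,
              monthly_trend = monthly_trend,
              promo_fraction = promo_fraction,
              noisy_keyword_fraction = noisy_keyword_fraction,
              noisy_keyword = norm_keyword(noisy_keyword),
              noisy_category = noisy_category,
              noisy_precision = noisy_precision,
              sentiment_mix = sentiment_mix,
              multi_flavor_fraction = multi_flavor_fraction,
              platform = platform)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

default_sentiment_mix <- function() {
  list(fruit = c(0.50, 0.30, 0.20),
       sweets = c(0.50, 0.30, 0.20),
       menthol_or_mint = c(0.50, 0.30, 0.20),
       beverage = c(0.25, 0.30, 0.45),
       tobacco = c(0.25, 0.30, 0.45),
       others = c(1, 1, 1) / 3,
       mixed = c(1, 1, 1) / 3)
}

validate_generator_config <- function(cfg) {
  p <- cfg$category_distribution
  if (!setequal(names(p), flavor_categories())) {
    rlang::abort("category_distribution must name all seven categories")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    rlang::abort("category_distribution must be probabilities summing to 1")
  }
  for (cat in names(cfg$sentiment_mix)) {
    m <- cfg$sentiment_mix[[cat]]
    if (length(m) != 3 || any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      rlang::abort(paste0("sentiment_mix for '", cat,
                          "' must be 3 probabilities summing to 1"))
    }
  }
  for (f in c("promo_fraction", "noisy_keyword_fraction",
              "noisy_precision", "multi_flavor_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      rlang::abort(paste0(f, " must be in [0, 1]"))
    }
  }
  if (cfg$n_posts < 0) rlang::abort("n_posts must be non-negative")
  invisible(cfg)
}

# scoped RNG: seed the generator, restore global state on exit
with_rng <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic post corpus with a ground-truth ledger
#'
#' Composes template posts that embed taxonomy flavor keywords (including
#' hashtag and multi-word forms) per the configured category distribution,
#' promotion posts detectable by handle or body keywords, optional
#' ambiguous noisy-keyword posts, and sentiment cue words with planted
#' valences readable by [stub_valence_scorer()]. Every post carries a topic
#' keyword, emulating a corpus already reduced to the e-cigarette subset.
#' The ledger records the planted truth for every post exactly once, so
#' pipeline output can be checked against known parameters.
#'
#' @param config A [generator_config()].
#' @param tax Taxonomy supplying the keyword pools; when
#'   `noisy_keyword_fraction > 0` it should contain the noisy keyword (see
#'   [load_taxonomy()] with a data-frame input to extend the bundled one).
#' @return List with `posts` (tibble in [read_posts()] layout), `ledger`
#'   (tibble: `post_id`, `month`, `category`, `keyword`, `keyword2`,
#'   `promo`, `promo_step`, `label`, `valence`, `noisy`, `is_relevant`) and
#'   `config`.
#' @examples
#' corp <- generate_corpus(generator_config(seed = 7, n_posts = 50))
#' table(corp$ledger$category)
#' @export
generate_corpus <- function(config = generator_config(),
                            tax = load_taxonomy()) {
  validate_generator_config(config)
  with_rng(config$seed, {
    n <- config$n_posts
    cats <- flavor_categories()
    kw_pool <- split(tax$table$keyword, tax$table$category)

    span <- month_span(tibble::tibble(), config$date_range[[1]],
                       config$date_range[[2]])
    n_months <- nrow(span)
    month_idx <- sample.int(n_months, n, replace = TRUE)

    # per-post category probabilities, with optional linear drift
    base_p <- config$category_distribution[cats]
    category <- character(n)
    if (is.null(config$monthly_trend) || n_months == 1) {
      if (n > 0) category <- sample(cats, n, replace = TRUE, prob = base_p)
    } else {
      tfrac <- (month_idx - 1) / (n_months - 1)
      drift <- stats::setNames(rep(0, length(cats)), cats)
      drift[names(config$monthly_trend)] <- config$monthly_trend
      for (i in seq_len(n)) {
        p <- pmax(base_p + drift * (tfrac[[i]] - 0.5), 0)
        category[[i]] <- sample(cats, 1, prob = p / sum(p))
      }
    }

    role <- sample(c("promo", "post"), n, replace = TRUE,
                   prob = c(config$promo_fraction, 1 - config$promo_fraction))
    noisy <- role == "post" &
      stats::runif(n) < config$noisy_keyword_fraction
    relevant <- !noisy | stats::runif(n) < config$noisy_precision

    keyword <- character(n)
    keyword2 <- rep(NA_character_, n)
    label <- rep(NA_character_, n)
    valence <- rep(NA_real_, n)
    author <- sprintf("user%05d", sample.int(99999, n, replace = TRUE))
    text <- character(n)
    promo_step <- rep(NA_character_, n)

    pos_cues <- c("amazing", "delicious", "love", "fantastic", "smooth")
    neg_cues <- c("awful", "hate", "nasty", "disgusting", "harsh")
    cue_val <- sentiment_cues()
    topic_tokens <- c("vaping", "#vaping", "ejuice", "vape", "juul",
                      "e-liquid", "#vapenation")
    openers <- c("just tried", "picked up", "quick take on",
                 "today i tested", "been running")
    promo_handles <- c("bestvapestoreUS", "dailyejuicedeals",
                       "cloudsupplyco", "vapedealer24")
    promo_bodies <- c("big sale this weekend on every pod",
                      "discount for every new customer today",
                      "free shipping on all orders this month",
                      "summer promotion now live in our shop")

    for (i in seq_len(n)) {
      topic <- sample(topic_tokens, 1)
      if (role[[i]] == "promo") {
        category[[i]] <- NA_character_
        by_handle <- stats::runif(1) < 0.5
        if (by_handle) {
          author[[i]] <- sample(promo_handles, 1)
          promo_step[[i]] <- "handle"
          text[[i]] <- paste("new stock just landed, grab your", topic, "now")
        } else {
          promo_step[[i]] <- "body"
          text[[i]] <- paste(sample(promo_bodies, 1), topic)
        }
        next
      }
      if (noisy[[i]]) {
        keyword[[i]] <- config$noisy_keyword
        category[[i]] <- config$noisy_category
      } else {
        keyword[[i]] <- sample(kw_pool[[category[[i]]]], 1)
      }
      mix <- config$sentiment_mix[[category[[i]]]]
      lab <- sample(c("positive", "neutral", "negative"), 1, prob = mix)
      label[[i]] <- lab
      cue <- switch(lab,
                    positive = sample(pos_cues, 1),
                    negative = sample(neg_cues, 1),
                    neutral = NA_character_)
      valence[[i]] <- if (is.na(cue)) 0 else cue_val[[cue]]
      cue_phrase <- switch(lab,
                           positive = paste("so", cue),
                           negative = paste("so", cue),
                           neutral = "will post impressions later")
      kw_surface <- keyword[[i]]
      if (!grepl(" ", kw_surface, fixed = TRUE) && stats::runif(1) < 0.3) {
        kw_surface <- paste0("#", kw_surface)
      }
      if (noisy[[i]] && !relevant[[i]]) {
        text[[i]] <- paste("that last cloud comp felt like a", kw_surface,
                           "straight to the chest,", topic, "crowd was wild")
      } else {
        body <- paste(sample(openers, 1), "the", kw_surface, "flavor in my",
                      topic, "setup,", cue_phrase)
        if (!noisy[[i]] && stats::runif(1) < config$multi_flavor_fraction) {
          other_cats <- setdiff(cats[lengths(kw_pool[cats]) > 0],
                                category[[i]])
          cat2 <- sample(other_cats, 1)
          keyword2[[i]] <- sample(kw_pool[[cat2]], 1)
          body <- paste(body, "and a bit of", keyword2[[i]], "on the side")
        }
        text[[i]] <- body
      }
    }

    days <- lubridate::days_in_month(
      as.Date(sprintf("%04d-%02d-01", span$year, span$month)))[month_idx]
    month_start <- as.POSIXct(sprintf("%04d-%02d-01", span$year[month_idx],
                                      span$month[month_idx]), tz = "UTC")
    created <- month_start + floor(stats::runif(n) * (days * 86400 - 1))

    ids <- sprintf("p%06d", seq_len(n))
    posts <- tibble::tibble(
      id = ids, platform = rep(config$platform, n), author = author,
      created_utc = created, text = text)
    ledger <- tibble::tibble(
      post_id = ids,
      month = sprintf("%04d-%02d", span$year[month_idx],
                      span$month[month_idx]),
      category = category, keyword = dplyr::na_if(keyword, ""),
      keyword2 = keyword2,
      promo = role == "promo", promo_step = promo_step,
      label = label, valence = valence, noisy = noisy,
      is_relevant = ifelse(role == "promo", NA, relevant))
    list(posts = posts, ledger = ledger, config = config)
  })
}

#' Export keyword labels from a ground-truth ledger
#'
#' Turns the generator's ledger into the labeled-sample format the denoise
#' harness consumes: one row per (post, keyword) for each requested
#' keyword, with `is_relevant` 1/0 as planted.
#'
#' @param ledger Ledger tibble from [generate_corpus()].
#' @param keywords Keywords to export labels for; defaults to all non-promo
#'   planted keywords.
#' @return Tibble `post_id`, `keyword`, `is_relevant`.
#' @export
ledger_labels <- function(ledger, keywords = NULL) {
  lg <- ledger[!ledger$promo & !is.na(ledger$keyword), , drop = FALSE]
  if (!is.null(keywords)) {
    lg <- lg[lg$keyword %in% norm_keyword(keywords), , drop = FALSE]
  }
  tibble::tibble(post_id = lg$post_id, keyword = lg$keyword,
                 is_relevant = as.integer(lg$is_relevant))
}
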