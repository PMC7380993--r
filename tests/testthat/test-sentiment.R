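test_that("threshold labels assign boundaries outward and 0 to neutral", {
  expect_equal(sentiment_label(c(0.05, -0.05, 0, 1, -1, 0.0499, -0.0499)),
               c("positive", "negative", "neutral", "positive", "negative",
                 "neutral", "neutral"))
})

test_that("scorer contract violations are errors", {
  posts <- make_posts("anything")
  expect_error(score_posts(posts, scorer = function(t) rep(1.5, length(t))),
               "contract")
  expect_error(score_posts(posts, scorer = function(t) numeric(0)),
               "contract")
})

test_that("stub scorer reads planted cue valences deterministically", {
  sc <- stub_valence_scorer()
  expect_equal(sc(c("this is so amazing", "so awful really",
                    "no cue words at all")),
               c(0.7, -0.7, 0))
  # token boundary: cue inside a longer word does not fire
  expect_equal(sc("smoothie texture"), 0)
})

test_that("lexicon scorer averages matched words and honors negators", {
  sc <- lexicon_valence_scorer()
  expect_gt(sc("this is good"), 0)
  expect_lt(sc("this is not good"), 0)
  expect_equal(sc("completely neutral text"), 0)
  expect_true(all(abs(sc(c("best best best", "worst worst"))) <= 1))
})

test_that("category aggregation computes means, sample SD and proportions", {
  scores <- tibble::tibble(post_id = c("a", "b", "c", "d"),
                           score = c(0.5, -0.5, 0.5, 0.5),
                           label = sentiment_label(c(0.5, -0.5, 0.5, 0.5)))
  cats <- tibble::tibble(post_id = c("a", "b", "c", "d"),
                         category = c("fruit", "fruit", "fruit", "fruit"))
  agg <- aggregate_category(scores, cats, min_count = 2)
  expect_equal(agg$n_posts, 4L)
  expect_equal(agg$mean_score, 0.25)
  expect_equal(agg$sd_score, sd(c(0.5, -0.5, 0.5, 0.5)))
  expect_equal(agg$prop_pos, 0.75)
  expect_equal(agg$prop_neg, 0.25)
  expect_equal(agg$prop_pos + agg$prop_neu + agg$prop_neg, 1, tolerance = 1e-9)
  expect_false(agg$flagged)
  # two-score symmetric case
  s2 <- tibble::tibble(post_id = c("x", "y"), score = c(0.5, -0.5),
                       label = sentiment_label(c(0.5, -0.5)))
  c2 <- tibble::tibble(post_id = c("x", "y"), category = "sweets")
  a2 <- aggregate_category(s2, c2, min_count = 1)
  expect_equal(a2$mean_score, 0)
  expect_equal(a2$prop_pos, 0.5)
  expect_equal(a2$prop_neg, 0.5)
  # low-count categories are flagged
  a3 <- aggregate_category(s2, c2, min_count = 300)
  expect_true(a3$flagged)
})

test_that("aggregation is permutation-invariant and conserves counts", {
  set.seed(17)
  n <- 200
  scores <- tibble::tibble(post_id = sprintf("p%03d", 1:n),
                           score = runif(n, -1, 1))
  scores$label <- sentiment_label(scores$score)
  cats <- tibble::tibble(post_id = scores$post_id,
                         category = sample(c("fruit", "sweets"), n, TRUE))
  a1 <- aggregate_category(scores, cats, min_count = 1)
  perm <- sample(n)
  a2 <- aggregate_category(scores[perm, ], cats, min_count = 1)
  expect_equal(a1, a2)
  expect_equal(a1$n_pos + a1$n_neu + a1$n_neg, a1$n_posts)
  expect_equal(sum(a1$n_posts), n)
})

test_that("planted sentiment mixes are recovered within binomial error", {
  mix <- list(fruit = c(0.7, 0.2, 0.1), sweets = c(0.7, 0.2, 0.1),
              menthol_or_mint = c(0.7, 0.2, 0.1),
              beverage = c(0.7, 0.2, 0.1), tobacco = c(0.7, 0.2, 0.1),
              others = c(0.7, 0.2, 0.1), mixed = c(0.7, 0.2, 0.1))
  corp <- generate_corpus(generator_config(
    seed = 23, n_posts = 3000, promo_fraction = 0,
    multi_flavor_fraction = 0, sentiment_mix = mix))
  scores <- score_posts(corp$posts, stub_valence_scorer())
  # stub labels equal planted labels exactly
  expect_equal(scores$label, corp$ledger$label)
  props <- prop.table(table(scores$label))
  for (lab in c("positive", "neutral", "negative")) {
    p <- c(positive = 0.7, neutral = 0.2, negative = 0.1)[[lab]]
    se <- sqrt(p * (1 - p) / 3000)
    expect_lt(abs(props[[lab]] - p), 3 * se)
  }
})
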