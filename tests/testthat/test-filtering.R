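test_that("topic matching respects token boundaries, case and hashtags", {
  expect_true(match_topic("I love my JUUL"))
  expect_false(match_topic("grapevine festival", keywords = "vape"))
  expect_true(match_topic("#vaping all day"))
  expect_false(match_topic("nothing relevant here"))
  # hyphenated keywords match as whole tokens only
  expect_true(match_topic("my e-cig broke", keywords = "e-cig"))
  expect_false(match_topic("my e-cigs broke", keywords = "e-cig"))
})

test_that("promotion filtering removes by handle then body, conserving counts", {
  posts <- make_posts(
    c("new mango pods in stock", "20% discount this week",
      "this mango pod is great", "free shipping on everything"),
    authors = c("BestVapeStore", "jane_doe", "jane_doe", "bob"))
  res <- filter_promotions(posts)
  expect_equal(res$removed_step1$author, "BestVapeStore")
  expect_setequal(res$removed_step2$id, c("t002", "t004"))
  expect_equal(res$posts$text, "this mango pod is great")
  expect_equal(nrow(posts),
               nrow(res$posts) + nrow(res$removed_step1) + nrow(res$removed_step2))
})

test_that("mention extraction is longest-match-first at token boundaries", {
  tax <- mini_taxonomy()
  m <- extract_mentions("strawberry custard all day", tax)
  expect_equal(m$canonical, c("strawberry", "custard"))
  expect_equal(m$category, c("fruit", "sweets"))
  # overlapping keywords: only the longer match survives
  m2 <- extract_mentions("i adore cotton candy now", tax)
  expect_equal(m2$canonical, "cotton candy")
  # no mentions
  expect_equal(nrow(extract_mentions("no flavors here", tax)), 0)
  # spans index the original text, 0-based half-open, case-folding to the match
  text <- "Cotton Candy #strawberry"
  m3 <- extract_mentions(text, tax)
  for (i in seq_len(nrow(m3))) {
    expect_equal(tolower(substr(text, m3$start[i] + 1, m3$end[i])),
                 m3$keyword[i])
  }
  expect_setequal(m3$canonical, c("cotton candy", "strawberry"))
})

test_that("enlarging the exclusion set never increases mention counts", {
  tax <- mini_taxonomy()
  texts <- c("strawberry custard", "mango and melon", "candy candy candy",
             "apple juice with menthol", "cigar lounge", "nothing")
  kws <- unique(tax$table$keyword)
  prev <- nrow(extract_mentions(texts, tax))
  for (k in seq_along(kws)) {
    cur <- nrow(extract_mentions(texts, tax, excluded = kws[seq_len(k)]))
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 0)
})

test_that("keyword evaluation reproduces confusion-matrix arithmetic", {
  # planted counts: tp=18 fp=2 fn=2 -> precision .90 recall .90 -> keep
  mk_case <- function(tp, fp, fn) {
    n <- tp + fp + fn
    ids <- sprintf("s%03d", seq_len(n))
    labels <- tibble::tibble(
      post_id = ids, keyword = "melon",
      is_relevant = c(rep(1, tp), rep(0, fp), rep(1, fn)))
    mentions <- tibble::tibble(post_id = ids[seq_len(tp + fp)],
                               canonical = "melon")
    evaluate_keyword("melon", labels, mentions)
  }
  keep <- mk_case(18, 2, 2)
  expect_equal(keep$precision, 0.90)
  expect_equal(keep$recall, 0.90)
  expect_equal(keep$decision, "keep")
  # precision passes but recall 19/29 = 0.655 fails
  rec <- mk_case(19, 1, 10)
  expect_equal(rec$precision, 0.95)
  expect_equal(rec$recall, 19 / 29, tolerance = 1e-12)
  expect_equal(rec$decision, "exclude")
  # degenerate: no labeled positives or predictions
  deg <- evaluate_keyword("melon",
    tibble::tibble(post_id = "x", keyword = "melon", is_relevant = 0),
    tibble::tibble(post_id = character(), canonical = character()))
  expect_true(is.na(deg$precision) && is.na(deg$recall))
  expect_equal(deg$decision, "exclude")
})

test_that("evaluate_keyword matches brute-force confusion matrices on a random corpus", {
  tax <- mini_taxonomy()
  set.seed(31)
  kws <- c("strawberry", "mango", "candy")
  n <- 60
  texts <- vapply(seq_len(n), function(i) {
    kw <- sample(c(kws, "nothing here"), 1)
    paste("post about", kw, "today")
  }, character(1))
  posts <- make_posts(texts)
  labels <- dplyr::bind_rows(lapply(kws, function(kw) {
    tibble::tibble(post_id = posts$id, keyword = kw,
                   is_relevant = rbinom(n, 1, 0.5))
  }))
  mentions <- extract_mentions(posts, tax)
  for (kw in kws) {
    got <- evaluate_keyword(kw, labels, mentions)
    # independent brute force over every labeled post
    lab <- labels[labels$keyword == kw, ]
    tp <- fp <- fn <- 0
    for (j in seq_len(nrow(lab))) {
      predicted <- any(mentions$post_id == lab$post_id[j] &
                         mentions$canonical == kw)
      rel <- lab$is_relevant[j] == 1
      if (predicted && rel) tp <- tp + 1
      if (predicted && !rel) fp <- fp + 1
      if (!predicted && rel) fn <- fn + 1
    }
    expect_equal(c(got$tp, got$fp, got$fn), c(tp, fp, fn))
    expect_equal(got$decision,
                 if (tp + fp > 0 && tp + fn > 0 && tp / (tp + fp) >= 0.9 &&
                       tp / (tp + fn) >= 0.75) "keep" else "exclude")
  }
})

test_that("single-flavor subset keeps exactly-one-distinct-keyword posts", {
  tax <- mini_taxonomy()
  posts <- make_posts(c("this mango pod is great",
                        "mango and menthol together",
                        "mango mango mango",
                        "no flavor talk"))
  out <- single_flavor_subset(posts, tax)
  expect_setequal(out$id, c("t001", "t003"))
  expect_equal(unique(out$flavor_keyword), "mango")
  expect_equal(unique(out$flavor_category), "fruit")
})

test_that("filtering results are order-independent sets", {
  tax <- mini_taxonomy()
  posts <- make_posts(
    c("strawberry day", "discount mango", "custard #vaping", "plain post"),
    authors = c("u1", "vapestore", "u3", "u4"))
  set.seed(5)
  shuf <- posts[sample(nrow(posts)), ]
  a <- extract_mentions(posts, tax)
  b <- extract_mentions(shuf, tax)
  expect_equal(dplyr::arrange(a, post_id, start),
               dplyr::arrange(b, post_id, start))
  fa <- filter_promotions(posts)
  fb <- filter_promotions(shuf)
  expect_setequal(fa$posts$id, fb$posts$id)
  expect_setequal(fa$removed_step1$id, fb$removed_step1$id)
})
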