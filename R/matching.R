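# Token-boundary keyword matching.
#
# All matching is done on a normalized copy of the text: lower-cased, with
# '#' replaced by a space so hashtag prefixes are stripped without shifting
# character offsets. A keyword matches at token boundaries: the characters
# immediately before and after the match must not be letters or digits.
# Multi-word keywords match across single spaces. Spans therefore index the
# original text (0-based, half-open) and the covered slice case-folds to the
# matched surface.

norm_text <- function(text) {
  stringr::str_replace_all(stringr::str_to_lower(text), stringr::fixed("#"), " ")
}

norm_keyword <- function(kw) {
  stringr::str_squish(stringr::str_to_lower(kw))
}

keyword_pattern <- function(keyword) {
  esc <- stringr::str_replace_all(keyword, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
  stringr::regex(paste0("(?<![\\p{L}\\p{N}])", esc, "(?![\\p{L}\\p{N}])"))
}

# Locate all token-boundary occurrences of each keyword in each text.
# Returns a tibble: text_idx, keyword, start, end (0-based half-open).
locate_keywords <- function(texts, keywords) {
  norm <- norm_text(texts)
  out <- vector("list", length(keywords))
  for (i in seq_along(keywords)) {
    kw <- keywords[[i]]
    # cheap substring prefilter before the boundary regex
    cand <- which(stringr::str_detect(norm, stringr::fixed(kw)))
    if (length(cand) == 0) next
    loc <- stringr::str_locate_all(norm[cand], keyword_pattern(kw))
    n_hit <- vapply(loc, nrow, integer(1))
    keep <- n_hit > 0
    if (!any(keep)) next
    mat <- do.call(rbind, loc[keep])
    out[[i]] <- tibble::tibble(
      text_idx = rep(cand[keep], n_hit[keep]),
      keyword = kw,
      start = mat[, 1] - 1L,   # to 0-based half-open
      end = mat[, 2]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(text_idx = integer(), keyword = character(),
                          start = integer(), end = integer()))
  }
  res
}

# Detect whether any keyword matches each text (token-boundary rule).
detect_any_keyword <- function(texts, keywords) {
  norm <- norm_text(texts)
  hit <- rep(FALSE, length(texts))
  for (kw in keywords) {
    rest <- which(!hit)
    if (length(rest) == 0) break
    cand <- rest[stringr::str_detect(norm[rest], stringr::fixed(kw))]
    if (length(cand) == 0) next
    hit[cand] <- stringr::str_detect(norm[cand], keyword_pattern(kw))
  }
  hit
}

# Greedy longest-match-first resolution of overlapping matches within one
# text. `m` is a tibble with start/end; returns the retained row indices.
resolve_overlaps <- function(start, end) {
  ord <- order(-(end - start), start)
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(length(start))
  for (i in ord) {
    s <- start[i]; e <- end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  which(keep)
}
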