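# Valence scorers. Any function `character -> numeric in [-1, 1]` satisfies
# the scorer contract; these two are bundled so the pipeline is exercisable
# without an external sentiment model.

# cue words the synthetic generator plants; valences are fixed by design so
# the stub scorer can read them back deterministically.
sentiment_cues <- function() {
  c(amazing = 0.7, delicious = 0.6, love = 0.6, fantastic = 0.7,
    smooth = 0.4, awful = -0.7, hate = -0.6, nasty = -0.6,
    disgusting = -0.7, harsh = -0.4)
}

#' Deterministic stub valence scorer
#'
#' Reads the valence a synthetic post carries in its text: the generator
#' plants at most one cue word per post from a fixed cue table
#' (`love` = +0.6, `awful` = -0.7, ...), and this scorer returns the sum of
#' cue valences found at token boundaries (0 when none), clipped to
#' \[-1, 1\]. Deterministic and lexicon-independent, so end-to-end tests
#' recover planted sentiment proportions exactly.
#'
#' @return A scorer function `character -> numeric`.
#' @export
stub_valence_scorer <- function() {
  cues <- sentiment_cues()
  function(texts) {
    score <- rep(0, length(texts))
    norm <- norm_text(texts)
    for (i in seq_along(cues)) {
      kw <- names(cues)[[i]]
      hit <- stringr::str_detect(norm, keyword_pattern(kw))
      score <- score + ifelse(hit, cues[[i]], 0)
    }
    pmin(1, pmax(-1, score))
  }
}

#' Simple lexicon valence scorer
#'
#' A small lexicon-and-rules scorer for real text: the mean valence of
#' lexicon words found at token boundaries (0 when none), with a negator
#' (`not`, `no`, `never`, `don't`, `doesn't`, `isn't`, `can't`, `won't`)
#' immediately before a lexicon word flipping its sign. This is a compact
#' general-purpose word list, not a tuned sentiment model; for production
#' surveillance inject a full lexicon-and-rules analyzer through the scorer
#' contract instead.
#'
#' @return A scorer function `character -> numeric`.
#' @export
lexicon_valence_scorer <- function() {
  lex <- c(sentiment_cues(),
    good = 0.5, great = 0.6, excellent = 0.7, best = 0.6, tasty = 0.5,
    nice = 0.4, perfect = 0.7, favorite = 0.5, enjoy = 0.5, happy = 0.5,
    wonderful = 0.6, sweet = 0.3, fresh = 0.3, recommend = 0.4, like = 0.3,
    bad = -0.5, worst = -0.7, terrible = -0.7, horrible = -0.7,
    gross = -0.6, bland = -0.3, weak = -0.3, stale = -0.4, burnt = -0.4,
    disappointing = -0.5, avoid = -0.4, sick = -0.4, dislike = -0.4,
    bitter = -0.3, overpriced = -0.4)
  negators <- c("not", "no", "never", "don't", "doesn't", "isn't",
                "can't", "won't")
  function(texts) {
    norm <- norm_text(texts)
    tokens <- stringr::str_split(norm, "[^\\p{L}\\p{N}']+")
    vapply(tokens, function(tok) {
      tok <- tok[tok != ""]
      idx <- match(tok, names(lex))
      found <- which(!is.na(idx))
      if (length(found) == 0) return(0)
      vals <- lex[idx[found]]
      neg <- found > 1 & tok[pmax(found - 1, 1)] %in% negators
      vals[neg] <- -vals[neg]
      pmin(1, pmax(-1, mean(vals)))
    }, numeric(1))
  }
}
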