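#' flavorwatch: social-media surveillance of e-liquid flavor mentions
#'
#' Tools for monitoring discussion of electronic-cigarette liquid flavors on
#' social media: a hierarchical flavor-keyword taxonomy, staged corpus
#' filtering (topic keywords, promotion removal, precision/recall keyword
#' denoising, single-flavor subsetting), monthly mention-trend tables,
#' threshold-based sentiment classification with an injectable valence
#' scorer, pooled two-proportion z-tests with Bonferroni adjustment, and a
#' seeded synthetic-corpus generator with a ground-truth ledger.
#'
#' @keywords internal
"_PACKAGE"

#' The seven top-level flavor categories
#'
#' Fixed category set used throughout: `fruit`, `sweets`, `beverage`,
#' `tobacco`, `menthol_or_mint`, `mixed`, `others`. Trend normalization
#' always reports all seven so months are comparable.
#'
#' @return Character vector of the seven category names.
#' @export
flavor_categories <- function() {
  c("fruit", "sweets", "beverage", "tobacco", "menthol_or_mint",
    "mixed", "others")
}

#' Round half-up
#'
#' Rounds halves away from zero (so 0.125 -> 0.13 at 2 digits), matching the
#' conventional presentation of percentage tables, rather than base R's
#' round-half-even. A small epsilon guards against binary representation of
#' decimal halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# path to a bundled config file
fw_extdata <- function(file) {
  path <- system.file("extdata", file, package = "flavorwatch")
  if (identical(path, "")) {
    rlang::abort(paste0("bundled file not found: ", file))
  }
  path
}

#' Read a one-keyword-per-line configuration file
#'
#' Keyword-set configs (topic keywords, promotion keywords, exclusion lists)
#' are plain UTF-8 text, one keyword per line; blank lines and lines starting
#' with `#` are ignored. Keywords are lower-cased and whitespace-normalized.
#'
#' @param path Path to the file.
#' @return Character vector of keywords.
#' @export
read_keyword_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_squish(stringr::str_to_lower(lines))
  kws <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (anyDuplicated(kws)) {
    rlang::abort(paste0("duplicate keywords in ", path, ": ",
                        paste(unique(kws[duplicated(kws)]), collapse = ", ")))
  }
  kws
}

#' Default keyword sets
#'
#' The bundled keyword configurations: `default_topic_keywords()` returns the
#' 20 e-cigarette topic keywords used to pull e-cigarette posts out of a raw
#' corpus; `default_promo_id_keywords()` the handle substrings that mark
#' promotional accounts (step 1 of promotion filtering);
#' `default_promo_body_keywords()` the five promotion body keywords
#' (step 2). All are plain-text files under `inst/extdata/` and can be
#' replaced by user files via [read_keyword_file()].
#'
#' @return Character vector of keywords.
#' @export
default_topic_keywords <- function() {
  read_keyword_file(fw_extdata("topic_keywords.txt"))
}

#' @rdname default_topic_keywords
#' @export
default_promo_id_keywords <- function() {
  read_keyword_file(fw_extdata("promo_id_keywords.txt"))
}

#' @rdname default_topic_keywords
#' @export
default_promo_body_keywords <- function() {
  read_keyword_file(fw_extdata("promo_body_keywords.txt"))
}
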