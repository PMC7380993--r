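#' Monthly per-category mention counts
#'
#' Counts flavor mentions per UTC calendar month and top-level category.
#' Every month inside the requested range appears for all seven categories,
#' zero-filled, so trend tables are rectangular and months comparable.
#'
#' @param mentions Mention tibble from [extract_mentions()].
#' @param posts Post tibble supplying timestamps; every `post_id` in
#'   `mentions` must be present.
#' @param from,to Optional `"YYYY-MM"` strings bounding the table; default
#'   to the span of `posts`.
#' @return Tibble with columns `year`, `month`, `category`, `count`.
#' @export
monthly_counts <- function(mentions, posts, from = NULL, to = NULL) {
  missing_ids <- setdiff(mentions$post_id, posts$id)
  if (length(missing_ids) > 0) {
    rlang::abort(paste0("mentions reference unknown post ids: ",
                        paste(utils::head(missing_ids, 3), collapse = ", ")))
  }
  span <- month_span(posts, from, to)
  grid <- tidyr::expand_grid(span, category = flavor_categories())

  if (nrow(mentions) > 0) {
    mk <- month_of(posts$created_utc[match(mentions$post_id, posts$id)])
    counted <- dplyr::count(
      tibble::tibble(year = mk$year, month = mk$month,
                     category = mentions$category),
      .data$year, .data$month, .data$category, name = "count")
  } else {
    counted <- tibble::tibble(year = integer(), month = integer(),
                              category = character(), count = integer())
  }
  out <- dplyr::left_join(grid, counted, by = c("year", "month", "category"))
  out$count[is.na(out$count)] <- 0L
  dplyr::arrange(out, .data$year, .data$month, .data$category)
}

month_span <- function(posts, from, to) {
  parse_ym <- function(s) {
    m <- stringr::str_match(s, "^([0-9]{4})-([0-9]{2})$")
    if (is.na(m[1, 1])) rlang::abort(paste0("expected 'YYYY-MM', got: ", s))
    c(as.integer(m[1, 2]), as.integer(m[1, 3]))
  }
  if (is.null(from) || is.null(to)) {
    if (nrow(posts) == 0) rlang::abort("empty corpus and no explicit month range")
    mk <- month_of(posts$created_utc)
    idx <- mk$year * 12L + mk$month
    lo <- which.min(idx); hi <- which.max(idx)
    f <- c(mk$year[lo], mk$month[lo]); t <- c(mk$year[hi], mk$month[hi])
    if (!is.null(from)) f <- parse_ym(from)
    if (!is.null(to)) t <- parse_ym(to)
  } else {
    f <- parse_ym(from); t <- parse_ym(to)
  }
  seq_idx <- seq.int(f[1] * 12L + (f[2] - 1L), t[1] * 12L + (t[2] - 1L))
  if (length(seq_idx) == 0 || seq_idx[1] > seq_idx[length(seq_idx)]) {
    rlang::abort("month range is empty")
  }
  tibble::tibble(year = seq_idx %/% 12L, month = seq_idx %% 12L + 1L)
}

#' Normalize a monthly trend table
#'
#' Divides each month's per-category counts by that month's total mention
#' count, so category proportions sum to 1 within every active month —
#' the normalization that makes competition between flavor categories
#' visible independent of overall posting volume. Months with no mentions
#' get proportion 0 for all categories and are flagged.
#'
#' @param counts Table from [monthly_counts()].
#' @return The table with added columns `month_total`, `proportion`, and
#'   `zero_month` (logical flag).
#' @export
normalize_trends <- function(counts) {
  out <- dplyr::mutate(dplyr::group_by(counts, .data$year, .data$month),
                       month_total = sum(.data$count))
  out <- dplyr::ungroup(out)
  out$zero_month <- out$month_total == 0L
  out$proportion <- ifelse(out$zero_month, 0, out$count / out$month_total)
  out
}

#' Subcategory percentage table for one category
#'
#' Percentage distribution of subcategory mention counts within a category,
#' reported to 2 decimals with half-up rounding (the presentation used in
#' published flavor-distribution tables).
#'
#' @param x Either a mention tibble from [extract_mentions()] (requires
#'   `category`), or a precomputed count table with columns `subcategory`
#'   and `count` (printed table rows can be fed in directly).
#' @param category Category to tabulate when `x` is a mention tibble.
#' @return Tibble `subcategory`, `count`, `percent`, sorted by descending
#'   count; zero rows when the category is empty.
#' @examples
#' tbl <- tibble::tibble(
#'   subcategory = c("menthol", "mint"),
#'   count = c(173641, 56176))
#' subcategory_percentages(tbl)
#' @export
subcategory_percentages <- function(x, category = NULL) {
  if ("post_id" %in% names(x)) {
    if (is.null(category)) rlang::abort("`category` required for mention input")
    m <- x[x$category == category, , drop = FALSE]
    tab <- dplyr::count(m, subcategory = .data$subcategory, name = "count")
  } else {
    stopifnot(all(c("subcategory", "count") %in% names(x)))
    tab <- tibble::tibble(subcategory = x$subcategory,
                          count = as.numeric(x$count))
  }
  if (nrow(tab) == 0 || sum(tab$count) == 0) {
    return(tibble::tibble(subcategory = character(), count = numeric(),
                          percent = numeric()))
  }
  tab$percent <- round_half_up(100 * tab$count / sum(tab$count), 2)
  dplyr::arrange(tab, dplyr::desc(.data$count))
}
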