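#' Read a post corpus from JSON-lines
#'
#' One JSON object per line with fields `id`, `platform`, `author`,
#' `created_utc` and `text`. `created_utc` may be epoch seconds or an
#' ISO-8601 string; all timestamps are interpreted as UTC. Malformed lines
#' (unparseable JSON, missing/empty `id`, unparseable timestamp, or a
#' duplicate `id`) are counted and skipped with a warning; more than 50%
#' malformed lines is a corpus error. Unrecognized platforms are mapped to
#' `"other"`.
#'
#' @param path Path to a `.jsonl` file.
#' @return Tibble with columns `id`, `platform`, `author`, `created_utc`
#'   (POSIXct, UTC) and `text`, in file order, with attribute `n_skipped`.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cannot read corpus: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!stringr::str_detect(lines, "^\\s*$")]
  recs <- lapply(lines, function(l) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) return(NULL)
    id <- as.character(obj$id %||% "")
    if (length(id) != 1 || is.na(id) || id == "") return(NULL)
    ts <- parse_created_utc(obj$created_utc %||% NA)
    if (is.na(ts)) return(NULL)
    tibble::tibble(
      id = id,
      platform = norm_platform(obj$platform %||% "other"),
      author = as.character(obj$author %||% ""),
      created_utc = ts,
      text = as.character(obj$text %||% ""))
  })
  ok <- !vapply(recs, is.null, logical(1))
  posts <- dplyr::bind_rows(recs[ok])
  if (nrow(posts) > 0) {
    dup <- duplicated(posts$id)
    if (any(dup)) posts <- posts[!dup, ]
  }
  n_skipped <- length(lines) - nrow(posts)
  if (length(lines) > 0 && n_skipped > length(lines) / 2) {
    rlang::abort(paste0("corpus error: ", n_skipped, " of ", length(lines),
                        " lines malformed"))
  }
  if (n_skipped > 0) {
    rlang::warn(paste0("skipped ", n_skipped, " malformed line",
                       if (n_skipped > 1) "s", " in ", path))
  }
  if (nrow(posts) == 0) {
    posts <- tibble::tibble(id = character(), platform = character(),
                            author = character(),
                            created_utc = as.POSIXct(character(), tz = "UTC"),
                            text = character())
  }
  attr(posts, "n_skipped") <- n_skipped
  posts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

norm_platform <- function(p) {
  p <- stringr::str_to_lower(as.character(p))
  ifelse(p %in% c("reddit", "twitter"), p, "other")
}

parse_created_utc <- function(x) {
  if (length(x) != 1 || is.na(x)) return(as.POSIXct(NA))
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  x <- as.character(x)
  if (stringr::str_detect(x, "^-?[0-9]+(\\.[0-9]+)?$")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  }
  ts <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
  if (is.na(ts)) ts <- suppressWarnings(lubridate::ymd(x, tz = "UTC", quiet = TRUE))
  ts
}

#' Write a post corpus to JSON-lines
#'
#' Inverse of [read_posts()]: timestamps are serialized as ISO-8601 UTC, so
#' read/write/read round-trips are identity on well-formed corpora.
#'
#' @param posts Post tibble as returned by [read_posts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(
      id = posts$id[[i]],
      platform = posts$platform[[i]],
      author = posts$author[[i]],
      created_utc = format(posts$created_utc[[i]], "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
      text = posts$text[[i]]), auto_unbox = TRUE)
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Calendar month of a post timestamp
#'
#' UTC calendar month, independent of the machine's locale or timezone.
#'
#' @param x POSIXct vector, or a post tibble with a `created_utc` column.
#' @return Tibble with integer columns `year` and `month`.
#' @export
month_of <- function(x) {
  if (is.data.frame(x)) x <- x$created_utc
  lt <- as.POSIXlt(x, tz = "UTC")
  tibble::tibble(year = lt$year + 1900L, month = lt$mon + 1L)
}
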