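#' Load and validate a hierarchical flavor taxonomy
#'
#' The taxonomy is a three-level hierarchy — category, subcategory, specific
#' flavor keyword — mirroring the classification used for e-liquid flavor
#' surveillance: seven top-level categories (`fruit`, `sweets`, `beverage`,
#' `tobacco`, `menthol_or_mint`, `mixed`, `others`), subcategories within
#' each, and keyword lists within each subcategory. `mixed` is the fallback
#' for multi-ingredient flavors spanning several categories and `others` for
#' anything unmapped, so both must be present.
#'
#' The config is UTF-8 tab-delimited text with one row per keyword and
#' columns `category`, `subcategory`, `keyword`, and optionally `aliases`
#' (pipe- or comma-separated alternative surfaces that standardize to the
#' keyword) and `ingredients` (comma-separated category names for
#' multi-ingredient flavors). A data frame with the same columns is accepted
#' directly. The bundled fixture `table1_taxonomy.tsv` carries the published
#' category/subcategory/keyword scheme.
#'
#' Validation is strict: an invalid taxonomy is an error, never a warning.
#' Category names must belong to the seven-category set; `mixed` and
#' `others` must both be present; no keyword (or alias) may appear under two
#' different category/subcategory paths; every subcategory has at least one
#' keyword. Keywords are lower-cased and whitespace-normalized on load.
#'
#' @param x Path to a taxonomy config file, or a data frame with the columns
#'   described above. Defaults to the bundled fixture.
#' @param version Free-text label attached to the taxonomy.
#' @return A `flavor_taxonomy` object: list with elements `table` (tibble of
#'   category/subcategory/keyword/ingredients), `aliases` (tibble of
#'   alias/keyword), `categories` (category names in config order), and
#'   `version`.
#' @examples
#' tax <- load_taxonomy()
#' classify_term("strawberry", tax)
#' @export
load_taxonomy <- function(x = NULL, version = "table1") {
  if (is.null(x)) x <- fw_extdata("table1_taxonomy.tsv")
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) rlang::abort(paste0("taxonomy file not found: ", x))
    df <- tryCatch(
      utils::read.delim(x, sep = "\t", header = TRUE,
                        colClasses = "character", quote = "",
                        blank.lines.skip = TRUE,
                        stringsAsFactors = FALSE),
      error = function(e) {
        rlang::abort(paste0("taxonomy config is empty or unparseable: ", x))
      })
  } else if (is.data.frame(x)) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    rlang::abort("`x` must be a file path or a data frame")
  }
  req <- c("category", "subcategory", "keyword")
  if (!all(req %in% names(df)) || nrow(df) == 0) {
    rlang::abort("taxonomy config is empty or lacks category/subcategory/keyword columns")
  }
  if (!"aliases" %in% names(df)) df$aliases <- ""
  if (!"ingredients" %in% names(df)) df$ingredients <- ""
  df$aliases[is.na(df$aliases)] <- ""
  df$ingredients[is.na(df$ingredients)] <- ""

  tbl <- tibble::tibble(
    category = norm_keyword(df$category),
    subcategory = norm_keyword(df$subcategory),
    keyword = norm_keyword(df$keyword),
    ingredients = lapply(df$ingredients, function(s) {
      out <- norm_keyword(strsplit(s, ",", fixed = TRUE)[[1]])
      out[out != ""]
    })
  )
  if (any(tbl$keyword == "" | tbl$category == "" | tbl$subcategory == "")) {
    rlang::abort("taxonomy rows must have non-empty category, subcategory and keyword")
  }

  bad_cat <- setdiff(unique(tbl$category), flavor_categories())
  if (length(bad_cat) > 0) {
    rlang::abort(paste0("unknown flavor categories: ",
                        paste(bad_cat, collapse = ", ")))
  }
  for (need in c("mixed", "others")) {
    if (!need %in% tbl$category) {
      rlang::abort(paste0("taxonomy must contain a '", need,
                          "' category (fallback target)"))
    }
  }
  bad_ing <- setdiff(unique(unlist(tbl$ingredients)), flavor_categories())
  if (length(bad_ing) > 0) {
    rlang::abort(paste0("unknown ingredient categories: ",
                        paste(bad_ing, collapse = ", ")))
  }

  dup <- tbl$keyword[duplicated(tbl$keyword)]
  if (length(dup) > 0) {
    kw <- dup[[1]]
    paths <- tbl[tbl$keyword == kw, ]
    rlang::abort(paste0(
      "keyword '", kw, "' appears under multiple paths: ",
      paste(paste0(paths$category, "/", paths$subcategory), collapse = " and ")))
  }

  aliases <- tibble::tibble(
    alias = unlist(lapply(df$aliases, function(s) {
      out <- norm_keyword(strsplit(s, "[,|]")[[1]])
      out[out != ""]
    })),
    keyword = rep(tbl$keyword, vapply(df$aliases, function(s) {
      out <- norm_keyword(strsplit(s, "[,|]")[[1]])
      sum(out != "")
    }, integer(1)))
  )
  if (anyDuplicated(aliases$alias)) {
    rlang::abort("duplicate alias in taxonomy config")
  }
  clash <- intersect(aliases$alias, tbl$keyword)
  if (length(clash) > 0) {
    rlang::abort(paste0("alias also listed as a keyword: ",
                        paste(clash, collapse = ", ")))
  }

  structure(
    list(table = tbl, aliases = aliases,
         categories = unique(tbl$category), version = version),
    class = "flavor_taxonomy")
}

#' @export
print.flavor_taxonomy <- function(x, ...) {
  cat("<flavor_taxonomy> version:", x$version, "\n")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  cat("  keywords:", nrow(x$table), " aliases:", nrow(x$aliases), "\n")
  invisible(x)
}

#' All matchable surfaces of a taxonomy
#'
#' Keywords plus aliases, each with its canonical keyword, optionally
#' dropping surfaces whose canonical keyword is in `excluded` (the
#' denoise exclusion set).
#'
#' @param tax A `flavor_taxonomy`.
#' @param excluded Character vector of canonical keywords to drop.
#' @return Tibble with columns `surface`, `keyword`.
#' @export
taxonomy_surfaces <- function(tax, excluded = character()) {
  stopifnot(inherits(tax, "flavor_taxonomy"))
  excluded <- norm_keyword(excluded)
  s <- dplyr::bind_rows(
    tibble::tibble(surface = tax$table$keyword, keyword = tax$table$keyword),
    tibble::tibble(surface = tax$aliases$alias, keyword = tax$aliases$keyword)
  )
  s[!s$keyword %in% excluded, ]
}

#' Construct a flavor term
#'
#' A flavor term is a raw surface string plus, optionally, the set of
#' category names implied by its ingredients (multi-ingredient flavors are
#' configured, never parsed from compound names). [classify_term()] fills in
#' the standardized form.
#'
#' @param surface Raw flavor name as written.
#' @param ingredient_categories Character vector of category names implied
#'   by the term's components.
#' @return A `flavor_term` object.
#' @export
flavor_term <- function(surface, ingredient_categories = character()) {
  structure(
    list(surface = as.character(surface),
         standardized = NA_character_,
         ingredient_categories = norm_keyword(ingredient_categories)),
    class = "flavor_term")
}

#' Classify a flavor term into its taxonomy path
#'
#' Resolution order: the surface is standardized (lower-cased,
#' whitespace-normalized, alias-resolved); a term whose standardized form is
#' a taxonomy keyword gets that keyword's path. Otherwise the term's
#' ingredient-category set decides: two or more distinct non-`others`
#' categories place it under `mixed/mixed`; exactly one category places it
#' under that category (in its `others` subcategory when one exists,
#' otherwise its first subcategory); an empty or unresolvable set falls back
#' to `others/others`. The function is total and deterministic: every term
#' receives exactly one path.
#'
#' @param term A character string or a [flavor_term()].
#' @param tax A `flavor_taxonomy`.
#' @return One-row tibble with columns `category`, `subcategory`, `keyword`.
#' @examples
#' tax <- load_taxonomy()
#' classify_term("Strawberry", tax)
#' classify_term("unobtainium", tax)
#' classify_term(flavor_term("dragon punch", c("fruit", "menthol_or_mint")), tax)
#' @export
classify_term <- function(term, tax) {
  stopifnot(inherits(tax, "flavor_taxonomy"))
  if (inherits(term, "flavor_term")) {
    surface <- term$surface
    ingredients <- term$ingredient_categories
  } else {
    surface <- as.character(term)
    ingredients <- character()
  }
  s <- norm_keyword(surface)
  hit <- match(s, tax$aliases$alias)
  if (!is.na(hit)) s <- tax$aliases$keyword[[hit]]
  row <- match(s, tax$table$keyword)
  if (!is.na(row)) {
    return(tibble::tibble(category = tax$table$category[[row]],
                          subcategory = tax$table$subcategory[[row]],
                          keyword = tax$table$keyword[[row]]))
  }
  ing <- setdiff(unique(ingredients), "")
  non_others <- setdiff(ing, "others")
  if (length(non_others) >= 2) {
    return(tibble::tibble(category = "mixed", subcategory = "mixed", keyword = s))
  }
  if (length(ing) == 1 && ing %in% tax$categories) {
    subs <- unique(tax$table$subcategory[tax$table$category == ing])
    sub <- if ("others" %in% subs) "others" else subs[[1]]
    return(tibble::tibble(category = ing, subcategory = sub, keyword = s))
  }
  tibble::tibble(category = "others", subcategory = "others", keyword = s)
}
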