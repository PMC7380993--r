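# In-code fixtures shared across the suite.

# minimal valid taxonomy: a few keywords per category plus the mandatory
# mixed/others fallbacks
mini_taxonomy_df <- function() {
  data.frame(
    category = c("fruit", "fruit", "fruit", "sweets", "sweets", "sweets",
                 "beverage", "menthol_or_mint", "tobacco",
                 "mixed", "others"),
    subcategory = c("berry", "tropical", "melon", "dessert", "candy",
                    "candy", "juice", "menthol", "tobacco",
                    "mixed", "others"),
    keyword = c("strawberry", "mango", "melon", "custard", "cotton candy",
                "candy", "apple juice", "menthol", "cigar",
                "fruit + mint", "pure vg"),
    aliases = c("", "", "", "", "", "", "", "", "", "", ""),
    ingredients = c("", "", "", "", "", "", "", "", "",
                    "fruit,menthol_or_mint", ""),
    stringsAsFactors = FALSE)
}

mini_taxonomy <- function() load_taxonomy(mini_taxonomy_df(), version = "mini")

# bundled fixture extended with an ambiguous keyword for denoise tests
punch_taxonomy <- function() {
  df <- utils::read.delim(system.file("extdata", "table1_taxonomy.tsv",
                                      package = "flavorwatch"),
                          sep = "\t", colClasses = "character", quote = "")
  df <- rbind(df, data.frame(category = "beverage",
                             subcategory = "soft drinks",
                             keyword = "punch", aliases = "",
                             ingredients = ""))
  load_taxonomy(df, version = "table1+punch")
}

make_posts <- function(texts, authors = NULL,
                       times = NULL, platform = "reddit") {
  n <- length(texts)
  if (is.null(authors)) authors <- sprintf("user%03d", seq_len(n))
  if (is.null(times)) {
    times <- as.POSIXct("2016-06-16 12:00:00", tz = "UTC") + seq_len(n)
  }
  tibble::tibble(id = sprintf("t%03d", seq_len(n)), platform = platform,
                 author = authors, created_utc = times, text = texts)
}

write_jsonl <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path)
  path
}
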