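## Worked example: cross-library means recomputed from a published cotton
## drought/salinity library-categorization table shipped as plain text.

#' Load the bundled cotton library-categorization counts
#'
#' Unique/redundant read counts per category for a published three-library
#' (control/drought/salt) cotton small-RNA experiment, transcribed as plain
#' counts; all percentages are recomputed by [categorization_means()].
#'
#' @return Tibble with `category` and per-library unique/redundant counts
#'   (last row: library totals).
#' @export
cotton_library_categorization <- function() {
  path <- system.file("extdata", "cotton_library_categorization.tsv",
                      package = "stressmir", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Cross-library category and match-rate means from a categorization table
#'
#' Recomputes, from raw counts, each category's percentage of the library
#' total (unique and redundant separately) and averages over the three
#' libraries, rounding to 2 decimals as conventionally printed.
#'
#' @param tbl Counts table in the layout of
#'   [cotton_library_categorization()]: a `category` column, per-library
#'   `unique_*`/`redundant_*` columns, and a `total` row.
#' @return Tibble: `category`, `mean_unique_pct`, `mean_redundant_pct`.
#' @export
#' @examples
#' categorization_means(cotton_library_categorization())
categorization_means <- function(tbl) {
  stopifnot("category" %in% names(tbl), "total" %in% tbl$category)
  tot <- tbl[tbl$category == "total", , drop = FALSE]
  body <- tbl[tbl$category != "total", , drop = FALSE]
  ucols <- grep("^unique_", names(tbl), value = TRUE)
  rcols <- grep("^redundant_", names(tbl), value = TRUE)
  upct <- sapply(ucols, function(cl) 100 * body[[cl]] / tot[[cl]])
  rpct <- sapply(rcols, function(cl) 100 * body[[cl]] / tot[[cl]])
  tibble::tibble(
    category = body$category,
    mean_unique_pct = round(rowMeans(upct), 2),
    mean_redundant_pct = round(rowMeans(rpct), 2)
  )
}
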