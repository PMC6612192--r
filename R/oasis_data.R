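#' Shipped reference tables for the OASIS Korean-medicine corpus
#'
#' Two small reference tables for the 29,876-article OASIS corpus
#' (1963-2018) ship with the package: the top-30 keyword frequency ranking
#' and per-phase appearance counts for selected keywords over the six-phase
#' segmentation of [oasis_phases()] (only rows whose published digits admit
#' a single consistent transcription are included). The full corpus is not
#' redistributable, so these tables serve as cross-check fixtures: e.g.
#' each keyword's six phase counts must sum to its total frequency, and the
#' per-phase article totals to the corpus size.
#'
#' @return `oasis_top_keywords()`: data frame `rank`, `keyword`,
#'   `frequency`. `oasis_phase_counts()`: list with `counts` (data frame:
#'   `keyword` plus one column per phase), `article_totals` (integer vector,
#'   articles per phase) and `phases` (the [oasis_phases()] preset).
#' @export
oasis_top_keywords <- function() {
  path <- system.file("extdata", "oasis_top30.tsv", package = "kwtrends",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

#' @rdname oasis_top_keywords
#' @export
oasis_phase_counts <- function() {
  path <- system.file("extdata", "oasis_phase_counts.tsv",
                      package = "kwtrends", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tot_line <- grep("^# article_totals:", lines, value = TRUE)
  totals <- as.integer(strsplit(sub("^# article_totals:\\s*", "",
                                    tot_line), "\\s+")[[1]])
  counts <- utils::read.delim(path, comment.char = "#",
                              fileEncoding = "UTF-8",
                              stringsAsFactors = FALSE)
  list(counts = counts,
       article_totals = stats::setNames(
         totals, paste0(oasis_phases()$start, "-", oasis_phases()$end)),
       phases = oasis_phases())
}
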