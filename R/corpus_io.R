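#' Normalize a raw keyword string to a canonical token
#'
#' Applies the normalization used throughout the pipeline: Unicode NFC
#' composition, case folding, and removal of every character that is not a
#' lowercase Latin letter, a decimal digit, or a Greek letter (Greek and
#' Greek Extended blocks). Spaces, hyphens, apostrophes and all punctuation
#' disappear, so spelling variants such as `"Anti-Inflammation"` and
#' `"antiinflammation"` collapse to the same token.
#'
#' The rule is idempotent: applying it to its own output is a no-op. Input
#' from which nothing survives (e.g. symbols only) yields the empty string;
#' callers decide whether to drop such tokens.
#'
#' @param raw Character vector of raw keyword strings.
#' @return Character vector of normalized tokens, same length as `raw`.
#' @examples
#' normalize_keyword("Anti-Inflammation")  # "antiinflammation"
#' normalize_keyword("TNF-α")         # "tnfα"
#' normalize_keyword("Bell's palsy")       # "bellspalsy"
#' @export
normalize_keyword <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- stringi::stri_trans_nfc(as.character(raw))
  x <- stringi::stri_trans_tolower(x)
  # keep lowercase Latin, digits, Greek (U+0370-03FF) and Greek Extended
  # (U+1F00-1FFF); everything else (whitespace, punctuation, other scripts)
  # is removed
  x <- stringi::stri_replace_all_regex(
    x, "[^a-z0-9\\u0370-\\u03ff\\u1f00-\\u1fff]", ""
  )
  x[is.na(raw)] <- ""
  x
}

#' Read an article-metadata corpus
#'
#' Reads article records (id, publication year, keyword list) from CSV or
#' JSON-lines. The CSV dialect has header `id,year,keywords` with the
#' keywords cell a `;`-separated list (RFC-4180 quoting, UTF-8). JSON-lines
#' holds one object per line with fields `id` (string), `year` (integer) and
#' `keywords` (array of strings). Raw keyword strings are preserved untouched
#' at this stage; normalization happens downstream.
#'
#' Rows with a missing or unparsable year are rejected with a warning that
#' reports how many records were dropped. A structurally malformed file
#' (missing columns, invalid JSON) is a hard error naming the offending line.
#'
#' @param path Path to the corpus file.
#' @param format `"csv"` or `"jsonl"`; by default inferred from the file
#'   extension (`.csv` vs `.jsonl`/`.ndjson`/`.json`).
#' @param quiet Suppress the record-count message.
#' @return A data frame with columns `id` (character), `year` (integer) and
#'   `keywords` (list of character vectors), one row per accepted record, in
#'   input order.
#' @seealso [write_corpus()], [build_annual_matrix()]
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl"),
                        quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv",
      jsonl = , ndjson = , json = "jsonl",
      stop("cannot infer corpus format from extension '.", ext,
           "'; pass format explicitly", call. = FALSE)
    )
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
    need <- c("id", "year", "keywords")
    if (!all(need %in% names(raw))) {
      stop("corpus CSV must have header id,year,keywords; got: ",
           paste(names(raw), collapse = ","), call. = FALSE)
    }
    ids <- raw$id
    years <- suppressWarnings(as.integer(raw$year))
    kws <- lapply(raw$keywords, function(cell) {
      if (is.na(cell) || !nzchar(cell)) character(0)
      else strsplit(cell, ";", fixed = TRUE)[[1]]
    })
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      recs[[i]] <- tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
        error = function(e) {
          stop("malformed JSON on line ", i, " of ", path, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
    }
    ids <- vapply(recs, function(r) {
      if (is.null(r$id)) NA_character_ else as.character(r$id)
    }, character(1))
    years <- vapply(recs, function(r) {
      y <- suppressWarnings(as.integer(r$year))
      if (length(y) != 1L || is.null(r$year)) NA_integer_ else y
    }, integer(1))
    kws <- lapply(recs, function(r) {
      k <- r$keywords
      if (is.null(k)) character(0) else as.character(k)
    })
  }
  ok <- !is.na(years)
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning(n_bad, " record(s) rejected: missing or unparsable year",
            call. = FALSE)
  }
  out <- data.frame(id = ids[ok], year = years[ok],
                    stringsAsFactors = FALSE)
  out$keywords <- kws[ok]
  if (!quiet) {
    message("read_corpus: ", nrow(out), " record(s) read from ", path,
            if (n_bad > 0L) paste0(" (", n_bad, " rejected)") else "")
  }
  out
}

#' Write an article-metadata corpus
#'
#' Inverse of [read_corpus()]: writes the same CSV / JSON-lines dialects.
#'
#' @param articles Data frame with columns `id`, `year`, `keywords` (list).
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(articles, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(all(c("id", "year", "keywords") %in% names(articles)))
  if (format == "csv") {
    cells <- vapply(articles$keywords, paste, character(1), collapse = ";")
    utils::write.csv(
      data.frame(id = articles$id, year = articles$year, keywords = cells,
                 stringsAsFactors = FALSE),
      path, row.names = FALSE, fileEncoding = "UTF-8"
    )
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(articles))) {
      writeLines(jsonlite::toJSON(list(
        id = articles$id[[i]],
        year = articles$year[[i]],
        keywords = as.character(articles$keywords[[i]])
      ), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Load a synonym map
#'
#' Reads a two-column TSV (`variant<TAB>canonical`, UTF-8, `#` comment lines
#' ignored), normalizes both columns with [normalize_keyword()], collapses
#' transitive chains (a→b, b→c becomes a→c, b→c) and validates the result:
#' after collapsing, no key may still map to another key, and a variant
#' mapped to two distinct canonicals is an error naming the variant.
#'
#' Synonym merging in this pipeline is a user-supplied data file, not an
#' algorithm: which spelling variants denote the same concept is a curation
#' decision.
#'
#' @param path Path to the TSV file.
#' @return A named character vector of class `synonym_map`: names are variant
#'   tokens, values the canonical tokens they merge into.
#' @export
load_synonym_map <- function(path) {
  if (!file.exists(path)) {
    stop("synonym map not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) {
    return(synonym_map(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop("synonym map line ", bad[1], " does not have two TAB-separated ",
         "columns", call. = FALSE)
  }
  synonym_map(
    variant = vapply(parts, `[[`, character(1), 1L),
    canonical = vapply(parts, `[[`, character(1), 2L)
  )
}

#' Construct a synonym map from variant/canonical vectors
#'
#' @param variant,canonical Character vectors of equal length; both are put
#'   through [normalize_keyword()].
#' @return A `synonym_map` (named character vector, variant → canonical).
#' @export
synonym_map <- function(variant, canonical) {
  stopifnot(length(variant) == length(canonical))
  v <- normalize_keyword(variant)
  k <- normalize_keyword(canonical)
  keep <- nzchar(v)
  v <- v[keep]; k <- k[keep]
  # conflicting duplicate keys are an error; exact duplicates collapse
  dup <- duplicated(v)
  if (any(dup)) {
    for (tok in unique(v[dup])) {
      tgt <- unique(k[v == tok])
      if (length(tgt) > 1L) {
        stop("synonym map: variant '", tok, "' mapped to multiple ",
             "canonicals: ", paste(tgt, collapse = ", "), call. = FALSE)
      }
    }
    k <- k[!dup]; v <- v[!dup]
  }
  map <- stats::setNames(k, v)
  # collapse chains a->b, b->c to a->c; bounded pass count detects cycles
  for (pass in seq_len(length(map) + 1L)) {
    hop <- map[map]          # NA where value is not itself a key
    chained <- !is.na(hop) & hop != map & map != names(map)
    if (!any(chained)) break
    if (any(hop[chained] == names(map)[chained])) {
      stop("synonym map: cycle detected involving '",
           names(map)[chained][hop[chained] == names(map)[chained]][1],
           "'", call. = FALSE)
    }
    if (pass > length(map)) {
      stop("synonym map: cycle detected involving '",
           names(map)[chained][1], "'", call. = FALSE)
    }
    map[chained] <- hop[chained]
  }
  structure(map, class = c("synonym_map", "character"))
}

#' Apply a synonym map to normalized tokens
#'
#' @param tokens Character vector of already-normalized tokens.
#' @param map A `synonym_map`, or `NULL` for the identity.
#' @return Character vector with variants replaced by their canonicals.
#' @export
apply_synonym_map <- function(tokens, map = NULL) {
  if (is.null(map) || length(map) == 0L) return(tokens)
  hit <- match(tokens, names(map))
  tokens[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  tokens
}

# normalize + merge + drop empties + article-level dedup, for one article
canonical_tokens <- function(raw_keywords, map = NULL) {
  tok <- normalize_keyword(raw_keywords)
  tok <- tok[nzchar(tok)]
  unique(apply_synonym_map(tok, map))
}

#' Count articles containing each keyword
#'
#' Frequency here is the number of *articles* containing a keyword, not the
#' number of raw occurrences: within one article, all raw keywords that
#' normalize and merge to the same canonical token contribute a single count.
#'
#' @param articles Corpus data frame (see [read_corpus()]).
#' @param map Optional [synonym_map()].
#' @return Named integer vector, canonical token → article count, sorted by
#'   decreasing count then token.
#' @export
count_keywords <- function(articles, map = NULL) {
  toks <- unlist(lapply(articles$keywords, canonical_tokens, map = map),
                 use.names = FALSE)
  if (is.null(toks) || length(toks) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(toks)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(-counts, names(counts))]
}
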