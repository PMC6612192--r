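#' Build the annual keyword-frequency matrix
#'
#' The pipeline's central object: a keywords-by-years matrix whose entry is
#' the number of articles published in that year that contain that keyword
#' (after normalization, synonym merging and article-level deduplication).
#' Keywords whose total frequency over the whole study range falls below
#' `min_freq` are dropped *after* merging, so rare spelling variants of a
#' common concept are not lost. Year columns span the full configured range
#' even where all-zero.
#'
#' Rows are ordered by descending total frequency with lexicographic
#' tie-break, so a matrix built from the same corpus is byte-reproducible.
#'
#' @param articles Corpus data frame (see [read_corpus()]).
#' @param map Optional [synonym_map()].
#' @param min_freq Minimum total article count for a keyword to be kept
#'   (default 10).
#' @param years Inclusive integer year range, e.g. `c(1963, 2018)`; defaults
#'   to the range observed in `articles`. Articles outside the range are
#'   rejected with a warning.
#' @return An object of class `annual_matrix`: a list with elements
#'   `counts` (integer matrix, keywords x years), `years` (integer vector of
#'   the column years), `min_freq`, `n_articles` (accepted articles) and
#'   `articles_per_year` (named integer vector over the full year range).
#' @export
build_annual_matrix <- function(articles, map = NULL, min_freq = 10,
                                years = NULL) {
  stopifnot(min_freq >= 1)
  if (!is.null(map) && (!is.character(map) || is.null(names(map)))) {
    stop("'map' must be a synonym_map (named character vector) or NULL",
         call. = FALSE)
  }
  if (nrow(articles) > 0L) {
    stopifnot(is.numeric(articles$year))
  }
  if (is.null(years)) {
    if (nrow(articles) == 0L) {
      stop("empty corpus and no explicit year range", call. = FALSE)
    }
    years <- range(articles$year)
  }
  stopifnot(length(years) == 2L, years[1] <= years[2])
  yr_axis <- seq.int(years[1], years[2])

  in_range <- articles$year >= years[1] & articles$year <= years[2]
  if (any(!in_range)) {
    warning(sum(!in_range), " article(s) outside year range [", years[1],
            ", ", years[2], "] rejected", call. = FALSE)
    articles <- articles[in_range, , drop = FALSE]
  }

  per_year <- table(factor(articles$year, levels = yr_axis))
  toks <- lapply(articles$keywords, canonical_tokens, map = map)
  n_per <- lengths(toks)
  tok_flat <- unlist(toks, use.names = FALSE)
  yr_flat <- rep(articles$year, n_per)

  if (length(tok_flat) == 0L) {
    counts <- matrix(0L, nrow = 0, ncol = length(yr_axis),
                     dimnames = list(character(0), as.character(yr_axis)))
  } else {
    counts <- table(factor(tok_flat), factor(yr_flat, levels = yr_axis))
    counts <- matrix(as.integer(counts), nrow = nrow(counts),
                     dimnames = dimnames(counts))
  }
  totals <- rowSums(counts)
  counts <- counts[totals >= min_freq, , drop = FALSE]
  totals <- totals[totals >= min_freq]
  ord <- order(-totals, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  names(dimnames(counts)) <- NULL

  structure(list(
    counts = counts,
    years = yr_axis,
    min_freq = min_freq,
    n_articles = nrow(articles),
    articles_per_year = stats::setNames(as.integer(per_year), names(per_year))
  ), class = "annual_matrix")
}

#' @export
print.annual_matrix <- function(x, ...) {
  cat("Annual keyword-frequency matrix\n")
  cat("  keywords : ", nrow(x$counts), " (min total frequency ",
      x$min_freq, ")\n", sep = "")
  cat("  years    : ", x$years[1], "-", x$years[length(x$years)], " (",
      length(x$years), " columns)\n", sep = "")
  cat("  articles : ", x$n_articles, "\n", sep = "")
  if (nrow(x$counts) > 0) {
    top <- utils::head(rownames(x$counts), 5)
    cat("  top keywords:", paste(top, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.annual_matrix <- function(x, ...) x$counts

#' Weighted Jaccard similarity between two frequency lists
#'
#' For equal-length non-negative vectors S and T,
#' \deqn{J(S,T) = \sum_k \min(S_k, T_k) / \sum_k \max(S_k, T_k).}
#' The value is 1 for identical non-zero lists, 0 for lists with disjoint
#' support, and by convention 0 when both lists are entirely zero (flagged
#' with a warning, since two empty years carry no evidence of similarity and
#' treating them as identical would fuse empty periods).
#'
#' @param s,t Non-negative numeric vectors of equal length.
#' @param warn_zero Warn when both lists are all-zero.
#' @return A similarity in `[0, 1]`.
#' @examples
#' weighted_jaccard(c(1, 2, 3), c(1, 2, 3))  # 1
#' weighted_jaccard(c(0, 5), c(5, 0))        # 0
#' weighted_jaccard(c(1, 2), c(2, 4))        # 0.5
#' @export
weighted_jaccard <- function(s, t, warn_zero = TRUE) {
  if (length(s) != length(t)) {
    stop("frequency lists differ in length (", length(s), " vs ",
         length(t), ")", call. = FALSE)
  }
  if (anyNA(s) || anyNA(t)) stop("frequency lists contain NA", call. = FALSE)
  if (any(s < 0) || any(t < 0)) {
    stop("frequency lists must be non-negative", call. = FALSE)
  }
  denom <- sum(pmax(s, t))
  if (denom == 0) {
    if (warn_zero) {
      warning("both frequency lists are all-zero; returning 0 by convention",
              call. = FALSE)
    }
    return(0)
  }
  sum(pmin(s, t)) / denom
}

#' Define phase boundaries
#'
#' @param start,end Integer vectors of inclusive phase start/end years.
#' @return Data frame of class `phase_set` with columns `phase`, `start`,
#'   `end`.
#' @export
phase_set <- function(start, end) {
  stopifnot(length(start) == length(end), all(start <= end))
  if (length(start) > 1L) {
    stopifnot(all(diff(start) > 0))
    if (any(start[-1] != end[-length(end)] + 1L)) {
      stop("phases must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  structure(
    data.frame(phase = seq_along(start), start = as.integer(start),
               end = as.integer(end)),
    class = c("phase_set", "data.frame")
  )
}

#' Reference six-phase segmentation of the OASIS study period
#'
#' The chronological phases used for the OASIS Korean-medicine corpus
#' (1963-2018): 1963-1978, 1979-1986, 1987-1994, 1995-2001, 2002-2012,
#' 2013-2018. Shipped as a named preset so phase tables over that corpus can
#' be reproduced without re-running the segmentation heuristic.
#'
#' @return A [phase_set()] with six phases covering 1963-2018.
#' @export
oasis_phases <- function() {
  phase_set(start = c(1963L, 1979L, 1987L, 1995L, 2002L, 2013L),
            end   = c(1978L, 1986L, 1994L, 2001L, 2012L, 2018L))
}

check_phase_cover <- function(p, years) {
  stopifnot(inherits(p, "data.frame"), all(c("start", "end") %in% names(p)))
  covered <- unlist(Map(seq.int, p$start, p$end))
  if (length(covered) != length(years) || any(sort(covered) != years)) {
    stop("phases do not partition the year range ", years[1], "-",
         years[length(years)], call. = FALSE)
  }
  invisible(TRUE)
}

#' Aggregate an annual matrix to phase totals
#'
#' Sums each keyword's annual counts over each phase's years, and likewise
#' the per-year article totals, reproducing the phase-table view of the
#' corpus. Row totals are conserved: each keyword's phase counts sum to its
#' total corpus frequency.
#'
#' @param m An [build_annual_matrix()] result.
#' @param phases A [phase_set()] covering `m`'s year range exactly (gaps or
#'   overlaps are an error).
#' @param per_year_articles Named integer vector of article counts per year;
#'   defaults to the counts recorded in `m`.
#' @return An object of class `phase_table`: list with `counts` (keywords x
#'   phases integer matrix, columns named `"start-end"`), `article_totals`
#'   (per-phase article counts) and `phases`.
#' @export
phase_aggregate <- function(m, phases, per_year_articles = NULL) {
  stopifnot(inherits(m, "annual_matrix"))
  check_phase_cover(phases, m$years)
  if (is.null(per_year_articles)) per_year_articles <- m$articles_per_year
  lab <- paste0(phases$start, "-", phases$end)
  cols <- lapply(seq_len(nrow(phases)), function(i) {
    yrs <- as.character(seq.int(phases$start[i], phases$end[i]))
    rowSums(m$counts[, yrs, drop = FALSE])
  })
  counts <- matrix(as.integer(unlist(cols)), nrow = nrow(m$counts),
                   dimnames = list(rownames(m$counts), lab))
  art <- vapply(seq_len(nrow(phases)), function(i) {
    yrs <- as.character(seq.int(phases$start[i], phases$end[i]))
    sum(per_year_articles[yrs])
  }, numeric(1))
  structure(list(
    counts = counts,
    article_totals = stats::setNames(as.integer(art), lab),
    phases = phases
  ), class = "phase_table")
}

#' @export
print.phase_table <- function(x, ...) {
  cat("Phase table:", nrow(x$counts), "keywords x", ncol(x$counts),
      "phases\n")
  cat("  articles per phase:",
      paste(names(x$article_totals), x$article_totals, sep = ": ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Rank keywords by total frequency
#'
#' @param m An [build_annual_matrix()] result.
#' @param n Number of keywords to return (capped at the number of rows).
#' @return Data frame with columns `rank`, `keyword`, `frequency`, in
#'   descending frequency order with lexicographic tie-break.
#' @export
top_keywords <- function(m, n = 30) {
  stopifnot(inherits(m, "annual_matrix"), n >= 1)
  totals <- rowSums(m$counts)
  ord <- order(-totals, names(totals))
  k <- min(n, length(totals))
  idx <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), keyword = names(totals)[idx],
             frequency = as.integer(totals[idx]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Serialize / read an annual matrix as TSV plus metadata sidecar
#'
#' The TSV has a header row of years and the keyword token in the first
#' column; a YAML sidecar (`<path>.meta.yaml`) records the frequency filter,
#' year range, corpus size and per-year article counts so the matrix can be
#' reconstructed losslessly.
#'
#' @param m An `annual_matrix`.
#' @param path Output TSV path.
#' @return `path` invisibly (write); an `annual_matrix` (read).
#' @export
write_annual_matrix <- function(m, path) {
  stopifnot(inherits(m, "annual_matrix"))
  df <- data.frame(keyword = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  yaml::write_yaml(list(
    min_freq = m$min_freq,
    year_min = m$years[1],
    year_max = m$years[length(m$years)],
    n_articles = m$n_articles,
    articles_per_year = as.list(m$articles_per_year)
  ), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_annual_matrix
#' @export
read_annual_matrix <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  structure(list(
    counts = counts,
    years = seq.int(meta$year_min, meta$year_max),
    min_freq = meta$min_freq,
    n_articles = meta$n_articles,
    articles_per_year = stats::setNames(
      as.integer(unlist(meta$articles_per_year)),
      names(meta$articles_per_year))
  ), class = "annual_matrix")
}
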