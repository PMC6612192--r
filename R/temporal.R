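#' Year-over-year keyword similarity series
#'
#' For each year after the first, the weighted Jaccard similarity between
#' that year's keyword-frequency column and the previous year's. A high
#' value means the keyword mix (and its volume) changed little; a drop marks
#' topic drift. Years in which both columns are all-zero yield 0 by
#' convention; a single message reports how many such pairs occurred.
#'
#' @param m An [build_annual_matrix()] result spanning at least two years.
#' @return Data frame with columns `year` and `similarity`, starting at the
#'   second year of the matrix range.
#' @export
similarity_series <- function(m) {
  stopifnot(inherits(m, "annual_matrix"))
  ny <- length(m$years)
  if (ny < 2L) stop("matrix must span at least two years", call. = FALSE)
  sims <- numeric(ny - 1L)
  n_zero <- 0L
  for (i in 2:ny) {
    s <- m$counts[, i]; t <- m$counts[, i - 1L]
    if (sum(s) == 0 && sum(t) == 0) n_zero <- n_zero + 1L
    sims[i - 1L] <- weighted_jaccard(s, t, warn_zero = FALSE)
  }
  if (n_zero > 0L) {
    message("similarity_series: ", n_zero,
            " year pair(s) with no keywords on either side (similarity 0)")
  }
  data.frame(year = m$years[-1], similarity = sims)
}

#' Segment a similarity series into chronological phases
#'
#' A deterministic, parameterized version of the trend-break heuristic used
#' in co-word trend studies: a new phase begins where the year-over-year
#' similarity starts to rise again after a sharp drop. Because the heuristic
#' has no single canonical form, all thresholds are explicit parameters, and
#' externally supplied boundaries (see [oasis_phases()]) or fixed-width bins
#' are equally valid modes.
#'
#' Method `"drop"` works as follows. (1) The first phase absorbs the sparse
#' early era: it extends through the last year with similarity at or below
#' `zero_eps` that occurs before the first run of `min_len` consecutive
#' years above `zero_eps`. (2) After that, a boundary is placed before any
#' year `t` whose similarity fell by at least `delta` from the year before
#' and whose following year rises again (a trough). (3) Candidate phases
#' shorter than `min_len` years are merged into the preceding phase (the
#' first phase, having no predecessor, merges forward). Method `"fixed"`
#' simply cuts the range into `width`-year bins (the final bin may be
#' shorter).
#'
#' @param s A [similarity_series()] data frame (method `"drop"`), or any
#'   object for method `"fixed"` when `years` is given.
#' @param delta Minimum similarity decrease that counts as sharp
#'   (default 0.1).
#' @param zero_eps Similarity at or below which a year counts as
#'   zero-similarity (default 0).
#' @param min_len Minimum phase length in years (default 3).
#' @param method `"drop"` (trough rule) or `"fixed"` (equal-width bins).
#' @param width Bin width in years for method `"fixed"` (default 10).
#' @param years Inclusive year range `c(min, max)` of the underlying matrix;
#'   defaults to `c(min(s$year) - 1, max(s$year))` since the series starts
#'   one year into the matrix range.
#' @return A [phase_set()] partitioning the year range.
#' @export
segment_phases <- function(s, delta = 0.1, zero_eps = 0, min_len = 3,
                           method = c("drop", "fixed"), width = 10,
                           years = NULL) {
  method <- match.arg(method)
  if (is.null(years)) {
    stopifnot(is.data.frame(s), nrow(s) >= 1)
    years <- c(min(s$year) - 1L, max(s$year))
  }
  y_min <- years[1]; y_max <- years[2]

  if (method == "fixed") {
    stopifnot(width >= 1)
    starts <- seq.int(y_min, y_max, by = width)
    ends <- c(starts[-1] - 1L, y_max)
    return(phase_set(starts, ends))
  }

  stopifnot(delta > 0, zero_eps >= 0, min_len >= 1)
  sim <- s$similarity
  yr <- s$year
  n <- length(sim)

  # (1) leading zero-similarity era
  phase1_end <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    if (sim[i] <= zero_eps) {
      phase1_end <- yr[i]
      run <- 0L
    } else {
      run <- run + 1L
      if (run >= min_len) break
    }
  }

  # (2) trough boundaries: sharp decrease into year t, rise after it
  bounds <- integer(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if ((sim[i] - sim[i - 1L]) <= -delta && sim[i + 1L] > sim[i]) {
        bounds <- c(bounds, yr[i])  # new phase starts at the trough year
      }
    }
  }
  if (!is.na(phase1_end)) {
    bounds <- bounds[bounds > phase1_end + 1L]
    bounds <- c(phase1_end + 1L, bounds)
  }
  bounds <- sort(unique(bounds[bounds > y_min & bounds <= y_max]))

  starts <- c(y_min, bounds)
  ends <- c(bounds - 1L, y_max)

  # (3) merge short candidate phases into the preceding phase
  i <- 1L
  while (length(starts) > 1L && i <= length(starts)) {
    len <- ends[i] - starts[i] + 1L
    if (len < min_len) {
      if (i == 1L) {       # no predecessor: merge forward
        starts <- starts[-2L]
        ends <- ends[-1L]
      } else {
        ends[i - 1L] <- ends[i]
        starts <- starts[-i]
        ends <- ends[-i]
      }
    } else {
      i <- i + 1L
    }
  }
  phase_set(starts, ends)
}
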