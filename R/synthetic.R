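#' Configuration for the synthetic corpus generator
#'
#' Describes a corpus with planted temporal structure. Defaults emulate a
#' six-decade Korean-medicine-style literature stream: article volume grows
#' from a few dozen per year in the 1960s to well over a thousand per year
#' in the 2000s (the per-phase totals 643, 498, 1889, 5758, 15921, 5167 —
#' 29,876 articles in all — spread uniformly within each phase), four
#' keyword groups with distinct temporal profiles, spelling/synonym variants
#' of every concept, and one terminology rename in 2012 in which an old
#' label's frequency collapses while its replacement's rises.
#'
#' Group profiles (all evaluated per year): `stable` is constant;
#' `emerging` is a logistic ramp with onset `onset_year` (default 2010,
#' emulating late-emerging topics); `declining` is a falling logistic with
#' midpoint 1985 (topics fading after the early era); `pulse` is a Gaussian
#' bump centred on 1996 (methods fashionable for about a decade). Within a
#' year, each article draws 3-8 keywords without replacement with
#' probability proportional to profile value x group intensity; each
#' concept's probability mass is split between its canonical spelling and a
#' variant spelling (rate `synonym_rate`), so both variants of one concept
#' can co-occur in an article and exercise the deduplication path.
#'
#' @param years Inclusive year range (default `c(1963, 2018)`).
#' @param phase_article_totals Article totals per phase of the default
#'   six-phase split of `years`; ignored when `annual_articles` is given.
#' @param annual_articles Optional explicit per-year article counts (named
#'   or in year order).
#' @param groups Named list of group definitions; each has `profile` (one of
#'   `"stable"`, `"emerging"`, `"declining"`, `"pulse"`), `n_tokens`,
#'   `intensity`, and optionally `onset`, `midpoint`, `centre`, `scale`.
#' @param keywords_per_article Integer range, default `c(3, 8)`.
#' @param synonym_rate Probability an emission uses the variant spelling
#'   (default 0.1).
#' @param rename Rename event: list with `year`, `old`, `new`, `group`
#'   (the concept's group), or `NULL` for none. Default renames
#'   `"easternmedicine"` to `"nationalmedicine"` in 2012.
#' @param decorate_rate Probability a raw keyword string is emitted with
#'   cosmetic casing/hyphenation that [normalize_keyword()] removes
#'   (default 0.3).
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(years = c(1963L, 2018L),
                          phase_article_totals = c(643L, 498L, 1889L,
                                                   5758L, 15921L, 5167L),
                          annual_articles = NULL,
                          groups = default_groups(),
                          keywords_per_article = c(3L, 8L),
                          synonym_rate = 0.1,
                          rename = list(year = 2012L,
                                        old = "easternmedicine",
                                        new = "nationalmedicine",
                                        group = "stable"),
                          decorate_rate = 0.3) {
  stopifnot(length(years) == 2L, years[1] <= years[2],
            length(groups) >= 1,
            keywords_per_article[1] >= 1,
            keywords_per_article[1] <= keywords_per_article[2],
            synonym_rate >= 0, synonym_rate < 1,
            decorate_rate >= 0, decorate_rate <= 1)
  yr_axis <- seq.int(years[1], years[2])
  if (is.null(annual_articles)) {
    annual_articles <- spread_phase_totals(phase_article_totals, yr_axis)
  } else {
    stopifnot(length(annual_articles) == length(yr_axis),
              all(annual_articles >= 0))
    annual_articles <- stats::setNames(as.integer(annual_articles),
                                       as.character(yr_axis))
  }
  if (!is.null(rename)) {
    stopifnot(all(c("year", "old", "new", "group") %in% names(rename)),
              rename$group %in% names(groups))
  }
  structure(list(
    years = as.integer(years),
    annual_articles = annual_articles,
    groups = groups,
    keywords_per_article = as.integer(keywords_per_article),
    synonym_rate = synonym_rate,
    rename = rename,
    decorate_rate = decorate_rate
  ), class = "corpus_config")
}

# default four planted groups, 10 tokens each, equal intensity
default_groups <- function() {
  list(
    stable = list(profile = "stable", n_tokens = 10L, intensity = 1),
    emerging = list(profile = "emerging", n_tokens = 10L, intensity = 1,
                    onset = 2010, scale = 1.5),
    declining = list(profile = "declining", n_tokens = 10L, intensity = 1,
                     midpoint = 1985, scale = 3),
    pulse = list(profile = "pulse", n_tokens = 10L, intensity = 1,
                 centre = 1996, scale = 3.5)
  )
}

# distribute each phase's article total uniformly over its years; the
# remainder r goes one-per-year to the last r years of the phase
spread_phase_totals <- function(totals, yr_axis) {
  y0 <- yr_axis[1]; y1 <- yr_axis[length(yr_axis)]
  edges <- default_phase_edges(y0, y1, length(totals))
  out <- integer(length(yr_axis))
  names(out) <- as.character(yr_axis)
  for (i in seq_along(totals)) {
    yrs <- as.character(seq.int(edges$start[i], edges$end[i]))
    len <- length(yrs)
    base <- totals[i] %/% len
    rem <- totals[i] %% len
    cnt <- rep(base, len)
    if (rem > 0) cnt[(len - rem + 1L):len] <- cnt[(len - rem + 1L):len] + 1L
    out[yrs] <- as.integer(cnt)
  }
  out
}

default_phase_edges <- function(y0, y1, k) {
  if (y0 == 1963L && y1 == 2018L && k == 6L) {
    return(oasis_phases())
  }
  # otherwise split the range into k near-equal contiguous phases
  cuts <- round(seq(y0, y1 + 1L, length.out = k + 1L))
  phase_set(start = cuts[-(k + 1L)], end = cuts[-1L] - 1L)
}

profile_value <- function(group, year) {
  switch(group$profile,
    stable = rep(1, length(year)),
    emerging = stats::plogis(year,
                             location = group$onset %||% 2010,
                             scale = group$scale %||% 1.5),
    declining = 1 - stats::plogis(year,
                                  location = group$midpoint %||% 1985,
                                  scale = group$scale %||% 3),
    pulse = exp(-((year - (group$centre %||% 1996))^2) /
                  (2 * (group$scale %||% 3.5)^2)),
    stop("unknown profile: ", group$profile, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic article corpus with ground truth
#'
#' Draws, for each year, the configured number of articles; each article
#' samples its keywords without replacement from the concept pool with
#' year-specific weights (group profile value x intensity, split between
#' canonical and variant spellings). Raw strings are emitted with cosmetic
#' casing/hyphen decoration at the configured rate, and the rename event
#' swaps the concept's emitted label after the event year. Fully
#' reproducible from `seed`; the global RNG state is left untouched.
#'
#' @param cfg A [corpus_config()].
#' @param seed Integer seed.
#' @return A list with elements `articles` (corpus data frame as from
#'   [read_corpus()]), `truth` (list: `groups` named character vector token
#'   → group label covering every canonical token incl. both rename labels,
#'   `profiles` matrix of expected per-year sampling weight per token,
#'   `rename` the rename record or `NULL`), and `synonyms` (a
#'   [synonym_map()] mapping every variant spelling to its canonical token).
#' @export
generate_corpus <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "corpus_config"))
  yr_axis <- seq.int(cfg$years[1], cfg$years[2])

  tokens <- character(0); tok_group <- character(0)
  for (gname in names(cfg$groups)) {
    g <- cfg$groups[[gname]]
    tk <- sprintf("%s%02d", gname, seq_len(g$n_tokens))
    tokens <- c(tokens, tk)
    tok_group <- c(tok_group, rep(gname, g$n_tokens))
  }
  rn <- cfg$rename
  if (!is.null(rn)) {
    tokens <- c(tokens, "renameconcept")
    tok_group <- c(tok_group, rn$group)
  }
  names(tok_group) <- tokens
  m <- length(tokens)

  # expected sampling weight per token per year (before renormalization)
  W <- sapply(names(cfg$groups), function(gname) {
    g <- cfg$groups[[gname]]
    g$intensity * profile_value(g, yr_axis)
  })
  weight <- matrix(0, nrow = m, ncol = length(yr_axis),
                   dimnames = list(tokens, as.character(yr_axis)))
  for (i in seq_len(m)) weight[i, ] <- W[, tok_group[i]]

  variants <- stats::setNames(paste0(tokens, "syn"), tokens)

  kmin <- cfg$keywords_per_article[1]
  kmax <- cfg$keywords_per_article[2]
  v <- cfg$synonym_rate

  art_year <- rep(yr_axis, cfg$annual_articles[as.character(yr_axis)])
  n_art <- length(art_year)
  kw_lists <- vector("list", n_art)

  withr::with_seed(seed, {
    sizes <- sample.int(kmax - kmin + 1L, n_art, replace = TRUE) +
      kmin - 1L
    pos <- 1L
    for (yi in seq_along(yr_axis)) {
      ny <- cfg$annual_articles[[yi]]
      if (ny == 0L) next
      wy <- weight[, yi]
      active <- which(wy > 0)
      # expanded pool: canonical + variant spelling per active concept
      pool_tok <- c(tokens[active], variants[tokens[active]])
      pool_concept <- c(tokens[active], tokens[active])
      pool_w <- c(wy[active] * (1 - v), wy[active] * v)
      keep <- pool_w > 0
      pool_tok <- pool_tok[keep]
      pool_concept <- pool_concept[keep]
      pool_w <- pool_w[keep]
      year <- yr_axis[yi]
      for (a in seq_len(ny)) {
        k <- sizes[pos]
        if (k > length(pool_tok)) {
          stop("infeasible draw in year ", year, ": ", k,
               " keywords requested but only ", length(pool_tok),
               " sampleable spellings", call. = FALSE)
        }
        idx <- sample.int(length(pool_tok), k, prob = pool_w)
        lab <- pool_tok[idx]
        # rename event: swap the concept's emitted label by era
        if (!is.null(rn)) {
          is_rc <- pool_concept[idx] == "renameconcept"
          if (any(is_rc)) {
            base <- if (year <= rn$year) rn$old else rn$new
            lab[is_rc] <- ifelse(endsWith(lab[is_rc], "syn"),
                                 paste0(base, "syn"), base)
          }
        }
        # cosmetic decoration removed by normalize_keyword
        dec <- stats::runif(k) < cfg$decorate_rate
        if (any(dec)) {
          lab[dec] <- vapply(lab[dec], decorate_token, character(1))
        }
        kw_lists[[pos]] <- unname(lab)
        pos <- pos + 1L
      }
    }
  })

  articles <- data.frame(
    id = sprintf("A%06d", seq_len(n_art)),
    year = art_year,
    stringsAsFactors = FALSE
  )
  articles$keywords <- kw_lists

  # ground truth over emitted canonical labels
  truth_groups <- tok_group
  syn_var <- unname(variants)
  syn_can <- names(variants)
  if (!is.null(rn)) {
    gr <- tok_group[["renameconcept"]]
    truth_groups <- truth_groups[names(truth_groups) != "renameconcept"]
    truth_groups[rn$old] <- gr
    truth_groups[rn$new] <- gr
    # variant spellings of both rename labels map to those labels
    keepv <- syn_can != "renameconcept"
    syn_var <- c(syn_var[keepv], paste0(rn$old, "syn"),
                 paste0(rn$new, "syn"))
    syn_can <- c(syn_can[keepv], rn$old, rn$new)
  }
  list(
    articles = articles,
    truth = list(groups = truth_groups, profiles = weight, rename = rn),
    synonyms = synonym_map(syn_var, syn_can)
  )
}

# uppercase the first letter and hyphenate the midpoint: removed again by
# normalize_keyword, so it only exercises the normalization path
decorate_token <- function(tok) {
  n <- nchar(tok)
  mid <- max(2L, n %/% 2L)
  paste0(toupper(substr(tok, 1L, 1L)), substr(tok, 2L, mid), "-",
         substr(tok, mid + 1L, n))
}

#' Adjusted Rand index between a ground-truth grouping and a clustering
#'
#' Chance-corrected agreement between two partitions of the same node set,
#' from the closed-form contingency-table formula. 1 for identical
#' partitions, about 0 for independent ones (the all-singletons vs
#' all-in-one comparison is exactly 0).
#'
#' @param truth Either the `truth` element of [generate_corpus()] output, or
#'   a named vector of group labels.
#' @param clustering A `clustering` (see [extract_clusters()]) or a named
#'   vector of cluster labels. Node universes must agree exactly.
#' @return The adjusted Rand index, in `[-1, 1]`.
#' @export
evaluate_recovery <- function(truth, clustering) {
  a <- if (is.list(truth) && !is.null(truth$groups)) truth$groups else truth
  b <- if (inherits(clustering, "clustering")) clustering$labels
       else clustering
  stopifnot(!is.null(names(a)), !is.null(names(b)))
  if (!setequal(names(a), names(b))) {
    stop("node universes differ between truth and clustering",
         call. = FALSE)
  }
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Test a phase table for a terminology-rename signature
#'
#' A rename shows up in phase-aggregated counts as an old label whose
#' final-phase count falls strictly below its peak while the new label's
#' counts never decrease across phases and rise strictly into the final
#' phase (the old label collapses, the replacement takes over).
#'
#' @param pt A [phase_aggregate()] result.
#' @param old,new Keyword tokens to test.
#' @return `TRUE` when the signature holds.
#' @export
rename_signature <- function(pt, old, new) {
  stopifnot(inherits(pt, "phase_table"),
            old %in% rownames(pt$counts), new %in% rownames(pt$counts))
  o <- pt$counts[old, ]
  u <- pt$counts[new, ]
  np <- length(o)
  old_collapses <- o[np] < max(o)
  new_rises <- all(diff(u) >= 0) && u[np] > u[np - 1L]
  unname(old_collapses && new_rises)
}
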