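one_token_cfg <- function() {
  corpus_config(
    years = c(2000L, 2001L),
    annual_articles = c(10L, 10L),
    groups = list(solo = list(profile = "stable", n_tokens = 1L,
                              intensity = 1)),
    keywords_per_article = c(1L, 1L),
    synonym_rate = 0, rename = NULL, decorate_rate = 0
  )
}

test_that("generate_corpus honours the configuration and the seed", {
  gen <- generate_corpus(one_token_cfg(), seed = 5)
  expect_equal(nrow(gen$articles), 20)
  expect_true(all(vapply(gen$articles$keywords, identical,
                         logical(1), "solo01")))

  # byte-identical under the same seed, different under another
  gen2 <- generate_corpus(one_token_cfg(), seed = 5)
  expect_identical(gen, gen2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_corpus(gen$articles, f1); write_corpus(gen2$articles, f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg_big <- corpus_config(years = c(2000L, 2001L),
                           annual_articles = c(30L, 30L))
  expect_false(identical(generate_corpus(cfg_big, seed = 1)$articles,
                         generate_corpus(cfg_big, seed = 2)$articles))

  # infeasible draw: more keywords requested than sampleable spellings
  cfg_bad <- one_token_cfg()
  cfg_bad$keywords_per_article <- c(3L, 3L)
  expect_error(generate_corpus(cfg_bad, seed = 1), "infeasible")
})

test_that("the rename event swaps the emitted label at the event year", {
  cfg <- corpus_config(
    years = c(2000L, 2009L), annual_articles = rep(40L, 10),
    rename = list(year = 2004L, old = "oldname", new = "newname",
                  group = "stable"),
    decorate_rate = 0, synonym_rate = 0
  )
  gen <- generate_corpus(cfg, seed = 3)
  m <- build_annual_matrix(gen$articles, gen$synonyms, min_freq = 1)
  expect_true(all(m$counts["oldname", as.character(2005:2009)] == 0))
  expect_true(all(m$counts["newname", as.character(2000:2004)] == 0))
  expect_gt(sum(m$counts["oldname", ]), 0)
  expect_gt(sum(m$counts["newname", ]), 0)
  # both labels carry the concept's group in the ground truth
  expect_equal(unname(gen$truth$groups[c("oldname", "newname")]),
               c("stable", "stable"))
})

test_that("generated frequencies converge to the configured profile", {
  # law-of-large-numbers check: at 5000 articles/year the empirical token
  # shares match the renormalized profile weights
  cfg <- corpus_config(years = c(2000L, 2001L),
                       annual_articles = c(5000L, 5000L),
                       synonym_rate = 0, rename = NULL,
                       decorate_rate = 0)
  gen <- generate_corpus(cfg, seed = 17)
  m <- build_annual_matrix(gen$articles, gen$synonyms, min_freq = 1)
  for (yr in c("2000", "2001")) {
    w <- gen$truth$profiles[rownames(m$counts), yr]
    expected <- w / sum(w)
    observed <- m$counts[, yr] / sum(m$counts[, yr])
    big <- expected > 0.001
    expect_equal(observed[big], expected[big], tolerance = 0.15)
  }
})

test_that("synonym variants are emitted and merge back to their concepts", {
  cfg <- corpus_config(years = c(2000L, 2001L),
                       annual_articles = c(400L, 400L),
                       synonym_rate = 0.3, rename = NULL)
  gen <- generate_corpus(cfg, seed = 8)
  raw_tokens <- normalize_keyword(unlist(gen$articles$keywords))
  expect_gt(sum(endsWith(raw_tokens, "syn")), 0)
  merged <- count_keywords(gen$articles, gen$synonyms)
  expect_false(any(endsWith(names(merged), "syn")))
  expect_true(all(names(merged) %in% names(gen$truth$groups)))
})

test_that("evaluate_recovery implements the adjusted Rand index", {
  u <- letters[1:6]
  same <- stats::setNames(c(1, 1, 1, 2, 2, 2), u)
  expect_equal(evaluate_recovery(same, same), 1)

  singletons <- stats::setNames(1:6, u)
  lumped <- stats::setNames(rep(1, 6), u)
  expect_equal(evaluate_recovery(singletons, lumped), 0)

  # hand-built contingency example: partitions {abc|def} vs {ab|cde|f}
  # has ARI (2 - 1.6) / (5 - 1.6) = 2/17
  other <- stats::setNames(c(1, 1, 2, 2, 2, 3), u)
  expect_equal(evaluate_recovery(same, other), 2 / 17)

  # independent cross-check against mclust's implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    withr::with_seed(77, {
      for (i in 1:20) {
        a <- stats::setNames(sample(1:4, 12, replace = TRUE), letters[1:12])
        b <- stats::setNames(sample(1:3, 12, replace = TRUE), letters[1:12])
        expect_equal(evaluate_recovery(a, b),
                     unname(mclust::adjustedRandIndex(a, b[names(a)])))
      }
    })
  }

  mismatched <- stats::setNames(1:5, letters[2:6])
  expect_error(evaluate_recovery(same, mismatched), "universe")
})

test_that("phase-aggregated rename counts show the handover signature", {
  gen <- generate_corpus(corpus_config(), seed = 11)
  m <- build_annual_matrix(gen$articles, gen$synonyms, min_freq = 10)
  pt <- phase_aggregate(m, oasis_phases())
  rn <- gen$truth$rename
  expect_true(rename_signature(pt, rn$old, rn$new))
  # the published handover pair satisfies the same signature
  ref <- oasis_phase_counts()
  refm <- as.matrix(ref$counts[, -1])
  rownames(refm) <- normalize_keyword(ref$counts$keyword)
  fake_pt <- structure(list(counts = refm,
                            article_totals = ref$article_totals,
                            phases = ref$phases),
                       class = "phase_table")
  expect_true(rename_signature(fake_pt, "orientalmedicine",
                               "koreanmedicine"))
})
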